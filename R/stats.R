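# Statistical observables: offset-from-median profiles, ERCC end
# accuracy, relative end positions, isoform event counts, exon
# connectivity, coding vs non-coding junction variability, sharing and
# major-isoform summaries.

#' Offsets from the median position
#'
#' For every context (e.g. a gene + exon structure, or a UMI group) with
#' at least two members, the deviation of each position from the context
#' median (lower-median convention, so for odd sizes one member has
#' offset exactly 0). Singleton contexts are excluded.
#'
#' @param positions Integer vector of genomic positions.
#' @param context Context identifier per position.
#' @param site Optional site label per position (recycled).
#' @return A data frame `context`, `site`, `position`, `offset`.
#' @export
offset_from_median <- function(positions, context, site = NA_character_) {
  stopifnot(length(positions) == length(context))
  df <- data.frame(context = as.character(context),
                   site = rep_len(site, length(positions)),
                   position = as.integer(positions),
                   stringsAsFactors = FALSE)
  parts <- lapply(split(seq_len(nrow(df)), paste(df$context, df$site)),
                  function(idx) {
    if (length(idx) < 2L) return(NULL)
    d <- df[idx, , drop = FALSE]
    d$offset <- d$position - lower_median(d$position)
    d
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(context = character(0), site = character(0),
                      position = integer(0), offset = integer(0))
  rownames(out) <- NULL
  out
}

# Site table of one transcript: 5' end, each junction start/end, 3' end,
# with strand-aware kinds ("junction_start" is the end of the upstream
# exon in transcript orientation).
transcript_sites <- function(blocks, strand) {
  blocks <- as_blocks(blocks)
  k <- nrow(blocks)
  sites <- data.frame(
    site = "end5", kind = "end5",
    position = end5_pos(blocks, strand), stringsAsFactors = FALSE)
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      jx <- if (strand == "+") j else k - j   # junction index, tx order
      e <- blocks[j, 2L]; s <- blocks[j + 1L, 1L]
      kinds <- if (strand == "+") c("junction_start", "junction_end")
               else c("junction_end", "junction_start")
      sites <- rbind(sites, data.frame(
        site = paste0("j", jx, c("_a", "_b")), kind = kinds,
        position = c(e, s), stringsAsFactors = FALSE))
    }
  }
  rbind(sites, data.frame(site = "end3", kind = "end3",
                          position = end3_pos(blocks, strand),
                          stringsAsFactors = FALSE))
}

#' Offset records for transcripts grouped by gene and exon structure
#'
#' Builds per-site offset-from-median records over multi-exon
#' transcripts sharing a gene and exon structure (structures with at
#' least two transcripts). Sites are the 5' position, each exon-exon
#' junction start and end, and the 3' position.
#'
#' @param transcripts Transcript table (non-ERCC rows are used).
#' @param models Endogenous `iso_models`.
#' @return Offset records: `gene_id`, `context`, `site`, `site_kind`,
#'   `position`, `offset`, `transcript_id`.
#' @export
transcript_offsets <- function(transcripts, models) {
  transcripts <- transcripts[!transcripts$is_ercc, , drop = FALSE]
  recs <- site_records(transcripts, models)
  offsets_by_context(recs)
}

site_records <- function(transcripts, models) {
  parts <- lapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i, ]
    b <- parse_blocks(t$blocks)
    if (nrow(b) < 2L) return(NULL)  # only multi-exon structures
    s <- transcript_sites(b, t$strand)
    struct <- exon_structure(b, model_exons(models, t$gene_id), t$strand)
    data.frame(gene_id = t$gene_id,
               context = paste(t$gene_id, struct, nrow(b), sep = "|"),
               site = s$site, site_kind = s$kind, position = s$position,
               transcript_id = t$transcript_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

offsets_by_context <- function(recs) {
  if (is.null(recs) || nrow(recs) == 0L)
    return(data.frame(gene_id = character(0), context = character(0),
                      site = character(0), site_kind = character(0),
                      position = integer(0), offset = integer(0),
                      transcript_id = character(0)))
  parts <- lapply(split(recs, paste(recs$context, recs$site)),
                  function(d) {
    if (length(unique(d$transcript_id)) < 2L) return(NULL)
    d$offset <- d$position - lower_median(d$position)
    d
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- recs[0, ]
  rownames(out) <- NULL
  out
}

#' Within-UMI offset records
#'
#' The same offset-from-median computation over the raw reads of each
#' UMI group before consensus (groups of two or more reads sharing the
#' block count); measures the technical variability between reads of
#' one molecule.
#'
#' @param aligned Gene-annotated aligned reads from [annotate_genes()].
#' @return Offset records with the UMI group as context.
#' @export
within_umi_offsets <- function(aligned) {
  aligned <- aligned[!is.na(aligned$gene_id), , drop = FALSE]
  key <- paste(aligned$barcode_id, aligned$gene_id, aligned$umi, sep = ":")
  parts <- lapply(split(seq_len(nrow(aligned)), key), function(idx) {
    if (length(idx) < 2L) return(NULL)
    g <- aligned[idx, , drop = FALSE]
    counts <- vapply(g$blocks, function(b) nrow(parse_blocks(b)),
                     integer(1))
    if (length(unique(counts)) > 1L) return(NULL)
    recs <- lapply(seq_len(nrow(g)), function(i) {
      s <- transcript_sites(parse_blocks(g$blocks[i]), g$strand[i])
      data.frame(gene_id = g$gene_id[i],
                 context = paste(g$barcode_id[i], g$gene_id[i], g$umi[i],
                                 sep = ":"),
                 site = s$site, site_kind = s$kind, position = s$position,
                 transcript_id = g$read_id[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  offsets_by_context(do.call(rbind, parts))
}

#' ERCC spike-in end accuracy
#'
#' Offsets of observed transcript 5'/3' ends from the exactly known
#' spike-in reference ends, and the fraction of ends within `within` bp.
#'
#' @param transcripts Transcript table (`is_ercc` rows are used).
#' @param ercc ERCC `iso_models`.
#' @param within Integer vector of bp windows to summarize (default
#'   `c(1, 5)`).
#' @return A list with `offsets` (`ercc_id`, `site`, `offset`) and
#'   `summary` (`site`, `within`, `fraction`).
#' @export
ercc_end_offsets <- function(transcripts, ercc, within = c(1L, 5L)) {
  tx <- transcripts[transcripts$is_ercc, , drop = FALSE]
  unknown <- setdiff(tx$gene_id, ercc$genes$gene_id)
  if (length(unknown)) stop("unknown ERCC id: ", unknown[1L])
  parts <- lapply(seq_len(nrow(tx)), function(i) {
    b <- parse_blocks(tx$blocks[i])
    ref <- model_row(ercc, tx$gene_id[i])
    data.frame(ercc_id = tx$gene_id[i], site = c("end5", "end3"),
               offset = c(b[1L, 1L] - ref$tss,
                          b[nrow(b), 2L] - ref$tts),
               stringsAsFactors = FALSE)
  })
  offsets <- do.call(rbind, parts)
  if (is.null(offsets))
    offsets <- data.frame(ercc_id = character(0), site = character(0),
                          offset = integer(0))
  summary <- do.call(rbind, lapply(c("end5", "end3"), function(side) {
    o <- offsets$offset[offsets$site == side]
    data.frame(site = side, within = within,
               fraction = vapply(within, function(k)
                 if (length(o)) mean(abs(o) <= k) else NA_real_,
                 numeric(1)))
  }))
  list(offsets = offsets, summary = summary)
}

#' Relative transcript end positions
#'
#' Positions of each transcript's 5' and 3' end relative to the
#' annotated gene span (0 = annotated TSS, 1 = annotated TTS,
#' strand-aware). Ends overhanging the annotation by at most `clamp_tol`
#' bp are clamped into `[0, 1]`; larger overhangs give `NA`. A 3' end
#' before `premature_frac` of the gene length marks a prematurely
#' terminated transcript.
#'
#' @param transcripts Transcript table (non-ERCC rows are used).
#' @param models Endogenous `iso_models`.
#' @param clamp_tol Clamp window in bp (default 5).
#' @param premature_frac Premature-termination threshold (default 0.15).
#' @return A list with `ends` (`transcript_id`, `gene_id`, `rel5`,
#'   `rel3`, `premature`) and `premature_fraction`.
#' @export
relative_end_positions <- function(transcripts, models, clamp_tol = 5L,
                                   premature_frac = 0.15) {
  tx <- transcripts[!transcripts$is_ercc, , drop = FALSE]
  rel_of <- function(pos, g, len) {
    r <- if (g$strand == "+") (pos - g$tss) / len else (g$tss - pos) / len
    if (r < 0 && r >= -clamp_tol / len) r <- 0
    if (r > 1 && r <= 1 + clamp_tol / len) r <- 1
    if (r < 0 || r > 1) NA_real_ else r
  }
  ends <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    t <- tx[i, ]
    g <- model_row(models, t$gene_id)
    len <- abs(g$tts - g$tss)
    if (len == 0L) stop("zero-length gene: ", t$gene_id)
    b <- parse_blocks(t$blocks)
    data.frame(transcript_id = t$transcript_id, gene_id = t$gene_id,
               rel5 = rel_of(end5_pos(b, t$strand), g, len),
               rel3 = rel_of(end3_pos(b, t$strand), g, len),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ends))
    ends <- data.frame(transcript_id = character(0),
                       gene_id = character(0), rel5 = numeric(0),
                       rel3 = numeric(0))
  ends$premature <- !is.na(ends$rel3) & ends$rel3 < premature_frac
  list(ends = ends,
       premature_fraction = if (nrow(ends)) mean(ends$premature) else
         NA_real_)
}

#' Count isoform-generating events
#'
#' Classifies isoform diversity per gene into four event types, each
#' counted beyond the first variant in its context:
#' \describe{
#'   \item{cassette}{number of distinct exon structures minus 1;}
#'   \item{tss}{per shared first exon, number of 5' end clusters minus 1;}
#'   \item{tts}{per shared last exon, number of 3' end clusters minus 1;}
#'   \item{position}{per (exon structure, junction site), number of
#'     junction-position clusters (single-linkage at `junction_tol` bp,
#'     pooled per gene) minus 1.}
#' }
#'
#' @param transcripts Transcript table (non-ERCC rows are used).
#' @param models Endogenous `iso_models`.
#' @param link_dist End-cluster link distance in bp (default 5).
#' @param junction_tol Position-event tolerance in bp (default 1).
#' @param by_cell Count per cell (`TRUE`) or pooled (`FALSE`).
#' @return A list with `counts` (`cell`, `gene_id`, `tss`, `tts`,
#'   `position`, `cassette`) and `mix` (percentage of total events per
#'   type).
#' @export
count_events <- function(transcripts, models, link_dist = 5L,
                         junction_tol = 1L, by_cell = FALSE) {
  tx <- transcripts[!transcripts$is_ercc, , drop = FALSE]
  groups <- if (by_cell) split(tx, tx$cell) else list(pooled = tx)
  counts <- do.call(rbind, lapply(names(groups), function(cell) {
    g <- groups[[cell]]
    do.call(rbind, lapply(split(g, g$gene_id), function(d) {
      ev <- count_events_gene(d, models, link_dist, junction_tol)
      cbind(data.frame(cell = cell, gene_id = d$gene_id[1L],
                       stringsAsFactors = FALSE), ev)
    }))
  }))
  rownames(counts) <- NULL
  total <- colSums(counts[, c("tss", "tts", "position", "cassette"),
                          drop = FALSE])
  mix <- if (sum(total) > 0) 100 * total / sum(total) else total * NA
  list(counts = counts, mix = mix)
}

count_events_gene <- function(tx, models, link_dist, junction_tol) {
  ends <- end_cluster_table(tx, models, link_dist)
  tss <- sum(vapply(split(ends$cluster_5p, ends$anchor5), function(cl)
    length(unique(cl)) - 1L, integer(1)))
  tts <- sum(vapply(split(ends$cluster_3p, ends$anchor3), function(cl)
    length(unique(cl)) - 1L, integer(1)))

  blocks <- lapply(tx$blocks, parse_blocks)
  structs <- vapply(seq_len(nrow(tx)), function(i)
    paste(exon_structure(blocks[[i]], model_exons(models, tx$gene_id[1L]),
                         tx$strand[i]),
          nrow(blocks[[i]]), sep = "|"), character(1))
  cassette <- length(unique(structs)) - 1L

  # junction-position clusters pooled over the gene
  chains <- lapply(blocks, junction_chain)
  all_vals <- unlist(chains)
  position <- 0L
  if (length(all_vals)) {
    u <- sort(unique(all_vals))
    cl_of <- setNames(single_linkage_1d(u, junction_tol), u)
    for (s in unique(structs)) {
      idx <- which(structs == s)
      if (length(idx) < 2L || length(chains[[idx[1L]]]) == 0L) next
      m <- vapply(chains[idx], function(v) cl_of[as.character(v)],
                  integer(length(chains[[idx[1L]]])))
      m <- matrix(m, ncol = length(idx))
      position <- position +
        sum(apply(m, 1L, function(r) length(unique(r)) - 1L))
    }
  }
  data.frame(tss = tss, tts = tts, position = position,
             cassette = cassette)
}

#' Exon co-inclusion test
#'
#' Two-sided Fisher's exact test of whether two cassette exons of a gene
#' are included/excluded together. Only transcripts whose aligned span
#' covers both exon loci are informative (absence is unobservable
#' otherwise); inclusion means any block overlaps the exon.
#'
#' @param transcripts Transcript table.
#' @param models Endogenous `iso_models`.
#' @param gene_id Gene to test.
#' @param exon_a,exon_b Transcript-orientation exon indices.
#' @return A list with the 2x2 `table` (inclusion of a x inclusion of
#'   b) and `p_value`.
#' @export
exon_connectivity_test <- function(transcripts, models, gene_id,
                                   exon_a, exon_b) {
  g <- model_row(models, gene_id)
  ex <- parse_blocks(g$exons)
  k <- nrow(ex)
  to_genomic <- function(i) if (g$strand == "+") i else k - i + 1L
  ea <- ex[to_genomic(exon_a), ]; eb <- ex[to_genomic(exon_b), ]
  tx <- transcripts[transcripts$gene_id == gene_id, , drop = FALSE]
  inc <- function(blocks, e)
    any(pmin(blocks[, 2L], e[2L]) - pmax(blocks[, 1L], e[1L]) > 0L)
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(a = c("in", "out"), b = c("in", "out")))
  for (i in seq_len(nrow(tx))) {
    b <- parse_blocks(tx$blocks[i])
    span <- c(b[1L, 1L], b[nrow(b), 2L])
    covers <- span[1L] <= min(ea[1L], eb[1L]) &&
      span[2L] >= max(ea[2L], eb[2L])
    if (!covers) next
    ia <- if (inc(b, ea)) 1L else 2L
    ib <- if (inc(b, eb)) 1L else 2L
    tab[ia, ib] <- tab[ia, ib] + 1L
  }
  list(table = tab, p_value = fisher_p(tab))
}

# Two-sided Fisher exact p for a 2x2 table; degenerate tables give 1.
fisher_p <- function(tab) {
  if (sum(tab) == 0L || min(rowSums(tab)) == 0L || min(colSums(tab)) == 0L)
    return(1)
  fisher.test(tab)$p.value
}

#' Label sites as coding or non-coding
#'
#' A site is coding when its genomic position lies within a coding
#' (CCDS-style) interval of its gene (interval ends inclusive, so exon
#' boundaries flush with the CDS count as coding). Genes without CDS
#' annotation give non-coding everywhere.
#'
#' @param offsets Offset records with `gene_id` and `position` columns.
#' @param models `iso_models` carrying `cds` intervals.
#' @param drop_coding_ends Exclude transcript 5'/3' end sites labelled
#'   coding (a full-length mRNA should not end inside the CDS; such
#'   ends are presumed artifacts).
#' @return `offsets` with a logical `coding` column (rows possibly
#'   dropped when `drop_coding_ends`).
#' @export
label_coding <- function(offsets, models, drop_coding_ends = TRUE) {
  coding <- vapply(seq_len(nrow(offsets)), function(i) {
    cds <- model_cds(models, offsets$gene_id[i])
    if (is.null(cds)) return(FALSE)
    any(cds[, 1L] <= offsets$position[i] &
          offsets$position[i] <= cds[, 2L])
  }, logical(1))
  offsets$coding <- coding
  if (drop_coding_ends && nrow(offsets)) {
    is_end <- offsets$site_kind %in% c("end5", "end3")
    offsets <- offsets[!(is_end & coding), , drop = FALSE]
  }
  rownames(offsets) <- NULL
  offsets
}

#' Compare coding and non-coding junction variability
#'
#' Two-sided Wilcoxon test of absolute offsets at coding versus
#' non-coding junction sites, reported separately for junction starts
#' and ends. By default the rank-sum (unpaired) form is used, since the
#' two site classes are independent site sets; `paired = TRUE` uses the
#' signed-rank form on per-gene mean absolute offsets (genes with both
#' classes observed).
#'
#' @param offsets Labelled offset records from [label_coding()].
#' @param paired Use the matched per-gene signed-rank form.
#' @return A data frame: `site_kind`, `method`, `p_value`, `n_coding`,
#'   `n_noncoding`.
#' @export
coding_vs_noncoding_test <- function(offsets, paired = FALSE) {
  do.call(rbind, lapply(c("junction_start", "junction_end"),
                        function(kind) {
    d <- offsets[offsets$site_kind == kind, , drop = FALSE]
    x <- abs(d$offset[d$coding])
    y <- abs(d$offset[!d$coding])
    if (paired) {
      per_gene <- lapply(split(d, d$gene_id), function(dd) {
        if (!any(dd$coding) || !any(!dd$coding)) return(NULL)
        c(coding = mean(abs(dd$offset[dd$coding])),
          noncoding = mean(abs(dd$offset[!dd$coding])))
      })
      per_gene <- do.call(rbind, per_gene)
      diffs <- per_gene[, "coding"] - per_gene[, "noncoding"]
      p <- if (is.null(per_gene) || nrow(per_gene) == 0L ||
               all(diffs == 0)) 1
           else wilcox.test(per_gene[, "coding"], per_gene[, "noncoding"],
                            paired = TRUE)$p.value
      data.frame(site_kind = kind, method = "signed-rank", p_value = p,
                 n_coding = if (is.null(per_gene)) 0L else nrow(per_gene),
                 n_noncoding = if (is.null(per_gene)) 0L else
                   nrow(per_gene), stringsAsFactors = FALSE)
    } else {
      p <- if (length(x) == 0L || length(y) == 0L ||
               (all(x == x[1L]) && all(y == y[1L]) && x[1L] == y[1L])) 1
           else wilcox.test(x, y)$p.value
      data.frame(site_kind = kind, method = "rank-sum", p_value = p,
                 n_coding = length(x), n_noncoding = length(y),
                 stringsAsFactors = FALSE)
    }
  }))
}

#' Isoform sharing between cell types
#'
#' Restricts to genes represented by at least one transcript in every
#' cell type, then counts every Venn region of isoform presence across
#' cell types, the fraction of isoforms shared by any two cell types,
#' and the fraction shared by all. Isoforms must come from one pooled
#' isoform call so that keys are comparable; a member transcript's cell
#' is read from its `cell:gene:umi` id.
#'
#' @param isoforms Isoform table built on pooled transcripts.
#' @param celltype_of Optional named vector mapping cell to cell type
#'   (default: each cell is its own type).
#' @return A list: `venn` (`region`, `count`), `any_two_fraction`,
#'   `all_fraction`, `expression` (`key`, `n_celltypes`,
#'   `n_transcripts`, `shared`).
#' @export
isoform_sharing <- function(isoforms, celltype_of = NULL) {
  members <- isoform_membership(isoforms)
  members$cell <- sub(":.*$", "", members$transcript_id)
  members$celltype <- if (is.null(celltype_of)) members$cell else
    unname(celltype_of[members$cell])
  types <- sort(unique(members$celltype))
  if (length(types) < 2L) stop("need at least 2 cell types")

  members$gene_id <- isoforms$gene_id[match(members$key, isoforms$key)]
  gene_types <- lapply(split(members$celltype, members$gene_id), unique)
  complete <- names(gene_types)[vapply(gene_types, function(tt)
    all(types %in% tt), logical(1))]
  m <- members[members$gene_id %in% complete, , drop = FALSE]
  if (nrow(m) == 0L)
    return(list(venn = data.frame(region = character(0),
                                  count = integer(0)),
                any_two_fraction = NA_real_, all_fraction = NA_real_,
                expression = NULL))

  key_types <- lapply(split(m$celltype, m$key), unique)
  region <- vapply(key_types, function(tt)
    paste(sort(tt), collapse = "&"), character(1))
  venn <- as.data.frame(table(region), stringsAsFactors = FALSE)
  names(venn) <- c("region", "count")
  n_types <- vapply(key_types, length, integer(1))
  expression <- data.frame(
    key = names(key_types), n_celltypes = n_types,
    n_transcripts = isoforms$n_transcripts[match(names(key_types),
                                                 isoforms$key)],
    shared = n_types >= 2L, stringsAsFactors = FALSE)
  list(venn = venn,
       any_two_fraction = mean(n_types >= 2L),
       all_fraction = mean(n_types == length(types)),
       expression = expression)
}

#' Major isoform fraction per gene
#'
#' For genes with more than `min_transcripts` transcripts, the fraction
#' of the gene's transcripts carried by its most expressed isoform.
#'
#' @param isoforms An isoform table (one level).
#' @param min_transcripts Genes with at most this many transcripts are
#'   excluded (default 10).
#' @return A list with `per_gene` (`gene_id`, `n_isoforms`,
#'   `n_transcripts`, `major_fraction`) and `mean_fraction`.
#' @export
major_isoform_fraction <- function(isoforms, min_transcripts = 10L) {
  per_gene <- do.call(rbind, lapply(split(isoforms, isoforms$gene_id),
                                    function(iso) {
    total <- sum(iso$n_transcripts)
    if (total <= min_transcripts) return(NULL)
    data.frame(gene_id = iso$gene_id[1L], n_isoforms = nrow(iso),
               n_transcripts = total,
               major_fraction = max(iso$n_transcripts) / total,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_gene))
    per_gene <- data.frame(gene_id = character(0), n_isoforms = integer(0),
                           n_transcripts = integer(0),
                           major_fraction = numeric(0))
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       mean_fraction = if (nrow(per_gene)) mean(per_gene$major_fraction)
         else NA_real_)
}

#' Variable-width offset histogram
#'
#' Bins signed offsets into the standard variable-width layout used for
#' offset plots: 0, +/-1, +/-2-5, +/-6-10, +/-11-100, beyond +/-100.
#'
#' @param offsets Integer vector of signed offsets.
#' @return A data frame `bin`, `count`, with bins ordered from most
#'   negative to most positive.
#' @export
bin_offsets <- function(offsets) {
  edges <- c(-Inf, -100.5, -10.5, -5.5, -1.5, -0.5, 0.5, 1.5, 5.5, 10.5,
             100.5, Inf)
  labels <- c("<-100", "-100..-11", "-10..-6", "-5..-2", "-1", "0", "+1",
              "+2..+5", "+6..+10", "+11..+100", ">+100")
  cuts <- cut(offsets, breaks = edges, labels = labels)
  data.frame(bin = labels, count = as.integer(table(cuts)[labels]))
}
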
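#' Generate synthetic gene models
#'
#' Lays out `n_genes` non-overlapping multi-exon gene models on one
#' simulated chromosome, with random exon/intron sizes drawn from the
#' configured ranges and a random genomic sequence. One reference
#' structure is kept per gene (the structure with all exons), mirroring
#' the use of a single annotated isoform per gene as the coordinate
#' frame. The CDS of each gene excludes `utr_margin` exonic bp at both
#' transcript ends, so coding and non-coding junction classes both occur.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `iso_models`: a list with `genes` (one row
#'   per gene: `gene_id`, `chrom`, `strand`, `n_exons`, `tss`, `tts`,
#'   serialized `exons` and `cds`) and `seqs` (named chromosome
#'   sequences).
#' @seealso [write_gene_annotation()] to export GTF and coding BED.
#' @export
generate_gene_models <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  min_exonic <- cfg$exon_count_range[1] * cfg$exon_len_range[1]
  if (min_exonic <= 2L * cfg$utr_margin + 2L)
    stop("exon length distribution cannot accommodate the UTR margins")

  genes <- vector("list", cfg$n_genes)
  pos <- cfg$gene_spacing
  for (i in seq_len(cfg$n_genes)) {
    n_ex <- sample_range(cfg$exon_count_range, 1L)
    lens <- sample_range(cfg$exon_len_range, n_ex)
    introns <- sample_range(cfg$intron_len_range, max(n_ex - 1L, 0L))
    starts <- pos + cumsum(c(0L, lens[-n_ex] + introns))
    ends <- starts + lens
    strand <- sample(c("+", "-"), 1L)
    exons <- cbind(start = starts, end = ends)
    cds <- cds_from_exons(exons, cfg$utr_margin)
    genes[[i]] <- data.frame(
      gene_id = sprintf("gene%03d", i), chrom = "chrS", strand = strand,
      n_exons = n_ex,
      tss = if (strand == "+") starts[1L] else ends[n_ex],
      tts = if (strand == "+") ends[n_ex] else starts[1L],
      exons = format_blocks(exons), cds = format_blocks(cds),
      is_ercc = FALSE, stringsAsFactors = FALSE
    )
    pos <- ends[n_ex] + cfg$gene_spacing
  }
  genes <- do.call(rbind, genes)
  seqs <- c(chrS = rand_dna(pos))
  structure(list(genes = genes, seqs = seqs), class = "iso_models")
}

# CDS = exonic span minus `margin` exonic bp at each end, as genomic
# intervals. Margins are taken in exonic (spliced) coordinates so the CDS
# is always contained in the union of exons.
cds_from_exons <- function(exons, margin) {
  exons <- as_blocks(exons)
  widths <- exons[, 2L] - exons[, 1L]
  total <- sum(widths)
  stopifnot(total > 2L * margin)
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  lo <- margin            # first exonic position inside the CDS
  hi <- total - margin    # one past the last
  out <- NULL
  for (j in seq_len(nrow(exons))) {
    a <- max(lo - offsets[j], 0L)
    b <- min(hi - offsets[j], widths[j])
    if (b > a) out <- rbind(out, c(exons[j, 1L] + a, exons[j, 1L] + b))
  }
  as_blocks(out)
}

sample_range <- function(range, n) {
  if (range[1] == range[2]) rep.int(range[1], n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Generate an ERCC-style spike-in reference set
#'
#' Creates `n` single-exon models of exactly known 5' and 3' ends, one
#' per reference sequence, with lengths uniform in
#' `[len_min, len_max]` (defaults matching the 255-2007 bp range of the
#' 92 commercial ERCC in vitro transcribed RNAs).
#'
#' @param n Number of spike-in species.
#' @param len_min,len_max Length range in bp.
#' @param seed Integer seed.
#' @return An `iso_models` object (ids `ERCC-00001` ...), plus a `tsv`
#'   attribute-free `genes` table with one row per spike-in.
#' @export
generate_ercc_set <- function(n = 92L, len_min = 255L, len_max = 2007L,
                              seed = 1L) {
  if (n <= 0L) stop("n must be positive")
  stopifnot(len_min <= len_max, len_min >= 50L)
  set.seed(seed)
  ids <- sprintf("ERCC-%05d", seq_len(n))
  lens <- sample_range(c(len_min, len_max), n)
  genes <- data.frame(
    gene_id = ids, chrom = ids, strand = "+", n_exons = 1L,
    tss = 0L, tts = lens,
    exons = paste0("0-", lens), cds = NA_character_,
    is_ercc = TRUE, stringsAsFactors = FALSE
  )
  seqs <- setNames(rand_dna_vec(lens, n), ids)
  structure(list(genes = genes, seqs = seqs), class = "iso_models")
}

#' Combine gene model sets
#'
#' @param ... `iso_models` objects (e.g. endogenous genes and ERCC).
#' @return A single `iso_models` object.
#' @export
combine_models <- function(...) {
  xs <- list(...)
  stopifnot(all(vapply(xs, inherits, logical(1), "iso_models")))
  structure(list(
    genes = do.call(rbind, lapply(xs, `[[`, "genes")),
    seqs = do.call(c, lapply(xs, `[[`, "seqs"))
  ), class = "iso_models")
}

model_row <- function(models, gene_id) {
  i <- match(gene_id, models$genes$gene_id)
  if (is.na(i)) stop("unknown gene id: ", gene_id)
  models$genes[i, ]
}

model_exons <- function(models, gene_id) {
  parse_blocks(model_row(models, gene_id)$exons)
}

model_cds <- function(models, gene_id) {
  cds <- model_row(models, gene_id)$cds
  if (is.na(cds)) NULL else parse_blocks(cds)
}

# Annotated first/last exon in transcript orientation.
model_first_exon <- function(models, gene_id) {
  g <- model_row(models, gene_id)
  ex <- parse_blocks(g$exons)
  if (g$strand == "+") ex[1L, , drop = TRUE] else ex[nrow(ex), , drop = TRUE]
}

model_last_exon <- function(models, gene_id) {
  g <- model_row(models, gene_id)
  ex <- parse_blocks(g$exons)
  if (g$strand == "+") ex[nrow(ex), , drop = TRUE] else ex[1L, , drop = TRUE]
}

#' Validate gene model invariants
#'
#' Checks that exons are sorted, disjoint and non-empty, that the CDS is
#' contained in the union of exons, and that the annotated TSS/TTS are
#' the transcript-orientation extremes of the first/last exon.
#'
#' @param models An `iso_models` object.
#' @return `TRUE` invisibly; otherwise an error naming the failing gene.
#' @export
validate_models <- function(models) {
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    ex <- parse_blocks(g$exons)
    tryCatch(validate_blocks(ex), error = function(e)
      stop(g$gene_id, ": ", conditionMessage(e)))
    expected_tss <- if (g$strand == "+") ex[1L, 1L] else ex[nrow(ex), 2L]
    expected_tts <- if (g$strand == "+") ex[nrow(ex), 2L] else ex[1L, 1L]
    if (g$tss != expected_tss || g$tts != expected_tts)
      stop(g$gene_id, ": annotated TSS/TTS do not match exon extremes")
    if (!is.na(g$cds)) {
      cds <- parse_blocks(g$cds)
      validate_blocks(cds)
      for (j in seq_len(nrow(cds))) {
        inside <- any(ex[, 1L] <= cds[j, 1L] & cds[j, 2L] <= ex[, 2L])
        if (!inside) stop(g$gene_id, ": CDS interval outside exons")
      }
    }
  }
  invisible(TRUE)
}
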
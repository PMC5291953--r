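# Transcript assembly: alignment ingestion, block gap-merging, gene
# annotation, and UMI consensus.

#' Load spliced alignments and join them to valid reads
#'
#' Reads a BED12 of spliced alignments (one record per read, blocks =
#' exons), drops read ids with more than one alignment record
#' (non-unique alignments), fuses blocks separated by small gaps, and
#' joins the result to the extraction output by read id.
#'
#' @param bed BED12 path or a data frame from [read_bed12()].
#' @param valid_reads `valid_reads` table from [extract_reads()].
#' @param gap_lt Gaps strictly below this many bp are fused (default 40).
#' @return A data frame of aligned reads: extraction columns plus
#'   `chrom`, `strand` and serialized `blocks`.
#' @export
load_alignments <- function(bed, valid_reads, gap_lt = 40L) {
  aln <- if (is.character(bed)) read_bed12(bed) else bed
  multi <- unique(aln$name[duplicated(aln$name)])
  aln <- aln[!aln$name %in% multi, , drop = FALSE]
  aln <- aln[aln$name %in% valid_reads$read_id, , drop = FALSE]
  aln$blocks <- vapply(aln$blocks, function(b)
    format_blocks(merge_close_blocks(parse_blocks(b), gap_lt)),
    character(1))
  i <- match(aln$name, valid_reads$read_id)
  out <- cbind(valid_reads[i, , drop = FALSE],
               aln[, c("chrom", "strand", "blocks")])
  rownames(out) <- NULL
  out
}

#' Fuse alignment blocks separated by small gaps
#'
#' Consecutive blocks whose inter-block gap is strictly less than
#' `gap_lt` bp are fused into one spanning block (iterated to fixpoint),
#' removing the small spurious gaps spliced aligners introduce.
#'
#' @param blocks Block matrix (or serialized string), sorted, disjoint.
#' @param gap_lt Gap threshold in bp; a gap of `gap_lt - 1` merges, a
#'   gap of `gap_lt` does not.
#' @return A block matrix.
#' @export
merge_close_blocks <- function(blocks, gap_lt = 40L) {
  if (is.character(blocks)) blocks <- parse_blocks(blocks)
  blocks <- as_blocks(blocks)
  if (nrow(blocks) < 2L) return(blocks)
  out <- blocks[1L, , drop = FALSE]
  for (j in 2:nrow(blocks)) {
    gap <- blocks[j, 1L] - out[nrow(out), 2L]
    if (gap < gap_lt) out[nrow(out), 2L] <- blocks[j, 2L]
    else out <- rbind(out, blocks[j, , drop = FALSE])
  }
  as_blocks(out)
}

#' Annotate aligned reads with genes
#'
#' Assigns each read to the unique gene whose annotated span (same
#' chromosome and strand) contains the majority of its aligned bases.
#' Reads overlapping zero or two or more gene spans are left unassigned
#' and excluded downstream. Reads aligned to an ERCC reference sequence
#' are assigned to that spike-in and flagged.
#'
#' @param aligned Data frame from [load_alignments()].
#' @param models Endogenous `iso_models`.
#' @param ercc Optional ERCC `iso_models`.
#' @return `aligned` with `gene_id` (`NA` when unassigned) and `is_ercc`
#'   columns added.
#' @export
annotate_genes <- function(aligned, models, ercc = NULL) {
  genes <- models$genes[!models$genes$is_ercc, , drop = FALSE]
  spans <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    start = vapply(genes$exons, function(x) parse_blocks(x)[1L, 1L],
                   integer(1)),
    end = vapply(genes$exons, function(x) {
      b <- parse_blocks(x); b[nrow(b), 2L]
    }, integer(1)), stringsAsFactors = FALSE
  )
  span_gr <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end),
    strand = spans$strand)
  ercc_ids <- if (is.null(ercc)) character(0) else ercc$genes$gene_id

  n <- nrow(aligned)
  gene_id <- rep(NA_character_, n)
  is_ercc <- aligned$chrom %in% ercc_ids
  gene_id[is_ercc] <- aligned$chrom[is_ercc]

  todo <- which(!is_ercc)
  if (length(todo)) {
    bl <- lapply(aligned$blocks[todo], parse_blocks)
    read_gr <- GenomicRanges::GRanges(
      aligned$chrom[todo],
      IRanges::IRanges(
        vapply(bl, function(b) b[1L, 1L] + 1L, integer(1)),
        vapply(bl, function(b) b[nrow(b), 2L], integer(1))),
      strand = aligned$strand[todo])
    ov <- GenomicRanges::findOverlaps(read_gr, span_gr)
    by_read <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    for (q in names(by_read)) {
      hits <- by_read[[q]]
      if (length(hits) != 1L) next
      qi <- as.integer(q)
      b <- bl[[qi]]
      inside <- sum(pmax(0L, pmin(b[, 2L], spans$end[hits]) -
                           pmax(b[, 1L], spans$start[hits])))
      if (inside > sum(b[, 2L] - b[, 1L]) / 2)
        gene_id[todo[qi]] <- spans$gene_id[hits]
    }
  }
  aligned$gene_id <- gene_id
  aligned$is_ercc <- is_ercc
  aligned
}

#' Collapse one UMI group into a consensus read
#'
#' Reads sharing a (cell, gene, UMI) key originate from one cDNA
#' molecule. Identical block lists deduplicate to one. Reads that differ
#' only in their extreme 5' position and share the same first 8 template
#' bases after the UMI take the most 5' position (the discrepancy is
#' then alignment-induced). Otherwise the per-coordinate median (lower
#' median for even group sizes) is used; groups with discordant exon
#' counts first vote on the structure (majority, ties broken towards
#' more exons) and the median is taken over the winning reads.
#'
#' @param blocks_list List of block matrices (or serialized strings).
#' @param strand Strand of the gene (`+` or `-`).
#' @param templates Optional character vector of template sequences,
#'   used for the first-8-bases rule.
#' @return A consensus block matrix.
#' @export
merge_umi_group <- function(blocks_list, strand, templates = NULL) {
  if (length(blocks_list) == 0L) stop("empty UMI group")
  bl <- lapply(blocks_list, function(b)
    if (is.character(b)) parse_blocks(b) else as_blocks(b))
  if (length(bl) == 1L) return(bl[[1L]])
  keys <- vapply(bl, format_blocks, character(1))
  if (length(unique(keys)) == 1L) return(bl[[1L]])

  counts <- vapply(bl, nrow, integer(1))
  if (length(unique(counts)) > 1L) {
    tab <- table(counts)
    winners <- as.integer(names(tab)[tab == max(tab)])
    win <- max(winners)                       # tie: more exons
    bl <- bl[counts == win]
    if (!is.null(templates)) templates <- templates[counts == win]
    keys <- vapply(bl, format_blocks, character(1))
    if (length(unique(keys)) == 1L) return(bl[[1L]])
  }

  mat5 <- vapply(bl, end5_pos, integer(1), strand = strand)
  rest <- vapply(bl, function(b) {
    paste(c(junction_chain(b), end3_pos(b, strand)), collapse = ",")
  }, character(1))
  only_5p_differs <- length(unique(rest)) == 1L && length(unique(mat5)) > 1L
  if (only_5p_differs && !is.null(templates) &&
      length(unique(substr(templates, 1L, 8L))) == 1L) {
    pick <- if (strand == "+") which.min(mat5) else which.max(mat5)
    return(bl[[pick]])
  }

  # per-coordinate lower median over the (structure-concordant) group
  coords <- vapply(bl, function(b) as.integer(t(b)), integer(2L * nrow(bl[[1L]])))
  cons <- apply(matrix(coords, ncol = length(bl)), 1L, lower_median)
  as_blocks(matrix(as.integer(cons), ncol = 2L, byrow = TRUE))
}

#' Build UMI consensus transcripts
#'
#' Groups gene-assigned reads by (cell barcode, gene, UMI) and collapses
#' each group with [merge_umi_group()]. The gene is part of the grouping
#' key to guard against 6-mer UMI collisions between genes. Transcripts
#' aligned to the excluded spike-in (default `ERCC-00074`, whose
#' reference has inconsistent 3' ends) are removed.
#'
#' @param aligned Data frame from [annotate_genes()].
#' @param exclude Gene/spike-in ids excluded from all analyses.
#' @return A data frame of transcripts: `transcript_id`
#'   (`cell:gene:umi`), `cell`, `gene_id`, `umi`, `chrom`, `strand`,
#'   serialized consensus `blocks`, `read_support`, `has_polya`,
#'   `is_ercc`.
#' @export
build_transcripts <- function(aligned, exclude = "ERCC-00074") {
  aligned <- aligned[!is.na(aligned$gene_id), , drop = FALSE]
  aligned <- aligned[!aligned$gene_id %in% exclude, , drop = FALSE]
  if (nrow(aligned) == 0L)
    return(data.frame(
      transcript_id = character(0), cell = character(0),
      gene_id = character(0), umi = character(0), chrom = character(0),
      strand = character(0), blocks = character(0),
      read_support = integer(0), has_polya = logical(0),
      is_ercc = logical(0)))
  key <- paste(aligned$barcode_id, aligned$gene_id, aligned$umi, sep = ":")
  groups <- split(seq_len(nrow(aligned)), key)
  out <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    g <- aligned[idx, , drop = FALSE]
    cons <- merge_umi_group(g$blocks, g$strand[1L], g$template_seq)
    data.frame(
      transcript_id = k, cell = g$barcode_id[1L], gene_id = g$gene_id[1L],
      umi = g$umi[1L], chrom = g$chrom[1L], strand = g$strand[1L],
      blocks = format_blocks(cons), read_support = length(idx),
      has_polya = any(g$has_polya), is_ercc = g$is_ercc[1L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$transcript_id), ]
  rownames(out) <- NULL
  out
}

#' Restrict to full-length transcripts
#'
#' Keeps transcripts that carry a poly-A tail and include the annotated
#' first exon: the 5'-most block must overlap the first exon and start
#' within its bounds (a small upstream overhang of at most `tol` bp is
#' tolerated, matching the end placement uncertainty). Transcripts whose
#' 5' end lies in a downstream exon — degradation products or incomplete
#' reverse transcription — are removed. ERCC transcripts are kept (their
#' reference is single-exon full length by construction).
#'
#' @param transcripts Data frame from [build_transcripts()].
#' @param models Endogenous `iso_models`.
#' @param tol Tolerated upstream overhang in bp (default 5).
#' @return The retained subset of `transcripts` with an added
#'   `covers_first_exon` column.
#' @export
filter_full_length <- function(transcripts, models, tol = 5L) {
  covers <- vapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i, ]
    if (t$is_ercc) return(TRUE)
    fe <- model_first_exon(models, t$gene_id)
    b <- parse_blocks(t$blocks)
    if (t$strand == "+") {
      first <- b[1L, ]
      first[2L] > fe[1L] && first[1L] < fe[2L] &&   # overlaps first exon
        first[1L] >= fe[1L] - tol                   # starts within bounds
    } else {
      first <- b[nrow(b), ]
      first[1L] < fe[2L] && first[2L] > fe[1L] &&
        first[2L] <= fe[2L] + tol
    }
  }, logical(1))
  out <- transcripts[covers & transcripts$has_polya, , drop = FALSE]
  out$covers_first_exon <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
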
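# Exon blocks are handled as two-column integer matrices (start, end) in
# 0-based half-open genomic coordinates, serialized as "s1-e1,s2-e2,..."
# strings when used as grouping keys.

#' Serialize and parse exon block lists
#'
#' Blocks are 0-based half-open `[start, end)` intervals, sorted and
#' pairwise disjoint. The string form `"s1-e1,s2-e2"` is used as a
#' canonical grouping key throughout the pipeline.
#'
#' @param blocks Integer matrix with columns `start`, `end`.
#' @param x A serialized block string.
#' @return `format_blocks()` a string; `parse_blocks()` an integer matrix.
#' @export
format_blocks <- function(blocks) {
  blocks <- as_blocks(blocks)
  paste(paste0(blocks[, 1L], "-", blocks[, 2L]), collapse = ",")
}

#' @rdname format_blocks
#' @export
parse_blocks <- function(x) {
  stopifnot(length(x) == 1L, nzchar(x))
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

as_blocks <- function(blocks) {
  if (is.null(dim(blocks))) blocks <- matrix(as.integer(blocks), ncol = 2L)
  storage.mode(blocks) <- "integer"
  colnames(blocks) <- c("start", "end")
  blocks
}

#' Validate an exon block matrix
#'
#' Checks the block invariants: sorted by coordinate, pairwise disjoint,
#' each of length >= 1.
#'
#' @param blocks Integer matrix of `[start, end)` intervals.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_blocks <- function(blocks) {
  blocks <- as_blocks(blocks)
  if (any(blocks[, 2L] <= blocks[, 1L]))
    stop("blocks must have length >= 1")
  if (nrow(blocks) > 1L) {
    if (is.unsorted(blocks[, 1L], strictly = TRUE))
      stop("blocks must be sorted by start")
    if (any(blocks[-1L, 1L] < blocks[-nrow(blocks), 2L]))
      stop("blocks must be pairwise disjoint")
  }
  invisible(TRUE)
}

# Lower median: for even n, the lower of the two central values. Keeps
# consensus coordinates integral and deterministic.
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

# Single-linkage clustering of integer positions on a line: connected
# components of the graph with an edge wherever |a - b| <= link_dist.
# Returns an integer cluster id per input position (ids ordered by
# coordinate), independent of input order.
single_linkage_1d <- function(positions, link_dist) {
  if (length(positions) == 0L) return(integer(0))
  u <- sort(unique(positions))
  breaks <- c(0L, cumsum(diff(u) > link_dist))
  ids <- breaks + 1L
  ids[match(positions, u)]
}

# Fast reverse complement for plain ACGTN character vectors.
revcomp <- function(x) {
  vapply(x, function(s)
    chartr("ACGTN", "TGCAN", intToUtf8(rev(utf8ToInt(s)))),
    character(1), USE.NAMES = FALSE)
}

# Hamming distance between a pattern and equal-length windows.
hamming_mm <- function(pattern, windows) {
  p <- charToRaw(pattern)
  vapply(windows, function(w) sum(charToRaw(w) != p), integer(1),
         USE.NAMES = FALSE)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_dna_vec <- function(len, n) {
  vapply(rep.int(len, n), rand_dna, character(1))
}

# Strand-aware 5'/3' end positions of a block matrix.
end5_pos <- function(blocks, strand) {
  blocks <- as_blocks(blocks)
  if (strand == "+") blocks[1L, 1L] else blocks[nrow(blocks), 2L]
}

end3_pos <- function(blocks, strand) {
  blocks <- as_blocks(blocks)
  if (strand == "+") blocks[nrow(blocks), 2L] else blocks[1L, 1L]
}

# Junction chain: all internal coordinates (end of exon i, start of exon
# i+1) in genomic order; empty for single-block transcripts.
junction_chain <- function(blocks) {
  blocks <- as_blocks(blocks)
  k <- nrow(blocks)
  if (k < 2L) return(integer(0))
  as.integer(rbind(blocks[-k, 2L], blocks[-1L, 1L]))
}
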
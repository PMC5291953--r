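# Isoform definition at three strictness levels: full (end clusters +
# exact junction chain), conservative (full-length transcripts, 1 bp
# junction tolerance), cassette (annotated exon membership only).

#' Single-linkage clustering of transcript end positions
#'
#' Positions within `link_dist` bp of each other are considered the same
#' start (or end) site; linkage is transitive, so a cluster's range can
#' extend beyond `link_dist` by chaining. The result is independent of
#' input order.
#'
#' @param positions Integer vector of end positions from one
#'   (gene, side, anchor exon) context.
#' @param link_dist Link distance in bp; `|a - b| <= link_dist` connects
#'   two positions (default 5).
#' @return A list with `assignment` (integer cluster id per input
#'   position, ids ordered by coordinate) and `clusters` (one row per
#'   cluster: `cluster`, `min`, `max`, `n_members`).
#' @export
build_end_clusters <- function(positions, link_dist = 5L) {
  ids <- single_linkage_1d(positions, link_dist)
  if (length(ids) == 0L)
    return(list(assignment = integer(0),
                clusters = data.frame(cluster = integer(0),
                                      min = integer(0), max = integer(0),
                                      n_members = integer(0))))
  clusters <- do.call(rbind, lapply(split(positions, ids), range))
  list(assignment = ids,
       clusters = data.frame(cluster = sort(unique(ids)),
                             min = clusters[, 1L], max = clusters[, 2L],
                             n_members = as.integer(table(ids))))
}

# Annotated exon index (transcript orientation) with maximal overlap
# with a block; 0 when the block overlaps no annotated exon.
anchor_exon <- function(block, exons, strand) {
  ov <- pmax(0L, pmin(block[2L], exons[, 2L]) - pmax(block[1L], exons[, 1L]))
  if (max(ov) == 0L) return(0L)
  g <- which.max(ov)
  if (strand == "+") g else nrow(exons) - g + 1L
}

# Per-transcript end context: 5'/3' positions, anchor exons, and end
# cluster ids built per (gene, side, anchor exon).
end_cluster_table <- function(transcripts, models, link_dist = 5L) {
  n <- nrow(transcripts)
  pos5 <- integer(n); pos3 <- integer(n)
  anc5 <- integer(n); anc3 <- integer(n)
  for (i in seq_len(n)) {
    b <- parse_blocks(transcripts$blocks[i])
    strand <- transcripts$strand[i]
    pos5[i] <- end5_pos(b, strand)
    pos3[i] <- end3_pos(b, strand)
    ex <- model_exons(models, transcripts$gene_id[i])
    first <- if (strand == "+") b[1L, ] else b[nrow(b), ]
    last <- if (strand == "+") b[nrow(b), ] else b[1L, ]
    anc5[i] <- anchor_exon(first, ex, strand)
    anc3[i] <- anchor_exon(last, ex, strand)
  }
  df <- data.frame(transcript_id = transcripts$transcript_id,
                   gene_id = transcripts$gene_id,
                   pos5 = pos5, pos3 = pos3, anchor5 = anc5,
                   anchor3 = anc3, stringsAsFactors = FALSE)
  ctx5 <- paste(df$gene_id, "5p", df$anchor5, sep = ":")
  ctx3 <- paste(df$gene_id, "3p", df$anchor3, sep = ":")
  df$cluster_5p <- cluster_within(df$pos5, ctx5, link_dist)
  df$cluster_3p <- cluster_within(df$pos3, ctx3, link_dist)
  df
}

cluster_within <- function(positions, context, link_dist) {
  out <- character(length(positions))
  for (ctx in unique(context)) {
    idx <- which(context == ctx)
    ids <- single_linkage_1d(positions[idx], link_dist)
    out[idx] <- paste(ctx, ids, sep = ":")
  }
  out
}

#' Assign transcripts to full isoforms
#'
#' A full isoform is an equivalence class of transcripts under
#' (5' end cluster, exact junction chain, 3' end cluster) identity
#' within a gene. End clusters are built by single-linkage at
#' `link_dist` bp per (gene, side, anchor exon). Every transcript is
#' assigned to exactly one isoform.
#'
#' @param transcripts Transcript table (non-ERCC rows are used).
#' @param models Endogenous `iso_models`.
#' @param link_dist End-cluster link distance in bp (default 5).
#' @return An isoform table: `gene_id`, `level` (`"full"`), `key`,
#'   `chain`, `n_blocks`, `cluster_5p`, `cluster_3p`, `n_transcripts`,
#'   `transcript_ids` (comma-separated), `blocks` (blocks of the modal
#'   member).
#' @export
assign_isoforms <- function(transcripts, models, link_dist = 5L) {
  transcripts <- transcripts[!transcripts$is_ercc, , drop = FALSE]
  if (nrow(transcripts) == 0L) return(empty_isoforms())
  ends <- end_cluster_table(transcripts, models, link_dist)
  chains <- vapply(transcripts$blocks, function(b)
    paste(junction_chain(parse_blocks(b)), collapse = ","), character(1))
  key <- paste(transcripts$gene_id, ends$cluster_5p, chains,
               ends$cluster_3p, sep = "|")
  groups <- split(seq_len(nrow(transcripts)), key)
  out <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    data.frame(
      gene_id = transcripts$gene_id[idx[1L]], level = "full", key = k,
      chain = chains[idx[1L]],
      n_blocks = nrow(parse_blocks(transcripts$blocks[idx[1L]])),
      cluster_5p = ends$cluster_5p[idx[1L]],
      cluster_3p = ends$cluster_3p[idx[1L]],
      n_transcripts = length(idx),
      transcript_ids = paste(transcripts$transcript_id[idx],
                             collapse = ","),
      blocks = modal_value(transcripts$blocks[idx]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$gene_id, -out$n_transcripts, out$key), ]
  rownames(out) <- NULL
  out
}

modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[tab == max(tab)][1L]   # ties: lexicographically smallest
}

empty_isoforms <- function() {
  data.frame(gene_id = character(0), level = character(0),
             key = character(0), chain = character(0),
             n_blocks = integer(0), cluster_5p = character(0),
             cluster_3p = character(0), n_transcripts = integer(0),
             transcript_ids = character(0), blocks = character(0))
}

#' Collapse full isoforms into conservative isoforms
#'
#' Junction start/end positions differing by at most `junction_tol` bp
#' are not considered distinct: per gene, all junction coordinates
#' observed in the input isoforms are clustered by single-linkage at
#' `junction_tol` bp, each junction chain is mapped to its sequence of
#' junction clusters, and isoforms sharing (5' cluster, junction-cluster
#' sequence, 3' cluster) merge. Clustering pools junction positions
#' across exon structures, so a junction shared by several structures is
#' supported by all of them. The merged isoform takes the
#' representative (most transcripts, ties towards the lexicographically
#' smallest chain) and sums transcript support.
#'
#' The input should be full isoforms built from full-length-filtered
#' transcripts (see [filter_full_length()]).
#'
#' @param isoforms Full-level isoform table from [assign_isoforms()].
#' @param junction_tol Junction link distance in bp (default 1).
#' @return An isoform table with `level = "conservative"`.
#' @export
collapse_conservative <- function(isoforms, junction_tol = 1L) {
  if (nrow(isoforms) == 0L) return(empty_isoforms())
  out <- lapply(split(isoforms, isoforms$gene_id), function(iso) {
    vals <- lapply(iso$chain, parse_chain)
    all_vals <- unlist(vals)
    u <- sort(unique(all_vals))
    cl <- single_linkage_1d(u, junction_tol)
    cl_of <- setNames(cl, u)
    ckey <- vapply(vals, function(v)
      paste(cl_of[as.character(v)], collapse = ","), character(1))
    key <- paste(iso$gene_id, iso$cluster_5p, iso$n_blocks, ckey,
                 iso$cluster_3p, sep = "|")
    groups <- split(seq_len(nrow(iso)), key)
    do.call(rbind, lapply(names(groups), function(k) {
      idx <- groups[[k]]
      rep_i <- idx[order(-iso$n_transcripts[idx], iso$chain[idx])][1L]
      data.frame(
        gene_id = iso$gene_id[1L], level = "conservative", key = k,
        chain = iso$chain[rep_i], n_blocks = iso$n_blocks[rep_i],
        cluster_5p = iso$cluster_5p[rep_i],
        cluster_3p = iso$cluster_3p[rep_i],
        n_transcripts = sum(iso$n_transcripts[idx]),
        transcript_ids = paste(iso$transcript_ids[idx], collapse = ","),
        blocks = iso$blocks[rep_i], stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$gene_id, -out$n_transcripts, out$key), ]
  rownames(out) <- NULL
  out
}

parse_chain <- function(chain) {
  if (!nzchar(chain)) return(integer(0))
  as.integer(strsplit(chain, ",", fixed = TRUE)[[1L]])
}

#' Exon-cassette isoforms
#'
#' The most conservative level: two transcripts are the same isoform
#' whenever they cover the same set of annotated exons; transcript ends
#' and junction micro-positions are ignored. Blocks overlapping no
#' annotated exon are ignored for the key.
#'
#' @param transcripts Transcript table (non-ERCC rows are used).
#' @param models Endogenous `iso_models`.
#' @return An isoform table with `level = "cassette"`; `chain` holds the
#'   exon structure (e.g. `"1-3-4"`, transcript orientation).
#' @export
cassette_isoforms <- function(transcripts, models) {
  transcripts <- transcripts[!transcripts$is_ercc, , drop = FALSE]
  if (nrow(transcripts) == 0L) return(empty_isoforms())
  struct <- vapply(seq_len(nrow(transcripts)), function(i)
    exon_structure(parse_blocks(transcripts$blocks[i]),
                   model_exons(models, transcripts$gene_id[i]),
                   transcripts$strand[i]), character(1))
  key <- paste(transcripts$gene_id, struct, sep = "|")
  groups <- split(seq_len(nrow(transcripts)), key)
  out <- do.call(rbind, lapply(names(groups), function(k) {
    idx <- groups[[k]]
    data.frame(
      gene_id = transcripts$gene_id[idx[1L]], level = "cassette", key = k,
      chain = struct[idx[1L]],
      n_blocks = nrow(parse_blocks(transcripts$blocks[idx[1L]])),
      cluster_5p = NA_character_, cluster_3p = NA_character_,
      n_transcripts = length(idx),
      transcript_ids = paste(transcripts$transcript_id[idx],
                             collapse = ","),
      blocks = modal_value(transcripts$blocks[idx]),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$gene_id, -out$n_transcripts, out$key), ]
  rownames(out) <- NULL
  out
}

# Exon structure of a transcript: sorted transcript-orientation indices
# of the annotated exons its blocks overlap, e.g. "1-3-4".
exon_structure <- function(blocks, exons, strand) {
  hit <- logical(nrow(exons))
  for (j in seq_len(nrow(blocks))) {
    ov <- pmin(blocks[j, 2L], exons[, 2L]) - pmax(blocks[j, 1L], exons[, 1L])
    hit <- hit | ov > 0L
  }
  g_idx <- which(hit)
  tx_idx <- if (strand == "+") g_idx else nrow(exons) - g_idx + 1L
  paste(sort(tx_idx), collapse = "-")
}

#' Expand isoform membership
#'
#' @param isoforms An isoform table.
#' @return A data frame mapping `transcript_id` to isoform `key`.
#' @export
isoform_membership <- function(isoforms) {
  do.call(rbind, lapply(seq_len(nrow(isoforms)), function(i)
    data.frame(
      transcript_id = strsplit(isoforms$transcript_ids[i], ",")[[1L]],
      key = isoforms$key[i], stringsAsFactors = FALSE)))
}
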
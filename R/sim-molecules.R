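# Configured isoform structures for one gene, in transcript orientation:
# structure 1 keeps all exons, structure j (j >= 2) drops internal exon j.
# Alternative structures therefore differ in adjacent cassette exons and
# every structure keeps the annotated first and last exon.
structure_blocks <- function(models, gene_id, structure_id) {
  g <- model_row(models, gene_id)
  ex <- parse_blocks(g$exons)
  if (structure_id == 1L) return(ex)
  k <- nrow(ex)
  drop_tx <- structure_id                 # exon index, transcript order
  stopifnot(drop_tx >= 2L, drop_tx <= k - 1L)
  drop_genomic <- if (g$strand == "+") drop_tx else k - drop_tx + 1L
  as_blocks(ex[-drop_genomic, , drop = FALSE])
}

# Apply an alternative TSS/TTS site to a block matrix: site k shifts the
# 5' (3') end (k-1)*spacing bp into the gene body, staying inside the
# first (last) exon.
apply_end_sites <- function(blocks, strand, tss_site, tts_site, spacing) {
  blocks <- as_blocks(blocks)
  k <- nrow(blocks)
  d5 <- (tss_site - 1L) * spacing
  d3 <- (tts_site - 1L) * spacing
  if (strand == "+") {
    blocks[1L, 1L] <- blocks[1L, 1L] + d5
    blocks[k, 2L] <- blocks[k, 2L] - d3
  } else {
    blocks[k, 2L] <- blocks[k, 2L] - d5
    blocks[1L, 1L] <- blocks[1L, 1L] + d3
  }
  stopifnot(blocks[1L, 2L] > blocks[1L, 1L], blocks[k, 2L] > blocks[k, 1L])
  blocks
}

#' Enumerate the configured true isoforms
#'
#' The ground-truth isoform set of a simulation: every combination of
#' configured exon structure, TSS site and TTS site per gene, keyed by
#' the canonical serialization of its exact exon blocks.
#'
#' @param models Endogenous `iso_models`.
#' @param cfg A [sim_config()].
#' @return A data frame with `gene_id`, `structure_id`, `tss_site`,
#'   `tts_site` and `isoform_key`.
#' @export
true_isoform_set <- function(models, cfg) {
  genes <- models$genes[!models$genes$is_ercc, ]
  grid <- expand.grid(
    gene_id = genes$gene_id,
    structure_id = seq_len(cfg$isoforms_per_gene),
    tss_site = seq_len(cfg$tss_sites_per_gene),
    tts_site = seq_len(cfg$tts_sites_per_gene),
    stringsAsFactors = FALSE
  )
  grid$isoform_key <- vapply(seq_len(nrow(grid)), function(i) {
    g <- model_row(models, grid$gene_id[i])
    b <- structure_blocks(models, grid$gene_id[i], grid$structure_id[i])
    b <- apply_end_sites(b, g$strand, grid$tss_site[i], grid$tts_site[i],
                         cfg$tss_site_spacing)
    paste(g$chrom, g$strand, format_blocks(b), sep = "|")
  }, character(1))
  grid
}

#' Sample true cDNA molecules
#'
#' Draws molecules per cell with gene- and isoform-level weights, assigns
#' each a uniform random 6 bp UMI, and 5'-truncates a fraction
#' `degradation_rate` of endogenous molecules to a random internal start
#' in exon 2 or later (the 3' end stays intact, as expected for 5'
#' degradation or incomplete reverse transcription). ERCC spike-in
#' molecules are always full length.
#'
#' @param models Endogenous `iso_models` (from [generate_gene_models()]).
#' @param cfg A [sim_config()].
#' @param ercc Optional ERCC `iso_models` (used when
#'   `cfg$ercc_per_cell > 0`).
#' @param path Optional path to write the truth table as TSV.
#' @return A data frame with one row per molecule: `molecule_id`, `cell`,
#'   `barcode` (16 bp), `gene_id`, `chrom`, `strand`, `umi` (6 bp),
#'   serialized `blocks`, `has_full_first_exon`, `is_ercc`,
#'   `isoform_key`, `structure_id`.
#' @export
sample_true_molecules <- function(models, cfg, ercc = NULL, path = NULL) {
  genes <- models$genes[!models$genes$is_ercc, ]
  if (nrow(genes) == 0L) stop("no gene models to sample from")
  set.seed(cfg$seed + 1L)
  cells <- names(PACBIO_BARCODES)[seq_len(cfg$n_cells)]

  out <- list()
  idx <- 0L
  for (cell in cells) {
    n <- cfg$molecules_per_cell
    if (n > 0L) {
      gid <- sample(genes$gene_id, n, replace = TRUE)
      sid <- sample.int(cfg$isoforms_per_gene, n, replace = TRUE,
                        prob = cfg$isoform_weights)
      tss <- sample.int(cfg$tss_sites_per_gene, n, replace = TRUE)
      tts <- sample.int(cfg$tts_sites_per_gene, n, replace = TRUE)
      degraded <- runif(n) < cfg$degradation_rate
      for (i in seq_len(n)) {
        idx <- idx + 1L
        g <- model_row(models, gid[i])
        b <- structure_blocks(models, gid[i], sid[i])
        b <- apply_end_sites(b, g$strand, tss[i], tts[i],
                             cfg$tss_site_spacing)
        key <- paste(g$chrom, g$strand, format_blocks(b), sep = "|")
        if (degraded[i]) b <- truncate_5p(b, g$strand)
        out[[idx]] <- data.frame(
          molecule_id = sprintf("mol%06d", idx), cell = cell,
          barcode = unname(PACBIO_BARCODES[cell]),
          gene_id = gid[i], chrom = g$chrom, strand = g$strand,
          umi = rand_dna(6L), blocks = format_blocks(b),
          has_full_first_exon = !degraded[i], is_ercc = FALSE,
          isoform_key = key, structure_id = sid[i],
          stringsAsFactors = FALSE
        )
      }
    }
    if (cfg$ercc_per_cell > 0L) {
      stopifnot(!is.null(ercc))
      eid <- sample(ercc$genes$gene_id, cfg$ercc_per_cell, replace = TRUE)
      for (id in eid) {
        idx <- idx + 1L
        e <- model_row(ercc, id)
        out[[idx]] <- data.frame(
          molecule_id = sprintf("mol%06d", idx), cell = cell,
          barcode = unname(PACBIO_BARCODES[cell]),
          gene_id = id, chrom = e$chrom, strand = "+",
          umi = rand_dna(6L), blocks = e$exons,
          has_full_first_exon = TRUE, is_ercc = TRUE,
          isoform_key = paste(e$chrom, "+", e$exons, sep = "|"),
          structure_id = 1L, stringsAsFactors = FALSE
        )
      }
    }
  }
  molecules <- do.call(rbind, out)
  rownames(molecules) <- NULL
  if (!is.null(path))
    write.table(molecules, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  molecules
}

# 5' truncation: drop everything upstream (transcript orientation) of a
# random position in a random exon >= 2, keeping at least 30 bp of the
# entry exon (or all of it when shorter).
truncate_5p <- function(blocks, strand) {
  blocks <- as_blocks(blocks)
  k <- nrow(blocks)
  stopifnot(k >= 2L)
  t_tx <- if (k == 2L) 2L else sample(2:k, 1L)
  if (strand == "+") {
    j <- t_tx
    keep <- blocks[j:k, , drop = FALSE]
    hi <- max(keep[1L, 1L], keep[1L, 2L] - 30L)
    keep[1L, 1L] <- if (hi > keep[1L, 1L])
      sample(seq.int(keep[1L, 1L], hi), 1L) else keep[1L, 1L]
  } else {
    j <- k - t_tx + 1L
    keep <- blocks[1:j, , drop = FALSE]
    lo <- min(keep[j, 2L], keep[j, 1L] + 30L)
    keep[j, 2L] <- if (lo < keep[j, 2L])
      sample(seq.int(lo, keep[j, 2L]), 1L) else keep[j, 2L]
  }
  as_blocks(keep)
}
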
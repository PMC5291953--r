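# Shared fixtures, built in code.

# Hand-built gene models without sequences, for coordinate-level tests.
toy_models <- function(exons, strand = "+", cds = NULL, gene_id = "g1",
                       chrom = "chrT") {
  exons <- matrix(as.integer(exons), ncol = 2L, byrow = TRUE)
  k <- nrow(exons)
  genes <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand, n_exons = k,
    tss = if (strand == "+") exons[1L, 1L] else exons[k, 2L],
    tts = if (strand == "+") exons[k, 2L] else exons[1L, 1L],
    exons = format_blocks(exons),
    cds = if (is.null(cds)) NA_character_ else
      format_blocks(matrix(as.integer(cds), ncol = 2L, byrow = TRUE)),
    is_ercc = FALSE, stringsAsFactors = FALSE
  )
  structure(list(genes = genes, seqs = character(0)),
            class = "iso_models")
}

# A transcript table row from a serialized block string.
toy_tx <- function(blocks, gene_id = "g1", cell = "idx1",
                   umi = NULL, strand = "+", chrom = "chrT",
                   support = 1L, has_polya = TRUE, id = NULL) {
  umi <- if (is.null(umi)) paste(sample(c("A", "C", "G", "T"), 6,
                                        replace = TRUE), collapse = "")
         else umi
  data.frame(
    transcript_id = if (is.null(id)) paste(cell, gene_id, umi, sep = ":")
      else id,
    cell = cell, gene_id = gene_id, umi = umi, chrom = chrom,
    strand = strand, blocks = blocks, read_support = support,
    has_polya = has_polya, is_ercc = FALSE, stringsAsFactors = FALSE
  )
}

toy_tx_table <- function(blocks_vec, ...) {
  out <- do.call(rbind, lapply(seq_along(blocks_vec), function(i)
    toy_tx(blocks_vec[i], umi = sprintf("UMI%03d", i), ...)))
  out$umi <- sprintf("%06d", seq_along(blocks_vec))
  out$transcript_id <- paste(out$cell, out$gene_id, out$umi, sep = ":")
  out
}

# One small shared simulation with ERCC spike-ins and concatemers;
# computed once per test run.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 6L, n_cells = 2L,
                        molecules_per_cell = 60L, ercc_per_cell = 10L,
                        n_ercc = 12L, concatemer_rate = 0.3,
                        seed = 11L)
      dir <- file.path(tempdir(), "isoscope-small-sim")
      cache <<- list(cfg = cfg,
                     sim = simulate_dataset(cfg, outdir = dir),
                     dir = dir)
    }
    cache
  }
})

# Brute-force single-linkage oracle: union-find over all pairs.
oracle_clusters <- function(positions, link_dist) {
  n <- length(positions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(positions[i] - positions[j]) <= link_dist) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
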
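test_that("block gap-merging pins the 40 bp boundary", {
  expect_equal(merge_close_blocks(rbind(c(0L, 100L), c(139L, 200L))),
               matrix(c(0L, 200L), 1L,
                      dimnames = list(NULL, c("start", "end"))))
  b <- rbind(c(0L, 100L), c(140L, 200L))
  expect_equal(unname(merge_close_blocks(b)), unname(b))
  one <- matrix(c(5L, 50L), 1L)
  expect_equal(unname(merge_close_blocks(one)), unname(one))
  # chained gaps merge to fixpoint
  expect_equal(nrow(merge_close_blocks(
    rbind(c(0L, 10L), c(20L, 30L), c(40L, 50L)))), 1L)
})

test_that("alignment loading drops non-unique reads and round-trips", {
  sc <- small_sim()
  sim <- sc$sim
  ext <- extract_reads(sim$reads$fastq, default_barcodes(2L))
  aligned <- load_alignments(file.path(sc$dir, "alignments.bed"),
                             ext$valid_reads)
  expect_equal(nrow(aligned), nrow(ext$valid_reads))
  # round trip: every valid read recovers its truth blocks
  seg <- sim$reads$segments
  truth <- seg$blocks[match(paste0(seg$record_id, "/", seg$subread_index),
                            aligned$read_id)]
  expect_identical(aligned$blocks, truth[!is.na(truth)])

  # duplicate ids are excluded
  bed <- read_bed12(file.path(sc$dir, "alignments.bed"))
  dup <- rbind(bed, bed[1L, ])
  aligned2 <- load_alignments(dup, ext$valid_reads)
  expect_false(bed$name[1L] %in% aligned2$read_id)
  expect_equal(nrow(aligned2), nrow(aligned) - 1L)
})

test_that("gene annotation assigns by majority overlap on one strand", {
  models <- toy_models(c(100, 200, 300, 400), gene_id = "g1")
  aligned <- data.frame(
    read_id = c("r1", "r2"), barcode_id = "idx1", umi = "AAAAAA",
    template_seq = "ACGT", has_polya = TRUE, case = 1L,
    record_id = c("r1", "r2"), subread_index = 1L,
    chrom = "chrT", strand = "+",
    blocks = c("120-180,310-390", "5000-5100"),
    stringsAsFactors = FALSE
  )
  ann <- annotate_genes(aligned, models)
  expect_equal(ann$gene_id, c("g1", NA))

  sim <- small_sim()$sim
  ext <- extract_reads(sim$reads$fastq, default_barcodes(2L))
  aligned <- load_alignments(file.path(small_sim()$dir, "alignments.bed"),
                             ext$valid_reads)
  ann <- annotate_genes(aligned, sim$models, sim$ercc)
  seg <- sim$reads$segments
  truth_gene <- sim$molecules$gene_id[
    match(seg$molecule_id[match(ann$read_id,
                                paste0(seg$record_id, "/",
                                       seg$subread_index))],
          sim$molecules$molecule_id)]
  expect_identical(ann$gene_id, truth_gene)
})

test_that("UMI consensus follows the dedupe / most-5' / median rules", {
  # identical reads dedupe with support preserved
  b <- "100-200,300-400"
  expect_equal(format_blocks(merge_umi_group(rep(b, 3L), "+")), b)

  # 5'-only differences with shared first 8 template bases: most 5'
  bl <- c("100-200,300-400", "105-200,300-400", "103-200,300-400")
  tm <- rep("ACGTACGTXX", 3L)
  expect_equal(format_blocks(merge_umi_group(bl, "+", tm)),
               "100-200,300-400")
  # on the minus strand the most 5' position is the largest end
  blm <- c("100-200,300-400", "100-205,300-400")
  blm_m <- c("300-400,500-600", "300-400,500-605")
  expect_equal(format_blocks(merge_umi_group(blm_m, "-", rep("AC", 2L))),
               "300-400,500-605")

  # differing templates fall back to the per-coordinate median
  bl2 <- c("100-200,300-400", "100-202,300-400", "100-204,300-400")
  tm2 <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG")
  expect_equal(format_blocks(merge_umi_group(bl2, "+", tm2)),
               "100-202,300-400")
  # lower median for even group sizes
  bl3 <- c("100-200", "100-210")
  expect_equal(format_blocks(merge_umi_group(bl3, "+", c("A", "C"))),
               "100-200")

  # discordant exon counts: majority structure wins, ties to more exons
  bl4 <- c("100-400", "100-200,300-400", "100-200,300-400")
  expect_equal(format_blocks(merge_umi_group(bl4, "+")),
               "100-200,300-400")
  bl5 <- c("100-400", "100-200,300-400")
  expect_equal(format_blocks(merge_umi_group(bl5, "+")),
               "100-200,300-400")

  expect_error(merge_umi_group(list(), "+"), "empty")
})

test_that("consensus is permutation-invariant and conserves reads", {
  sc <- small_sim()
  sim <- sc$sim
  ext <- extract_reads(sim$reads$fastq, default_barcodes(2L))
  aligned <- annotate_genes(
    load_alignments(file.path(sc$dir, "alignments.bed"), ext$valid_reads),
    sim$models, sim$ercc)
  tx <- build_transcripts(aligned)
  expect_equal(sum(tx$read_support),
               sum(!is.na(aligned$gene_id) &
                     aligned$gene_id != "ERCC-00074"))
  expect_lte(nrow(tx), nrow(aligned))

  set.seed(1)
  shuffled <- aligned[sample.int(nrow(aligned)), ]
  tx2 <- build_transcripts(shuffled)
  expect_identical(tx, tx2)

  # zero-noise consensus equals the true molecule blocks (for UMI keys
  # not hit by a 6-mer collision within the same cell and gene)
  truth <- sim$molecules
  tkey <- paste(truth$cell, truth$gene_id, truth$umi, sep = ":")
  unique_keys <- names(table(tkey))[table(tkey) == 1L]
  tb <- truth$blocks[match(tx$transcript_id, tkey)]
  sel <- !is.na(tb) & tx$transcript_id %in% unique_keys
  expect_gt(sum(sel), 0L)
  expect_identical(tx$blocks[sel], tb[sel])
})

test_that("the excluded spike-in never reaches the transcript table", {
  sim <- small_sim()$sim
  ext <- extract_reads(sim$reads$fastq, default_barcodes(2L))
  aligned <- annotate_genes(
    load_alignments(file.path(small_sim()$dir, "alignments.bed"),
                    ext$valid_reads), sim$models, sim$ercc)
  if (!"ERCC-00074" %in% aligned$gene_id)
    aligned$gene_id[which(aligned$is_ercc)[1L]] <- "ERCC-00074"
  tx <- build_transcripts(aligned)
  expect_false("ERCC-00074" %in% tx$gene_id)
})

test_that("full-length filtering keeps annotated first exon + poly-A", {
  models <- toy_models(c(100, 300, 500, 700, 900, 1100))
  keep <- toy_tx("100-300,500-700,900-1100", umi = "A")
  degraded <- toy_tx("600-700,900-1100", umi = "B")     # 5' start in exon 2
  tailless <- toy_tx("100-300,500-700,900-1100", umi = "C",
                     has_polya = FALSE)
  tx <- rbind(keep, degraded, tailless)
  tx$umi <- c("A", "B", "C")
  tx$transcript_id <- paste0("idx1:g1:", tx$umi)
  out <- filter_full_length(tx, models)
  expect_equal(out$transcript_id, "idx1:g1:A")

  # retained fraction tracks the degradation rate
  cfg <- sim_config(n_genes = 4L, n_cells = 1L,
                    molecules_per_cell = 400L, degradation_rate = 0.5,
                    reads_per_umi_mean = 1, concatemer_rate = 0,
                    seed = 77L)
  mod <- generate_gene_models(cfg)
  mol <- sample_true_molecules(mod, cfg)
  frac <- mean(mol$has_full_first_exon)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 400))
})
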
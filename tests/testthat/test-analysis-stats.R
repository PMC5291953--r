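test_that("offset from median uses the lower-median convention", {
  out <- offset_from_median(c(10L, 12L, 14L), rep("c1", 3L))
  expect_equal(sort(out$offset), c(-2L, 0L, 2L))
  expect_true(0L %in% out$offset)             # odd n: one exact zero

  same <- offset_from_median(rep(7L, 4L), rep("c1", 4L))
  expect_true(all(same$offset == 0L))

  two <- offset_from_median(c(10L, 12L), rep("c1", 2L))
  expect_equal(sort(two$offset), c(0L, 2L))   # lower median

  # singleton contexts are excluded
  mix <- offset_from_median(c(5L, 9L, 11L), c("a", "b", "b"))
  expect_equal(unique(mix$context), "b")
})

test_that("within-UMI offsets measure read-level variability", {
  aligned <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    barcode_id = "idx1", gene_id = "g1", umi = c("U", "U", "U", "V"),
    chrom = "chrT", strand = "+",
    blocks = c("100-200,300-400", "100-200,300-400", "101-200,300-400",
               "100-200,300-400"),
    stringsAsFactors = FALSE)
  out <- within_umi_offsets(aligned)
  e5 <- out[out$site == "end5", ]
  expect_equal(sort(e5$offset), c(0L, 0L, 1L))
  # the singleton UMI V contributes nothing
  expect_false(any(grepl(":V$", out$context)))
  # zero-noise groups have all offsets zero
  expect_true(all(out$offset[out$site != "end5"] == 0L))
})

test_that("ERCC end offsets quantify end accuracy", {
  ercc <- generate_ercc_set(5L, 300L, 500L, seed = 4L)
  lens <- ercc$genes$tts
  # exact ends: everything within 0
  tx <- do.call(rbind, lapply(1:5, function(i) {
    t <- toy_tx(paste0("0-", lens[i]), gene_id = ercc$genes$gene_id[i],
                chrom = ercc$genes$gene_id[i], umi = sprintf("%06d", i))
    t$is_ercc <- TRUE
    t
  }))
  res <- ercc_end_offsets(tx, ercc)
  expect_true(all(res$offsets$offset == 0L))
  expect_true(all(res$summary$fraction == 1))

  # uniform +/-5 end noise: all within 5, about 3/11 within 1
  set.seed(8)
  n <- 400L
  ids <- sample(ercc$genes$gene_id, n, replace = TRUE)
  d5 <- sample(-5:5, n, replace = TRUE)
  d3 <- sample(-5:5, n, replace = TRUE)
  txn <- do.call(rbind, lapply(seq_len(n), function(i) {
    L <- lens[match(ids[i], ercc$genes$gene_id)]
    t <- toy_tx(paste0(d5[i], "-", L + d3[i]), gene_id = ids[i],
                chrom = ids[i], umi = sprintf("%06d", i))
    t$is_ercc <- TRUE
    t
  }))
  txn <- txn[d5 >= 0, ]   # keep valid coordinates
  res <- ercc_end_offsets(txn, ercc)
  s <- res$summary
  expect_equal(s$fraction[s$site == "end3" & s$within == 5L], 1)
  expect_lt(abs(s$fraction[s$site == "end3" & s$within == 1L] - 3 / 11),
            0.1)
  expect_true(all(abs(res$offsets$offset) <= 5L))

  expect_error(ercc_end_offsets(
    within(txn[1L, ], gene_id <- "ERCC-99999"), ercc), "unknown")
})

test_that("relative end positions are strand-aware and clamped", {
  models <- toy_models(c(1000, 1200, 1800, 2000))
  at_tts <- toy_tx("1000-1200,1800-2000", umi = "A")
  premature <- toy_tx("1000-1100", umi = "B")       # ends at 10% of span
  overhang <- toy_tx("996-1200,1800-2003", umi = "C")
  tx <- rbind(at_tts, premature, overhang)
  res <- relative_end_positions(tx, models)
  expect_equal(res$ends$rel3[1L], 1.0)
  expect_equal(res$ends$rel3[2L], 0.1)
  expect_true(res$ends$premature[2L])
  expect_equal(res$ends$rel5[3L], 0)                # clamped
  expect_equal(res$ends$rel3[3L], 1)
  expect_true(all(res$ends$rel5 >= 0 & res$ends$rel5 <= 1, na.rm = TRUE))
  expect_equal(res$premature_fraction, 1 / 3)
})

test_that("event counting matches the worked taxonomy", {
  models <- toy_models(c(100, 300, 500, 700, 900, 1100, 1300, 1500))
  # 5x 1-2-3-4 (one with a 2 bp junction shift, TSS at two clusters),
  # 2x 1-3-4; all TTS identical
  full <- "100-300,500-700,900-1100,1300-1500"
  shift <- "100-300,500-700,900-1102,1300-1500"
  alt_tss <- "120-300,500-700,900-1100,1300-1500"
  skip <- "100-300,900-1100,1300-1500"
  tx <- toy_tx_table(c(full, full, shift, alt_tss, alt_tss, skip, skip))
  ev <- count_events(tx, models)
  expect_equal(ev$counts$tss, 1L)
  expect_equal(ev$counts$tts, 0L)
  expect_equal(ev$counts$cassette, 1L)
  expect_equal(ev$counts$position, 1L)

  # one start cluster, one structure, identical junctions: no events
  ev0 <- count_events(toy_tx_table(c(full, full, full)), models)
  expect_true(all(ev0$counts[, c("tss", "tts", "position",
                                 "cassette")] == 0L))

  # adding one novel structure increments exactly the cassette counter
  ev1 <- count_events(toy_tx_table(c(full, full, skip)), models)
  expect_equal(unlist(ev1$counts[, c("tss", "tts", "position",
                                     "cassette")], use.names = FALSE),
               c(0L, 0L, 0L, 1L))
})

test_that("exon connectivity uses a two-sided Fisher exact test", {
  fisher_p <- isoscope:::fisher_p
  expect_equal(fisher_p(matrix(c(3L, 0L, 0L, 3L), 2L)), 0.1,
               tolerance = 1e-12)
  expect_equal(fisher_p(matrix(c(1L, 1L, 1L, 1L), 2L)), 1.0)
  expect_equal(fisher_p(matrix(0L, 2L, 2L)), 1.0)

  # transcripts spanning both exons, co-included or co-excluded
  models <- toy_models(c(100, 300, 500, 700, 900, 1100, 1300, 1500))
  both <- "100-300,500-700,900-1100,1300-1500"
  neither <- "100-300,1300-1500"
  tx <- toy_tx_table(rep(c(both, neither), each = 3L))
  res <- exon_connectivity_test(tx, models, "g1", 2L, 3L)
  expect_equal(unname(res$table[1L, 1L]), 3L)
  expect_equal(unname(res$table[2L, 2L]), 3L)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
})

test_that("Fisher p matches hypergeometric enumeration (margins <= 10)", {
  fisher_p <- isoscope:::fisher_p
  oracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; k <- a + c
    x <- max(0L, k - r2):min(k, r1)
    probs <- dhyper(x, r1, r2, k)
    obs <- dhyper(a, r1, r2, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  for (a in 0:6) for (b in 0:6) for (c in 0:6) for (d in 0:6) {
    if (a + b > 10 || c + d > 10 || a + c > 10 || b + d > 10) next
    tab <- matrix(c(a, c, b, d), 2L)
    if (sum(tab) == 0L || min(rowSums(tab)) == 0L ||
        min(colSums(tab)) == 0L) next
    expect_equal(fisher_p(tab), oracle(a, b, c, d), tolerance = 1e-10)
  }
})

test_that("coding labels follow the CDS intervals", {
  models <- toy_models(c(100, 300, 500, 700, 900, 1100),
                       cds = c(200, 300, 500, 700, 900, 1000))
  offs <- data.frame(
    gene_id = "g1",
    context = "g1|1-2-3|3", site = c("j1_a", "end3", "end5"),
    site_kind = c("junction_start", "end3", "end5"),
    position = c(300L, 1100L, 100L), offset = 0L,
    transcript_id = "t1", stringsAsFactors = FALSE)
  lab <- label_coding(offs, models, drop_coding_ends = FALSE)
  expect_equal(lab$coding, c(TRUE, FALSE, FALSE))

  # coding transcript ends are excluded as presumed artifacts
  offs2 <- offs
  offs2$position[2L] <- 950L
  lab2 <- label_coding(offs2, models)
  expect_false("end3" %in% lab2$site)

  # gene without CDS: everything non-coding
  models0 <- toy_models(c(100, 300, 500, 700, 900, 1100))
  expect_false(any(label_coding(offs, models0)$coding))
})

test_that("Wilcoxon signed-rank p matches sign-assignment enumeration", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 6L + rep
    x <- round(runif(n, 0, 10), 3)
    d <- x - round(runif(n, 0, 10), 3)
    y <- x - d
    got <- wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    # enumerate all 2^n sign assignments of the |d| ranks
    r <- rank(abs(d))
    W <- vapply(0:(2^n - 1), function(mask) {
      signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
      sum(r[signs])
    }, numeric(1))
    w_obs <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    p_oracle <- min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
    expect_equal(got, p_oracle, tolerance = 1e-12)
  }
})

test_that("degenerate coding/non-coding comparisons give p = 1", {
  offs <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 2L), context = "c",
    site = "j1_a", site_kind = "junction_start",
    position = 100L, offset = 0L, transcript_id = "t",
    coding = c(TRUE, FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  res <- coding_vs_noncoding_test(offs)
  expect_true(all(res$p_value == 1))
  res_p <- coding_vs_noncoding_test(offs, paired = TRUE)
  expect_true(all(res_p$p_value == 1))
})

test_that("constrained coding sites separate from noisy non-coding ones", {
  set.seed(33)
  mk <- function(n_sites, spread, coding) {
    do.call(rbind, lapply(seq_len(n_sites), function(s) {
      pos <- 1000L + sample(seq.int(-spread, spread), 3L, replace = TRUE)
      data.frame(gene_id = sprintf("g%04d", s),
                 context = sprintf("ctx%04d%s", s, coding),
                 site = "j1_a", site_kind = "junction_start",
                 position = pos, transcript_id = paste0("t", 1:3),
                 stringsAsFactors = FALSE)
    }))
  }
  recs <- rbind(mk(250L, 1L, TRUE), mk(250L, 10L, FALSE))
  offs <- isoscope:::offsets_by_context(recs)
  offs$coding <- grepl("TRUE", offs$context)
  res <- coding_vs_noncoding_test(offs)
  p <- res$p_value[res$site_kind == "junction_start"]
  expect_lt(p, 0.001)
  # directional sanity: coding spread below non-coding spread
  expect_lt(mean(abs(offs$offset[offs$coding])),
            mean(abs(offs$offset[!offs$coding])))
})

test_that("isoform sharing restricts to genes seen in every cell type", {
  iso <- data.frame(
    gene_id = "g1", level = "conservative",
    key = c("A", "B", "C", "D"), chain = "", n_blocks = 2L,
    cluster_5p = "x", cluster_3p = "y",
    n_transcripts = c(1L, 3L, 1L, 1L),
    transcript_ids = c("c1:g1:u1",
                       "c1:g1:u2,c2:g1:u3,c3:g1:u4",
                       "c2:g1:u5", "c3:g1:u6"),
    blocks = "0-1", stringsAsFactors = FALSE)
  res <- isoform_sharing(iso)
  expect_equal(res$all_fraction, 0.25)        # only B in all three
  expect_equal(res$any_two_fraction, 0.25)
  expect_equal(sum(res$venn$count), 4L)

  # identical sets across two cells
  iso2 <- iso[2L, ]
  res2 <- isoform_sharing(iso2)
  expect_equal(res2$all_fraction, 1.0)

  # disjoint sets: gene not complete in all types, nothing to compare
  iso3 <- iso[c(1L, 3L), ]
  iso3$gene_id <- c("g1", "g2")
  res3 <- isoform_sharing(iso3)
  expect_true(is.na(res3$all_fraction) || res3$all_fraction == 0)
  expect_error(isoform_sharing(iso[1L, ]), "2 cell types")
})

test_that("major isoform fraction summarizes genes above 10 transcripts", {
  iso <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2"), level = "conservative",
    key = paste0("k", 1:4), chain = "", n_blocks = 2L,
    cluster_5p = "x", cluster_3p = "y",
    n_transcripts = c(6L, 3L, 3L, 20L),
    transcript_ids = "t", blocks = "0-1", stringsAsFactors = FALSE)
  res <- major_isoform_fraction(iso)
  expect_equal(res$per_gene$major_fraction[res$per_gene$gene_id == "g1"],
               0.5)
  expect_equal(res$per_gene$major_fraction[res$per_gene$gene_id == "g2"],
               1.0)
  # a gene with exactly 10 transcripts is excluded
  iso10 <- iso[1:2, ]
  iso10$n_transcripts <- c(5L, 5L)
  expect_equal(nrow(major_isoform_fraction(iso10)$per_gene), 0L)
})

test_that("configured isoform weights recover a ~50% major isoform", {
  cfg <- sim_config(n_genes = 10L, n_cells = 1L,
                    molecules_per_cell = 600L, reads_per_umi_mean = 1,
                    concatemer_rate = 0, degradation_rate = 0,
                    seed = 41L)
  mod <- generate_gene_models(cfg)
  mol <- sample_true_molecules(mod, cfg)
  reads <- emit_reads(mol, mod, cfg)
  seg <- reads$segments
  aligned <- data.frame(
    read_id = paste0(seg$record_id, "/", seg$subread_index),
    barcode_id = "idx1",
    umi = mol$umi[match(seg$molecule_id, mol$molecule_id)],
    template_seq = "N", has_polya = TRUE, chrom = seg$chrom,
    strand = seg$strand, blocks = seg$blocks,
    gene_id = mol$gene_id[match(seg$molecule_id, mol$molecule_id)],
    is_ercc = FALSE, stringsAsFactors = FALSE)
  tx <- build_transcripts(aligned)
  iso <- collapse_conservative(assign_isoforms(tx, mod))
  res <- major_isoform_fraction(iso)
  expect_lt(abs(res$mean_fraction - 0.5), 0.06)
})

test_that("configured alternative TSS sites surface as TSS events", {
  cfg <- sim_config(n_genes = 4L, n_cells = 1L,
                    molecules_per_cell = 400L, isoforms_per_gene = 1L,
                    isoform_weights = 1, tss_sites_per_gene = 3L,
                    reads_per_umi_mean = 1, concatemer_rate = 0,
                    degradation_rate = 0, seed = 61L)
  mod <- generate_gene_models(cfg)
  mol <- sample_true_molecules(mod, cfg)
  tx <- data.frame(
    transcript_id = paste(mol$cell, mol$gene_id, mol$umi, sep = ":"),
    cell = mol$cell, gene_id = mol$gene_id, umi = mol$umi,
    chrom = mol$chrom, strand = mol$strand, blocks = mol$blocks,
    read_support = 1L, has_polya = TRUE, is_ercc = FALSE,
    stringsAsFactors = FALSE)
  ev <- count_events(tx, mod)
  expect_true(all(ev$counts$tss == 2L))   # 3 start clusters per gene
  expect_true(all(ev$counts$cassette == 0L))
  # and the three sites give three conservative isoforms per gene
  iso <- collapse_conservative(assign_isoforms(tx, mod))
  expect_true(all(table(iso$gene_id) == 3L))
})

test_that("offset histogram binning uses the variable-width layout", {
  b <- bin_offsets(c(0L, 0L, 1L, -1L, 3L, -7L, 50L, 200L))
  expect_equal(b$count[b$bin == "0"], 2L)
  expect_equal(b$count[b$bin == "+2..+5"], 1L)
  expect_equal(b$count[b$bin == ">+100"], 1L)
  expect_equal(sum(b$count), 8L)
})
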
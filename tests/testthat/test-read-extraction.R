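brute_force_scan <- function(seq, pattern, max_mm) {
  # sliding-window Hamming oracle
  L <- nchar(seq); k <- nchar(pattern)
  hits <- integer(0)
  for (p in seq_len(L - k + 1L)) {
    w <- substr(seq, p, p + k - 1L)
    mm <- sum(strsplit(w, "")[[1L]] != strsplit(pattern, "")[[1L]])
    if (mm <= max_mm) hits <- c(hits, p)
  }
  hits
}

test_that("adapter matching finds hits up to 2 substitutions", {
  set.seed(42)
  ill <- illumina_adapter()
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  seq <- paste0(pad(50), ill, pad(50))
  m <- find_adapters(seq, c(illumina = ill))
  expect_equal(nrow(m[m$which == "illumina", ]), 1L)
  expect_equal(m$start[m$which == "illumina"], 51L)
  expect_equal(m$mismatches[m$which == "illumina"], 0L)

  expect_equal(nrow(find_adapters(strrep("N", 200), c(illumina = ill))),
               0L)

  corrupt <- function(x, k) {
    ch <- strsplit(x, "")[[1L]]
    pos <- sample(seq_along(ch), k)
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(ch, collapse = "")
  }
  for (rep in 1:10) {
    s2 <- paste0(pad(40), corrupt(ill, 2L), pad(40))
    s3 <- paste0(pad(40), corrupt(ill, 3L), pad(40))
    m2 <- find_adapters(s2, c(illumina = ill))
    expect_equal(m2$start[m2$which == "illumina"],
                 brute_force_scan(s2, ill, 2L))
    m3 <- find_adapters(s3, c(illumina = ill))
    expect_equal(m3$start[m3$which == "illumina"],
                 brute_force_scan(s3, ill, 2L))
  }
})

test_that("concatemers split at internal barcode pairs", {
  sim <- small_sim()$sim
  seg <- sim$reads$segments
  bcs <- default_barcodes(2L)
  tri <- unique(seg$record_id[seg$arity == 3L])
  expect_true(length(tri) > 0L)
  for (r in head(tri, 3L)) {
    s <- sim$reads$fastq[[r]]
    m <- find_adapters(s, c(illumina = illumina_adapter(), bcs))
    iv <- split_concatemers(m, nchar(s))
    expect_equal(nrow(iv), 3L)
    truth <- seg[seg$record_id == r, ]
    mol <- sim$molecules[match(truth$molecule_id,
                               sim$molecules$molecule_id), ]
    for (k in 1:3) {
      res <- parse_valid_read(substr(s, iv$start[k], iv$end[k]), bcs)
      expect_true(res$valid)
      expect_equal(res$barcode_id, mol$cell[k])
      expect_equal(res$umi, mol$umi[k])
    }
  }

  # monomer and adapterless reads give one interval
  mono <- seg$record_id[seg$arity == 1L][1L]
  s <- sim$reads$fastq[[mono]]
  m <- find_adapters(s, c(illumina = illumina_adapter(), bcs))
  expect_equal(split_concatemers(m, nchar(s)),
               data.frame(start = 1L, end = nchar(s)))
  empty <- find_adapters(strrep("N", 100), c(illumina = illumina_adapter()))
  expect_equal(split_concatemers(empty, 100L),
               data.frame(start = 1L, end = 100L))
})

test_that("grammar parsing rejects malformed subreads with a reason", {
  bcs <- default_barcodes(3L)
  ill <- illumina_adapter()
  rc <- isoscope:::revcomp
  tmpl <- strrep("CAGT", 100)
  good <- paste0(bcs[["idx1"]], ill, "ACGTAC", "GGG", tmpl,
                 strrep("A", 30), rc(ill), rc(bcs[["idx1"]]))
  res <- parse_valid_read(good, bcs)
  expect_true(res$valid)
  expect_equal(res$umi, "ACGTAC")
  expect_equal(res$template_seq, tmpl)

  # a second barcode inside the pair: conflict
  conflict <- paste0(bcs[["idx1"]], ill, "ACGTAC", "GGG", tmpl,
                     bcs[["idx2"]], tmpl, strrep("A", 30), rc(ill),
                     rc(bcs[["idx1"]]))
  expect_equal(parse_valid_read(conflict, bcs)$reason,
               "barcode_conflict")

  # no homopolymer tail
  tailless <- paste0(bcs[["idx1"]], ill, "ACGTAC", "GGG", tmpl,
                     rc(ill), rc(bcs[["idx1"]]))
  expect_equal(parse_valid_read(tailless, bcs)$reason, "no_polya")

  # no barcode at all
  expect_equal(parse_valid_read(paste0(ill, tmpl), bcs)$reason,
               "no_barcode")
})

test_that("poly-A/poly-T artifact filter uses a 10-base run threshold", {
  expect_false(filter_polya_polyt(
    paste0("CG", strrep("A", 12), "CG", strrep("T", 12), "CG")))
  expect_true(filter_polya_polyt(paste0("CG", strrep("A", 12), "CG")))
  expect_true(filter_polya_polyt(
    paste0("CG", strrep("A", 9), "CG", strrep("T", 9), "CG")))
})

test_that("noise-free extraction recovers every embedded molecule", {
  sc <- small_sim()
  sim <- sc$sim
  ext <- extract_reads(sim$reads$fastq, default_barcodes(2L))
  expect_equal(nrow(ext$valid_reads), nrow(sim$reads$segments))
  joined <- merge(ext$valid_reads, sim$reads$segments,
                  by = c("record_id", "subread_index"))
  joined <- merge(joined, sim$molecules, by = "molecule_id")
  expect_true(all(joined$barcode_id == joined$cell))
  expect_true(all(joined$umi.x == joined$umi.y))
  expect_true(all(joined$case.x == joined$case.y))
  # demultiplexing partitions the valid reads
  expect_true(all(table(ext$valid_reads$read_id) == 1L))
})

test_that("extraction tolerates 2-substitution adapter corruption", {
  set.seed(101)
  cfg <- sim_config(n_genes = 4L, n_cells = 2L, molecules_per_cell = 50L,
                    concatemer_rate = 0, reads_per_umi_mean = 1,
                    p_case2 = 0, seed = 51L)
  mod <- generate_gene_models(cfg)
  mol <- sample_true_molecules(mod, cfg)
  reads <- emit_reads(mol, mod, cfg)
  corrupt_at <- function(s, pos_offsets) {
    ch <- strsplit(s, "")[[1L]]
    for (p in pos_offsets)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
  }
  # corrupt 2 bases of the leading barcode and 2 of the adapter
  fq <- vapply(reads$fastq, function(s)
    corrupt_at(s, c(sample(1:16, 2L), 16L + sample(1:21, 2L))),
    character(1))
  names(fq) <- names(reads$fastq)
  ext <- extract_reads(fq, default_barcodes(2L))
  joined <- merge(ext$valid_reads, reads$segments,
                  by = c("record_id", "subread_index"))
  joined <- merge(joined, mol, by = "molecule_id")
  recovered <- mean(mol$molecule_id %in%
                      joined$molecule_id[joined$umi.x == joined$umi.y])
  expect_gte(recovered, 0.99)
})
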
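# Per-read placement noise: end offsets uniform on {-e..e} at the 5' and
# 3' transcript ends, junction coordinate offsets uniform on {-j..j},
# all independent. Clamped so blocks keep length >= 10 and stay disjoint
# (the clamp is a safety net; with default gene geometry it never binds).
apply_read_noise <- function(blocks, strand, cfg) {
  blocks <- as_blocks(blocks)
  k <- nrow(blocks)
  unif <- function(e) if (e > 0L) sample(seq.int(-e, e), 1L) else 0L
  if (k > 1L && cfg$junction_noise > 0L) {
    for (j in seq_len(k - 1L)) {
      blocks[j, 2L] <- blocks[j, 2L] + unif(cfg$junction_noise)
      blocks[j + 1L, 1L] <- blocks[j + 1L, 1L] + unif(cfg$junction_noise)
    }
  }
  if (strand == "+") {
    blocks[1L, 1L] <- blocks[1L, 1L] + unif(cfg$end_noise_5p)
    blocks[k, 2L] <- blocks[k, 2L] + unif(cfg$end_noise_3p)
  } else {
    blocks[k, 2L] <- blocks[k, 2L] + unif(cfg$end_noise_5p)
    blocks[1L, 1L] <- blocks[1L, 1L] + unif(cfg$end_noise_3p)
  }
  # defensive clamps
  blocks[1L, 1L] <- max(blocks[1L, 1L], 0L)
  for (j in seq_len(k)) {
    if (j > 1L) blocks[j, 1L] <- max(blocks[j, 1L], blocks[j - 1L, 2L] + 1L)
    blocks[j, 2L] <- max(blocks[j, 2L], blocks[j, 1L] + 10L)
  }
  blocks
}

extract_template <- function(seqs, chrom, strand, blocks) {
  blocks <- as_blocks(blocks)
  s <- seqs[[chrom]]
  parts <- substring(s, blocks[, 1L] + 1L, blocks[, 2L])
  tmpl <- paste(parts, collapse = "")
  if (strand == "-") revcomp(tmpl) else tmpl
}

# Case-1 segment layout: barcode, Illumina adapter, UMI, GGG, template,
# poly-A, adapter reverse complement, barcode reverse complement. A
# case-2 segment (opposite strand read) is exactly the reverse
# complement of the case-1 string.
build_segment <- function(barcode, umi, template, polya_len, case) {
  s <- paste0(barcode, ILLUMINA_ADAPTER, umi, "GGG", template,
              strrep("A", polya_len),
              revcomp(ILLUMINA_ADAPTER), revcomp(barcode))
  if (case == 2L) revcomp(s) else s
}

#' Emit synthetic long reads
#'
#' Emits each molecule a geometric (>= 1) number of times, injects end
#' and junction placement noise per read, renders the STRT read grammar
#' in case-1 or (with probability `p_case2`) reverse-complement case-2
#' orientation, and ligates a fraction `concatemer_rate` of the emitted
#' segments end-to-end into 2-4-mer concatemer records, emulating
#' concatemerization during library circularization.
#'
#' @param molecules Truth table from [sample_true_molecules()].
#' @param models Combined `iso_models` covering every `chrom` used
#'   (endogenous plus ERCC).
#' @param cfg A [sim_config()].
#' @param fastq,reads_bed,truth_bed Optional output paths: the FASTQ
#'   (constant Q30 placeholder qualities), the per-segment alignment
#'   BED12 (noisy blocks; names `<record>/<subread>` match the read ids
#'   the extraction stage produces), and the noise-free truth BED12 (one
#'   line per molecule).
#' @return A list with `fastq` (named character vector of record
#'   sequences) and `segments` (one row per embedded molecule copy:
#'   `record_id`, `subread_index`, `arity`, `molecule_id`, `case`,
#'   `chrom`, `strand`, serialized noisy `blocks`).
#' @export
emit_reads <- function(molecules, models, cfg, fastq = NULL,
                       reads_bed = NULL, truth_bed = NULL) {
  if (nrow(molecules) == 0L) stop("empty molecule list")
  set.seed(cfg$seed + 2L)

  n_reads <- rgeom(nrow(molecules), prob = 1 / cfg$reads_per_umi_mean) + 1L
  seg_mol <- rep(seq_len(nrow(molecules)), n_reads)
  n_seg <- length(seg_mol)

  seg_seq <- character(n_seg)
  seg_case <- integer(n_seg)
  seg_blocks <- character(n_seg)
  for (i in seq_len(n_seg)) {
    m <- molecules[seg_mol[i], ]
    b <- apply_read_noise(parse_blocks(m$blocks), m$strand, cfg)
    tmpl <- extract_template(models$seqs, m$chrom, m$strand, b)
    case <- if (runif(1) < cfg$p_case2) 2L else 1L
    seg_seq[i] <- build_segment(m$barcode, m$umi, tmpl, cfg$polya_len, case)
    seg_case[i] <- case
    seg_blocks[i] <- format_blocks(b)
  }

  # group shuffled segments into monomer or 2-4-mer concatemer records
  ord <- sample.int(n_seg)
  rec_of <- integer(n_seg)   # record number per segment slot
  sub_of <- integer(n_seg)   # subread index within record
  rec <- 0L
  i <- 1L
  while (i <= n_seg) {
    rec <- rec + 1L
    k <- 1L
    if (runif(1) < cfg$concatemer_rate && n_seg - i >= 1L)
      k <- min(sample(2:4, 1L), n_seg - i + 1L)
    take <- ord[seq.int(i, i + k - 1L)]
    rec_of[take] <- rec
    sub_of[take] <- seq_len(k)
    i <- i + k
  }

  record_ids <- sprintf("read%06d", seq_len(rec))
  segments <- data.frame(
    record_id = record_ids[rec_of], subread_index = sub_of,
    arity = as.integer(table(rec_of)[as.character(rec_of)]),
    molecule_id = molecules$molecule_id[seg_mol],
    case = seg_case, chrom = molecules$chrom[seg_mol],
    strand = molecules$strand[seg_mol], blocks = seg_blocks,
    stringsAsFactors = FALSE
  )
  segments <- segments[order(segments$record_id, segments$subread_index), ]
  rownames(segments) <- NULL

  o <- order(rec_of, sub_of)
  fq <- vapply(split(seg_seq[o], rec_of[o]), paste, character(1),
               collapse = "")
  names(fq) <- record_ids[as.integer(names(fq))]
  fq <- fq[record_ids]

  if (!is.null(fastq)) write_fastq(fq, fastq)
  if (!is.null(reads_bed)) {
    df <- segments
    df$name <- paste0(df$record_id, "/", df$subread_index)
    write_bed12(df[, c("chrom", "strand", "blocks", "name")], reads_bed)
  }
  if (!is.null(truth_bed)) {
    df <- molecules[, c("chrom", "strand", "blocks", "molecule_id")]
    names(df)[4L] <- "name"
    write_bed12(df, truth_bed)
  }
  list(fastq = fq, segments = segments)
}

#' Run the full synthetic data generator
#'
#' Convenience wrapper: gene models, optional ERCC reference, true
#' molecules and raw reads, optionally written to an output directory
#' (`genes.gtf`, `cds.bed`, `ercc.tsv`, `molecules.tsv`, `reads.fastq`,
#' `alignments.bed`, `truth.bed`).
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional output directory (created if missing).
#' @return A list with `cfg`, `models`, `ercc` (or `NULL`), `molecules`,
#'   and `reads` (the [emit_reads()] result).
#' @export
simulate_dataset <- function(cfg = sim_config(), outdir = NULL) {
  models <- generate_gene_models(cfg)
  ercc <- NULL
  if (cfg$ercc_per_cell > 0L)
    ercc <- generate_ercc_set(cfg$n_ercc, cfg$ercc_len_range[1],
                              cfg$ercc_len_range[2], seed = cfg$seed)
  combined <- if (is.null(ercc)) models else combine_models(models, ercc)

  paths <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      gtf = file.path(outdir, "genes.gtf"),
      cds = file.path(outdir, "cds.bed"),
      ercc = file.path(outdir, "ercc.tsv"),
      molecules = file.path(outdir, "molecules.tsv"),
      fastq = file.path(outdir, "reads.fastq"),
      reads_bed = file.path(outdir, "alignments.bed"),
      truth_bed = file.path(outdir, "truth.bed")
    )
    write_gene_annotation(models, paths$gtf, paths$cds)
    if (!is.null(ercc)) write_ercc_reference(ercc, paths$ercc)
  }
  molecules <- sample_true_molecules(models, cfg, ercc = ercc,
                                     path = paths$molecules)
  reads <- emit_reads(molecules, combined, cfg, fastq = paths$fastq,
                      reads_bed = paths$reads_bed,
                      truth_bed = paths$truth_bed)
  list(cfg = cfg, models = models, ercc = ercc, molecules = molecules,
       reads = reads)
}
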
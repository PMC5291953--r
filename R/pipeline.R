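# Pipeline orchestration: config validation, staged execution with
# per-stage loss accounting, and a reproducibility manifest.

config_defaults <- function() {
  list(
    seed = 1L,
    simulate = formals(sim_config),
    extract = list(max_mm = 2L, proximity = 10L, max_g_run = 5L),
    assemble = list(gap_lt = 40L, exclude = "ERCC-00074",
                    full_length_tol = 5L),
    isoforms = list(link_dist = 5L, junction_tol = 1L),
    stats = list(clamp_tol = 5L, premature_frac = 0.15,
                 ercc_within = c(1L, 5L), min_transcripts = 10L)
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a nested list) with one section per
#' stage (`simulate`, `extract`, `assemble`, `isoforms`, `stats`) plus a
#' top-level `seed`, fills defaults (2-mismatch adapter matching, 10 bp
#' proximity, 40 bp gap merge, 5 bp end-cluster link distance, 1 bp
#' junction tolerance, 10-base homopolymer tails), and reports unknown
#' keys and out-of-range values collectively.
#'
#' @param config Path to a YAML file, a list, or `NULL` for defaults.
#' @return The normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  defaults <- config_defaults()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, paste("unknown section:", unknown))
  out <- list(seed = as.integer(config$seed %||% defaults$seed))
  for (section in setdiff(names(defaults), "seed")) {
    given <- config[[section]] %||% list()
    allowed <- names(defaults[[section]])
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      errors <- c(errors, paste0("unknown key: ", section, ".", bad))
    merged <- utils::modifyList(
      lapply(defaults[[section]], function(x)
        if (is.language(x)) eval(x) else x),
      given[intersect(names(given), allowed)])
    out[[section]] <- merged
  }
  out$simulate$seed <- out$seed
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(out$extract$max_mm >= 0, "extract.max_mm must be >= 0")
  chk(out$extract$proximity >= 0, "extract.proximity must be >= 0")
  chk(out$assemble$gap_lt >= 0, "assemble.gap_lt must be >= 0")
  chk(out$isoforms$link_dist >= 0, "isoforms.link_dist must be >= 0")
  chk(out$isoforms$junction_tol >= 0,
      "isoforms.junction_tol must be >= 0")
  cfg_try <- tryCatch(do.call(sim_config, out$simulate),
                      error = function(e) conditionMessage(e))
  if (is.character(cfg_try)) errors <- c(errors, cfg_try)
  else out$simulate <- cfg_try
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Simulate, extract, assemble, build isoforms at all three levels, and
#' compute the summary statistics, writing every stage artifact plus a
#' reproducibility manifest (`manifest.json`) and a plain-text report
#' under one run directory. The manifest records the configuration
#' hash, seed, per-stage input/output counts and rejection reasons;
#' counts are conserved (subreads in = valid reads + rejections).
#'
#' @param config Configuration (path, list, or `NULL`), see
#'   [validate_config()].
#' @param outdir Run directory (created if needed).
#' @return Invisibly, a list with all stage results and the `manifest`.
#' @export
run_pipeline <- function(config = NULL, outdir) {
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_dataset(cfg$simulate, outdir = outdir)
  barcodes <- default_barcodes(cfg$simulate$n_cells)

  ext <- extract_reads(sim$reads$fastq, barcodes,
                       max_mm = cfg$extract$max_mm,
                       proximity = cfg$extract$proximity,
                       max_g_run = cfg$extract$max_g_run)

  models <- sim$models
  combined <- if (is.null(sim$ercc)) models else
    combine_models(models, sim$ercc)
  aln_bed <- file.path(outdir, "alignments.bed")
  aligned <- load_alignments(aln_bed, ext$valid_reads,
                             gap_lt = cfg$assemble$gap_lt)
  aligned <- annotate_genes(aligned, models, sim$ercc)
  transcripts <- build_transcripts(aligned,
                                   exclude = cfg$assemble$exclude)
  write_transcripts(transcripts, bed = file.path(outdir, "transcripts.bed"),
                    tsv = file.path(outdir, "transcripts.tsv"))
  full_length <- filter_full_length(transcripts, models,
                                    tol = cfg$assemble$full_length_tol)

  iso_full <- assign_isoforms(transcripts, models,
                              link_dist = cfg$isoforms$link_dist)
  iso_full_fl <- assign_isoforms(full_length, models,
                                 link_dist = cfg$isoforms$link_dist)
  iso_cons <- collapse_conservative(iso_full_fl,
                                    junction_tol = cfg$isoforms$junction_tol)
  iso_cass <- cassette_isoforms(full_length, models)
  isoforms <- rbind(iso_full, iso_cons, iso_cass)
  write.table(isoforms, file.path(outdir, "isoforms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  offsets <- transcript_offsets(transcripts, models)
  offsets <- label_coding(offsets, models)
  umi_off <- within_umi_offsets(aligned)
  rel_ends <- relative_end_positions(
    transcripts, models, clamp_tol = cfg$stats$clamp_tol,
    premature_frac = cfg$stats$premature_frac)
  events <- count_events(transcripts, models,
                         link_dist = cfg$isoforms$link_dist,
                         junction_tol = cfg$isoforms$junction_tol,
                         by_cell = TRUE)
  cn_test <- if (nrow(offsets)) coding_vs_noncoding_test(offsets) else NULL
  ercc_acc <- if (!is.null(sim$ercc))
    ercc_end_offsets(transcripts, sim$ercc,
                     within = cfg$stats$ercc_within) else NULL
  sharing <- if (cfg$simulate$n_cells >= 2L && nrow(iso_cons))
    isoform_sharing(iso_cons) else NULL
  major <- major_isoform_fraction(iso_cons,
                                  min_transcripts = cfg$stats$min_transcripts)

  manifest <- build_manifest(cfg, sim, ext, aligned, transcripts,
                             full_length, isoforms)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_report(file.path(outdir, "report.md"), manifest, events,
               rel_ends, cn_test, ercc_acc, sharing, major)

  invisible(list(
    cfg = cfg, sim = sim, extraction = ext, aligned = aligned,
    transcripts = transcripts, full_length = full_length,
    isoforms = isoforms, offsets = offsets, umi_offsets = umi_off,
    relative_ends = rel_ends, events = events,
    coding_test = cn_test, ercc_accuracy = ercc_acc, sharing = sharing,
    major_isoform = major, manifest = manifest
  ))
}

build_manifest <- function(cfg, sim, ext, aligned, transcripts,
                           full_length, isoforms) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[setdiff(names(cfg), "simulate")], tmp)
  reject_counts <- as.list(table(ext$rejects$reason))
  list(
    tool = "isoscope",
    version = as.character(utils::packageVersion("isoscope")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(tmp)),
    counts = list(
      molecules = nrow(sim$molecules),
      fastq_records = length(sim$reads$fastq),
      embedded_segments = nrow(sim$reads$segments),
      subreads = nrow(ext$valid_reads) + nrow(ext$rejects),
      valid_reads = nrow(ext$valid_reads),
      rejected = nrow(ext$rejects),
      aligned = nrow(aligned),
      gene_assigned = sum(!is.na(aligned$gene_id)),
      transcripts = nrow(transcripts),
      full_length_transcripts = nrow(full_length),
      isoforms_full = sum(isoforms$level == "full"),
      isoforms_conservative = sum(isoforms$level == "conservative"),
      isoforms_cassette = sum(isoforms$level == "cassette")
    ),
    rejection_reasons = reject_counts
  )
}

write_report <- function(path, manifest, events, rel_ends, cn_test,
                         ercc_acc, sharing, major) {
  lines <- c(
    "# isoscope run report", "",
    "## Per-stage accounting", "",
    paste0("- ", names(manifest$counts), ": ",
           unlist(manifest$counts)), "",
    "## Isoform event mix (% of events)", "",
    paste0("- ", names(events$mix), ": ", round(events$mix, 1)), "",
    paste0("- premature 3' termination fraction: ",
           signif(rel_ends$premature_fraction, 3))
  )
  if (!is.null(cn_test))
    lines <- c(lines, "", "## Coding vs non-coding junction variability",
               "", paste0("- ", cn_test$site_kind, " (", cn_test$method,
                          "): p = ", signif(cn_test$p_value, 3)))
  if (!is.null(ercc_acc))
    lines <- c(lines, "", "## ERCC end accuracy", "",
               paste0("- ", ercc_acc$summary$site, " within ",
                      ercc_acc$summary$within, " bp: ",
                      round(100 * ercc_acc$summary$fraction, 1), "%"))
  if (!is.null(sharing))
    lines <- c(lines, "", "## Isoform sharing", "",
               paste0("- shared by any two cells: ",
                      round(100 * sharing$any_two_fraction, 1), "%"),
               paste0("- shared by all cells: ",
                      round(100 * sharing$all_fraction, 1), "%"))
  if (nrow(major$per_gene))
    lines <- c(lines, "", paste0("- mean major-isoform fraction: ",
                                 signif(major$mean_fraction, 3)))
  writeLines(lines, path)
  invisible(path)
}
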
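#' Simulation configuration
#'
#' Parameters of the synthetic dataset generator. The generator emulates
#' the STRT long-read grammar (16 bp sample barcode, Illumina adapter,
#' 6 bp UMI, GGG, template, poly-A, and the reverse-complement layout when
#' the opposite strand is read), concatemerization during circularization,
#' PCR read redundancy per UMI, 5' degradation, alternative TSS/TTS and
#' cassette usage, junction and end placement noise, and ERCC spike-ins of
#' known ends.
#'
#' @param n_genes Number of endogenous gene models.
#' @param n_cells Number of cells (one sample barcode each, max 6).
#' @param exon_count_range,exon_len_range,intron_len_range Integer ranges
#'   (inclusive) the gene structure is drawn from.
#' @param gene_spacing Intergenic distance in bp on the simulated
#'   chromosome.
#' @param utr_margin Exonic bp at each transcript end excluded from the
#'   CDS, so that both coding and non-coding junction classes occur.
#' @param isoforms_per_gene Number of distinct exon structures per gene.
#'   Structure 1 uses all exons; structure k (k >= 2) drops internal exon
#'   k, so alternative structures differ in adjacent cassette exons.
#' @param isoform_weights Sampling weights of the structures; the default
#'   makes the major isoform about half of gene expression.
#' @param tss_sites_per_gene,tts_sites_per_gene Number of alternative
#'   transcription start/termination sites per gene, spaced
#'   `tss_site_spacing` bp apart inside the first/last exon.
#' @param tss_site_spacing Spacing (bp) between alternative end sites;
#'   larger than the 5 bp end-cluster link distance so configured sites
#'   map to distinct clusters.
#' @param molecules_per_cell Endogenous molecules sampled per cell.
#' @param ercc_per_cell ERCC spike-in molecules sampled per cell.
#' @param reads_per_umi_mean Mean of the geometric (>= 1) read-redundancy
#'   distribution per molecule. The default 1.6 makes about 60% of UMIs
#'   singletons.
#' @param concatemer_rate Fraction of emitted FASTQ records that are
#'   end-to-end concatemers of 2-4 molecules.
#' @param p_case2 Probability that a molecule copy is emitted as the
#'   reverse-complement (case 2) layout.
#' @param end_noise_5p,end_noise_3p Maximum absolute end placement offset
#'   in bp; offsets are uniform on `{-e, ..., e}` per read.
#' @param junction_noise Maximum absolute junction coordinate offset in
#'   bp, uniform per read and junction coordinate.
#' @param degradation_rate Probability that an endogenous molecule is 5'
#'   truncated to a random internal start (in exon 2 or later). The
#'   default reflects that in real single-cell data most transcript 5'
#'   ends do not reach the annotated first exon.
#' @param polya_len Length of the simulated poly-A tail (detection
#'   threshold downstream is a run of 10).
#' @param n_ercc,ercc_len_range Size and length range of the ERCC
#'   reference set.
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical
#'   across runs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       n_cells = 3L,
                       exon_count_range = c(4L, 8L),
                       exon_len_range = c(100L, 300L),
                       intron_len_range = c(200L, 1000L),
                       gene_spacing = 5000L,
                       utr_margin = 150L,
                       isoforms_per_gene = 3L,
                       isoform_weights = c(0.5, 0.3, 0.2),
                       tss_sites_per_gene = 1L,
                       tts_sites_per_gene = 1L,
                       tss_site_spacing = 25L,
                       molecules_per_cell = 500L,
                       ercc_per_cell = 0L,
                       reads_per_umi_mean = 1.6,
                       concatemer_rate = 0.33,
                       p_case2 = 0.5,
                       end_noise_5p = 0L,
                       end_noise_3p = 0L,
                       junction_noise = 0L,
                       degradation_rate = 0.7,
                       polya_len = 30L,
                       n_ercc = 92L,
                       ercc_len_range = c(255L, 2007L),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    exon_count_range = as.integer(exon_count_range),
    exon_len_range = as.integer(exon_len_range),
    intron_len_range = as.integer(intron_len_range),
    gene_spacing = as.integer(gene_spacing),
    utr_margin = as.integer(utr_margin),
    isoforms_per_gene = as.integer(isoforms_per_gene),
    isoform_weights = as.numeric(isoform_weights),
    tss_sites_per_gene = as.integer(tss_sites_per_gene),
    tts_sites_per_gene = as.integer(tts_sites_per_gene),
    tss_site_spacing = as.integer(tss_site_spacing),
    molecules_per_cell = as.integer(molecules_per_cell),
    ercc_per_cell = as.integer(ercc_per_cell),
    reads_per_umi_mean = as.numeric(reads_per_umi_mean),
    concatemer_rate = as.numeric(concatemer_rate),
    p_case2 = as.numeric(p_case2),
    end_noise_5p = as.integer(end_noise_5p),
    end_noise_3p = as.integer(end_noise_3p),
    junction_noise = as.integer(junction_noise),
    degradation_rate = as.numeric(degradation_rate),
    polya_len = as.integer(polya_len),
    n_ercc = as.integer(n_ercc),
    ercc_len_range = as.integer(ercc_len_range),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_genes >= 1L, n_cells >= 1L, n_cells <= length(PACBIO_BARCODES),
      length(exon_count_range) == 2L, exon_count_range[1] >= 2L,
      diff(exon_count_range) >= 0L,
      exon_len_range[1] >= 20L, diff(exon_len_range) >= 0L,
      intron_len_range[1] >= 50L, diff(intron_len_range) >= 0L,
      isoforms_per_gene >= 1L,
      length(isoform_weights) == isoforms_per_gene,
      all(isoform_weights > 0),
      tss_sites_per_gene >= 1L, tts_sites_per_gene >= 1L,
      tss_site_spacing > 0L,
      molecules_per_cell >= 0L, ercc_per_cell >= 0L,
      reads_per_umi_mean >= 1,
      concatemer_rate >= 0, concatemer_rate <= 1,
      p_case2 >= 0, p_case2 <= 1,
      end_noise_5p >= 0L, end_noise_3p >= 0L, junction_noise >= 0L,
      degradation_rate >= 0, degradation_rate <= 1,
      polya_len >= 10L,
      n_ercc >= 1L, ercc_len_range[1] >= 50L, diff(ercc_len_range) >= 0L,
      is.finite(seed)
    )
    # alternative structures drop internal exon k (k = 2..isoforms), so the
    # smallest exon count must leave enough internal exons
    if (isoforms_per_gene > 1L &&
        exon_count_range[1] < isoforms_per_gene + 1L)
      stop("exon_count_range too small for the requested number of ",
           "alternative exon structures")
    # alternative end sites must fit inside the first/last exon
    if (max(tss_sites_per_gene, tts_sites_per_gene) > 1L &&
        (max(tss_sites_per_gene, tts_sites_per_gene) - 1L) *
          tss_site_spacing >= exon_len_range[1] - 20L)
      stop("alternative TSS/TTS sites do not fit in the shortest exon")
  })
  invisible(cfg)
}
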
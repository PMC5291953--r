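# File formats: FASTQ via Biostrings; BED12 and GTF via rtracklayer.
# Internally all coordinates are 0-based half-open; BED12 is native in
# that convention, GTF (1-based inclusive) is converted on read/write.

#' Read and write FASTQ
#'
#' Thin wrappers around Biostrings. Written qualities are a constant Q30
#' placeholder (the pipeline does not use quality values).
#'
#' @param seqs Named character vector of read sequences.
#' @param path File path.
#' @return `read_fastq()` returns a named character vector.
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(nchar(seqs), strrep, character(1),
                                     x = "?"))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read and write BED12
#'
#' @param df Data frame with columns `chrom`, `strand`, `blocks`
#'   (serialized 0-based half-open blocks), `name`, and optionally
#'   `score`.
#' @param path File path.
#' @return `read_bed12()` returns a data frame with `name`, `chrom`,
#'   `strand`, `score` and serialized absolute `blocks`.
#' @export
write_bed12 <- function(df, path) {
  stopifnot(all(c("chrom", "strand", "blocks", "name") %in% names(df)))
  bl <- lapply(df$blocks, parse_blocks)
  first <- vapply(bl, function(b) b[1L, 1L], integer(1))
  last <- vapply(bl, function(b) b[nrow(b), 2L], integer(1))
  rel <- IRanges::IRangesList(lapply(seq_along(bl), function(i)
    IRanges::IRanges(start = bl[[i]][, 1L] - first[i] + 1L,
                     end = bl[[i]][, 2L] - first[i])))
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(first + 1L, last), strand = df$strand,
    name = df$name,
    score = if ("score" %in% names(df)) df$score else 0L,
    blocks = rel
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed12
#' @export
read_bed12 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e)
                   stop("malformed BED12 file '", path, "': ",
                        conditionMessage(e)))
  off <- GenomicRanges::start(gr) - 1L  # 0-based feature start
  if (!is.null(gr$blocks)) {
    s_list <- as.list(IRanges::start(gr$blocks))
    e_list <- as.list(IRanges::end(gr$blocks))
    blocks <- vapply(seq_along(gr), function(i)
      paste(paste0(off[i] + s_list[[i]] - 1L, "-", off[i] + e_list[[i]]),
            collapse = ","), character(1))
  } else {
    blocks <- paste0(off, "-", GenomicRanges::end(gr))
  }
  data.frame(
    name = if (is.null(gr$name)) as.character(seq_along(gr)) else gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    score = if (is.null(gr$score)) 0 else as.numeric(gr$score),
    blocks = blocks, stringsAsFactors = FALSE
  )
}

#' Write gene models as GTF plus coding-interval BED
#'
#' One transcript per gene (the reference structure); CDS intervals go to
#' a BED6 file named by gene, the convention used for CCDS-style coding
#' annotation.
#'
#' @param models An `iso_models` object.
#' @param gtf,cds_bed Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_gene_annotation <- function(models, gtf = NULL, cds_bed = NULL) {
  genes <- models$genes
  if (!is.null(gtf)) {
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      ex <- parse_blocks(genes$exons[i])
      GenomicRanges::GRanges(
        genes$chrom[i],
        IRanges::IRanges(ex[, 1L] + 1L, ex[, 2L]),
        strand = genes$strand[i], type = "exon",
        gene_id = genes$gene_id[i],
        transcript_id = paste0(genes$gene_id[i], ".ref")
      )
    })
    rtracklayer::export(do.call(c, rows), gtf, format = "gtf")
  }
  if (!is.null(cds_bed)) {
    keep <- !is.na(genes$cds)
    rows <- lapply(which(keep), function(i) {
      cds <- parse_blocks(genes$cds[i])
      data.frame(chrom = genes$chrom[i], start = cds[, 1L],
                 end = cds[, 2L], name = genes$gene_id[i], score = 0L,
                 strand = genes$strand[i])
    })
    df <- do.call(rbind, rows)
    write.table(df, cds_bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(list(gtf = gtf, cds_bed = cds_bed))
}

#' Read gene models from GTF plus coding BED
#'
#' Rebuilds the `iso_models` gene table (without sequences) from a GTF of
#' exon features (one transcript per gene) and an optional BED of coding
#' intervals named by gene.
#'
#' @param gtf Path to the GTF.
#' @param cds_bed Optional path to the coding-interval BED.
#' @return An `iso_models` object with an empty `seqs` slot.
#' @export
read_gene_annotation <- function(gtf, cds_bed = NULL) {
  gr <- rtracklayer::import(gtf)
  gr <- gr[gr$type == "exon"]
  ids <- unique(gr$gene_id)
  cds_map <- list()
  if (!is.null(cds_bed)) {
    cds <- read.table(cds_bed, sep = "\t", stringsAsFactors = FALSE)
    names(cds)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
    cds_map <- lapply(split(cds, cds$name), function(d) {
      d <- d[order(d$start), ]
      format_blocks(cbind(d$start, d$end))
    })
  }
  rows <- lapply(ids, function(id) {
    g <- gr[gr$gene_id == id]
    g <- g[order(GenomicRanges::start(g))]
    ex <- cbind(GenomicRanges::start(g) - 1L, GenomicRanges::end(g))
    strand <- as.character(GenomicRanges::strand(g))[1L]
    data.frame(
      gene_id = id, chrom = as.character(GenomicRanges::seqnames(g))[1L],
      strand = strand, n_exons = nrow(ex),
      tss = if (strand == "+") ex[1L, 1L] else ex[nrow(ex), 2L],
      tts = if (strand == "+") ex[nrow(ex), 2L] else ex[1L, 1L],
      exons = format_blocks(ex),
      cds = if (!is.null(cds_map[[id]])) cds_map[[id]] else NA_character_,
      is_ercc = FALSE, stringsAsFactors = FALSE
    )
  })
  structure(list(genes = do.call(rbind, rows), seqs = character(0)),
            class = "iso_models")
}

#' Read and write the ERCC reference table
#'
#' A two-column TSV (`id`, `length`) describing spike-in species with
#' exactly known ends.
#'
#' @param ercc An ERCC `iso_models` object.
#' @param path File path.
#' @return `read_ercc_reference()` returns an `iso_models` object
#'   (without sequences).
#' @export
write_ercc_reference <- function(ercc, path) {
  lens <- vapply(ercc$genes$exons, function(x) parse_blocks(x)[1L, 2L],
                 integer(1))
  write.table(data.frame(id = ercc$genes$gene_id, length = lens),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ercc_reference
#' @export
read_ercc_reference <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = df$id, chrom = df$id, strand = "+", n_exons = 1L,
    tss = 0L, tts = df$length, exons = paste0("0-", df$length),
    cds = NA_character_, is_ercc = TRUE, stringsAsFactors = FALSE
  )
  structure(list(genes = genes, seqs = character(0)), class = "iso_models")
}

#' Write transcripts as BED12 plus TSV sidecar
#'
#' BED12 names are `cell:gene:umi`, the score column carries the read
#' support of each UMI consensus.
#'
#' @param transcripts Transcript table from [build_transcripts()].
#' @param bed,tsv Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_transcripts <- function(transcripts, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    df <- transcripts
    df$name <- df$transcript_id
    df$score <- df$read_support
    write_bed12(df[, c("chrom", "strand", "blocks", "name", "score")], bed)
  }
  if (!is.null(tsv))
    write.table(transcripts, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(bed = bed, tsv = tsv))
}
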
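# Read extraction: adapter matching with mismatches, concatemer
# splitting at internal adapter pairs, case-1/case-2 grammar parsing,
# UMI and template trimming, and artifact filtering.

#' Find adapter matches in a read
#'
#' Scans a sequence for every adapter and its reverse complement,
#' allowing up to `max_mm` substitutions (Hamming matching; the inputs
#' are circular-consensus sequences where substitutions dominate).
#' Overlapping matches of the same adapter are resolved by keeping the
#' lower-mismatch (tie: leftmost) hit.
#'
#' @param seq A character string or `DNAString`.
#' @param adapters Named character vector of adapter sequences; reverse
#'   complements are searched automatically and reported with a `_rc`
#'   suffix on the name.
#' @param max_mm Maximum number of substitutions (default 2).
#' @return A data frame sorted by position: `which`, `start`, `end`
#'   (1-based inclusive), `mismatches`.
#' @export
find_adapters <- function(seq,
                          adapters = c(illumina = ILLUMINA_ADAPTER,
                                       default_barcodes()),
                          max_mm = 2L) {
  stopifnot(length(adapters) >= 1L, max_mm >= 0L)
  subject <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(seq)
  pats <- adapter_patterns(adapters)
  out <- lapply(names(pats), function(nm) {
    m <- Biostrings::matchPattern(pats[[nm]], subject,
                                  max.mismatch = max_mm, fixed = TRUE)
    s <- Biostrings::start(m); e <- Biostrings::end(m)
    keep <- s >= 1L & e <= length(subject)
    s <- s[keep]; e <- e[keep]
    if (length(s) == 0L) return(NULL)
    seq_chr <- as.character(subject)
    mm <- hamming_mm(as.character(pats[[nm]]), substring(seq_chr, s, e))
    data.frame(which = nm, start = s, end = e, mismatches = mm,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df))
    return(data.frame(which = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0)))
  resolve_overlaps(df)
}

adapter_patterns <- function(adapters) {
  stopifnot(!is.null(names(adapters)), all(nzchar(names(adapters))))
  pats <- c(as.list(adapters),
            setNames(as.list(revcomp(unlist(adapters))),
                     paste0(names(adapters), "_rc")))
  lapply(pats, Biostrings::DNAString)
}

# Keep, per adapter, a best-first non-overlapping subset of matches.
resolve_overlaps <- function(df) {
  parts <- lapply(split(df, df$which), function(d) {
    d <- d[order(d$mismatches, d$start), ]
    kept <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      ok <- !any(kept & d$start <= d$end[i] & d$end >= d$start[i])
      kept[i] <- ok
    }
    d[kept, ]
  })
  df <- do.call(rbind, parts)
  df <- df[order(df$start), ]
  rownames(df) <- NULL
  df
}

is_barcode_match <- function(which) {
  !startsWith(which, "illumina")
}

#' Split a concatemer read into subread intervals
#'
#' Each embedded molecule starts with a forward sample barcode and ends
#' with a barcode reverse complement, so a read is partitioned at every
#' boundary where a barcode reverse-complement match is immediately
#' followed (in match order) by a forward barcode match. A read with a
#' single embedded structure, or with no adapter matches at all, yields
#' one interval spanning the whole read.
#'
#' @param matches Adapter match table from [find_adapters()].
#' @param read_len Read length in bp.
#' @return A data frame of 1-based inclusive intervals (`start`, `end`).
#' @export
split_concatemers <- function(matches, read_len) {
  cuts <- integer(0)
  bm <- matches[is_barcode_match(matches$which), , drop = FALSE]
  if (nrow(matches) >= 2L) {
    is_rc <- endsWith(matches$which, "_rc")
    is_bc <- is_barcode_match(matches$which)
    for (i in seq_len(nrow(matches) - 1L)) {
      if (is_bc[i] && is_rc[i] && is_bc[i + 1L] && !is_rc[i + 1L])
        cuts <- c(cuts, (matches$end[i] + matches$start[i + 1L]) %/% 2L)
    }
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, read_len)
  data.frame(start = starts, end = ends)
}

#' Parse one subread interval into a valid read
#'
#' A subread is valid when one sample barcode and its reverse complement
#' are identified with no other barcode in between, the barcode is
#' adjacent (within `proximity` bp) to the Illumina adapter, and the
#' molecule carries a homopolymer tail of at least 10 bases: an A-run
#' before the reverse-complement adapter (case 1) or a T-run after the
#' forward adapter (case 2; the read is reverse complemented into
#' transcript orientation and re-parsed). The UMI is the 6 bases after
#' the adapter end; the template is trimmed of adapters, UMI, the
#' template-switch G-run (at most `max_g_run` G) and the poly-A tail.
#'
#' @param seq Subread sequence (character).
#' @param barcodes Named character vector of sample barcodes.
#' @param matches Optional precomputed [find_adapters()] table for `seq`.
#' @param max_mm,proximity Matching tolerance and adjacency window (bp).
#' @param max_g_run Maximal length of the trimmed template-switch G-run.
#' @return A list: either `valid = TRUE` with `barcode_id`, `barcode`,
#'   `umi`, `case`, `template_seq`, `has_polya`, or `valid = FALSE` with
#'   a `reason` in `no_barcode`, `barcode_conflict`, `no_adapter`,
#'   `no_polya`, `empty_template`.
#' @export
parse_valid_read <- function(seq, barcodes = default_barcodes(),
                             matches = NULL, max_mm = 2L,
                             proximity = 10L, max_g_run = 5L) {
  if (is.null(matches))
    matches <- find_adapters(seq, c(illumina = ILLUMINA_ADAPTER, barcodes),
                             max_mm = max_mm)
  reject <- function(reason) list(valid = FALSE, reason = reason)

  bm <- matches[is_barcode_match(matches$which), , drop = FALSE]
  ids <- unique(sub("_rc$", "", bm$which))
  if (length(ids) == 0L) return(reject("no_barcode"))
  if (length(ids) >= 2L) return(reject("barcode_conflict"))
  id <- ids[1L]
  fwd <- bm[bm$which == id, , drop = FALSE]
  rcm <- bm[bm$which == paste0(id, "_rc"), , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rcm) == 0L) return(reject("no_barcode"))
  fwd <- fwd[1L, ]                 # leftmost forward barcode
  rcm <- rcm[nrow(rcm), ]          # rightmost reverse complement
  if (rcm$start <= fwd$end) return(reject("no_barcode"))

  im <- matches[matches$which == "illumina", , drop = FALSE]
  im <- im[im$start > fwd$end & im$start - fwd$end - 1L <= proximity, ,
           drop = FALSE]
  if (nrow(im) == 0L) return(reject("no_adapter"))
  im <- im[1L, ]
  rci <- matches[matches$which == "illumina_rc", , drop = FALSE]
  rci <- rci[rci$end < rcm$start & rcm$start - rci$end - 1L <= proximity, ,
             drop = FALSE]
  if (nrow(rci) == 0L) return(reject("no_adapter"))
  rci <- rci[nrow(rci), ]

  # case 2: a T-run of >= 10 starting within the proximity window after
  # the forward adapter; reverse complement and re-parse as case 1
  t_runs <- homopolymer_runs(seq, "T")
  is_case2 <- any(t_runs$end > im$end &
                  t_runs$start <= im$end + proximity + 1L)
  if (is_case2) {
    res <- parse_valid_read(revcomp(seq), barcodes,
                            matches = flip_matches(matches, nchar(seq)),
                            max_mm = max_mm, proximity = proximity,
                            max_g_run = max_g_run)
    if (res$valid) res$case <- 2L
    return(res)
  }

  a_runs <- homopolymer_runs(seq, "A")
  a_runs <- a_runs[a_runs$start < rci$start &
                   a_runs$end >= rci$start - proximity - 1L &
                   a_runs$start > im$end + 6L, , drop = FALSE]
  if (nrow(a_runs) == 0L) return(reject("no_polya"))
  polya_start <- a_runs$start[nrow(a_runs)]

  if (im$end + 6L >= polya_start) return(reject("empty_template"))
  umi <- substr(seq, im$end + 1L, im$end + 6L)
  pos <- im$end + 7L
  g <- 0L
  while (g < max_g_run && pos + g < polya_start &&
         substr(seq, pos + g, pos + g) == "G")
    g <- g + 1L
  if (pos + g > polya_start - 1L) return(reject("empty_template"))
  template <- substr(seq, pos + g, polya_start - 1L)
  list(valid = TRUE, barcode_id = id, barcode = unname(barcodes[id]),
       umi = umi, case = 1L, template_seq = template, has_polya = TRUE)
}

# Runs of >= 10 identical bases.
homopolymer_runs <- function(seq, base) {
  m <- gregexpr(paste0(base, "{10,}"), seq)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Map a match table onto the reverse complement of its read.
flip_matches <- function(matches, read_len) {
  out <- matches
  out$start <- read_len - matches$end + 1L
  out$end <- read_len - matches$start + 1L
  out$which <- ifelse(endsWith(matches$which, "_rc"),
                      sub("_rc$", "", matches$which),
                      paste0(matches$which, "_rc"))
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

#' Poly-A/poly-T artifact filter
#'
#' A trimmed template that still contains both an A-homopolymer and a
#' T-homopolymer of at least 10 bases is flagged as a likely PCR
#' artifact and dropped.
#'
#' @param template_seq Trimmed template sequence.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_polya_polyt <- function(template_seq) {
  !(grepl("A{10,}", template_seq) && grepl("T{10,}", template_seq))
}

#' Extract valid reads from raw FASTQ records
#'
#' The full extraction stage: adapter matching, concatemer splitting,
#' grammar parsing and artifact filtering, batched over all records.
#'
#' @param fastq FASTQ path or named character vector of read sequences.
#' @param barcodes Named character vector of sample barcodes in use.
#' @param max_mm,proximity,max_g_run See [parse_valid_read()].
#' @return A list with `valid_reads` (one row per accepted subread:
#'   `read_id` = `<record>/<subread>`, `record_id`, `subread_index`,
#'   `barcode_id`, `barcode`, `umi`, `case`, `template_seq`,
#'   `has_polya`) and `rejects` (`read_id`, `reason`).
#' @export
extract_reads <- function(fastq, barcodes = default_barcodes(),
                          max_mm = 2L, proximity = 10L, max_g_run = 5L) {
  seqs <- if (is.character(fastq) && length(fastq) == 1L &&
              file.exists(fastq)) read_fastq(fastq) else fastq
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  adapters <- c(illumina = ILLUMINA_ADAPTER, barcodes)
  match_list <- batch_find_adapters(seqs, adapters, max_mm)

  valid <- list()
  rejects <- list()
  for (r in seq_along(seqs)) {
    rec_id <- names(seqs)[r]
    seq <- seqs[[r]]
    matches <- match_list[[r]]
    intervals <- split_concatemers(matches, nchar(seq))
    for (k in seq_len(nrow(intervals))) {
      a <- intervals$start[k]; b <- intervals$end[k]
      sub_seq <- substr(seq, a, b)
      sub_m <- matches[matches$start >= a & matches$end <= b, ,
                       drop = FALSE]
      sub_m$start <- sub_m$start - a + 1L
      sub_m$end <- sub_m$end - a + 1L
      res <- parse_valid_read(sub_seq, barcodes, matches = sub_m,
                              max_mm = max_mm, proximity = proximity,
                              max_g_run = max_g_run)
      rid <- paste0(rec_id, "/", k)
      if (res$valid && !filter_polya_polyt(res$template_seq)) {
        res <- list(valid = FALSE, reason = "polya_polyt_artifact")
      }
      if (res$valid) {
        valid[[length(valid) + 1L]] <- data.frame(
          read_id = rid, record_id = rec_id, subread_index = k,
          barcode_id = res$barcode_id, barcode = res$barcode,
          umi = res$umi, case = res$case,
          template_seq = res$template_seq, has_polya = res$has_polya,
          stringsAsFactors = FALSE
        )
      } else {
        rejects[[length(rejects) + 1L]] <- data.frame(
          read_id = rid, reason = res$reason, stringsAsFactors = FALSE
        )
      }
    }
  }
  empty_valid <- data.frame(
    read_id = character(0), record_id = character(0),
    subread_index = integer(0), barcode_id = character(0),
    barcode = character(0), umi = character(0), case = integer(0),
    template_seq = character(0), has_polya = logical(0)
  )
  list(
    valid_reads = if (length(valid)) do.call(rbind, valid) else empty_valid,
    rejects = if (length(rejects)) do.call(rbind, rejects) else
      data.frame(read_id = character(0), reason = character(0))
  )
}

# One vmatchPattern sweep per adapter orientation over all records.
batch_find_adapters <- function(seqs, adapters, max_mm) {
  subject <- Biostrings::DNAStringSet(seqs)
  pats <- adapter_patterns(adapters)
  per_read <- rep(list(NULL), length(seqs))
  for (nm in names(pats)) {
    mi <- Biostrings::vmatchPattern(pats[[nm]], subject,
                                    max.mismatch = max_mm, fixed = TRUE)
    hits <- which(S4Vectors::elementNROWS(mi) > 0L)
    pat_chr <- as.character(pats[[nm]])
    ir <- as.list(mi[hits])
    for (h in seq_along(hits)) {
      i <- hits[h]
      s <- Biostrings::start(ir[[h]]); e <- Biostrings::end(ir[[h]])
      keep <- s >= 1L & e <= nchar(seqs[[i]])
      s <- s[keep]; e <- e[keep]
      if (length(s) == 0L) next
      mm <- hamming_mm(pat_chr, substring(seqs[[i]], s, e))
      per_read[[i]] <- rbind(per_read[[i]], data.frame(
        which = nm, start = s, end = e, mismatches = mm,
        stringsAsFactors = FALSE))
    }
  }
  lapply(per_read, function(df) {
    if (is.null(df))
      data.frame(which = character(0), start = integer(0),
                 end = integer(0), mismatches = integer(0))
    else resolve_overlaps(df)
  })
}
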
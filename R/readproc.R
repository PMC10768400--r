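# Read processing: FASTQ IO, dual-barcode demultiplexing and
# Trimmomatic-semantics quality trimming.

#' Read a FASTQ file (phred+33; plain or gzipped)
#' @param path FASTQ path.
#' @return list with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # the constructor drops the (unused) metadata columns; that is fine
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(id = names(x), seq = as.character(x),
       qual = as.character(Biostrings::quality(x)))
}

#' Write a FASTQ file (phred+33)
#' @param id,seq,qual parallel character vectors.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Demultiplex a pooled paired-end FASTQ pair by dual 8-bp barcodes
#'
#' A read pair is assigned to a sample iff exactly one sample's
#' (forward, reverse) barcode pair matches the leading 8-mers of mate 1
#' and mate 2 within `max_mismatch`; barcode bases are then removed from
#' both mates.  Pairs matching no sample are `unknown_barcode`, pairs
#' matching more than one sample are `ambiguous`; every input pair lands
#' in exactly one class.
#'
#' @param fastq1,fastq2 paths to the pooled mate files.
#' @param samples sample sheet data frame (sample_id, fwd_barcode,
#'   rev_barcode, ...).
#' @param max_mismatch allowed mismatches per barcode (0, the default, or 1).
#' @return list with `id`, `seq1`, `qual1`, `seq2`, `qual2` (barcode bases
#'   removed), `sample` (NA when unassigned), `status`
#'   (assigned/unknown_barcode/ambiguous) and a per-sample `report`.
#' @export
demultiplex <- function(fastq1, fastq2, samples, max_mismatch = 0) {
  stopifnot(max_mismatch %in% c(0, 1))
  if (any(nchar(samples$fwd_barcode) != 8) ||
      any(nchar(samples$rev_barcode) != 8))
    stop("barcodes must be exactly 8 bp")
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (length(r1$seq) != length(r2$seq))
    stop("mate files have unequal read counts")

  bc1 <- substring(r1$seq, 1, 8)
  bc2 <- substring(r2$seq, 1, 8)
  n <- length(bc1)

  if (max_mismatch == 0) {
    key <- paste(bc1, bc2)
    skey <- paste(samples$fwd_barcode, samples$rev_barcode)
    hit <- match(key, skey)
    sample <- samples$sample_id[hit]
    status <- ifelse(is.na(hit), "unknown_barcode", "assigned")
  } else {
    fset <- unique(samples$fwd_barcode)
    rset <- unique(samples$rev_barcode)
    d1 <- hamming_to_set_cpp(bc1, fset)   # n x |fset|
    d2 <- hamming_to_set_cpp(bc2, rset)
    fi <- match(samples$fwd_barcode, fset)
    ri <- match(samples$rev_barcode, rset)
    # count of samples whose barcode pair is within distance on both mates
    nmatch <- integer(n)
    hit <- rep(NA_integer_, n)
    for (s in seq_len(nrow(samples))) {
      ok <- d1[, fi[s]] <= max_mismatch & d2[, ri[s]] <= max_mismatch
      nmatch <- nmatch + ok
      hit[ok & is.na(hit)] <- s
    }
    status <- ifelse(nmatch == 0, "unknown_barcode",
                     ifelse(nmatch > 1, "ambiguous", "assigned"))
    hit[status != "assigned"] <- NA_integer_
    sample <- samples$sample_id[hit]
  }

  assigned <- status == "assigned"
  seq1 <- ifelse(assigned, substring(r1$seq, 9), r1$seq)
  qual1 <- ifelse(assigned, substring(r1$qual, 9), r1$qual)
  seq2 <- ifelse(assigned, substring(r2$seq, 9), r2$seq)
  qual2 <- ifelse(assigned, substring(r2$qual, 9), r2$qual)

  counts <- table(factor(sample, levels = samples$sample_id))
  report <- data.frame(sample = c(samples$sample_id, "unknown_barcode",
                                  "ambiguous"),
                       n_pairs = c(as.integer(counts),
                                   sum(status == "unknown_barcode"),
                                   sum(status == "ambiguous")),
                       stringsAsFactors = FALSE)
  report$fraction <- report$n_pairs / max(1L, n)
  list(id = r1$id, seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
       sample = sample, status = status, report = report)
}

#' Trimming parameters (Trimmomatic semantics)
#'
#' Defaults reproduce `LEADING:3 TRAILING:3 SLIDINGWINDOW:4:20 MINLEN:36`.
#'
#' @param leading,trailing minimum quality to keep a leading/trailing base.
#' @param window_size,window_quality sliding-window width and mean-quality
#'   threshold; the read is cut at the start of the first window whose mean
#'   quality falls below the threshold (truncated windows at the read end
#'   use the available bases).
#' @param min_length reads shorter than this after trimming are dropped.
#' @return a `trim_params` list.
#' @export
trim_params <- function(leading = 3, trailing = 3, window_size = 4,
                        window_quality = 20, min_length = 36) {
  stopifnot(leading >= 0, trailing >= 0, window_size >= 1,
            window_quality >= 0, min_length >= 0)
  structure(list(leading = leading, trailing = trailing,
                 window_size = window_size, window_quality = window_quality,
                 min_length = min_length), class = "trim_params")
}

#' Quality-trim a single read
#'
#' Steps applied in order LEADING, TRAILING, SLIDINGWINDOW, MINLEN; the
#' output is always a contiguous substring of the input.
#'
#' @param seq,qual sequence and phred+33 quality string.
#' @param params a [trim_params()].
#' @return list with `seq` and `qual` (empty strings when the read is
#'   dropped) and `dropped`.
#' @export
trim_read <- function(seq, qual, params = trim_params()) {
  stopifnot(nchar(seq) == nchar(qual))
  se <- trim_reads_cpp(seq, qual, params$leading, params$trailing,
                       params$window_size, params$window_quality,
                       params$min_length)
  if (se[1, 1] == 0) return(list(seq = "", qual = "", dropped = TRUE))
  list(seq = substring(seq, se[1, 1], se[1, 2]),
       qual = substring(qual, se[1, 1], se[1, 2]), dropped = FALSE)
}

#' Quality-trim read pairs
#'
#' Mates are trimmed independently; a pair is kept only when both mates
#' survive MINLEN (no orphan handling).
#'
#' @param seq1,qual1,seq2,qual2 parallel vectors for the two mates.
#' @param params a [trim_params()].
#' @return list with the trimmed surviving pairs (`seq1`, `qual1`, `seq2`,
#'   `qual2`), `keep` (logical over input pairs) and `n_dropped`.
#' @export
trim_pairs <- function(seq1, qual1, seq2, qual2, params = trim_params()) {
  se1 <- trim_reads_cpp(seq1, qual1, params$leading, params$trailing,
                        params$window_size, params$window_quality,
                        params$min_length)
  se2 <- trim_reads_cpp(seq2, qual2, params$leading, params$trailing,
                        params$window_size, params$window_quality,
                        params$min_length)
  keep <- se1[, 1] > 0 & se2[, 1] > 0
  list(seq1 = substring(seq1[keep], se1[keep, 1], se1[keep, 2]),
       qual1 = substring(qual1[keep], se1[keep, 1], se1[keep, 2]),
       seq2 = substring(seq2[keep], se2[keep, 1], se2[keep, 2]),
       qual2 = substring(qual2[keep], se2[keep, 1], se2[keep, 2]),
       keep = keep, n_dropped = sum(!keep))
}
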
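# Shared fixtures and independent oracles, built in code at test time.

demo <- build_demo_panel()

# zero-noise simulation settings: no substitution errors, flat qualities
# comfortably above the pileup cutoff
zero_error_config <- function(n_samples, allele_freq, depth = 60, seed = 1) {
  sim_config(n_samples = n_samples, allele_freq = allele_freq, depth = depth,
             error_rate = 0, qual_mean = 38, qual_sd = 0, qual_decay = 0,
             seed = seed)
}

# independent brute-force re-implementation of the trimming semantics:
# LEADING / TRAILING by scanning, SLIDINGWINDOW by enumerating every window
# start and cutting at the first below-threshold mean, MINLEN last
trim_oracle <- function(seq, qual, params = trim_params()) {
  q <- as.integer(charToRaw(qual)) - 33L
  keep <- seq_along(q)
  while (length(keep) > 0 && q[keep[1]] < params$leading)
    keep <- keep[-1]
  while (length(keep) > 0 && q[keep[length(keep)]] < params$trailing)
    keep <- keep[-length(keep)]
  if (length(keep) > 0) {
    cut_at <- NA
    for (w in seq_along(keep)) {
      win <- keep[w:min(w + params$window_size - 1, length(keep))]
      if (mean(q[win]) < params$window_quality) { cut_at <- w; break }
    }
    if (!is.na(cut_at)) keep <- keep[seq_len(cut_at - 1)]
  }
  if (length(keep) < params$min_length)
    return(list(seq = "", qual = "", dropped = TRUE))
  list(seq = substring(seq, keep[1], keep[length(keep)]),
       qual = substring(qual, keep[1], keep[length(keep)]),
       dropped = FALSE)
}

random_read <- function(len, qmin = 2, qmax = 40) {
  list(seq = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = ""),
       qual = rawToChar(as.raw(33L + sample(qmin:qmax, len, replace = TRUE))))
}

# Pearson chi-square by the textbook formula sum((O - E)^2 / E), with the
# optional Yates |O - E| - 0.5 continuity correction
chi2_oracle <- function(tab, yates = FALSE) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - E)
  if (yates) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / E)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# write a small FASTQ pair for demultiplexing tests
write_pair <- function(seq1, qual1, seq2, qual2, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  ids <- sprintf("r%03d", seq_along(seq1))
  f1 <- file.path(dir, "t_R1.fastq")
  f2 <- file.path(dir, "t_R2.fastq")
  write_fastq(ids, seq1, qual1, f1)
  write_fastq(ids, seq2, qual2, f2)
  list(f1 = f1, f2 = f2)
}

qflat <- function(n, q = 38) strrep(rawToChar(as.raw(33L + q)), n)
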
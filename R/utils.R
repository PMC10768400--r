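# Internal helpers shared across modules

#' @useDynLib ampliresist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbinom rbinom rpois runif setNames chisq.test p.adjust
#' @importFrom utils read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA string
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a DNA codon to a one-letter amino acid
#' @param codon 3-base character vector (sense strand).
#' @return one-letter amino-acid code ("*" for stop).
#' @export
translate_codon <- function(codon) {
  stopifnot(all(nchar(codon) == 3L))
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

# phred+33 string <-> integer qualities
qual_to_int <- function(q) {
  lapply(q, function(s) as.integer(charToRaw(s)) - 33L)
}

int_to_qual <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

# round half away from zero at `digits` decimals (report convention; R's
# round() would round half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# strict TSV reader: header row required, "#" comment lines ignored
read_tsv_strict <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = NA,
                   fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("file ", basename(path), " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# deterministic pseudo-random bases independent of the user's RNG stream
# (linear congruential generator; used only to lay down fixture sequences)
lcg_bases <- function(n, seed) {
  state <- as.double(seed %% 2147483647)
  out <- integer(n)
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- (state %% 4) + 1
  }
  BASES[out]
}
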
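# Panel-restricted alignment and quality-filtered pileups.  Reads are
# known amplicon products, so whole-genome mapping is replaced by
# candidate selection through shared-k-mer voting followed by a banded
# affine-gap alignment that is global in the read and local in the
# reference amplicon.

#' Align reads to the amplicon panel
#'
#' Candidate amplicon and band centre are chosen by shared 15-mer voting;
#' the banded alignment scores match +1, mismatch -2, gap open -4, gap
#' extend -1 (the first gap base costs open + extend).  A read whose
#' matched fraction falls below `min_identity` is reported unaligned.
#' Both orientations are tried (amplicon sequencing fixes mate 1 to the
#' forward-primer end, so mate 2 reads the bottom strand); coordinates and
#' CIGAR are always reported on the reference top strand, with `strand`
#' recording the read's orientation.
#'
#' @param seqs character vector of (trimmed) read sequences.
#' @param panel an `amplicon_panel`.
#' @param band half-width of the alignment band; at least the largest
#'   indel expected (default 10).
#' @param k seed k-mer length.
#' @param min_identity minimum fraction of read bases matching the
#'   reference.
#'
#' @return data frame with `amplicon` (NA when unaligned), `start`
#'   (1-based amplicon-local position of the first aligned reference
#'   base), `strand` (+/-), `cigar` (M/I/D along the oriented read), `nm`
#'   (edit distance: mismatches plus gap bases) and `score`.
#' @export
align_reads <- function(seqs, panel, band = 10, k = 15, min_identity = 0.8) {
  ids <- panel$amplicons$id
  res <- align_reads_cpp(seqs, unname(panel$sequences[ids]), k = k,
                         band = band, min_identity = min_identity)
  data.frame(amplicon = ifelse(res$ref == 0, NA_character_, ids[res$ref]),
             start = ifelse(res$ref == 0, NA_integer_, res$start),
             strand = ifelse(res$ref == 0, NA_character_,
                             as.character(res$strand)),
             cigar = ifelse(res$ref == 0, NA_character_,
                            as.character(res$cigar)),
             nm = ifelse(res$ref == 0, NA_integer_, res$nm),
             score = ifelse(res$ref == 0, NA_integer_, res$score),
             stringsAsFactors = FALSE)
}

#' Build per-amplicon pileups from aligned reads
#'
#' A read base contributes to a column iff it is an aligned match or
#' mismatch (not inside or within `gap_pad` bases of an alignment gap) and
#' its phred quality is strictly greater than `min_base_quality`.  Both
#' mates contribute, but where mates of one pair overlap, each position is
#' counted once, keeping the higher-quality base.
#'
#' @param aln alignment data frame from [align_reads()] (both mates).
#' @param seqs,quals read sequences/qualities parallel to `aln`.
#' @param pair_id integer vector identifying mates of the same fragment.
#' @param panel an `amplicon_panel`.
#' @param min_base_quality phred cutoff; bases must exceed it (strict >).
#' @param gap_pad bases excluded on either side of an alignment gap.
#' @return a `pileup_set`: named list (per amplicon) of 5 x L integer
#'   matrices with rows A, C, G, T and `filtered`.
#' @export
build_pileup <- function(aln, seqs, quals, pair_id, panel,
                         min_base_quality = 30, gap_pad = 3) {
  ids <- panel$amplicons$id
  # orient minus-strand reads onto the top strand to match their CIGAR
  minus <- !is.na(aln$strand) & aln$strand == "-"
  if (any(minus)) {
    seqs[minus] <- rev_comp(seqs[minus])
    quals[minus] <- as.character(
      Biostrings::reverse(Biostrings::BStringSet(quals[minus])))
  }
  ord <- order(pair_id)
  ref_idx <- match(aln$amplicon, ids)
  ref_idx[is.na(ref_idx)] <- 0L
  ref_start <- aln$start
  ref_start[is.na(ref_start)] <- 0L
  cig <- aln$cigar
  cig[is.na(cig)] <- ""
  mats <- pileup_cpp(ref_idx[ord], ref_start[ord], cig[ord], seqs[ord],
                     quals[ord], pair_id[ord],
                     nchar(unname(panel$sequences[ids])),
                     min_bq = min_base_quality, gap_pad = gap_pad)
  names(mats) <- ids
  for (i in seq_along(mats)) rownames(mats[[i]]) <- c(BASES, "filtered")
  structure(mats, class = "pileup_set")
}

#' One pileup column
#'
#' Convenience accessor returning the base counts, filtered count and
#' passing depth at a single amplicon-local position.
#'
#' @param pileups a `pileup_set`.
#' @param amplicon amplicon id.
#' @param pos 1-based amplicon-local position.
#' @return list with `counts` (named A/C/G/T), `filtered` and `depth`.
#' @export
pileup_column <- function(pileups, amplicon, pos) {
  m <- pileups[[amplicon]]
  if (is.null(m) || pos < 1 || pos > ncol(m))
    stop("position outside the panel: ", amplicon, ":", pos)
  counts <- m[BASES, pos]
  list(counts = counts, filtered = m["filtered", pos],
       depth = sum(counts))
}

#' Write alignments as SAM (informational)
#'
#' Minimal unsorted SAM with amplicon `@SQ` lines; mates are written as
#' unpaired records.  The pipeline's internal contract is the pileup, not
#' this file.
#'
#' @param aln alignment data frame from [align_reads()].
#' @param ids,seqs,quals read names, sequences, qualities parallel to `aln`.
#' @param panel an `amplicon_panel`.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ids, seqs, quals, panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_len(nrow(panel$amplicons)))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", panel$amplicons$id[i],
                       nchar(panel$sequences[[panel$amplicons$id[i]]])), con)
  mapped <- !is.na(aln$amplicon)
  flag <- ifelse(mapped, ifelse(aln$strand == "-", 16L, 0L), 4L)
  writeLines(paste(ids, flag,
                   ifelse(mapped, aln$amplicon, "*"),
                   ifelse(mapped, aln$start, 0L),
                   ifelse(mapped, 60L, 0L),
                   ifelse(mapped, aln$cigar, "*"),
                   "*", 0L, 0L, seqs, quals,
                   ifelse(mapped, paste0("NM:i:", aln$nm), ""),
                   sep = "\t"), con)
  invisible(path)
}
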
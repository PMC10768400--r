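# In-silico PCR-RFLP species identification for the Anopheles gambiae
# complex: IGS amplification with a universal forward primer and
# species-specific reverse primers, HhaI digestion, and band-pattern
# classification.

#' The IGS PCR-RFLP assay definition
#'
#' Universal forward primer, species-specific reverse primers and the
#' HhaI enzyme (recognition site GCGC, cutting after the third base,
#' GCG^C, on the top strand; the site is its own reverse complement).
#'
#' @return list with `universal_f`, `reverse` (named: gambiae,
#'   arabiensis, melas), `enzyme`, `site`, `cut_offset`.
#' @export
rflp_assay <- function() {
  list(universal_f = "GTGTGCCCCTTCCTCGATGT",
       reverse = c(gambiae = "CTGGTTTGGTCGGCACGTTT",
                   arabiensis = "AAGTGTCCTTCTCCATCCTA",
                   melas = "TGACCAACCCACTCCCTTGA"),
       enzyme = "HhaI", site = "GCGC", cut_offset = 3L)
}

#' In-silico PCR on a template
#'
#' Products span from the forward primer's 5' end to the 5' end of the
#' reverse-complemented reverse primer on the template top strand.
#' Binding is exact by default; no product is returned when either primer
#' is absent or in the wrong orientation.  All products from multiple
#' binding sites are reported.
#'
#' @param template template sequence (top strand, 5'->3').
#' @param forward,reverse primers as synthesized (each >= 15 bp).
#' @param max_mismatch allowed mismatches per primer binding site.
#' @return character vector of product sequences (empty when none).
#' @export
insilico_pcr <- function(template, forward, reverse, max_mismatch = 0) {
  stopifnot(nchar(forward) >= 15, nchar(reverse) >= 15)
  subj <- Biostrings::DNAString(template)
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(forward), subj,
                                    max.mismatch = max_mismatch)
  rhits <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(reverse)), subj,
    max.mismatch = max_mismatch)
  if (length(fhits) == 0 || length(rhits) == 0) return(character(0))
  products <- character(0)
  for (fs in IRanges::start(fhits)) {
    for (re in IRanges::end(rhits)) {
      if (re > fs + nchar(forward) - 1)
        products <- c(products, substring(template, fs, re))
    }
  }
  products
}

#' Restriction digestion of a sequence
#'
#' Cuts after `cut_offset` bases at every occurrence of the recognition
#' site on the given strand; fragment lengths always sum to the input
#' length.
#'
#' @param sequence DNA string.
#' @param site recognition site (default HhaI, GCGC).
#' @param cut_offset bases 5' of the cut within the site (default 3:
#'   GCG^C).
#' @return integer vector of fragment lengths, 5'->3'.
#' @export
digest <- function(sequence, site = "GCGC", cut_offset = 3L) {
  L <- nchar(sequence)
  if (L == 0) return(integer(0))
  hits <- Biostrings::matchPattern(Biostrings::DNAString(site),
                                   Biostrings::DNAString(sequence))
  cuts <- sort(unique(IRanges::start(hits) + cut_offset - 1L))
  cuts <- cuts[cuts >= 1 & cuts < L]
  diff(c(0L, cuts, L))
}

#' Classify a specimen's band pattern
#'
#' Matches the combined fragment sizes from all primer reactions against
#' the printed diagnostic patterns with a gel-resolution tolerance:
#' An. gambiae s.s. 257 + 110; An. arabiensis 292; An. melas 435;
#' An. coluzzii 367 (uncut); gambiae/coluzzii hybrid 257 + 110 + 367.
#'
#' @param bands numeric vector of observed fragment sizes (bp).
#' @param tolerance per-band size tolerance in bp (default 5).
#' @return species call: `"An. gambiae s.s."`, `"An. arabiensis"`,
#'   `"An. melas"`, `"An. coluzzii"`, `"hybrid"` or `"unresolved"`.
#' @export
classify_bands <- function(bands, tolerance = 5) {
  patterns <- list(
    "An. gambiae s.s." = c(110, 257),
    "An. arabiensis" = 292,
    "An. melas" = 435,
    "An. coluzzii" = 367,
    "hybrid" = c(110, 257, 367))
  obs <- sort(bands)
  for (sp in names(patterns)) {
    pat <- sort(patterns[[sp]])
    if (length(obs) == length(pat) && all(abs(obs - pat) <= tolerance))
      return(sp)
  }
  "unresolved"
}

#' Run the full in-silico PCR-RFLP assay on specimen templates
#'
#' For each specimen: amplify with the universal forward primer and each
#' species-specific reverse primer, digest every product with HhaI, pool
#' the fragment sizes and classify the pattern.
#'
#' @param templates named character vector (or list of vectors for
#'   specimens with several IGS copies, e.g. hybrids) of template
#'   sequences.
#' @param assay the assay definition from [rflp_assay()].
#' @param tolerance band-size tolerance passed to [classify_bands()].
#' @return data frame: specimen, bands (comma-separated, descending),
#'   species_call.
#' @export
rflp_identify <- function(templates, assay = rflp_assay(), tolerance = 5) {
  if (!is.list(templates)) templates <- as.list(templates)
  res <- lapply(names(templates), function(nm) {
    bands <- integer(0)
    for (tmpl in templates[[nm]]) {
      for (rv in names(assay$reverse)) {
        for (p in insilico_pcr(tmpl, assay$universal_f, assay$reverse[[rv]]))
          bands <- c(bands, digest(p, assay$site, assay$cut_offset))
      }
    }
    bands <- sort(unique(bands), decreasing = TRUE)
    data.frame(specimen = nm,
               bands = paste(bands, collapse = ","),
               species_call = classify_bands(bands, tolerance),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
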
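# Bundled demonstration panel: a miniature synthetic stand-in for the
# seven-amplicon resistance panel (vgsc I-IV, rdl, gste2, ace1).  Amplicon
# backbones are deterministic pseudo-random DNA; gene models carry
# codon-numbering offsets chosen so that each target SNP sits at its
# conventional residue number (e.g. vgsc L995F, the kdr-west allele), and
# genome coordinates are anchored to the published positions of the
# best-known sites.  The real AgamP4 chromosome sequences are not shipped.

DEMO_AMPLICON_LEN <- 470L

# layout shared by the single-exon amplicons: one CDS exon at local 31..450
# (140 codons), phase 0
demo_layout <- list(
  `vgsc-I`   = list(gene = "vgsc",  chrom = "2L", start = 2391072L,
                    strand = "+", offset = 359L),
  `vgsc-II`  = list(gene = "vgsc",  chrom = "2L", start = 2422413L,
                    strand = "+", offset = 925L),
  `vgsc-III` = list(gene = "vgsc",  chrom = "2L", start = 2429508L,
                    strand = "+", offset = 1500L),
  `vgsc-IV`  = list(gene = "vgsc",  chrom = "2L", start = 2430379L,
                    strand = "+", offset = 1740L),
  rdl        = list(gene = "rdl",   chrom = "2L", start = 25429007L,
                    strand = "+", offset = 229L),
  gste2      = list(gene = "gste2", chrom = "3R", start = 28597670L,
                    strand = "-", offset = 99L),
  ace1       = list(gene = "ace1",  chrom = "2R", start = 3491700L,
                    strand = "+", offset = 240L))

# reference codons pinned into each amplicon backbone, keyed by published
# residue number (sense strand)
demo_codons <- list(
  `vgsc-I`   = c(`389` = "TTT", `402` = "GTG", `429` = "GAA", `466` = "GAC"),
  `vgsc-II`  = c(`995` = "TTA"),
  `vgsc-III` = c(`1527` = "ATA", `1570` = "AAT"),
  `vgsc-IV`  = c(`1746` = "GCT", `1874` = "CCA"),
  rdl        = c(`296` = "GCA", `327` = "GTA"),
  gste2      = c(`114` = "ATT", `119` = "CTT", `120` = "TTC", `154` = "ACT",
                 `171` = "GGT", `174` = "CCA", `187` = "ATT"),
  ace1       = c(`280` = "GGC"))

# the 17 target SNPs: label, amplicon, codon, position-in-codon (sense),
# sense ref/alt bases, association
demo_targets <- data.frame(
  amplicon = c("vgsc-I", "vgsc-I", "vgsc-II", "vgsc-II", "vgsc-III",
               "vgsc-III", "vgsc-IV", "vgsc-IV", "rdl", "rdl", "ace1",
               "gste2", "gste2", "gste2", "gste2", "gste2", "gste2"),
  label = c("V402L", "D466H", "L995F", "L995S", "I1527T", "N1570Y",
            "A1746S", "P1874S", "A296G", "V327I", "G280S",
            "I114T", "L119F", "L119V", "F120L", "T154S", "P174L"),
  codon = c(402L, 466L, 995L, 995L, 1527L, 1570L, 1746L, 1874L, 296L, 327L,
            280L, 114L, 119L, 119L, 120L, 154L, 174L),
  pos_in_codon = c(1L, 1L, 3L, 2L, 2L, 1L, 1L, 1L, 2L, 1L, 1L,
                   2L, 1L, 1L, 1L, 2L, 2L),
  sense_alt = c("T", "C", "T", "C", "C", "T", "T", "T", "G", "A", "A",
                "C", "T", "G", "C", "G", "T"),
  association = c("pyrethroid (candidate)", "pyrethroid (candidate)",
                  "pyrethroid/DDT (kdr-west)", "pyrethroid/DDT (kdr-east)",
                  "pyrethroid (candidate)", "pyrethroid (with L995F)",
                  "pyrethroid (candidate)", "pyrethroid (candidate)",
                  "dieldrin", "dieldrin (candidate)",
                  "carbamate/organophosphate",
                  "pyrethroid", "pyrethroid/DDT", "DDT", "DDT",
                  "DDT (candidate)", "DDT (candidate)"),
  stringsAsFactors = FALSE)

# local positions (top strand) of the three bases of a residue's codon,
# given the demo layout
demo_codon_local <- function(id, codon) {
  off <- demo_layout[[id]]$offset
  c_local <- codon - off
  if (id == "gste2")            # minus strand: codon 1 ends at local 450
    (451L - 3L * c_local):(453L - 3L * c_local)  # sense pos 3,2,1
  else if (id == "ace1") {
    if (c_local <= 60L) (31L + 3L * (c_local - 1L)):(33L + 3L * (c_local - 1L))
    else {
      s <- 271L + 3L * (c_local - 61L)
      s:(s + 2L)
    }
  } else (31L + 3L * (c_local - 1L)):(33L + 3L * (c_local - 1L))
}

#' Build the bundled demonstration panel
#'
#' Constructs, entirely in code, the synthetic seven-amplicon panel used
#' throughout the package examples and tests: ~470-bp amplicons for vgsc
#' domains I-IV, rdl, gste2 (minus strand) and ace1 (two exons with an
#' intron), 17 target SNPs at their conventional residue numbers, 20-bp
#' primers, ten forward and ten reverse 8-bp barcodes, and a 40-mosquito
#' example sample sheet spanning five islands and four species labels.
#' The build is deterministic.
#'
#' @param dir optional directory; when given the panel files are written
#'   there (see [write_panel()]).
#' @return an `amplicon_panel`.
#' @export
build_demo_panel <- function(dir = NULL) {
  ids <- names(demo_layout)
  seqs <- character(length(ids))
  names(seqs) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    s <- paste(lcg_bases(DEMO_AMPLICON_LEN, seed = 7000 + i * 131), collapse = "")
    # pin reference codons (sense strand; reverse-complemented on '-')
    for (res in names(demo_codons[[id]])) {
      lp <- demo_codon_local(id, as.integer(res))
      cod <- demo_codons[[id]][[res]]
      top <- if (demo_layout[[id]]$strand == "-") rev_comp(cod) else cod
      substring(s, min(lp), max(lp)) <- top
    }
    # keep the ace1 intron donor/acceptor away from stop-like content and
    # scrub homopolymer runs that could weaken k-mer seeding
    seqs[i] <- s
  }

  amplicons <- data.frame(
    id = ids,
    gene = vapply(demo_layout, `[[`, "", "gene"),
    chrom = vapply(demo_layout, `[[`, "", "chrom"),
    start = vapply(demo_layout, function(x) x$start, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  models <- lapply(ids, function(id) {
    lay <- demo_layout[[id]]
    ex <- if (id == "ace1")
      data.frame(start = lay$start + c(30L, 270L), end = lay$start + c(209L, 449L))
    else
      data.frame(start = lay$start + 30L, end = lay$start + 449L)
    list(amplicon = id, gene = lay$gene, strand = lay$strand, exons = ex,
         phase = 0L, codon_offset = lay$offset)
  })
  names(models) <- ids

  primers <- data.frame(
    amplicon = ids,
    forward = substring(seqs, 1, 20),
    reverse = rev_comp(substring(seqs, DEMO_AMPLICON_LEN - 19, DEMO_AMPLICON_LEN)),
    row.names = NULL, stringsAsFactors = FALSE)

  targets <- demo_targets
  targets$gene <- vapply(demo_layout[targets$amplicon], `[[`, "", "gene")
  targets$chrom <- vapply(demo_layout[targets$amplicon], `[[`, "", "chrom")
  gp <- ref <- alt <- character(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    id <- targets$amplicon[i]
    lay <- demo_layout[[id]]
    lp <- demo_codon_local(id, targets$codon[i])
    # lp is in top-strand order; sense position k maps to lp[k] on '+' and
    # lp[4-k] on '-'
    k <- targets$pos_in_codon[i]
    loc <- if (lay$strand == "-") lp[4L - k] else lp[k]
    gp[i] <- lay$start + loc - 1L
    sense_ref <- substring(demo_codons[[id]][[as.character(targets$codon[i])]], k, k)
    if (lay$strand == "-") {
      ref[i] <- unname(COMPLEMENT[sense_ref])
      alt[i] <- unname(COMPLEMENT[targets$sense_alt[i]])
    } else {
      ref[i] <- sense_ref
      alt[i] <- targets$sense_alt[i]
    }
  }
  targets <- data.frame(gene = targets$gene, amplicon = targets$amplicon,
                        chrom = targets$chrom, pos = as.integer(gp),
                        ref = ref, alt = alt, label = targets$label,
                        association = targets$association,
                        stringsAsFactors = FALSE)

  barcodes <- demo_barcodes()
  samples <- demo_sample_sheet(barcodes)

  panel <- structure(
    list(amplicons = amplicons, sequences = seqs, models = models,
         primers = primers, targets = targets, barcodes = barcodes,
         samples = samples),
    class = "amplicon_panel")
  validate_panel(panel)
  if (!is.null(dir)) write_panel(panel, dir)
  panel
}

# ten forward + ten reverse 8-bp barcodes, greedily chosen from a
# deterministic stream so that any two barcodes differ at >= 4 positions
demo_barcodes <- function() {
  pool <- character(0)
  seed <- 424243
  while (length(pool) < 20) {
    cand <- paste(lcg_bases(8, seed), collapse = "")
    seed <- seed + 1
    if (length(pool) == 0 ||
        all(vapply(pool, function(b) {
          sum(strsplit(b, "")[[1]] != strsplit(cand, "")[[1]]) >= 4
        }, logical(1))))
      pool <- c(pool, cand)
  }
  list(forward = setNames(pool[1:10], sprintf("F%02d", 1:10)),
       reverse = setNames(pool[11:20], sprintf("R%02d", 1:10)))
}

# 40-mosquito example sheet: five islands, four species labels
demo_sample_sheet <- function(barcodes) {
  n <- 40L
  islands <- rep(c("Bubaque", "Tchedega", "Orangozinho", "Soga", "Uno"),
                 length.out = n)
  species <- rep(c("An. gambiae s.s.", "hybrid", "An. melas", "An. coluzzii",
                   "An. gambiae s.s.", "hybrid", "An. gambiae s.s.", "hybrid"),
                 length.out = n)
  fi <- ((seq_len(n) - 1L) %% 10L) + 1L
  ri <- ((seq_len(n) - 1L) %/% 10L) + 1L
  data.frame(sample_id = sprintf("BIJ%03d", seq_len(n)),
             fwd_barcode = unname(barcodes$forward[fi]),
             rev_barcode = unname(barcodes$reverse[ri]),
             island = islands, species = species,
             stringsAsFactors = FALSE)
}

#' Path to the bundled demo panel directory
#' @return path to the installed plain-text panel files.
#' @export
demo_panel_dir <- function() {
  system.file("extdata", "demo_panel", package = "ampliresist", mustWork = TRUE)
}
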
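# Amplicon panel: reference sequences, gene models, primers, barcodes,
# target SNPs and the sample sheet.  All coordinates are 1-based, fully
# closed intervals; amplicon-local position p corresponds to genome
# position amplicon_start + p - 1.

#' Load and validate an amplicon panel directory
#'
#' A panel directory holds plain-text files: `amplicons.fasta` (reference
#' amplicon sequences), `amplicons.tsv` (id, gene, chrom, start),
#' `gene_models.tsv` (one row per exon: amplicon, gene, strand, exon_start,
#' exon_end, phase, codon_offset; genome coordinates), `primers.tsv`
#' (amplicon, forward, reverse — the reverse primer as synthesized, i.e. the
#' reverse complement of the top strand), `targets.tsv` (gene, amplicon,
#' chrom, pos, ref, alt, label, association), `barcodes.tsv` (role F/R,
#' name, sequence) and `samples.tsv` (sample_id, fwd_barcode, rev_barcode,
#' island, species).  Lines starting with `#` are ignored.
#'
#' Loading validates the panel: amplicon ids unique and sequences A/C/G/T
#' only; exons sorted, non-overlapping and in-bounds with CDS length a
#' multiple of three after phase; primers matching the template; every
#' target's ref base matching the reference sequence and every target label
#' reproduced by translating the reference and substituted codons; barcode
#' combinations unique.
#'
#' @param panel_dir path to the panel directory.
#' @return an object of class `amplicon_panel`.
#' @export
load_panel <- function(panel_dir) {
  if (!dir.exists(panel_dir)) stop("panel directory not found: ", panel_dir)
  fa <- file.path(panel_dir, "amplicons.fasta")
  if (!file.exists(fa)) stop("missing file: ", fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  sequences <- setNames(toupper(as.character(seqs)), names(seqs))

  amplicons <- read_tsv_strict(file.path(panel_dir, "amplicons.tsv"),
                               c("id", "gene", "chrom", "start"))
  gm <- read_tsv_strict(file.path(panel_dir, "gene_models.tsv"),
                        c("amplicon", "gene", "strand", "exon_start",
                          "exon_end", "phase", "codon_offset"))
  primers <- read_tsv_strict(file.path(panel_dir, "primers.tsv"),
                             c("amplicon", "forward", "reverse"))
  targets <- read_tsv_strict(file.path(panel_dir, "targets.tsv"),
                             c("gene", "amplicon", "chrom", "pos", "ref",
                               "alt", "label", "association"))
  barcodes <- read_tsv_strict(file.path(panel_dir, "barcodes.tsv"),
                              c("role", "name", "sequence"))
  samples <- read_tsv_strict(file.path(panel_dir, "samples.tsv"),
                             c("sample_id", "fwd_barcode", "rev_barcode",
                               "island", "species"))

  models <- lapply(split(gm, gm$amplicon), function(g) {
    g <- g[order(g$exon_start), ]
    list(amplicon = g$amplicon[1], gene = g$gene[1], strand = g$strand[1],
         exons = data.frame(start = g$exon_start, end = g$exon_end),
         phase = g$phase[1], codon_offset = g$codon_offset[1])
  })
  models <- models[amplicons$id]   # panel order, not alphabetical

  panel <- structure(
    list(amplicons = amplicons, sequences = sequences, models = models,
         primers = primers, targets = targets,
         barcodes = list(
           forward = setNames(barcodes$sequence[barcodes$role == "F"],
                              barcodes$name[barcodes$role == "F"]),
           reverse = setNames(barcodes$sequence[barcodes$role == "R"],
                              barcodes$name[barcodes$role == "R"])),
         samples = samples),
    class = "amplicon_panel")
  validate_panel(panel)
  panel
}

#' Write a panel back to a directory
#'
#' Inverse of [load_panel()]: writing then reloading yields an identical
#' panel.
#'
#' @param panel an `amplicon_panel`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(panel$sequences),
                              file.path(dir, "amplicons.fasta"), width = 60)
  write_tsv(panel$amplicons, file.path(dir, "amplicons.tsv"))
  gm <- do.call(rbind, lapply(panel$models, function(m) {
    data.frame(amplicon = m$amplicon, gene = m$gene, strand = m$strand,
               exon_start = m$exons$start, exon_end = m$exons$end,
               phase = m$phase, codon_offset = m$codon_offset)
  }))
  rownames(gm) <- NULL
  write_tsv(gm, file.path(dir, "gene_models.tsv"))
  write_tsv(panel$primers, file.path(dir, "primers.tsv"))
  write_tsv(panel$targets, file.path(dir, "targets.tsv"))
  bc <- rbind(
    data.frame(role = "F", name = names(panel$barcodes$forward),
               sequence = unname(panel$barcodes$forward)),
    data.frame(role = "R", name = names(panel$barcodes$reverse),
               sequence = unname(panel$barcodes$reverse)))
  write_tsv(bc, file.path(dir, "barcodes.tsv"))
  write_tsv(panel$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("amplicon panel:", nrow(x$amplicons), "amplicons,",
      nrow(x$targets), "target SNPs,", nrow(x$samples), "samples\n")
  invisible(x)
}

amplicon_length <- function(panel, id) nchar(panel$sequences[[id]])

amplicon_start <- function(panel, id) {
  panel$amplicons$start[match(id, panel$amplicons$id)]
}

# genome -> amplicon-local coordinate (1-based)
local_pos <- function(panel, id, genome_pos) {
  genome_pos - amplicon_start(panel, id) + 1L
}

noncoding_error <- function(msg) {
  stop(structure(class = c("noncoding_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# CDS genome positions of a model, in sense (translation) order, phase
# bases removed
cds_positions <- function(model) {
  pos <- unlist(Map(seq, model$exons$start, model$exons$end), use.names = FALSE)
  if (model$strand == "-") pos <- rev(pos)
  if (model$phase > 0) pos <- pos[-seq_len(model$phase)]
  pos
}

#' Codon index of a genome position within a gene model
#'
#' Maps a genome position to the published residue number and the position
#' within the codon, applying the model's phase and codon-numbering offset.
#' Works identically for plus- and minus-strand genes.
#'
#' @param model one element of `panel$models`.
#' @param genome_pos 1-based genome position.
#' @return list with `codon` (published residue number) and `pos_in_codon`
#'   (1, 2 or 3, in sense order).
#' @export
residue_number <- function(model, genome_pos) {
  pos <- cds_positions(model)
  i <- match(genome_pos, pos)
  if (is.na(i))
    noncoding_error(paste0("position ", genome_pos,
                           " is not in the CDS of ", model$amplicon))
  list(codon = (i - 1L) %/% 3L + 1L + model$codon_offset,
       pos_in_codon = (i - 1L) %% 3L + 1L)
}

# sense-strand codon sequence + genome positions (sense order) for a
# published residue number
codon_at <- function(panel, amplicon_id, codon_number) {
  model <- panel$models[[amplicon_id]]
  pos <- cds_positions(model)
  c_local <- codon_number - model$codon_offset
  idx <- (3L * (c_local - 1L) + 1L):(3L * (c_local - 1L) + 3L)
  if (c_local < 1 || max(idx) > length(pos))
    stop("codon ", codon_number, " outside the modeled CDS of ", amplicon_id)
  gpos <- pos[idx]
  lp <- local_pos(panel, amplicon_id, gpos)
  bases <- substring(panel$sequences[[amplicon_id]], lp, lp)
  if (model$strand == "-") bases <- unname(COMPLEMENT[bases])
  list(codon = paste(bases, collapse = ""), genome_pos = gpos)
}

#' Validate an amplicon panel
#'
#' Runs the panel self-consistency checks (see [load_panel()]); called
#' automatically at load.
#'
#' @param panel an `amplicon_panel`.
#' @return `panel`, invisibly; errors describe the first failure found.
#' @export
validate_panel <- function(panel) {
  a <- panel$amplicons
  if (anyDuplicated(a$id)) stop("duplicate amplicon id in panel")
  if (!setequal(a$id, names(panel$sequences)))
    stop("amplicons.tsv ids and FASTA names differ")
  if (any(grepl("[^ACGT]", panel$sequences)))
    stop("amplicon sequences must contain only A/C/G/T")
  longest_primer <- max(nchar(c(panel$primers$forward, panel$primers$reverse)))
  if (any(nchar(panel$sequences[a$id]) < 2 * longest_primer))
    stop("amplicon shorter than twice the longest primer")

  for (m in panel$models) {
    if (!m$amplicon %in% a$id) stop("gene model for unknown amplicon ", m$amplicon)
    ex <- m$exons
    if (is.unsorted(ex$start) || any(ex$end < ex$start))
      stop("exons of ", m$amplicon, " not sorted or malformed")
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in ", m$amplicon)
    L <- amplicon_length(panel, m$amplicon)
    st <- amplicon_start(panel, m$amplicon)
    if (any(ex$start < st) || any(ex$end > st + L - 1))
      stop("exon outside amplicon bounds in ", m$amplicon)
    if ((sum(ex$end - ex$start + 1) - m$phase) %% 3 != 0)
      stop("CDS length of ", m$amplicon, " not a multiple of 3 after phase")
  }

  for (i in seq_len(nrow(panel$primers))) {
    p <- panel$primers[i, ]
    tmpl <- panel$sequences[[p$amplicon]]
    fpos <- regexpr(p$forward, tmpl, fixed = TRUE)
    rpos <- regexpr(rev_comp(p$reverse), tmpl, fixed = TRUE)
    if (fpos < 0) stop("forward primer of ", p$amplicon,
                       " does not match the template top strand")
    if (rpos < 0 || rpos <= fpos)
      stop("reverse primer of ", p$amplicon,
           " does not match the template downstream of the forward primer")
  }

  t <- panel$targets
  for (i in seq_len(nrow(t))) {
    id <- t$amplicon[i]
    lp <- local_pos(panel, id, t$pos[i])
    have <- substring(panel$sequences[[id]], lp, lp)
    if (have != t$ref[i])
      stop("target ", t$label[i], ": ref base mismatch at ", t$chrom[i], ":",
           t$pos[i], " (amplicon ", id, " pos ", lp, " has ", have,
           ", table says ", t$ref[i], ")")
    model <- panel$models[[id]]
    rn <- residue_number(model, t$pos[i])
    lab_num <- as.integer(gsub("[^0-9]", "", t$label[i]))
    lab_ref <- substring(t$label[i], 1, 1)
    lab_alt <- substring(t$label[i], nchar(t$label[i]), nchar(t$label[i]))
    if (rn$codon != lab_num)
      stop("target ", t$label[i], ": model places ", t$pos[i],
           " at residue ", rn$codon)
    cod <- codon_at(panel, id, rn$codon)
    if (translate_codon(cod$codon) != lab_ref)
      stop("target ", t$label[i], ": reference codon ", cod$codon,
           " translates to ", translate_codon(cod$codon))
    alt_sense <- if (model$strand == "-") unname(COMPLEMENT[t$alt[i]]) else t$alt[i]
    alt_codon <- cod$codon
    substring(alt_codon, rn$pos_in_codon, rn$pos_in_codon) <- alt_sense
    if (translate_codon(alt_codon) != lab_alt)
      stop("target ", t$label[i], ": substituted codon ", alt_codon,
           " translates to ", translate_codon(alt_codon))
  }

  s <- panel$samples
  if (nrow(s) == 0) stop("no samples defined")
  if (any(nchar(s$fwd_barcode) != 8) || any(nchar(s$rev_barcode) != 8))
    stop("barcodes must be exactly 8 bp")
  key <- paste(s$fwd_barcode, s$rev_barcode)
  if (anyDuplicated(key))
    stop("duplicate barcode combination: ", key[duplicated(key)][1])
  if (any(!nzchar(s$island)) || any(!nzchar(s$species)))
    stop("every sample needs island and species")
  invisible(panel)
}
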
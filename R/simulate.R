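# Synthetic-data generator: Hardy-Weinberg genotypes at configurable allele
# frequencies, barcoded 2 x 250 bp paired amplicon reads with substitution
# errors and a per-base quality profile, and species-diagnostic IGS
# templates for the PCR-RFLP assay.

#' Simulation configuration
#'
#' @param n_samples number of mosquitoes to simulate.
#' @param allele_freq named numeric vector of true alternate-allele
#'   frequencies keyed by target label (e.g. `c(L995F = 0.122)`); targets
#'   not named are simulated at frequency 0.
#' @param depth mean read-pair depth per sample per amplicon (pairs are
#'   drawn Poisson around this mean).
#' @param read_length read length in bp for both mates (default 250,
#'   emulating a 2 x 250 bp paired-end run); each read carries its 8-bp
#'   barcode followed by template sequence.
#' @param error_rate i.i.d. per-base substitution error rate.
#' @param qual_mean,qual_sd,qual_decay per-base phred quality profile:
#'   quality at read position i is drawn from
#'   N(qual_mean - qual_decay * (i - 1), qual_sd), clamped to [2, 41].
#' @param seed integer seed fixing all randomness; two runs with the same
#'   configuration produce byte-identical output.
#' @param islands,species character vectors cycled over samples to assign
#'   metadata strata.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 40, allele_freq = c(L995F = 0.122),
                       depth = 200, read_length = 250, error_rate = 0.002,
                       qual_mean = 35, qual_sd = 3, qual_decay = 0.01,
                       seed = 1,
                       islands = c("Bubaque", "Tchedega", "Orangozinho",
                                   "Soga", "Uno"),
                       species = c("An. gambiae s.s.", "hybrid",
                                   "An. gambiae s.s.", "An. melas",
                                   "hybrid", "An. coluzzii")) {
  stopifnot(all(allele_freq >= 0 & allele_freq <= 1), depth > 0,
            n_samples >= 1, read_length > 8)
  structure(list(n_samples = as.integer(n_samples), allele_freq = allele_freq,
                 depth = depth, read_length = as.integer(read_length),
                 error_rate = error_rate, qual_mean = qual_mean,
                 qual_sd = qual_sd, qual_decay = qual_decay,
                 seed = as.integer(seed), islands = islands,
                 species = species),
            class = "sim_config")
}

#' Draw Hardy-Weinberg genotypes for a synthetic cohort
#'
#' Each sample's alternate-allele copy number at each target is drawn
#' Binomial(2, freq), i.e. genotype proportions p^2 / 2pq / q^2.  Samples
#' are assigned islands, species labels and unique dual-barcode
#' combinations (split into pools when the cohort exceeds the number of
#' barcode combinations).
#'
#' @param panel an `amplicon_panel`.
#' @param config a [sim_config()].
#' @return a `truth_set`: list with `samples` (sample_id, pool, barcodes,
#'   island, species) and `genotypes` (long data frame sample_id, label,
#'   copies).
#' @export
draw_genotypes <- function(panel, config) {
  set.seed(config$seed)
  n <- config$n_samples
  labels <- panel$targets$label
  freq <- setNames(rep(0, length(labels)), labels)
  known <- intersect(names(config$allele_freq), labels)
  unknown <- setdiff(names(config$allele_freq), labels)
  if (length(unknown) > 0)
    stop("allele_freq names not in the panel target list: ",
         paste(unknown, collapse = ", "))
  freq[known] <- config$allele_freq[known]

  geno <- do.call(rbind, lapply(labels, function(lab) {
    data.frame(sample_id = sprintf("SIM%04d", seq_len(n)), label = lab,
               copies = rbinom(n, 2L, freq[[lab]]), stringsAsFactors = FALSE)
  }))

  fwd <- panel$barcodes$forward
  rev <- panel$barcodes$reverse
  per_pool <- length(fwd) * length(rev)
  idx <- seq_len(n) - 1L
  within <- idx %% per_pool
  samples <- data.frame(
    sample_id = sprintf("SIM%04d", seq_len(n)),
    pool = idx %/% per_pool + 1L,
    fwd_barcode = unname(fwd[within %% length(fwd) + 1L]),
    rev_barcode = unname(rev[within %/% length(fwd) + 1L]),
    island = rep(config$islands, length.out = n),
    species = rep(config$species, length.out = n),
    stringsAsFactors = FALSE)

  structure(list(samples = samples, genotypes = geno, freq = freq),
            class = "truth_set")
}

#' True alternate-allele frequencies realized in a truth set
#' @param truth a `truth_set`.
#' @return named numeric vector, in percent, per target label.
#' @export
truth_frequencies <- function(truth) {
  with(truth$genotypes,
       100 * tapply(copies, label, sum) /
         (2 * tapply(copies, label, length)))[unique(truth$genotypes$label)]
}

# per-sample haplotype pair for one amplicon: top-strand sequences with
# hom-alt substitutions applied; het sites returned separately for
# per-fragment coin flips
sample_haplotype <- function(panel, amplicon_id, truth, sample_id) {
  seq <- panel$sequences[[amplicon_id]]
  tg <- panel$targets[panel$targets$amplicon == amplicon_id, , drop = FALSE]
  g <- truth$genotypes
  g <- g[g$sample_id == sample_id & g$label %in% tg$label, , drop = FALSE]
  het <- list()
  for (i in seq_len(nrow(g))) {
    copies <- g$copies[i]
    if (copies == 0) next
    row <- tg[tg$label == g$label[i], ]
    lp <- local_pos(panel, amplicon_id, row$pos)
    if (copies == 2) substring(seq, lp, lp) <- row$alt
    else het[[length(het) + 1]] <- list(local = lp, alt = row$alt)
  }
  list(seq = seq, het = het)
}

#' Simulate one pooled, barcoded paired-end FASTQ pair
#'
#' Emits reads for every sample of one pool across all panel amplicons.
#' Each mate is `[8-bp barcode][template window]`: mate 1 reads the
#' amplicon top strand from the forward-primer end, mate 2 the bottom
#' strand from the reverse-primer end.  Heterozygous sites place the
#' alternate allele on a fragment with probability 0.5 (both mates of a
#' fragment agree); substitution errors are i.i.d.; qualities follow the
#' configured profile.  Read names carry no information about the truth.
#'
#' @param panel an `amplicon_panel`.
#' @param config a [sim_config()].
#' @param truth a `truth_set` from [draw_genotypes()].
#' @param pool pool number to simulate.
#' @param prefix output path prefix; `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are written (`.gz` appended when `gzip = TRUE`).
#' @param gzip write gzip-compressed FASTQ.
#' @return list with `fastq1`, `fastq2`, `samples` (the pool's sample
#'   sheet) and `n_pairs`.
#' @export
simulate_pool <- function(panel, config, truth, pool = 1L, prefix, gzip = FALSE) {
  rl <- config$read_length
  tlen <- rl - 8L
  if (any(nchar(panel$sequences) < rl))
    stop("read length ", rl, " exceeds an amplicon length")
  sam <- truth$samples[truth$samples$pool == pool, , drop = FALSE]
  if (nrow(sam) == 0) stop("no samples in pool ", pool)

  s1 <- s2 <- vector("list", nrow(sam) * nrow(panel$amplicons))
  k <- 0L
  for (si in seq_len(nrow(sam))) {
    for (amp in panel$amplicons$id) {
      k <- k + 1L
      n_pairs <- rpois(1L, config$depth)
      if (n_pairs == 0) { s1[[k]] <- character(0); s2[[k]] <- character(0); next }
      hap <- sample_haplotype(panel, amp, truth, sam$sample_id[si])
      L <- nchar(hap$seq)
      m1 <- paste0(sam$fwd_barcode[si], substring(hap$seq, 1, tlen))
      m2 <- paste0(sam$rev_barcode[si], substring(rev_comp(hap$seq), 1, tlen))
      r1 <- rep(m1, n_pairs)
      r2 <- rep(m2, n_pairs)
      for (h in hap$het) {
        carry <- rbinom(n_pairs, 1L, 0.5) == 1L  # same fragment, both mates
        p1 <- 8L + h$local
        if (p1 <= rl && any(carry))
          substring(r1[carry], p1, p1) <- h$alt
        p2 <- 8L + (L - h$local + 1L)
        if (p2 <= rl && any(carry))
          substring(r2[carry], p2, p2) <- unname(COMPLEMENT[h$alt])
      }
      s1[[k]] <- r1
      s2[[k]] <- r2
    }
  }
  r1 <- unlist(s1, use.names = FALSE)
  r2 <- unlist(s2, use.names = FALSE)
  r1 <- add_errors_cpp(r1, config$error_rate)
  r2 <- add_errors_cpp(r2, config$error_rate)
  q1 <- sim_quals_cpp(length(r1), rl, config$qual_mean, config$qual_sd,
                      config$qual_decay)
  q2 <- sim_quals_cpp(length(r2), rl, config$qual_mean, config$qual_sd,
                      config$qual_decay)
  ids <- sprintf("pool%d_read%07d", pool, seq_along(r1))

  ext <- if (gzip) ".fastq.gz" else ".fastq"
  f1 <- paste0(prefix, "_R1", ext)
  f2 <- paste0(prefix, "_R2", ext)
  write_fastq(ids, r1, q1, f1)
  write_fastq(ids, r2, q2, f2)
  list(fastq1 = f1, fastq2 = f2,
       samples = sam[, c("sample_id", "fwd_barcode", "rev_barcode",
                         "island", "species")],
       n_pairs = length(r1))
}

#' Simulate a whole cohort (all pools) plus its truth set
#'
#' Convenience wrapper: draws genotypes, then simulates one FASTQ pair per
#' pool under a single seeded RNG stream.
#'
#' @inheritParams simulate_pool
#' @param out_dir directory for the FASTQ files.
#' @return list with `truth` and `pools` (list of [simulate_pool()]
#'   results).
#' @export
simulate_cohort <- function(panel, config, out_dir, gzip = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- draw_genotypes(panel, config)   # seeds the RNG stream
  pools <- lapply(sort(unique(truth$samples$pool)), function(p) {
    simulate_pool(panel, config, truth, pool = p,
                  prefix = file.path(out_dir, sprintf("pool%d", p)),
                  gzip = gzip)
  })
  # truth TSV for external harnesses
  write_tsv(truth$genotypes, file.path(out_dir, "truth_genotypes.tsv"))
  write_tsv(truth$samples, file.path(out_dir, "truth_samples.tsv"))
  list(truth = truth, pools = pools)
}

# ---- species-diagnostic IGS templates for the PCR-RFLP assay ------------

#' Diagnostic band specification for the IGS PCR-RFLP assay
#'
#' The published patterns: An. gambiae s.s. 367-bp product cut by HhaI into
#' 257 + 110 bp; An. coluzzii 367 bp uncut; An. arabiensis 292 bp; An.
#' melas 435 bp.
#'
#' @return data frame with species, reverse-primer key, product size and
#'   HhaI fragment sizes (comma-separated).
#' @export
igs_band_spec <- function() {
  data.frame(
    species = c("An. gambiae s.s.", "An. coluzzii", "An. arabiensis",
                "An. melas"),
    reverse = c("gambiae", "gambiae", "arabiensis", "melas"),
    product = c(367L, 367L, 292L, 435L),
    fragments = c("257,110", "367", "292", "435"),
    stringsAsFactors = FALSE)
}

#' Build synthetic IGS template sequences for the species assay
#'
#' Constructs, per species, a template whose in-silico PCR product with the
#' universal forward primer and the species' reverse primer has the
#' specified size, and whose HhaI digestion reproduces the specified
#' diagnostic fragments.  Templates are synthetic: the real IGS sequences
#' are not reproduced, only the printed band behaviour.
#'
#' @param spec a band specification as from [igs_band_spec()].
#' @param assay the primer/enzyme definition from [rflp_assay()].
#' @param file optional FASTA path to write the templates to.
#' @return named character vector of template sequences (top strand).
#' @export
build_igs_templates <- function(spec = igs_band_spec(), assay = rflp_assay(),
                                file = NULL) {
  templates <- character(nrow(spec))
  names(templates) <- spec$species
  for (i in seq_len(nrow(spec))) {
    frags <- as.integer(strsplit(spec$fragments[i], ",")[[1]])
    if (sum(frags) != spec$product[i])
      stop("band specification for ", spec$species[i],
           " is inconsistent: fragments ", spec$fragments[i],
           " do not sum to the product size ", spec$product[i])
    fwd <- assay$universal_f
    rev <- assay$reverse[[spec$reverse[i]]]
    inner_len <- spec$product[i] - nchar(fwd) - nchar(rev)
    if (inner_len < 0) stop("product shorter than the primers")
    # site-free filler with recognition sites written in only at the cut
    # points; retried deterministically if a junction recreates a site
    attempt <- 0L
    repeat {
      filler <- scrub_sites(
        paste(lcg_bases(inner_len, seed = 90210 + i * 17 + attempt * 1009),
              collapse = ""), assay$site)
      product <- paste0(fwd, filler, rev_comp(rev))
      if (length(frags) > 1) {
        for (cp in cumsum(frags[-length(frags)])) {
          # the enzyme cuts after `cut_offset` bases of the site, so a site
          # starting at cp - cut_offset + 1 cuts after position cp
          substring(product, cp - assay$cut_offset + 1,
                    cp - assay$cut_offset + nchar(assay$site)) <- assay$site
        }
      }
      if (identical(sort(digest(product, assay$site, assay$cut_offset)),
                    sort(frags))) break
      attempt <- attempt + 1L
      if (attempt > 100L) stop("could not realize the band specification")
    }
    pad5 <- scrub_sites(paste(lcg_bases(30, seed = 555 + i), collapse = ""),
                        assay$site)
    pad3 <- scrub_sites(paste(lcg_bases(30, seed = 777 + i), collapse = ""),
                        assay$site)
    templates[i] <- paste0(pad5, product, pad3)
  }
  if (!is.null(file)) {
    labels <- paste0(gsub("[. ]+", "_", names(templates)), "_synthetic_IGS")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(templates, labels)), file, width = 60)
  }
  templates
}

# remove every occurrence of an enzyme site from a sequence by toggling its
# first base
scrub_sites <- function(seq, site) {
  repeat {
    p <- regexpr(site, seq, fixed = TRUE)
    if (p < 0) return(seq)
    cur <- substring(seq, p, p)
    substring(seq, p, p) <- setdiff(BASES, cur)[1]
  }
}
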
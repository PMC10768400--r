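# SNP calling and genotyping: two internal callers over pileup columns,
# intersection (or union) combining, depth filters, alternate-allele
# fraction genotyping, cohort-level retention rules and coding-effect
# annotation.

#' Frequency-based caller (caller A)
#'
#' Emits the highest-count non-reference base of a column when its
#' fraction of the passing depth reaches `min_alt_frac`.
#'
#' @param counts named base counts (A/C/G/T) of one pileup column.
#' @param ref reference base at the column.
#' @param min_alt_frac minimum alternate-allele fraction.
#' @return list(alt, ad, dp) or NULL when no candidate.
#' @export
caller_frequency <- function(counts, ref, min_alt_frac = 0.05) {
  dp <- sum(counts)
  if (dp == 0) return(NULL)
  alt_counts <- counts[setdiff(BASES, ref)]
  ad <- max(alt_counts)
  if (ad == 0 || ad / dp < min_alt_frac) return(NULL)
  list(alt = names(alt_counts)[which.max(alt_counts)], ad = unname(ad),
       dp = unname(dp))
}

#' Error-model caller (caller B)
#'
#' Emits a column's top alternate base when its count is inconsistent with
#' sequencing error: the upper-tail binomial probability of observing at
#' least that many errors at `error_rate` must fall below `alpha`.
#'
#' @inheritParams caller_frequency
#' @param error_rate assumed per-base error rate.
#' @param alpha upper-tail significance cutoff.
#' @return list(alt, ad, dp, p) or NULL when no candidate.
#' @export
caller_binomial <- function(counts, ref, error_rate = 0.005, alpha = 1e-3) {
  dp <- sum(counts)
  if (dp == 0) return(NULL)
  alt_counts <- counts[setdiff(BASES, ref)]
  ad <- max(alt_counts)
  if (ad == 0) return(NULL)
  p <- pbinom(ad - 1, dp, error_rate, lower.tail = FALSE)  # P(X >= ad)
  if (p >= alpha) return(NULL)
  list(alt = names(alt_counts)[which.max(alt_counts)], ad = unname(ad),
       dp = unname(dp), p = unname(p))
}

#' Combine the two callers and apply depth filters (per sample)
#'
#' A site survives iff it is flagged by both callers (`combine =
#' "intersection"`, the default) or by either (`"union"`), its alternate
#' depth is at least `min_alt_depth` and its passing depth at least
#' `min_depth`.  Order-independent in its inputs.
#'
#' @param cand_a,cand_b candidate data frames with columns `key` (site
#'   identifier), `ad`, `dp` computed on identical pileups.
#' @param min_alt_depth minimum alternate allele depth (default 10).
#' @param min_depth minimum read depth (default 30).
#' @param combine `"intersection"` or `"union"`.
#' @return the surviving subset (columns of `cand_a`, or of the union).
#' @export
combine_and_filter <- function(cand_a, cand_b, min_alt_depth = 10,
                               min_depth = 30,
                               combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  if (combine == "intersection") {
    out <- cand_a[cand_a$key %in% cand_b$key, , drop = FALSE]
  } else {
    out <- rbind(cand_a, cand_b[!(cand_b$key %in% cand_a$key), , drop = FALSE])
  }
  out <- out[out$ad >= min_alt_depth & out$dp >= min_depth, , drop = FALSE]
  out[order(out$key), , drop = FALSE]
}

#' Genotype class from an alternate-allele fraction
#'
#' `< 0.25` homozygous reference; `0.25`-`0.75` (inclusive at both ends)
#' heterozygous; `> 0.75` homozygous alternate.  The three classes
#' partition `[0, 1]`.
#'
#' @param alt_fraction numeric vector in `[0, 1]`.
#' @return character vector: `hom_ref`, `het` or `hom_alt`.
#' @export
classify_genotype <- function(alt_fraction) {
  stopifnot(all(alt_fraction >= 0 & alt_fraction <= 1))
  ifelse(alt_fraction < 0.25, "hom_ref",
         ifelse(alt_fraction <= 0.75, "het", "hom_alt"))
}

# vectorized dual-caller candidate discovery over one sample's pileups
call_sample_variants <- function(pileups, panel, min_alt_frac = 0.05,
                                 error_rate = 0.005, alpha = 1e-3,
                                 min_alt_depth = 10, min_depth = 30,
                                 combine = "intersection") {
  out <- list()
  for (amp in names(pileups)) {
    m <- pileups[[amp]][BASES, , drop = FALSE]
    L <- ncol(m)
    refseq <- strsplit(panel$sequences[[amp]], "")[[1]]
    ref_row <- match(refseq, BASES)
    dp <- colSums(m)
    malt <- m
    malt[cbind(ref_row, seq_len(L))] <- -1L   # mask the reference base
    ad <- apply(malt, 2, max)
    alt <- BASES[apply(malt, 2, which.max)]
    ad[ad < 0] <- 0L
    frac <- ifelse(dp > 0, ad / dp, 0)
    a_flag <- dp > 0 & ad > 0 & frac >= min_alt_frac
    b_flag <- dp > 0 & ad > 0 &
      pbinom(ad - 1, dp, error_rate, lower.tail = FALSE) < alpha
    keep <- if (combine == "intersection") a_flag & b_flag else a_flag | b_flag
    keep <- keep & ad >= min_alt_depth & dp >= min_depth
    if (!any(keep)) next
    pos <- which(keep)
    out[[amp]] <- data.frame(
      amplicon = amp, local = pos,
      pos = amplicon_start(panel, amp) + pos - 1L,
      chrom = panel$amplicons$chrom[match(amp, panel$amplicons$id)],
      ref = refseq[pos], alt = alt[pos], ad = ad[pos], dp = dp[pos],
      caller_a = a_flag[pos], caller_b = b_flag[pos],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(amplicon = character(0), local = integer(0),
                      pos = integer(0), chrom = character(0),
                      ref = character(0), alt = character(0),
                      ad = integer(0), dp = integer(0),
                      caller_a = logical(0), caller_b = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genotype every sample at a list of sites
#'
#' Assigns the genotype class from the alternate-allele fraction of the
#' quality-passing pileup at each site; samples whose passing depth falls
#' below `min_depth` are `no_call`.
#'
#' @param pileups_by_sample named list (sample id) of `pileup_set`s.
#' @param panel an `amplicon_panel`.
#' @param sites data frame with `amplicon`, `local`, `pos`, `ref`, `alt`.
#' @param min_depth minimum passing depth for a call.
#' @return long data frame: sample_id, amplicon, pos, ref, alt, ref_depth,
#'   alt_depth (AD), depth (DP), alt_frac, class.
#' @export
genotype_sites <- function(pileups_by_sample, panel, sites, min_depth = 30) {
  res <- lapply(names(pileups_by_sample), function(s) {
    p <- pileups_by_sample[[s]]
    rd <- ad <- dp <- integer(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      m <- p[[sites$amplicon[i]]]
      rd[i] <- m[sites$ref[i], sites$local[i]]
      ad[i] <- m[sites$alt[i], sites$local[i]]
      dp[i] <- sum(m[BASES, sites$local[i]])
    }
    frac <- ifelse(dp > 0, ad / dp, 0)
    cls <- ifelse(dp < min_depth, "no_call", classify_genotype(frac))
    data.frame(sample_id = s, amplicon = sites$amplicon, pos = sites$pos,
               ref = sites$ref, alt = sites$alt, ref_depth = rd,
               alt_depth = ad, depth = dp, alt_frac = frac, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cohort-level site retention
#'
#' Drops sites whose alternate allele is carried (het or hom_alt) by at
#' most one sample, and sites classified species-specific: alternate
#' allele frequency at least `fixed_hi` within one species and at most
#' `other_lo` in every other species having at least `min_called` called
#' samples.
#'
#' @param geno long genotype data frame from [genotype_sites()].
#' @param species named character vector: species label per sample id.
#' @param fixed_hi,other_lo,min_called species-specificity rule
#'   parameters.
#' @return list with `retained` (site keys `amplicon:pos:alt`), and
#'   `dropped` (data frame site, reason).
#' @export
cohort_retention <- function(geno, species, fixed_hi = 0.95, other_lo = 0.05,
                             min_called = 5) {
  geno$key <- paste(geno$amplicon, geno$pos, geno$alt, sep = ":")
  keys <- unique(geno$key)
  retained <- character(0)
  dropped <- data.frame(site = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (k in keys) {
    g <- geno[geno$key == k & geno$class != "no_call", , drop = FALSE]
    carriers <- sum(g$class %in% c("het", "hom_alt"))
    if (carriers <= 1) {
      dropped <- rbind(dropped,
                       data.frame(site = k, reason = "singleton",
                                  stringsAsFactors = FALSE))
      next
    }
    sp <- species[g$sample_id]
    copies <- c(hom_ref = 0, het = 1, hom_alt = 2)[g$class]
    af <- tapply(copies, sp, sum) / (2 * tapply(copies, sp, length))
    n_called <- tapply(copies, sp, length)
    spec_specific <- FALSE
    for (s in names(af)) {
      others <- setdiff(names(af), s)
      others <- others[n_called[others] >= min_called]
      if (af[[s]] >= fixed_hi && length(others) > 0 &&
          all(af[others] <= other_lo)) spec_specific <- TRUE
    }
    if (spec_specific) {
      dropped <- rbind(dropped,
                       data.frame(site = k, reason = "species_specific",
                                  stringsAsFactors = FALSE))
    } else {
      retained <- c(retained, k)
    }
  }
  list(retained = retained, dropped = dropped)
}

#' Annotate the coding effect of a site
#'
#' Coding positions are translated through the gene model (synonymous or
#' missense, with a `REF<residue>ALT` label); intronic positions within
#' `splice_region` bases of an exon boundary are `splice_region`, other
#' intronic positions `intron`; positions 5' of the modeled transcript
#' within `upstream_limit` are `upstream`.
#'
#' @param panel an `amplicon_panel`.
#' @param amplicon amplicon id.
#' @param pos 1-based genome position.
#' @param ref,alt top-strand reference and alternate base.
#' @param splice_region intron bases near an exon boundary called splice
#'   region (default 3).
#' @param upstream_limit maximum 5' distance for `upstream` (default 5000).
#' @param strict error on unclassifiable positions (otherwise returns
#'   effect `"unclassified"`).
#' @return list with `effect` and `label` (NA unless coding).
#' @export
annotate_site <- function(panel, amplicon, pos, ref, alt, splice_region = 3,
                          upstream_limit = 5000, strict = TRUE) {
  model <- panel$models[[amplicon]]
  ex <- model$exons
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (in_exon) {
    rn <- residue_number(model, pos)
    cod <- codon_at(panel, amplicon, rn$codon)
    ref_aa <- translate_codon(cod$codon)
    alt_sense <- if (model$strand == "-") unname(COMPLEMENT[alt]) else alt
    alt_codon <- cod$codon
    substring(alt_codon, rn$pos_in_codon, rn$pos_in_codon) <- alt_sense
    alt_aa <- translate_codon(alt_codon)
    effect <- if (ref_aa == alt_aa) "synonymous" else "missense"
    return(list(effect = effect,
                label = paste0(ref_aa, rn$codon, alt_aa)))
  }
  if (pos > min(ex$start) && pos < max(ex$end)) {   # intronic
    d <- min(abs(pos - c(ex$start, ex$end)))
    effect <- if (d <= splice_region) "splice_region" else "intron"
    return(list(effect = effect, label = NA_character_))
  }
  five_prime_dist <- if (model$strand == "+") min(ex$start) - pos
                     else pos - max(ex$end)
  if (five_prime_dist > 0 && five_prime_dist <= upstream_limit)
    return(list(effect = "upstream", label = NA_character_))
  if (strict)
    stop("position ", pos, " on ", amplicon, " is outside all effect ",
         "categories")
  list(effect = "unclassified", label = NA_character_)
}

#' Write genotype calls as a multi-sample VCF 4.2
#'
#' One record per site; `FORMAT` is `GT:AD:DP` per sample; `INFO` carries
#' the gene, effect and amino-acid label.
#'
#' @param geno long genotype data frame from [genotype_sites()].
#' @param panel an `amplicon_panel`.
#' @param path output path.
#' @param annotations optional data frame keyed like `geno` sites with
#'   columns `amplicon`, `pos`, `effect`, `label`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, panel, path, annotations = NULL) {
  samples <- unique(geno$sample_id)
  sites <- unique(geno[, c("amplicon", "pos", "ref", "alt")])
  sites$chrom <- panel$amplicons$chrom[match(sites$amplicon,
                                             panel$amplicons$id)]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ampliresist",
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=AMP,Number=1,Type=String,Description=\"Amplicon\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect\">",
    "##INFO=<ID=AAL,Number=1,Type=String,Description=\"Amino acid label\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allele depths (ref,alt)\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Passing depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)

  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               no_call = "./.")
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    g <- geno[geno$amplicon == s$amplicon & geno$pos == s$pos &
                geno$alt == s$alt, , drop = FALSE]
    g <- g[match(samples, g$sample_id), , drop = FALSE]
    gene <- panel$amplicons$gene[match(s$amplicon, panel$amplicons$id)]
    info <- paste0("GENE=", gene, ";AMP=", s$amplicon)
    if (!is.null(annotations)) {
      a <- annotations[annotations$amplicon == s$amplicon &
                         annotations$pos == s$pos, , drop = FALSE]
      if (nrow(a) > 0) {
        info <- paste0(info, ";EFF=", a$effect[1])
        if (!is.na(a$label[1])) info <- paste0(info, ";AAL=", a$label[1])
      }
    }
    fmt <- sprintf("%s:%d,%d:%d", gt_code[g$class], g$ref_depth,
                   g$alt_depth, g$depth)
    writeLines(paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS",
                       info, "GT:AD:DP", fmt), collapse = "\t"), con)
  }
  invisible(path)
}
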
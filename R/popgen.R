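# Population-level summaries: genotype and allele-frequency tables per
# stratum, chi-square comparisons of allele counts between strata, and
# per-sample cumulative mutation loads.

#' Alternate-allele frequency from genotype frequencies
#'
#' For genotype frequencies in percent, the allele frequency is
#' `het / 2 + hom_alt` (each heterozygote carries one of two alternate
#' alleles, each homozygote two of two).
#'
#' @param hom_ref,het,hom_alt genotype frequencies in percent; they must
#'   sum to 100 within 0.2 (printed-rounding slack).
#' @return alternate-allele frequency in percent.
#' @export
allele_frequency <- function(hom_ref, het, hom_alt) {
  v <- c(hom_ref, het, hom_alt)
  if (any(v < 0 | v > 100)) stop("genotype frequencies must be in [0, 100]")
  if (abs(hom_ref + het + hom_alt - 100) > 0.2)
    stop("genotype frequencies must sum to 100 (+/- 0.2)")
  het / 2 + hom_alt
}

#' Genotype and allele-frequency tables per stratum
#'
#' One table per stratum level (island or species).  For each target SNP
#' the denominator counts only samples with a genotype call at that site
#' (N = 2 x called samples); strata with no alternate alleles report
#' frequency 0.
#'
#' @param geno long genotype data frame (see [genotype_sites()]) with a
#'   `label` column naming each site.
#' @param samples sample sheet with `sample_id` and the stratifying
#'   column.
#' @param stratify_by `"island"`, `"species"`, or `"all"` for a single
#'   pooled table.
#' @return data frame with stratum, label, n_called, n_alleles,
#'   hom_ref/het/hom_alt counts and percentages, and alt allele frequency
#'   (percent, full precision).
#' @export
stratified_table <- function(geno, samples, stratify_by = c("all", "island",
                                                            "species")) {
  stratify_by <- match.arg(stratify_by)
  if (stratify_by == "all") {
    strat <- setNames(rep("all", nrow(samples)), samples$sample_id)
  } else {
    if (!stratify_by %in% names(samples))
      stop("unknown stratifying label: ", stratify_by)
    strat <- setNames(samples[[stratify_by]], samples$sample_id)
  }
  if (any(!geno$sample_id %in% names(strat)))
    stop("genotypes include samples absent from the sample sheet")
  geno$stratum <- strat[geno$sample_id]

  out <- list()
  for (st in unique(geno$stratum)) {
    for (lab in unique(geno$label)) {
      g <- geno[geno$stratum == st & geno$label == lab &
                  geno$class != "no_call", , drop = FALSE]
      n <- nrow(g)
      cnt <- c(hom_ref = sum(g$class == "hom_ref"),
               het = sum(g$class == "het"),
               hom_alt = sum(g$class == "hom_alt"))
      af <- if (n > 0) 100 * (cnt[["het"]] + 2 * cnt[["hom_alt"]]) / (2 * n)
            else NA_real_
      out[[length(out) + 1]] <- data.frame(
        stratum = st, label = lab, n_called = n, n_alleles = 2L * n,
        hom_ref = cnt[["hom_ref"]], het = cnt[["het"]],
        hom_alt = cnt[["hom_alt"]],
        hom_ref_pct = if (n > 0) 100 * cnt[["hom_ref"]] / n else NA_real_,
        het_pct = if (n > 0) 100 * cnt[["het"]] / n else NA_real_,
        hom_alt_pct = if (n > 0) 100 * cnt[["hom_alt"]] / n else NA_real_,
        alt_freq_pct = af, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chi-square comparison of allele counts between two strata
#'
#' Pearson chi-square on the 2 x 2 table of alternate/reference allele
#' counts, df = 1, with Yates continuity correction by default (matching
#' R's `chisq.test` default for 2 x 2 tables).
#'
#' @param alt1,ref1 alternate/reference allele counts in stratum 1.
#' @param alt2,ref2 counts in stratum 2.
#' @param yates apply the continuity correction.
#' @return list with `table`, `statistic`, `df`, `p.value`, `yates`;
#'   degenerate tables (a zero margin) return NA statistic and p with
#'   `degenerate = TRUE`.
#' @export
chi2_compare <- function(alt1, ref1, alt2, ref2, yates = TRUE) {
  tab <- matrix(c(alt1, ref1, alt2, ref2), nrow = 2,
                dimnames = list(c("alt", "ref"), c("stratum1", "stratum2")))
  if (any(tab < 0)) stop("allele counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, statistic = NA_real_, df = 1L,
                p.value = NA_real_, yates = yates, degenerate = TRUE))
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  list(table = tab, statistic = unname(ct$statistic), df = 1L,
       p.value = ct$p.value, yates = yates, degenerate = FALSE)
}

#' Pairwise chi-square comparisons of a target's allele frequency across
#' strata
#'
#' @param tab a [stratified_table()] result filtered to one label.
#' @param yates continuity correction flag.
#' @param p_adjust multiple-testing adjustment method (`"none"`, the
#'   default, reports raw p-values; any `p.adjust` method is accepted).
#' @return data frame of stratum pairs with statistics and p-values.
#' @export
compare_strata <- function(tab, yates = TRUE, p_adjust = "none") {
  stopifnot(length(unique(tab$label)) == 1)
  res <- list()
  for (i in seq_len(nrow(tab))) for (j in seq_len(nrow(tab))) {
    if (j <= i) next
    alt_i <- tab$het[i] + 2 * tab$hom_alt[i]
    alt_j <- tab$het[j] + 2 * tab$hom_alt[j]
    ct <- chi2_compare(alt_i, tab$n_alleles[i] - alt_i,
                       alt_j, tab$n_alleles[j] - alt_j, yates = yates)
    res[[length(res) + 1]] <- data.frame(
      stratum1 = tab$stratum[i], stratum2 = tab$stratum[j],
      statistic = ct$statistic, p.value = ct$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p.adjusted <- p.adjust(out$p.value, method = p_adjust)
  out
}

#' Cumulative resistance-mutation load per sample
#'
#' Counts, per sample and gene, the target sites at which the sample
#' carries the alternate allele (het or hom_alt).
#'
#' @param geno long genotype data frame with `label` column.
#' @param panel an `amplicon_panel` (supplies the gene of each label).
#' @return data frame sample_id x gene with the mutation count, plus a
#'   wide column per gene of interest (`vgsc`, `rdl`, `gste2`, `ace1`).
#' @export
mutation_load <- function(geno, panel) {
  gene_of <- setNames(panel$targets$gene, panel$targets$label)
  g <- geno[geno$class %in% c("het", "hom_alt") &
              geno$label %in% names(gene_of), , drop = FALSE]
  samples <- unique(geno$sample_id)
  genes <- unique(panel$targets$gene)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (gn in genes) {
    labs <- names(gene_of)[gene_of == gn]
    cnt <- table(factor(g$sample_id[g$label %in% labs], levels = samples))
    out[[gn]] <- as.integer(cnt)
  }
  out
}

#' Render a frequency table in the report convention
#'
#' Percentages rounded to one decimal, half away from zero; strata with
#' zero alternate alleles rendered as `"-"`.
#'
#' @param tab a [stratified_table()] result.
#' @return data frame of formatted character columns.
#' @export
format_frequency_table <- function(tab) {
  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", round_half_up(x, 1)))
  data.frame(stratum = tab$stratum, label = tab$label, N = tab$n_alleles,
             hom_ref = fmt(tab$hom_ref_pct), het = fmt(tab$het_pct),
             hom_alt = fmt(tab$hom_alt_pct),
             alt_freq = ifelse(!is.na(tab$alt_freq_pct) & tab$alt_freq_pct == 0,
                               "-", fmt(tab$alt_freq_pct)),
             stringsAsFactors = FALSE)
}
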
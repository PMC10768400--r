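test_that("allele frequency is het/2 + hom_alt and bounded", {
  expect_equal(allele_frequency(100, 0, 0), 0)
  expect_equal(allele_frequency(0, 0, 100), 100)
  expect_equal(allele_frequency(0, 100, 0), 50)
  expect_error(allele_frequency(90, 20, 10), "sum to 100")
  expect_error(allele_frequency(-5, 55, 50), "\\[0, 100\\]")
  # linear in its arguments over a grid, always in [0, 100]
  for (het in seq(0, 100, by = 10)) {
    for (hom_alt in seq(0, 100 - het, by = 10)) {
      f <- allele_frequency(100 - het - hom_alt, het, hom_alt)
      expect_gte(f, 0)
      expect_lte(f, 100)
      expect_equal(f, het / 2 + hom_alt)
    }
  }
})

test_that("stratified tables count only called samples in the denominator", {
  # six-sample toy cohort, hand-counted: two hom_ref, one het, one hom_alt,
  # two no_call -> N = 8 alleles, alt freq = (1 + 2) / 8 = 37.5%
  geno <- data.frame(
    sample_id = sprintf("m%d", 1:6), amplicon = "rdl", pos = 100L,
    ref = "A", alt = "G", label = "A296G",
    class = c("hom_ref", "hom_ref", "het", "hom_alt", "no_call", "no_call"),
    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("m%d", 1:6),
                        island = rep(c("Bubaque", "Soga"), each = 3),
                        species = "An. gambiae s.s.", stringsAsFactors = FALSE)
  tab <- stratified_table(geno, samples, "all")
  expect_equal(tab$n_called, 4)
  expect_equal(tab$n_alleles, 8)
  expect_equal(tab$alt_freq_pct, 37.5)

  by_isl <- stratified_table(geno, samples, "island")
  bub <- by_isl[by_isl$stratum == "Bubaque", ]    # m1 m2 m3: 2 hom_ref 1 het
  expect_equal(bub$n_called, 3)
  expect_equal(bub$alt_freq_pct, 100 * 1 / 6)
  soga <- by_isl[by_isl$stratum == "Soga", ]      # m4 hom_alt, two no_call
  expect_equal(soga$n_called, 1)
  expect_equal(soga$alt_freq_pct, 100)

  # pooled frequency equals the call-weighted mean of stratum frequencies
  w <- by_isl$n_alleles / sum(by_isl$n_alleles)
  expect_equal(sum(w * by_isl$alt_freq_pct), tab$alt_freq_pct)

  expect_error(stratified_table(geno, samples, "village"), "should be one of")
})

test_that("chi-square matches the closed-form oracle", {
  # identical proportions give a zero statistic
  same <- chi2_compare(10, 90, 10, 90)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # worked 2x2: (21 alt / 59 ref) vs (1 alt / 55 ref), uncorrected
  got <- chi2_compare(21, 59, 1, 55, yates = FALSE)
  ora <- chi2_oracle(matrix(c(21, 59, 1, 55), 2), yates = FALSE)
  expect_equal(got$statistic, ora$statistic, tolerance = 1e-12)
  expect_equal(got$p.value, ora$p.value, tolerance = 1e-12)

  set.seed(2024)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    got <- chi2_compare(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2],
                        yates = FALSE)
    ora <- chi2_oracle(tab, yates = FALSE)
    expect_equal(got$statistic, ora$statistic, tolerance = 1e-10)
    expect_equal(got$p.value, ora$p.value, tolerance = 1e-10)
    expect_equal(got$df, 1L)
    # the continuity correction can only weaken the evidence
    yat <- chi2_compare(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2],
                        yates = TRUE)
    expect_gte(yat$p.value, got$p.value)
  }

  # degenerate margin
  dg <- chi2_compare(0, 0, 5, 10)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p.value))
  expect_error(chi2_compare(-1, 5, 5, 5), "non-negative")
})

test_that("pairwise stratum comparison reports raw p-values by default", {
  tab <- data.frame(stratum = c("Bubaque", "Soga", "Uno"), label = "L995F",
                    n_called = c(40, 28, 21), n_alleles = c(80, 56, 42),
                    hom_ref = c(20, 26, 21), het = c(16, 2, 0),
                    hom_alt = c(4, 0, 0), stringsAsFactors = FALSE)
  cmp <- compare_strata(tab)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$p.adjusted, cmp$p.value)
  bon <- compare_strata(tab, p_adjust = "bonferroni")
  expect_true(all(bon$p.adjusted >= cmp$p.value))
})

test_that("mutation load counts carried target mutations per gene", {
  geno <- data.frame(
    sample_id = c("m1", "m1", "m1", "m2", "m2", "m3"),
    label = c("L995F", "N1570Y", "A296G", "L995F", "A1746S", "L995F"),
    class = c("het", "het", "hom_alt", "hom_ref", "hom_ref", "hom_alt"),
    stringsAsFactors = FALSE)
  load <- mutation_load(geno, demo)
  expect_equal(load$vgsc[load$sample_id == "m1"], 2)   # L995F + N1570Y
  expect_equal(load$rdl[load$sample_id == "m1"], 1)
  expect_equal(load$vgsc[load$sample_id == "m2"], 0)   # hom_ref carries none
  expect_equal(load$vgsc[load$sample_id == "m3"], 1)
})

test_that("report formatting rounds half away from zero and dashes zeros", {
  tab <- data.frame(stratum = "all", label = "P174L", n_called = 182,
                    n_alleles = 364, hom_ref = 88, het = 5, hom_alt = 89,
                    hom_ref_pct = 48.35, het_pct = 2.75, hom_alt_pct = 48.9,
                    alt_freq_pct = 50.25, stringsAsFactors = FALSE)
  f <- format_frequency_table(tab)
  expect_equal(f$alt_freq, "50.3")
  expect_equal(f$het, "2.8")
  zero <- tab
  zero$alt_freq_pct <- 0
  expect_equal(format_frequency_table(zero)$alt_freq, "-")
})
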
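cnt <- function(a = 0, c = 0, g = 0, t = 0) c(A = a, C = c, G = g, T = t)

test_that("the frequency caller needs a 5% alternate fraction", {
  expect_null(caller_frequency(cnt(a = 100), ref = "A"))
  out <- caller_frequency(cnt(a = 60, t = 40), ref = "A")
  expect_equal(out$alt, "T")
  expect_equal(out$ad, 40)
  expect_equal(out$dp, 100)
  expect_null(caller_frequency(cnt(a = 96, t = 4), ref = "A"))   # 4% < 5%
  expect_equal(caller_frequency(cnt(a = 95, t = 5), ref = "A")$ad, 5)
})

test_that("the binomial caller tests the alternate count against the error
          model", {
  # one alternate read in 100 at 0.5% error: P(X >= 1) = 1 - 0.995^100,
  # about 0.394 -> no call
  expect_equal(pbinom(0, 100, 0.005, lower.tail = FALSE), 1 - 0.995^100)
  expect_gt(1 - 0.995^100, 1e-3)
  expect_null(caller_binomial(cnt(a = 99, t = 1), ref = "A"))
  # ten alternate reads are inconsistent with error
  expect_lt(pbinom(9, 100, 0.005, lower.tail = FALSE), 1e-3)
  out <- caller_binomial(cnt(a = 90, t = 10), ref = "A")
  expect_equal(out$ad, 10)
  expect_null(caller_binomial(cnt(), ref = "A"))   # empty column
})

test_that("combining is an intersection by default with depth filters", {
  a <- data.frame(key = c("s1", "s2", "s3", "s4"),
                  ad = c(15, 15, 9, 15), dp = c(100, 29, 100, 100))
  b <- data.frame(key = c("s2", "s3", "s4"),
                  ad = c(15, 9, 15), dp = c(29, 100, 100))
  got <- combine_and_filter(a, b)
  expect_equal(got$key, "s4")       # s1: one caller; s2: depth; s3: alt depth
  u <- combine_and_filter(a, b, combine = "union")
  expect_setequal(u$key, c("s1", "s4"))
  # order independence
  got2 <- combine_and_filter(a[sample(4), ], b[sample(3), ])
  expect_equal(got, got2)
})

test_that("genotype classes partition [0,1] with het boundaries inclusive", {
  expect_equal(classify_genotype(0.10), "hom_ref")
  expect_equal(classify_genotype(0.50), "het")
  expect_equal(classify_genotype(0.25), "het")
  expect_equal(classify_genotype(0.75), "het")
  expect_equal(classify_genotype(0.249999), "hom_ref")
  expect_equal(classify_genotype(0.750001), "hom_alt")
  fracs <- seq(0, 1, by = 0.001)
  cls <- classify_genotype(fracs)
  expect_true(all(cls %in% c("hom_ref", "het", "hom_alt")))
  # monotone: the class index never decreases as the fraction grows
  idx <- match(cls, c("hom_ref", "het", "hom_alt"))
  expect_true(all(diff(idx) >= 0))
})

test_that("cohort retention drops singletons and species-specific sites", {
  mk <- function(classes) {
    data.frame(sample_id = sprintf("s%02d", seq_along(classes)),
               amplicon = "rdl", pos = 100L, ref = "A", alt = "G",
               class = classes, stringsAsFactors = FALSE)
  }
  sp <- setNames(c(rep("An. melas", 6), rep("An. gambiae s.s.", 6)),
                 sprintf("s%02d", 1:12))
  # alternate in exactly one sample -> dropped
  g1 <- mk(c("het", rep("hom_ref", 11)))
  r1 <- cohort_retention(g1, sp)
  expect_equal(r1$retained, character(0))
  expect_equal(r1$dropped$reason, "singleton")
  # fixed in melas, absent elsewhere -> species specific
  g2 <- mk(c(rep("hom_alt", 6), rep("hom_ref", 6)))
  r2 <- cohort_retention(g2, sp)
  expect_equal(r2$dropped$reason, "species_specific")
  # intermediate frequency in both species -> retained
  g3 <- mk(c("het", "het", rep("hom_ref", 4), "het", rep("hom_ref", 5)))
  r3 <- cohort_retention(g3, sp)
  expect_equal(r3$retained, "rdl:100:G")
})

test_that("annotation classifies coding, splice, intron and upstream sites", {
  kdr <- demo$targets[demo$targets$label == "L995F", ]
  a <- annotate_site(demo, "vgsc-II", kdr$pos, kdr$ref, kdr$alt)
  expect_equal(a$effect, "missense")
  expect_equal(a$label, "L995F")

  # third-position Leu codon change TTA -> TTG is synonymous
  syn <- annotate_site(demo, "vgsc-II", kdr$pos, kdr$ref, "G")
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$label, "L995L")

  # minus-strand gene: the target labels come out in sense coordinates
  p174 <- demo$targets[demo$targets$label == "P174L", ]
  am <- annotate_site(demo, "gste2", p174$pos, p174$ref, p174$alt)
  expect_equal(am$label, "P174L")

  # ace1 intron spans local 211..270 (genome start+210 .. start+269)
  st <- demo$amplicons$start[demo$amplicons$id == "ace1"]
  deep <- annotate_site(demo, "ace1", st + 239L, "A", "G")
  expect_equal(deep$effect, "intron")
  near <- annotate_site(demo, "ace1", st + 268L, "A", "G")  # 2 bp from exon 2
  expect_equal(near$effect, "splice_region")
  up <- annotate_site(demo, "ace1", st + 10L, "A", "G")
  expect_equal(up$effect, "upstream")
  expect_error(annotate_site(demo, "ace1", st + 460L, "A", "G"),
               "outside all effect")
  relaxed <- annotate_site(demo, "ace1", st + 460L, "A", "G", strict = FALSE)
  expect_equal(relaxed$effect, "unclassified")
})

test_that("VCF output round-trips through an independent parser", {
  skip_if_not_installed("VariantAnnotation")
  geno <- data.frame(
    sample_id = rep(c("m1", "m2", "m3"), each = 2),
    amplicon = rep(c("vgsc-II", "rdl"), 3),
    pos = rep(c(2422652L, 25429236L), 3),
    ref = rep(c("A", "C"), 3), alt = rep(c("T", "G"), 3),
    ref_depth = c(30, 50, 28, 2, 40, 50), alt_depth = c(28, 0, 30, 55, 2, 1),
    depth = c(58, 50, 58, 57, 42, 51),
    alt_frac = c(28/58, 0, 30/58, 55/57, 2/42, 1/51),
    class = c("het", "hom_ref", "het", "hom_alt", "hom_ref", "hom_ref"),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_vcf(geno, demo, path)
  v <- VariantAnnotation::readVcf(path)
  expect_equal(dim(v), c(2L, 3L))
  gt <- VariantAnnotation::geno(v)$GT
  expect_equal(unname(gt["2L:2422652_A/T", c("m1", "m2", "m3")]),
               c("0/1", "0/1", "0/0"))
  expect_equal(unname(gt["2L:25429236_C/G", "m2"]), "1/1")
  ad <- VariantAnnotation::geno(v)$AD
  expect_equal(unname(unlist(ad["2L:2422652_A/T", "m1"])), c(30, 28))
  dp <- VariantAnnotation::geno(v)$DP
  expect_equal(unname(dp["2L:25429236_C/G", "m2"]), 57)
})
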
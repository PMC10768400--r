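test_that("genotype draws follow Hardy-Weinberg at the configured frequency", {
  cfg0 <- zero_error_config(20, c(L995F = 0))
  t0 <- draw_genotypes(demo, cfg0)
  expect_true(all(t0$genotypes$copies == 0))

  cfg1 <- zero_error_config(20, c(L995F = 1))
  t1 <- draw_genotypes(demo, cfg1)
  g1 <- t1$genotypes[t1$genotypes$label == "L995F", ]
  expect_true(all(g1$copies == 2))

  # frequency recovery: mean allele frequency within 3 SE of the truth
  n <- 10000
  p <- 0.122
  cfg <- sim_config(n_samples = n, allele_freq = c(L995F = p), seed = 99)
  tr <- draw_genotypes(demo, cfg)
  est <- truth_frequencies(tr)[["L995F"]] / 100
  se <- sqrt(p * (1 - p) / (2 * n))
  expect_lt(abs(est - p), 3 * se)

  expect_error(draw_genotypes(demo, sim_config(allele_freq = c(BOGUS = 0.5))),
               "not in the panel target list")
})

test_that("barcode combinations are unique within a pool", {
  cfg <- zero_error_config(150, c(L995F = 0.1))
  tr <- draw_genotypes(demo, cfg)
  expect_equal(sort(unique(tr$samples$pool)), c(1L, 2L))
  for (p in unique(tr$samples$pool)) {
    s <- tr$samples[tr$samples$pool == p, ]
    expect_false(anyDuplicated(paste(s$fwd_barcode, s$rev_barcode)) > 0)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 4, allele_freq = c(L995F = 0.5), depth = 20,
                    seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_cohort(demo, cfg, d1)
  simulate_cohort(demo, cfg, d2)
  for (f in c("pool1_R1.fastq", "pool1_R2.fastq", "truth_genotypes.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("simulated depth tracks the configured mean over many amplicons", {
  cfg <- zero_error_config(20, c(L995F = 0.2), depth = 60, seed = 3)
  sim <- simulate_cohort(demo, cfg, tempfile())
  n_units <- 20 * nrow(demo$amplicons)   # 140 sample-amplicon units
  mean_depth <- sum(vapply(sim$pools, `[[`, 0L, "n_pairs")) / n_units
  expect_lt(abs(mean_depth - 60) / 60, 0.05)
})

test_that("reads carry the expected structure and alleles", {
  # one hom-alt sample, zero error: every read covering the target carries
  # the alternate base
  cfg <- zero_error_config(1, c(L995F = 1), depth = 30, seed = 5)
  tr <- draw_genotypes(demo, cfg)
  pool <- simulate_pool(demo, cfg, tr, prefix = tempfile())
  r2 <- read_fastq(pool$fastq2)
  expect_true(all(nchar(r2$seq) == 250))
  expect_true(all(substring(r2$seq, 1, 8) == tr$samples$rev_barcode[1]))
  # mate 2 reads the bottom strand; the kdr site (local 240 of 470) sits at
  # read position 8 + (470 - 240 + 1) = 239, base complement of alt T
  aln <- align_reads(substring(r2$seq, 9), demo)
  sel <- which(aln$amplicon == "vgsc-II")
  expect_gt(length(sel), 0)
  expect_true(all(substring(r2$seq[sel], 239, 239) == "A"))

  # a heterozygote at high depth: alternate fraction near one half
  cfgh <- zero_error_config(1, c(L995F = 0.5), depth = 200, seed = 20260924)
  trh <- draw_genotypes(demo, cfgh)
  trh$genotypes$copies[trh$genotypes$label == "L995F"] <- 1L
  poolh <- simulate_pool(demo, cfgh, trh, prefix = tempfile())
  rh <- read_fastq(poolh$fastq2)
  alnh <- align_reads(substring(rh$seq, 9), demo)
  hsel <- which(alnh$amplicon == "vgsc-II")
  frac <- mean(substring(rh$seq[hsel], 239, 239) == "A")
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.75)
})

test_that("read length cannot exceed the amplicon length", {
  cfg <- sim_config(n_samples = 1, read_length = 600)
  tr <- draw_genotypes(demo, cfg)
  expect_error(simulate_pool(demo, cfg, tr, prefix = tempfile()),
               "exceeds an amplicon length")
})

test_that("inconsistent band specifications are rejected", {
  spec <- igs_band_spec()
  spec$fragments[1] <- "100,150"
  spec$product[1] <- 300L
  expect_error(build_igs_templates(spec), "inconsistent")
})
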
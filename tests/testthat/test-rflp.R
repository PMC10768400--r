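assay <- rflp_assay()
igs <- build_igs_templates()

test_that("in-silico PCR reproduces the printed product sizes", {
  melas <- insilico_pcr(igs[["An. melas"]], assay$universal_f,
                        assay$reverse[["melas"]])
  expect_length(melas, 1)
  expect_equal(nchar(melas), 435)

  gam <- insilico_pcr(igs[["An. gambiae s.s."]], assay$universal_f,
                      assay$reverse[["gambiae"]])
  expect_equal(nchar(gam), 367)
  arab <- insilico_pcr(igs[["An. arabiensis"]], assay$universal_f,
                       assay$reverse[["arabiensis"]])
  expect_equal(nchar(arab), 292)

  # missing reverse site, and inverted primer orientation, yield no product
  expect_length(insilico_pcr(igs[["An. melas"]], assay$universal_f,
                             assay$reverse[["gambiae"]]), 0)
  expect_length(insilico_pcr(igs[["An. melas"]], rev_comp(assay$universal_f),
                             rev_comp(assay$reverse[["melas"]])), 0)
})

test_that("HhaI digestion cuts GCG^C and conserves length", {
  expect_equal(digest("ATATATATAT"), 10L)
  # 20-mer with two sites: AAGCGCAAAAGCGCAAAAAA cuts after 5 and 13
  expect_equal(digest("AAGCGCAAAAGCGCAAAAAA"), c(5L, 8L, 7L))

  gam <- insilico_pcr(igs[["An. gambiae s.s."]], assay$universal_f,
                      assay$reverse[["gambiae"]])
  expect_equal(sort(digest(gam), decreasing = TRUE), c(257L, 110L))
  col <- insilico_pcr(igs[["An. coluzzii"]], assay$universal_f,
                      assay$reverse[["gambiae"]])
  expect_equal(digest(col), 367L)    # no site: single uncut band

  set.seed(31)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:400, 1),
                      replace = TRUE), collapse = "")
    expect_equal(sum(digest(s)), nchar(s))
  }
})

test_that("band patterns classify to the printed species diagnostics", {
  expect_equal(classify_bands(435), "An. melas")
  expect_equal(classify_bands(292), "An. arabiensis")
  expect_equal(classify_bands(367), "An. coluzzii")
  expect_equal(classify_bands(c(257, 110)), "An. gambiae s.s.")
  expect_equal(classify_bands(c(257, 110, 367)), "hybrid")
  expect_equal(classify_bands(c(254, 113)), "An. gambiae s.s.")  # +/- 5 bp
  expect_equal(classify_bands(c(600, 50)), "unresolved")
  expect_equal(classify_bands(c(248, 110)), "unresolved")        # beyond 5 bp
})

test_that("the full assay round-trips every species fixture", {
  res <- rflp_identify(as.list(igs))
  expect_equal(res$species_call, res$specimen)
  hyb <- rflp_identify(list(hyb1 = unname(c(igs[["An. gambiae s.s."]],
                                            igs[["An. coluzzii"]]))))
  expect_equal(hyb$species_call, "hybrid")
})
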
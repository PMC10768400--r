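test_that("error-free amplicon reads map back to their source coordinates", {
  reads <- c(substring(demo$sequences[["vgsc-II"]], 51, 200),
             substring(demo$sequences[["gste2"]], 1, 242),
             substring(rev_comp(demo$sequences[["ace1"]]), 1, 242))
  aln <- align_reads(reads, demo)
  expect_equal(aln$amplicon, c("vgsc-II", "gste2", "ace1"))
  expect_equal(aln$start, c(51L, 1L, 229L))
  expect_equal(aln$cigar[1], "150M")
  expect_equal(aln$nm, c(0L, 0L, 0L))
  # a bottom-strand read (mate 2 of a pair) maps with strand "-", with
  # coordinates on the top strand
  expect_equal(aln$strand, c("+", "+", "-"))
})

test_that("random sequence does not align", {
  set.seed(1)
  aln <- align_reads(random_read(200)$seq, demo)
  expect_true(is.na(aln$amplicon[1]))
})

test_that("substituted and gapped reads agree with an unbanded aligner", {
  skip_if_not_installed("Biostrings")
  set.seed(77)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (i in 1:50) {
    amp <- sample(demo$amplicons$id, 1)
    start <- sample(1:200, 1)
    read <- substring(demo$sequences[[amp]], start, start + 149)
    kind <- sample(c("sub", "del", "ins"), 1)
    if (kind == "sub") {
      at <- sample(20:130, 2)
      for (a in at)
        substring(read, a, a) <- setdiff(c("A", "C", "G", "T"),
                                         substring(read, a, a))[1]
    } else if (kind == "del") {
      at <- sample(30:100, 1)
      read <- paste0(substring(read, 1, at), substring(read, at + 3))
    } else {
      at <- sample(30:100, 1)
      read <- paste0(substring(read, 1, at), "ACG", substring(read, at + 1))
    }
    aln <- align_reads(read, demo)
    expect_equal(aln$amplicon[1], amp)
    if (kind == "sub") {
      expect_equal(aln$start[1], start)
      expect_equal(aln$nm[1], 2L)
    }
    # the banded score equals the optimal unbanded glocal score
    ora <- Biostrings::pairwiseAlignment(
      read, demo$sequences[[amp]], type = "global-local",
      substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
    expect_equal(aln$score[1], Biostrings::score(ora))
  }
})

test_that("pileups apply the strict per-base quality cutoff", {
  amp <- "rdl"
  read <- substring(demo$sequences[[amp]], 1, 100)
  n <- 40
  aln <- align_reads(rep(read, n), demo)

  p35 <- build_pileup(aln, rep(read, n), rep(qflat(100, 35), n), 1:n, demo)
  col <- pileup_column(p35, amp, 50)
  expect_equal(col$depth, 40)
  ref50 <- substring(demo$sequences[[amp]], 50, 50)
  expect_equal(unname(col$counts[ref50]), 40)
  expect_equal(sum(col$counts[setdiff(names(col$counts), ref50)]), 0)

  # bases at exactly Q30 fail the strict '> 30' rule
  p30 <- build_pileup(aln, rep(read, n), rep(qflat(100, 30), n), 1:n, demo)
  col30 <- pileup_column(p30, amp, 50)
  expect_equal(col30$depth, 0)
  expect_equal(unname(col30$filtered), 40)
})

test_that("overlapping mates are counted once, higher quality winning", {
  amp <- "rdl"
  ref <- demo$sequences[[amp]]
  m1 <- substring(ref, 1, 100)          # covers 1..100
  m2 <- substring(ref, 81, 180)         # covers 81..180 (pre-oriented)
  # mates disagree at position 90: mate 1 keeps the reference at Q35,
  # mate 2 carries an alternate at Q38 -> the alternate is counted once
  alt <- setdiff(c("A", "C", "G", "T"), substring(ref, 90, 90))[1]
  substring(m2, 10, 10) <- alt
  aln <- align_reads(c(m1, m2), demo)
  pile <- build_pileup(aln, c(m1, m2), c(qflat(100, 35), qflat(100, 38)),
                       c(1L, 1L), demo)
  col <- pileup_column(pile, amp, 90)
  expect_equal(col$depth, 1)
  expect_equal(unname(col$counts[alt]), 1)
  # non-overlapping positions get one count each
  expect_equal(pileup_column(pile, amp, 50)$depth, 1)
  expect_equal(pileup_column(pile, amp, 150)$depth, 1)
})

test_that("pileup depth accounting conserves aligned bases", {
  set.seed(5)
  amp <- "gste2"
  reads <- vapply(1:20, function(i) {
    s <- sample(1:300, 1)
    substring(demo$sequences[[amp]], s, s + 120)
  }, character(1))
  quals <- vapply(1:20, function(i) random_read(121)$qual, character(1))
  aln <- align_reads(reads, demo)
  pile <- build_pileup(aln, reads, quals, 1:20, demo)
  m <- pile[[amp]]
  total_aligned <- sum(nchar(reads))   # all gapless and within bounds
  expect_equal(sum(m), total_aligned)  # passing + filtered
})
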
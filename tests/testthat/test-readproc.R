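test_that("exact-match demultiplexing assigns, strips and conserves reads", {
  s <- demo$samples[1:3, ]
  tmpl <- substring(demo$sequences[["rdl"]], 1, 242)
  seq1 <- paste0(c(s$fwd_barcode, "TTTTTTTT"), tmpl)    # 3 good + 1 unknown
  seq2 <- paste0(c(s$rev_barcode, "TTTTTTTT"),
                 substring(rev_comp(demo$sequences[["rdl"]]), 1, 242))
  q <- qflat(250)
  fq <- write_pair(seq1, rep(q, 4), seq2, rep(q, 4))
  d <- demultiplex(fq$f1, fq$f2, s)
  expect_equal(d$status, c(rep("assigned", 3), "unknown_barcode"))
  expect_equal(d$sample[1:3], s$sample_id)
  expect_equal(nchar(d$seq1[1]), 242)          # barcode removed
  expect_equal(substring(d$seq1[1], 1, 242), tmpl)
  # conservation: every pair in exactly one class
  expect_equal(sum(d$report$n_pairs), 4)
})

test_that("one-mismatch demultiplexing rejects ambiguous barcode pairs", {
  s <- data.frame(sample_id = c("A", "B"),
                  fwd_barcode = c("AAAAAAAA", "AAAAAATT"),
                  rev_barcode = c("CCCCCCCC", "CCCCCCCC"),
                  island = "x", species = "y", stringsAsFactors = FALSE)
  tmpl <- strrep("ACGT", 20)
  # observed forward 8-mer at Hamming distance 1 from both samples
  seq1 <- paste0(c("AAAAAAAT", "AAAAAAAA", "GGGGGGGG"), tmpl)
  seq2 <- paste0(rep("CCCCCCCC", 3), tmpl)
  q <- qflat(88)
  fq <- write_pair(seq1, rep(q, 3), seq2, rep(q, 3))
  d <- demultiplex(fq$f1, fq$f2, s, max_mismatch = 1)
  expect_equal(d$status, c("ambiguous", "assigned", "unknown_barcode"))
  expect_true(is.na(d$sample[1]))
  expect_equal(d$sample[2], "A")
  # at max_mismatch = 0 the first read matches nobody
  d0 <- demultiplex(fq$f1, fq$f2, s, max_mismatch = 0)
  expect_equal(d0$status[1], "unknown_barcode")
})

test_that("mate files of unequal length are rejected", {
  q <- qflat(20)
  fq <- write_pair(rep(strrep("ACGT", 5), 2), rep(q, 2),
                   rep(strrep("ACGT", 5), 2), rep(q, 2))
  short <- tempfile(fileext = ".fastq")
  write_fastq("only", strrep("ACGT", 5), q, short)
  expect_error(demultiplex(fq$f1, short, demo$samples), "unequal")
})

test_that("trimming follows the LEADING/TRAILING/SLIDINGWINDOW/MINLEN order", {
  p <- trim_params()
  expect_equal(unclass(p)[c("leading", "trailing", "window_size",
                            "window_quality", "min_length")],
               list(leading = 3, trailing = 3, window_size = 4,
                    window_quality = 20, min_length = 36))

  # a clean read is untouched
  r <- list(seq = paste0(strrep("ACGT", 62), "AC"), qual = qflat(250, 40))
  tr <- trim_read(r$seq, r$qual, p)
  expect_false(tr$dropped)
  expect_equal(tr$seq, r$seq)

  # 40 bases, last 10 at Q2: trailing-trim leaves 30 < MINLEN:36 -> dropped
  tr2 <- trim_read(strrep("A", 40), paste0(qflat(30, 40), qflat(10, 2)), p)
  expect_true(tr2$dropped)

  # 30 x Q35, 4 x Q5, 10 x Q35: the first window whose mean drops below 20
  # starts at position 30 (35,5,5,5 -> 12.5), so at most 29 bases remain
  # and the read is dropped by MINLEN
  q3 <- paste0(qflat(30, 35), qflat(4, 5), qflat(10, 35))
  tr3 <- trim_read(strrep("A", 44), q3, p)
  expect_true(tr3$dropped)
  # the same profile with a 40-base clean prefix: first failing window at
  # 40 -> 39 bases survive
  q4 <- paste0(qflat(40, 35), qflat(4, 5), qflat(10, 35))
  tr4 <- trim_read(strrep("A", 54), q4, p)
  expect_false(tr4$dropped)
  expect_equal(nchar(tr4$seq), 39)
})

test_that("trimming matches a brute-force oracle on random reads", {
  set.seed(4242)
  p <- trim_params()
  for (i in 1:1000) {
    r <- random_read(sample(30:120, 1))
    fast <- trim_read(r$seq, r$qual, p)
    slow <- trim_oracle(r$seq, r$qual, p)
    expect_identical(fast, slow)
    # trimming yields a contiguous substring, never longer than the input
    if (!fast$dropped) {
      expect_true(grepl(fast$seq, r$seq, fixed = TRUE))
      expect_lte(nchar(fast$seq), nchar(r$seq))
    }
  }
})

test_that("pair trimming drops a pair when either mate fails MINLEN", {
  p <- trim_params()
  s1 <- c(strrep("A", 50), strrep("C", 50))
  q1 <- c(qflat(50, 40), qflat(50, 40))
  s2 <- c(strrep("G", 50), strrep("T", 50))
  q2 <- c(qflat(50, 40), qflat(50, 2))   # second mate all low quality
  tp <- trim_pairs(s1, q1, s2, q2, p)
  expect_equal(tp$keep, c(TRUE, FALSE))
  expect_equal(tp$n_dropped, 1)
  expect_equal(tp$seq1, strrep("A", 50))
})
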
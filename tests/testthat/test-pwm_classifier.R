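uniform_pwm <- function(width, kind = "donor") {
  structure(list(prob = matrix(0.25, 4, width,
                               dimnames = list(c("A", "C", "G", "T"),
                                               NULL)),
                 width = width, kind = kind, pseudocount = 1,
                 training_n = 0L),
            class = "pwm")
}

test_that("window extraction follows the 3+2+4 and 18+2+3 layouts", {
  # contig crafted so bases 97..105 spell CAGGTAAGT around start = 100
  set.seed(41)
  bg <- sample(c("A", "C", "G", "T"), 260, replace = TRUE)
  bg[97:105] <- strsplit("CAGGTAAGT", "")[[1]]
  end <- 200
  bg[(end - 19):(end + 3)] <-
    strsplit("TTTTTTTTTTTTTTTTTTAGGCA", "")[[1]]
  g <- toy_genome(chr = paste(bg, collapse = ""))

  d <- extract_window("chr", 100, end, "+", g, "donor")
  expect_true(d$valid)
  expect_equal(d$seq, "CAGGTAAGT")
  expect_equal(substr(d$seq, 4, 5), "GT")

  a <- extract_window("chr", 100, end, "+", g, "acceptor")
  expect_true(a$valid)
  expect_equal(a$seq, "TTTTTTTTTTTTTTTTTTAGGCA")
  expect_equal(substr(a$seq, 19, 20), "AG")

  # too close to the contig start for the 3-nt exonic flank
  near <- extract_window("chr", 2, 50, "+", g, "donor")
  expect_false(near$valid)
  expect_equal(near$reason, "extraction_failed")

  bgN <- bg
  bgN[99] <- "N"
  gN <- toy_genome(chr = paste(bgN, collapse = ""))
  dN <- extract_window("chr", 100, end, "+", gN, "donor")
  expect_false(dN$valid)
  expect_equal(dN$reason, "invalid_bases")
})

test_that("minus-strand windows are mirrored and reverse-complemented", {
  set.seed(43)
  bases <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  n <- length(bases)
  g_fwd <- toy_genome(c = paste(bases, collapse = ""))
  g_rev <- toy_genome(c = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste(bases, collapse = "")))))
  s <- 120; e <- 190
  for (kind in c("donor", "acceptor")) {
    w_plus <- extract_window("c", s, e, "+", g_fwd, kind)
    w_minus <- extract_window("c", n - e + 1, n - s + 1, "-", g_rev, kind)
    expect_equal(w_minus$seq, w_plus$seq)
  }
})

test_that("PWM probabilities implement Laplace smoothing", {
  p0 <- build_pwm(c("AC", "AG"), pseudocount = 0)
  expect_equal(unname(p0$prob["A", 1]), 1)
  expect_equal(unname(p0$prob["C", 2]), 0.5)
  expect_equal(unname(p0$prob["G", 2]), 0.5)
  expect_equal(unname(p0$prob["T", 2]), 0)

  p1 <- build_pwm("A", pseudocount = 1)
  expect_equal(unname(p1$prob["A", 1]), 0.4)
  expect_equal(unname(p1$prob[c("C", "G", "T"), 1]), rep(0.2, 3))

  expect_error(build_pwm(character(0)), "empty")
  expect_error(build_pwm(c("AC", "ACG")), "mixed lengths")
})

test_that("PWM columns sum to one at every position", {
  set.seed(47)
  for (pc in c(0, 0.5, 1, 2)) {
    windows <- replicate(20, paste(sample(c("A", "C", "G", "T"), 9,
                                          replace = TRUE), collapse = ""))
    pwm <- build_pwm(windows, pseudocount = pc)
    expect_true(all(abs(colSums(pwm$prob) - 1) < 1e-9))
  }
})

test_that("scores are log2-odds against a uniform background", {
  expect_equal(score_window(uniform_pwm(9), "CAGGTAAGT"), 0)
  expect_equal(score_window(uniform_pwm(23),
                            paste(rep("T", 23), collapse = "")), 0)

  # self-trained zero-pseudocount PWM: log2(1/0.25) = 2 bits per position
  w <- "CAGGTAAGT"
  expect_equal(score_window(build_pwm(w, pseudocount = 0), w), 18)

  # one informative position contributes exactly log2(0.5/0.25) = 1 bit
  pwm <- uniform_pwm(9)
  pwm$prob[, 5] <- c(A = 1 / 6, C = 1 / 6, G = 0.5, T = 1 / 6)
  expect_equal(score_window(pwm, "AAAAGAAAA"), 1)

  pz <- build_pwm(c("AC", "AG"), pseudocount = 0)
  expect_error(score_window(pz, "AT"), "pseudocount")
  expect_error(score_window(uniform_pwm(9), "AAAA"), "")
})

test_that("junction scoring is additive and tags every failure mode", {
  set.seed(53)
  bg <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  g <- toy_genome(chr = paste(bg, collapse = ""))
  dp <- uniform_pwm(9)
  ap <- uniform_pwm(23, "acceptor")

  ok <- score_junction("chr", 100, 200, "+", dp, ap, g)
  expect_true(ok$ok)
  expect_equal(ok$total_score, ok$donor_score + ok$acceptor_score)

  expect_equal(score_junction("chr", 100, 200, "unresolved", dp, ap,
                              g)$reason, "strand_unresolved")
  # acceptor window reaches past the contig end
  expect_equal(score_junction("chr", 100, 299, "+", dp, ap, g)$reason,
               "extraction_failed")
  bgN <- bg
  bgN[190] <- "N"
  gN <- toy_genome(chr = paste(bgN, collapse = ""))
  expect_equal(score_junction("chr", 100, 200, "+", dp, ap, gN)$reason,
               "invalid_bases")
})

test_that("the scrambled null preserves composition and the seed", {
  set.seed(59)
  w <- paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE),
             collapse = "")
  for (k in 1:10) {
    s <- ncsplice:::scramble_window(w)
    expect_equal(sort(strsplit(s, "")[[1]]), sort(strsplit(w, "")[[1]]))
  }

  dw <- replicate(15, paste(sample(c("A", "C", "G", "T"), 9,
                                   replace = TRUE), collapse = ""))
  aw <- replicate(15, paste(sample(c("A", "C", "G", "T"), 23,
                                   replace = TRUE), collapse = ""))
  dp <- build_pwm(dw)
  ap <- build_pwm(aw, kind = "acceptor")
  n1 <- build_null(dp, ap, dw, aw, n_scrambles = 200L, seed = 99L)
  n2 <- build_null(dp, ap, dw, aw, n_scrambles = 200L, seed = 99L)
  expect_identical(n1$null_scores, n2$null_scores)
  n3 <- build_null(dp, ap, dw, aw, n_scrambles = 200L, seed = 100L)
  expect_false(identical(n1$null_scores, n3$null_scores))
  expect_error(build_null(dp, ap, character(0), aw), "empty")
})

test_that("scrambling consensus-trained windows lowers their scores", {
  run <- recovery_run()
  catalog <- run$report$catalog
  genome <- run$sim$genome
  canon <- catalog[catalog$category == "canonical", ][1:200, ]
  dw <- aw <- character(0)
  for (i in seq_len(nrow(canon))) {
    d <- extract_window(canon$chrom[i], canon$start[i], canon$end[i],
                        canon$strand[i], genome, "donor")
    a <- extract_window(canon$chrom[i], canon$start[i], canon$end[i],
                        canon$strand[i], genome, "acceptor")
    if (d$valid && a$valid) {
      dw <- c(dw, d$seq)
      aw <- c(aw, a$seq)
    }
  }
  dp <- build_pwm(dw)
  ap <- build_pwm(aw, kind = "acceptor")
  training_totals <- vapply(seq_along(dw), function(i) {
    score_window(dp, dw[i]) + score_window(ap, aw[i])
  }, numeric(1))
  null <- build_null(dp, ap, dw, aw, n_scrambles = 1000L, seed = 1L)
  expect_lt(mean(null$null_scores), mean(training_totals))
})

test_that("the threshold is the linear-interpolation null percentile", {
  null <- structure(list(null_scores = c(0, 10)), class = "null_model")
  expect_equal(derive_threshold(null, 50), 5)
  # h = (n - 1) p + 1 = 95.05 for n = 100, p = 0.95
  expect_equal(derive_threshold(structure(list(null_scores = 1:100),
                                          class = "null_model"), 95),
               95.05)
  const <- structure(list(null_scores = rep(3.2, 50)),
                     class = "null_model")
  for (p in c(5, 50, 95)) expect_equal(derive_threshold(const, p), 3.2)
})

test_that("classification sends ties to non-U2/U12-like", {
  expect_equal(classify(10 + 1e-9, 10), "u2u12_like")
  expect_equal(classify(10, 10), "non_u2u12_like")
  expect_equal(classify(-1e6, 10), "non_u2u12_like")
})

test_that("raising the percentile never adds U2/U12-like calls", {
  run <- small_run()
  cls <- run$report$catalog
  totals <- cls$total_score[!is.na(cls$total_score)]
  null <- structure(list(null_scores = totals), class = "null_model")
  counts <- vapply(c(50, 75, 90, 95, 99), function(p) {
    sum(classify(totals, derive_threshold(null, p)) == "u2u12_like")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("not-classified junctions stay out of the length groups", {
  run <- small_run()
  catalog <- run$report$catalog
  groups <- group_lengths(catalog)
  expect_equal(length(groups$u2u12_like) + length(groups$non_u2u12_like),
               sum(catalog$classification %in%
                     c("u2u12_like", "non_u2u12_like")))
  expect_true(length(groups$u2u12_like) + length(groups$non_u2u12_like) <
                length(groups$non_canonical_all))
  # canonical junctions are never classified
  expect_true(all(catalog$classification[catalog$category == "canonical"]
                  == "not_applicable"))
})

test_that("classification runs are bit-identical under a fixed seed", {
  run <- small_run()
  sim <- run$sim
  genome <- sim$genome
  sj <- sim$sj
  catalog <- suppressMessages(build_catalog(sj, genome))
  c1 <- classify_junctions(catalog, genome, n_scrambles = 300L, seed = 5L)
  c2 <- classify_junctions(catalog, genome, n_scrambles = 300L, seed = 5L)
  expect_identical(c1$catalog, c2$catalog)
  expect_identical(c1$threshold, c2$threshold)
})
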
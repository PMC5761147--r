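test_that("match emissions follow the weighted-count pseudocount formula", {
  a <- alignment(c(r1 = "A", r2 = "A", r3 = "C"))
  p <- build_profile(a, weights = rep(1, 3), mask = TRUE, family = "toy")
  expect_equal(unname(p$match[1, "A"]), 3 / 23, tolerance = 1e-12)
  expect_equal(unname(p$match[1, "C"]), 2 / 23, tolerance = 1e-12)
  expect_equal(unname(p$match[1, "D"]), 1 / 23, tolerance = 1e-12)
  # all rows identical: argmax emission at every node is that residue
  b <- alignment(c(r1 = "AAAA", r2 = "AAAA"))
  pb <- build_profile(b, family = "t")
  expect_equal(profile_consensus(pb), "AAAA")
})

test_that("emission and transition rows are distributions; rows permutable", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    rows <- vapply(seq_len(n), function(i)
      paste(sample(c(AA20, "-"), 12, replace = TRUE,
                   prob = c(rep(1, 20), 4)), collapse = ""), "")
    substr(rows, 1, 2) <- "AC"
    a <- alignment(stats::setNames(rows, paste0("r", seq_len(n))))
    mask <- select_match_columns(a)
    w <- henikoff_weights(a, mask)
    p <- build_profile(a, w, mask, family = "r")
    expect_equal(rowSums(p$match), rep(1, p$L), tolerance = 1e-9)
    expect_equal(sum(p$background), 1, tolerance = 1e-9)
    if (p$L > 1) {
      expect_equal(rowSums(p$tM), rep(1, p$L - 1), tolerance = 1e-9)
      expect_equal(rowSums(p$tI), rep(1, p$L - 1), tolerance = 1e-9)
      expect_equal(rowSums(p$tD), rep(1, p$L - 1), tolerance = 1e-9)
    }
    expect_true(all(p$match > 0))
    # permuting rows (with matching weights) changes nothing
    perm <- sample(n)
    ap <- alignment(stats::setNames(rows[perm], paste0("r", seq_len(n))))
    pp <- build_profile(ap, w[perm], mask, family = "r")
    expect_equal(pp$match, p$match, tolerance = 1e-12)
    expect_equal(pp$tM, p$tM, tolerance = 1e-12)
  }
  expect_error(build_profile(structure(list(ids = "x",
                                            mat = matrix("A", 1, 1),
                                            width = 1),
                                       class = "tps_alignment"),
                             weights = 1, mask = TRUE),
               ">= 2 rows")
})

test_that("Viterbi DP equals exhaustive path enumeration on small instances", {
  n_cases <- 0
  for (seed in 1:120) {
    L <- (seed %% 3) + 1          # 1..3
    nlen <- (seed %% 4) + 1       # 1..4
    p <- random_small_profile(L, seed)
    set.seed(seed + 4000)
    s <- paste(sample(c(AA20, "X"), nlen, replace = TRUE,
                      prob = c(rep(1, 20), 1)), collapse = "")
    expect_equal(viterbi_score(p, s)$bit_score, oracle_viterbi(p, s),
                 tolerance = 1e-9)
    n_cases <- n_cases + 1
  }
  expect_gte(n_cases, 100)
})

test_that("consensus scores at least as high as any point substitution", {
  set.seed(21)
  a <- alignment(stats::setNames(
    replicate(6, paste(sample(AA20, 30, replace = TRUE), collapse = "")),
    paste0("r", 1:6)))
  # near-identical family: mutate one row lightly
  rows <- rep(a$rows[1], 6)
  for (i in 2:6) {
    ch <- strsplit(rows[i], "")[[1]]
    pos <- sample(30, 3)
    ch[pos] <- sample(AA20, 3, replace = TRUE)
    rows[i] <- paste(ch, collapse = "")
  }
  a <- alignment(stats::setNames(rows, paste0("r", 1:6)))
  p <- build_profile(a, family = "c")
  cons <- profile_consensus(p)
  s0 <- viterbi_score(p, cons)$bit_score
  for (rep in 1:10) {
    ch <- strsplit(cons, "")[[1]]
    pos <- sample(30, 1)
    ch[pos] <- sample(setdiff(AA20, ch[pos]), 1)
    expect_lte(viterbi_score(p, paste(ch, collapse = ""))$bit_score,
               s0 + 1e-9)
  }
  expect_error(viterbi_score(p, ""), "empty")
})

test_that("Gumbel MLE recovers known parameters and calibration is deterministic", {
  set.seed(77)
  x <- rgumbel(5000, mu = 10, lambda = 0.7)
  g <- fit_gumbel(x)
  expect_lt(abs(g$mu - 10) / 10, 0.05)
  expect_lt(abs(g$lambda - 0.7) / 0.7, 0.05)
  expect_error(fit_gumbel(rep(3, 100)), "degenerate")

  a <- alignment(c(r1 = "MKVADLGHE", r2 = "MKVADLGHE", r3 = "MKVCDLGHE"))
  p <- build_profile(a, family = "cal")
  g1 <- calibrate(p, n_samples = 60, sample_len = 40, seed = 5)
  g2 <- calibrate(p, n_samples = 60, sample_len = 40, seed = 5)
  expect_identical(g1, g2)
  expect_error(calibrate(p, n_samples = 10), ">= 50")
})

test_that("E-values follow the Gumbel tail and its exact properties", {
  g <- gumbel_params(mu = 10, lambda = 0.7)
  # s = mu, n = 1 -> 1 - exp(-1)
  expect_equal(evalue(g, 10, 1), 1 - exp(-1), tolerance = 1e-12)
  # linear in n_targets
  expect_equal(evalue(g, 12, 14), 7 * evalue(g, 12, 2), tolerance = 1e-12)
  # monotone decreasing in score (strictly, away from the saturated head
  # where E rounds to exactly 1), vanishing at +inf
  s <- seq(0, 60, by = 0.5)
  expect_true(all(diff(evalue(g, s, 1)) <= 0))
  s2 <- seq(9, 40, by = 0.5)
  expect_true(all(diff(evalue(g, s2, 1)) < 0))
  expect_lt(evalue(g, 1e4, 1), 1e-12)
  expect_error(evalue(g, 10, 0), "positive")
})

test_that("profile serialisation round-trips scores and calibration", {
  set.seed(31)
  rows <- replicate(5, paste(sample(AA20, 25, replace = TRUE), collapse = ""))
  rows[2:5] <- vapply(rows[2:5], function(r) {
    ch <- strsplit(rows[1], "")[[1]]
    pos <- sample(25, 5); ch[pos] <- sample(AA20, 5, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  a <- alignment(stats::setNames(rows, paste0("r", 1:5)))
  p <- calibrate_profile(build_profile(a, family = "ser"),
                         n_samples = 60, sample_len = 40, seed = 3)
  f <- tempfile(fileext = ".hmm")
  write_profile(p, f)
  q <- read_profile(f)
  expect_equal(q$family, p$family)
  expect_equal(q$match, p$match, tolerance = 1e-11)
  expect_equal(q$tM, p$tM, tolerance = 1e-11)
  expect_equal(q$calibration$mu, p$calibration$mu, tolerance = 1e-11)
  s <- random_protein(40)
  expect_equal(viterbi_score(q, s)$bit_score,
               viterbi_score(p, s)$bit_score, tolerance = 1e-9)
})
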
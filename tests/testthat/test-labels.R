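# Combination-class label algebra: encoding, decoding, candidate
# enumeration, completion and mixup.

test_that("combination-class encoding matches the worked panel examples", {
  expect_identical(encode_full_label(c(0, 0, 0, 0, 0)), 0L)
  expect_identical(encode_full_label(c(0, 1, 1, 0, 1)), 13L)
  expect_identical(encode_full_label(c(0, 1, 0, 0, 0)), 8L)
  expect_identical(encode_full_label(c(0, 1, 1, 0, 0)), 12L)
  expect_identical(encode_full_label(c(1, 1, 1, 1, 1)), 31L)
  expect_identical(decode_class(13, 5), c(0L, 1L, 1L, 0L, 1L))
  expect_identical(decode_class(0, 5), rep(0L, 5))
})

test_that("encode/decode is a bijection over all 32 five-target classes", {
  for (k in 0:31) {
    expect_identical(encode_full_label(decode_class(k, 5)), k)
  }
  # brute-force oracle: enumerate all 32 binary vectors and check the
  # MSB-first integer they represent round-trips
  combos <- as.matrix(expand.grid(rep(list(0:1), 5)))[, 5:1]
  idx <- apply(combos, 1L, function(v) sum(v * 2^(4:0)))
  for (r in seq_len(nrow(combos))) {
    expect_identical(encode_full_label(combos[r, ]), as.integer(idx[r]))
  }
})

test_that("encoding rejects missing or non-binary entries and guards 2^n", {
  expect_error(encode_full_label(c(0, 1, NA, 0, 0)), "missing")
  expect_error(encode_full_label(c(0, 2, 0, 0, 0)), "0 or 1")
  expect_error(decode_class(32, 5), "out of range")
  expect_error(decode_class(-1, 5), "out of range")
  expect_error(encode_full_label(rep(0, 17)), "at most 16")
})

test_that("candidate enumeration matches a brute-force oracle on all 3^5 partial vectors", {
  expect_identical(enumerate_candidates(c(0, 1, NA, 0, 0)), c(8L, 12L))
  expect_identical(enumerate_candidates(c(0, 1, 1, 0, 1)), 13L)
  expect_identical(enumerate_candidates(rep(NA, 5)), 0:31)

  # oracle: scan all 32 full labels and keep those consistent with the
  # observed entries
  oracle <- function(partial) {
    keep <- vapply(0:31, function(k) {
      full <- decode_class(k, 5)
      all(full[!is.na(partial)] == partial[!is.na(partial)])
    }, logical(1L))
    (0:31)[keep]
  }
  cells <- list(0, 1, NA)
  grid <- expand.grid(rep(list(1:3), 5))
  for (r in seq_len(nrow(grid))) {
    partial <- unlist(cells[as.integer(grid[r, ])])
    cand <- enumerate_candidates(partial)
    expect_identical(cand, oracle(partial))
    expect_length(cand, 2^sum(is.na(partial)))
  }
})

test_that("completion restricts and renormalizes teacher probabilities", {
  p <- rep(0, 32)
  p[8 + 1L] <- 0.3
  p[12 + 1L] <- 0.1
  out <- complete_partial_label(c(0, 1, NA, 0, 0), p)
  expect_equal(out[8 + 1L], 0.75)
  expect_equal(out[12 + 1L], 0.25)
  expect_equal(sum(out), 1)
  expect_true(all(out[-c(9, 13)] == 0))

  # uniform teacher -> uniform over candidates
  out2 <- complete_partial_label(c(0, 1, NA, 0, 0), rep(1 / 32, 32))
  expect_equal(out2[8 + 1L], 0.5)
  expect_equal(out2[12 + 1L], 0.5)

  # no missing entries -> hard one-hot regardless of the teacher
  out3 <- complete_partial_label(c(0, 1, 1, 0, 1), runif(32))
  expect_equal(out3[13 + 1L], 1)
  expect_equal(sum(out3), 1)

  # zero candidate mass -> uniform fallback, with a message
  p0 <- rep(0, 32)
  p0[2] <- 1
  expect_message(
    out4 <- complete_partial_label(c(0, 1, NA, 0, 0), p0),
    "uniform"
  )
  expect_equal(out4[c(9, 13)], c(0.5, 0.5))
})

test_that("completion output is always a distribution supported on the candidates", {
  set.seed(71)
  sum_err <- 0
  neg <- support_bad <- contradiction <- FALSE
  for (i in 1:1000) {
    partial <- sample(c(0L, 1L, NA), 5, replace = TRUE)
    out <- complete_partial_label(partial, runif(32))
    sum_err <- max(sum_err, abs(sum(out) - 1))
    neg <- neg || any(out < 0)
    cand <- enumerate_candidates(partial)
    supp <- which(out > 0) - 1L
    support_bad <- support_bad || !all(supp %in% cand)
    # support never contradicts an observed entry
    obs <- !is.na(partial)
    for (k in supp) {
      if (!all(decode_class(k, 5)[obs] == partial[obs])) contradiction <- TRUE
    }
  }
  expect_lt(sum_err, 1e-9)
  expect_false(neg)
  expect_false(support_bad)
  expect_false(contradiction)
})

test_that("multi-label completion keeps observed entries and fills missing ones", {
  out <- complete_partial_multilabel(c(1, NA, 0, NA), c(0.9, 0.2, 0.8, 0.6))
  expect_equal(out, c(1, 0.2, 0, 0.6))
  expect_error(complete_partial_multilabel(c(1, NA), c(0.5, 1.5)), "\\[0, 1\\]")
})

test_that("mixup forms convex combinations and preserves label mass", {
  m <- mixup_pair(c(1, 0), c(1, 0, 0), c(0, 1), c(0, 0.5, 0.5), 0.5)
  expect_equal(m$x, c(0.5, 0.5))
  expect_equal(sum(m$y), 1)

  id <- mixup_pair(c(1, 2), c(0, 1), c(3, 4), c(1, 0), 1)
  expect_equal(id$x, c(1, 2))
  expect_equal(id$y, c(0, 1))

  set.seed(4)
  for (i in 1:20) {
    y1 <- runif(8); y1 <- y1 / sum(y1)
    y2 <- runif(8); y2 <- y2 / sum(y2)
    lam <- runif(1)
    expect_equal(sum(mixup_pair(runif(3), y1, runif(3), y2, lam)$y), 1)
  }
  expect_error(mixup_pair(1:2, 1, 1:3, 1, 0.5), "length")
})

test_that("mixup coefficients follow Beta(alpha, alpha)", {
  cfg <- mixup_config(alpha = 0.4)
  set.seed(12)
  draws <- sample_lambda(cfg, 10000L)
  expect_true(all(draws >= 0 & draws <= 1))
  # Beta(a, a) has mean 1/2 and var 1/(4(2a+1))
  se <- sqrt(1 / (4 * (2 * 0.4 + 1)) / 10000)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
  set.seed(99)
  a <- sample_lambda(cfg, 5L)
  set.seed(99)
  expect_identical(a, sample_lambda(cfg, 5L))
  expect_error(mixup_config(alpha = 0), "> 0")
})
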
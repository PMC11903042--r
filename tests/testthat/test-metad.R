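test_that("quantile binning conserves trials and splits evenly", {
  ps <- simulate_perceptual(8, 25, seed = 1)
  cnt <- bin_confidence(ps, K = 4)
  expect_identical(sum(cnt$counts), 200L)
  marg <- apply(cnt$counts, 3, sum)
  expect_true(all(abs(marg - 50) <= 5))   # near-equal quantile bins
})

test_that("degenerate confidence collapses the bin count with a warning", {
  ps <- simulate_perceptual(2, 25, seed = 2)
  ps$confidence <- 75
  expect_warning(cnt <- bin_confidence(ps, K = 4), "distinct")
  expect_identical(cnt$n_bins, 1L)
  expect_identical(sum(cnt$counts), 50L)
})

test_that("type-1 fit reproduces normal-quantile arithmetic", {
  # HR = 0.84, FAR = 0.16 out of 100 trials per stimulus
  arr <- array(0, c(2, 2, 2))
  arr[2, 2, ] <- c(42, 42); arr[2, 1, ] <- c(8, 8)    # S2: 84 hits
  arr[1, 2, ] <- c(8, 8);   arr[1, 1, ] <- c(42, 42)  # S1: 16 false alarms
  t1 <- fit_type1(hand_counts(arr))
  expect_equal(t1$d_prime, qnorm(0.84) - qnorm(0.16), tolerance = 1e-10)
  expect_equal(t1$d_prime, 1.989, tolerance = 1e-3)
  expect_equal(t1$c, 0, tolerance = 1e-10)

  # HR = FAR implies zero sensitivity
  arr[1, , ] <- arr[2, , ]
  expect_equal(fit_type1(hand_counts(arr))$d_prime, 0)

  # perfect performance stays finite through the 1/(2N) correction
  arr <- array(0, c(2, 2, 2))
  arr[2, 2, 1] <- 20; arr[1, 1, 1] <- 20
  expect_true(is.finite(fit_type1(hand_counts(arr))$d_prime))
})

test_that("meta-d' MLE matches the dense grid-search oracle on small tables", {
  tables <- list(
    hand_counts(array(c(12, 2, 6, 2, 3, 8, 1, 6), c(2, 2, 2))),
    hand_counts(array(c(10, 4, 4, 2, 2, 6, 2, 10), c(2, 2, 2))),
    hand_counts(array(c(8, 3, 5, 4, 4, 5, 3, 8), c(2, 2, 2))))
  for (tb in tables) {
    fit <- fit_meta_d(tb)
    oracle <- grid_meta_d_oracle(tb)
    expect_equal(fit$meta_d, oracle$meta_d, tolerance = 0.01)
    expect_lte(fit$nll, oracle$nll + 1e-4)
  }
})

test_that("confidence carrying no accuracy information gives meta-d' near 0", {
  # identical rating distribution for every stimulus x response cell
  arr <- array(0, c(2, 2, 4))
  for (s in 1:2) for (r in 1:2) arr[s, r, ] <- c(30, 25, 25, 20) *
    (if (s == r) 2 else 1)
  fit <- fit_meta_d(hand_counts(arr))
  expect_lt(fit$meta_d, 0.1)
})

test_that("the ideal observer's M-ratio approaches 1 with many trials", {
  # constant difficulty: the SDT model's own regime, where meta-d' = d'
  ps <- simulate_perceptual(400, 25, start_level = 20, staircase = FALSE,
                            seed = 3)  # 10,000 trials
  fit <- fit_meta_d(bin_confidence(ps, 4))
  expect_gt(fit$m_ratio, 0.95)
  expect_lt(fit$m_ratio, 1.05)
})

test_that("M-ratio decreases with metacognitive noise in expectation", {
  mr <- vapply(c(0, 1, 2), function(tau) {
    mean(vapply(1:6, function(s) {
      ps <- simulate_perceptual(8, 25, obs = sdt_observer(meta_noise = tau),
                                n_practice = 60, seed = 100 * tau + s)
      fit_meta_d(bin_confidence(ps, 4))$m_ratio
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mr[1], mr[2])
  expect_gt(mr[2], mr[3])
})

test_that("QSR scores proper-score algebra and rejects mismatched input", {
  expect_equal(qsr(rep(100, 5), rep(1, 5)), 1)
  expect_equal(qsr(rep(100, 5), rep(0, 5)), 0)
  expect_equal(qsr(rep(50, 5), c(1, 0, 1, 0, 1)), 0.75)
  expect_error(qsr(c(60, 70), c(1)), "length")
})

test_that("QSR is maximized by reporting the true probability correct", {
  # accuracy 0.75; expected score 1 - E[(c - y)^2] peaks at c = 0.75
  set.seed(9)
  y <- rbinom(4000, 1, 0.75)
  scores <- vapply(seq(50, 100, by = 5), function(conf)
    qsr(rep(conf, length(y)), y), numeric(1))
  expect_equal(seq(50, 100, by = 5)[which.max(scores)], 75)
})
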
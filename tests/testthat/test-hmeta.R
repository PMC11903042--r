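quick_mcmc <- function(seed = 1) mcmc_control(chains = 3, draws = 1200,
                                              warmup = 400, seed = seed)

test_that("single-condition hierarchical fit recovers the normative M-ratio", {
  cnt <- lapply(1:12, function(s) {
    ps <- simulate_perceptual(8, 25, n_practice = 60, seed = 400 + s)
    bin_confidence(ps, 4)
  })
  post <- fit_hierarchical(cnt, quick_mcmc(5))
  g <- group_mratio(post)
  expect_equal(mean(g), 1, tolerance = 0.15)
  expect_true(all(post$rhat < 1.2, na.rm = TRUE))
  sm <- subject_mratio(post)
  expect_identical(dim(sm), c(12L, 1L))
  expect_true(all(sm > 0.5 & sm < 2))
})

test_that("two correlated conditions yield a positive posterior correlation", {
  # subject-specific metacognitive noise shared across both conditions
  # induces a strong true correlation of log M-ratio
  set.seed(11)
  taus <- runif(14, 0, 2)
  mk <- function(off) lapply(seq_along(taus), function(s) {
    ps <- simulate_perceptual(8, 25, obs = sdt_observer(meta_noise = taus[s]),
                              n_practice = 60, seed = off + s)
    bin_confidence(ps, 4)
  })
  post <- fit_hierarchical(list(a = mk(500), b = mk(600)), quick_mcmc(6))
  rho <- unlist(lapply(post$samples, function(m) as.numeric(m[, "rho"])))
  expect_gt(mean(rho), 0)
  # heterogeneous metacognition also pushes the group mean below 1
  expect_lt(mean(group_mratio(post, "b")), 1)
})

test_that("the three-condition correlated model samples and stays proper", {
  cnt1 <- lapply(1:8, function(s) {
    ps <- simulate_perceptual(6, 25, n_practice = 60, seed = 700 + s)
    bin_confidence(ps, 4)
  })
  cnt2 <- lapply(1:8, function(s) {
    ps <- simulate_perceptual(6, 25, obs = sdt_observer(meta_noise = 0.8),
                              n_practice = 60, seed = 800 + s)
    bin_confidence(ps, 4)
  })
  cnt3 <- lapply(1:8, function(s) {
    ps <- simulate_perceptual(6, 25, n_practice = 60, seed = 900 + s)
    bin_confidence(ps, 4)
  })
  post <- fit_hierarchical(list(pr = cnt1, pl = cnt2, ld = cnt3),
                           mcmc_control(chains = 2, draws = 800, warmup = 300,
                                        seed = 7))
  rho <- do.call(rbind, lapply(post$samples, function(m)
    as.matrix(m[, c("rho[1]", "rho[2]", "rho[3]")])))
  expect_true(all(rho > -1 & rho < 1))
  # every retained draw has a positive-definite correlation matrix
  detR <- 1 - rowSums(rho^2) + 2 * rho[, 1] * rho[, 2] * rho[, 3]
  expect_true(all(detR > 0))
  expect_identical(length(group_mratio(post, "ld")), nrow(rho))
})

test_that("posterior fractions behave like paired-draw probabilities", {
  set.seed(3)
  draws <- cbind(rnorm(4000), rnorm(4000))
  post <- fake_posterior(draws, conditions = c("a", "b"))
  expect_identical(posterior_fraction(post, "a", "a"), 0)  # strict inequality
  expect_equal(posterior_fraction(post, "a", "b"), 0.5, tolerance = 0.05)
  expect_equal(posterior_fraction(post, "a", "b") +
                 posterior_fraction(post, "b", "a"), 1)    # no ties, continuous
  shifted <- fake_posterior(cbind(draws[, 1] - 5, draws[, 1]),
                            conditions = c("lo", "hi"))
  expect_identical(posterior_fraction(shifted, "lo", "hi"), 1)
  expect_error(posterior_fraction(post, "a", "nope"), "unknown condition")
})

test_that("subsample Wilcoxon is calibrated under the null and powered apart", {
  set.seed(4)
  a <- rnorm(5000); b <- rnorm(5000)
  null_res <- subsample_wilcoxon(a, b, n_sub = 30, reps = 1000, seed = 1)
  expect_lt(abs(null_res$frac_sig - 0.05), 0.035)
  sep <- subsample_wilcoxon(a, b + 3, n_sub = 30, reps = 200, seed = 2)
  expect_gt(sep$frac_sig, 0.99)
  expect_error(subsample_wilcoxon(a, b, n_sub = 9999), "exceeds")
  # the procedure's default repetition count
  expect_identical(formals(subsample_wilcoxon)$reps, 1000)
})
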
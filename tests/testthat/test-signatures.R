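# Smaller cohorts than the headline dissociation check; these exercise the
# regression machinery and its contracts.

sim_records <- function(params, seed, n_subjects = 12, n_blocks = 5) {
  cohort <- simulate_bandit_cohort(n_subjects, params, n_blocks, 60, seed = seed)
  cohort_transitions(cohort)
}

test_that("pure-MF and pure-MB cohorts dissociate on the signature effects", {
  r_mf <- sim_records(agent_params(w_mf = 5, w_mb = 0), seed = 41)
  r_mb <- sim_records(agent_params(w_mf = 0, w_mb = 5), seed = 42)
  f_mfmf <- mf_regression(r_mf)
  f_mfmb <- mb_regression(r_mf)
  f_mbmf <- mf_regression(r_mb)
  f_mbmb <- mb_regression(r_mb)
  getC <- function(f) f$fixed[f$fixed$term == "C", ]
  expect_gt(getC(f_mfmf)$estimate, 0.3)
  expect_lt(getC(f_mfmf)$p, 0.001)
  expect_gt(getC(f_mbmb)$estimate, 0.3)
  expect_lt(getC(f_mbmb)$p, 0.001)
  # the cross effects are null: CIs cover 0
  expect_gt(getC(f_mfmb)$ci_hi, 0); expect_lt(getC(f_mfmb)$ci_lo, 0)
  expect_gt(getC(f_mbmf)$ci_hi, 0); expect_lt(getC(f_mbmf)$ci_lo, 0)
  # subject totals average to about the fixed effect (shrinkage identity)
  expect_equal(mean(f_mfmf$subject_total$total), getC(f_mfmf)$estimate,
               tolerance = 0.1)
})

test_that("a uniform-random chooser produces null coefficients throughout", {
  r0 <- sim_records(agent_params(w_mf = 0, w_mb = 0, pr = 0, pz = 0), seed = 43)
  for (f in list(mf_regression(r0), mb_regression(r0))) {
    expect_true(all(abs(f$fixed$estimate) < 0.25))
    expect_true(all(f$fixed$p[f$fixed$term != "(Intercept)"] > 0.001))
  }
})

test_that("fixed effects agree with plain logistic regression when the data
           carry no subject heterogeneity", {
  set.seed(44)
  n <- 600
  d <- data.frame(subject = rep(c("a", "b"), each = n / 2),
                  kind = "MF",
                  C = sample(c(-0.5, 0.5), n, TRUE),
                  U = sample(c(-0.5, 0.5), n, TRUE))
  d$y <- rbinom(n, 1, plogis(0.4 + 1.2 * d$C + 0.5 * d$U))
  fit <- mf_regression(d)
  ref <- glm(y ~ C * U, family = binomial(), data = d)
  if (all(fit$random_sd < 1e-3)) {
    expect_equal(fit$fixed$estimate, unname(coef(ref)), tolerance = 1e-4)
  } else {
    expect_equal(fit$fixed$estimate, unname(coef(ref)), tolerance = 0.05)
  }
})

test_that("degenerate generating probabilities drop the history regressor", {
  r <- sim_records(agent_params(), seed = 45, n_subjects = 4, n_blocks = 2)
  r$prob_C <- 0.5
  expect_warning(fit <- mb_regression(r), "constant")
  expect_false("prob_C" %in% fit$fixed$term)
})

test_that("interaction regressions recover the generative meta-control sign", {
  r_meta <- sim_records(agent_params(w_mf = 2, w_mb = 2, conf_noise = 0.8,
                                     meta_gain = 1.5), seed = 46,
                        n_subjects = 20)
  r_null <- sim_records(agent_params(w_mf = 2, w_mb = 2, conf_noise = 0.8),
                        seed = 47, n_subjects = 20)
  i_meta <- confidence_interaction(r_meta, "MB")
  i_null <- confidence_interaction(r_null, "MB")
  gx <- function(f) f$fixed[f$fixed$term == "C:conf", ]
  expect_gt(gx(i_meta)$estimate, 0.2)
  expect_lt(gx(i_meta)$p, 0.05)
  expect_gt(gx(i_null)$ci_hi, -0.05)
  expect_lt(gx(i_null)$ci_lo, 0.05)
  # continuous coding agrees in sign with the median split
  i_cont <- confidence_interaction(r_meta, "MB", "continuous")
  expect_gt(gx(i_cont)$estimate, 0)
  # per-subject totals are returned for the interaction term
  expect_identical(unique(i_meta$subject_total$term), "C:conf")
  expect_identical(nrow(i_meta$subject_total), 20L)
})

test_that("condition comparisons detect shifts and respect pairing", {
  set.seed(48)
  subjects <- sprintf("s%02d", 1:30)
  base <- rnorm(30, 0.5, 0.1)
  eff <- data.frame(
    subject = rep(subjects, 3),
    condition = rep(c("placebo", "drugA", "drugB"), each = 30),
    effect = c(base, base + rnorm(30, 0.3, 0.1), base + rnorm(30, 0, 0.1)))
  for (tst in c("mixed-linear", "signed-rank", "rank-sum")) {
    out <- compare_conditions(eff, test = tst, reference = "placebo")
    expect_identical(nrow(out), 2L)
    a <- out[out$contrast == "drugA vs placebo", ]
    b <- out[out$contrast == "drugB vs placebo", ]
    expect_lt(a$p, 0.05)
    expect_gt(b$p, 0.05)
    expect_equal(a$estimate, 0.3, tolerance = 0.12)
  }
  # identical columns give near-zero contrasts (the zero-residual fit is
  # degenerate, hence the suppressed convergence chatter)
  eff0 <- eff; eff0$effect <- rep(base, 3)
  out0 <- suppressWarnings(suppressMessages(compare_conditions(eff0)))
  expect_true(all(abs(out0$estimate) < 1e-10))
  # missing cells are reported
  expect_error(compare_conditions(eff[-1, ]), "missing")
})

test_that("label permutation keeps the false-positive rate near nominal", {
  set.seed(49)
  subjects <- sprintf("s%02d", 1:30)
  pvals <- replicate(400, {
    # exchangeable null: condition labels carry no information
    eff <- data.frame(subject = rep(subjects, 2),
                      condition = c(rep("x", 30), rep("y", 30)),
                      effect = rnorm(60))
    compare_conditions(eff, test = "rank-sum")$p
  })
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.03)
})
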
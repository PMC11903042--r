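test_that("the indifferent model's likelihood is exactly N log 2", {
  st <- make_structure(seed = 51)
  set.seed(52)
  sch <- simulate_session_schedule(2, 60)
  off <- make_offer_sequence(st, 2, 60)
  sess <- simulate_bandit_agent(st, sch, off, agent_params())
  p0 <- agent_params(w_mf = 0, w_mb = 0, pr = 0, pz = 0)
  expect_equal(nll_hybrid(sess, st, p0), 120 * log(2), tolerance = 1e-12)
})

test_that("a 3-trial hand-derived likelihood matches", {
  st <- fixed_structure()  # P1{g,l} P2{l,o} P3{o,c} P4{c,g}
  sess <- hand_session(st,
    block = c(1, 1, 1),
    left = c("P1", "P1", "P2"),
    right = c("P2", "P2", "P3"),
    choice = c("P1", "P2", "P2"),
    out1 = c(1, 0, 0),  # P1: garlic=1; P2: lettuce=0; P2: lettuce
    out2 = c(1, 0, 0))  # P1: lettuce=1; P2: onion=0
  p <- agent_params(alpha = 1, w_mf = 1, w_mb = 0, forget = 0, pr = 0, pz = 0)
  # trial 1: all Q_MF = 1, logit 0, chose left          -> log 0.5
  # trial 2: Q_MF(P1) = 2 after the double win, logit 1, chose right
  #                                                     -> log(1 - plogis(1))
  # trial 3: Q_MF(P2) = 0 after the double loss, logit 0 - 1 = -1, chose left
  #                                                     -> log(plogis(-1))
  expected <- -(log(0.5) + log(1 - plogis(1)) + log(plogis(-1)))
  expect_equal(nll_hybrid(sess, st, p), expected, tolerance = 1e-12)
})

test_that("the generating parameters sit near the likelihood optimum", {
  st <- make_structure(seed = 53)
  truth <- agent_params(alpha = 0.5, w_mf = 3, w_mb = 3, forget = 0.1,
                        pr = 0.3, pz = 0.1)
  set.seed(54)
  worse <- 0L; total <- 0L
  for (rep in 1:5) {
    sch <- simulate_session_schedule(5, 60)
    off <- make_offer_sequence(st, 5, 60)
    sess <- simulate_bandit_agent(st, sch, off, truth)
    nll_true <- nll_hybrid(sess, st, truth)
    for (j in 1:10) {
      theta <- agent_params(alpha = runif(1), w_mf = runif(1, 0, 8),
                            w_mb = runif(1, 0, 8), forget = runif(1),
                            pr = runif(1, -2, 2), pz = runif(1, -2, 2))
      total <- total + 1L
      if (nll_hybrid(sess, st, theta) < nll_true) worse <- worse + 1L
    }
  }
  expect_lt(worse / total, 0.1)
})

test_that("fitting recovers dispersed parameters on a small cohort", {
  set.seed(55)
  true <- lapply(1:8, function(i)
    agent_params(alpha = runif(1, 0.2, 0.8), w_mf = runif(1, 0.5, 6),
                 w_mb = runif(1, 0.5, 6), forget = runif(1, 0, 0.5),
                 pr = runif(1, -0.5, 1), pz = runif(1, -0.5, 0.5)))
  cohort <- simulate_bandit_cohort(8, true, 5, 60, seed = 56)
  fits <- lapply(cohort, function(su)
    fit_subject(su$session, su$structure, n_restarts = 5, seed = 57))
  tm <- sapply(true, function(p) c(p$alpha, p$w_mf, p$w_mb))
  fm <- sapply(fits, function(f)
    c(f$params$alpha, f$params$w_mf, f$params$w_mb))
  for (i in 1:3) expect_gt(cor(tm[i, ], fm[i, ]), 0.4)
  # fitted likelihood beats the indifferent model
  for (s in 1:8) {
    p0 <- agent_params(w_mf = 0, w_mb = 0, pr = 0, pz = 0)
    expect_lte(fits[[s]]$nll,
               nll_hybrid(cohort[[s]]$session, cohort[[s]]$structure, p0) + 1e-6)
  }
})

test_that("non-learning data pins the ridge fit to the null weights", {
  st <- make_structure(seed = 58)
  set.seed(59)
  sch <- simulate_session_schedule(5, 60)
  off <- make_offer_sequence(st, 5, 60)
  sess <- simulate_bandit_agent(st, sch, off,
                                agent_params(w_mf = 0, w_mb = 0, pr = 0, pz = 0))
  fit <- fit_subject(sess, st, n_restarts = 5, seed = 60, ridge = 0.5)
  expect_lt(fit$params$w_mf, 1)
  expect_lt(fit$params$w_mb, 1)
  # and the pure-MLE fit cannot beat chance by much
  fit0 <- fit_subject(sess, st, n_restarts = 5, seed = 61)
  expect_gt(fit0$nll, 300 * log(2) - 10)
})

test_that("simulate-then-regress reproduces a positive MB effect from MB truth", {
  st <- make_structure(seed = 62)
  pars <- rep(list(agent_params(w_mf = 0.5, w_mb = 5)), 8)
  sr <- simulate_and_regress(pars, st, n_sims = 4, seed = 63)
  expect_identical(sr$n_sims, 4)
  expect_true(all(is.finite(sr$per_subject$mean_effect)))
  expect_gt(mean(sr$per_subject$mean_effect), 0.3)
  expect_lte(sr$n_failed, 1)
  # the procedure's full-scale default
  expect_identical(formals(simulate_and_regress)$n_sims, 1000)
})
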
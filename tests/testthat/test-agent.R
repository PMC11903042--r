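sim_cohort_session <- function(params, seed, n_blocks = 5, tpb = 60,
                               st = make_structure(seed = 99)) {
  set.seed(seed)
  sch <- simulate_session_schedule(n_blocks, tpb)
  off <- make_offer_sequence(st, n_blocks, tpb)
  simulate_bandit_agent(st, sch, off, params)
}

test_that("an indifferent agent chooses each offered person at chance", {
  p0 <- agent_params(w_mf = 0, w_mb = 0, pr = 0, pz = 0)
  sess <- sim_cohort_session(p0, seed = 1, n_blocks = 20, tpb = 60)
  expect_equal(mean(sess$side == "left"), 0.5, tolerance = 0.05)
})

test_that("with alpha = 0 values never move, so even huge weights are inert", {
  pa <- agent_params(alpha = 0, w_mf = 50, w_mb = 50, pr = 0, pz = 0)
  sess <- sim_cohort_session(pa, seed = 2, n_blocks = 20, tpb = 60)
  expect_equal(mean(sess$side == "left"), 0.5, tolerance = 0.05)
  # likelihood check: all value differences stay zero
  st <- make_structure(seed = 99)
  expect_equal(nll_hybrid(sess, st, pa), nrow(sess) * log(2))
})

test_that("sessions are bit-for-bit reproducible under a seed", {
  st <- make_structure(seed = 7)
  sch <- simulate_session_schedule(2, 60, seed = 8)
  off <- make_offer_sequence(st, 2, 60, seed = 9)
  a <- simulate_bandit_agent(st, sch, off, agent_params(), seed = 10)
  b <- simulate_bandit_agent(st, sch, off, agent_params(), seed = 10)
  expect_identical(a, b)
})

test_that("confidence stays on the half-open report scale", {
  sess <- sim_cohort_session(agent_params(conf_noise = 3), seed = 3)
  expect_true(all(sess$confidence > 50 & sess$confidence < 100))
})

test_that("a strong MB agent earns more than an indifferent one", {
  # paired seeds: same structure, schedule and offers for both agents
  diffs <- vapply(1:15, function(s) {
    st <- make_structure(seed = 1000 + s)
    set.seed(2000 + s)
    sch <- simulate_session_schedule(5, 60)
    off <- make_offer_sequence(st, 5, 60)
    mb <- simulate_bandit_agent(st, sch, off,
                                agent_params(w_mf = 0, w_mb = 8, pr = 0, pz = 0),
                                seed = 3000 + s)
    rnd <- simulate_bandit_agent(st, sch, off,
                                 agent_params(w_mf = 0, w_mb = 0, pr = 0, pz = 0),
                                 seed = 3000 + s)
    mean(mb$out1 + mb$out2) - mean(rnd$out1 + rnd$out2)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("perseveration biases repeat choices of person and side", {
  p_pr <- agent_params(w_mf = 0, w_mb = 0, pr = 3, pz = 0, forget = 0)
  sess <- sim_cohort_session(p_pr, seed = 4, n_blocks = 10, tpb = 60)
  rep_rate <- mean(vapply(2:nrow(sess), function(t)
    sess$block[t] == sess$block[t - 1] &&
      sess$choice[t] == sess$choice[t - 1] &&
      sess$choice[t - 1] %in% c(sess$left[t], sess$right[t]), logical(1)))
  # pr = 3 makes re-offered previous choices strongly sticky
  expect_gt(rep_rate, 0.35)
})
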
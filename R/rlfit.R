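#' Negative log-likelihood of a session under the hybrid model
#'
#' Exact negative log-likelihood of the observed choice sequence under the
#' hybrid MF/MB policy, with the same update rules as the simulator
#' (delta-rule MF person values initialized at 1, MB vegetable values at
#' 0.5, decay of un-updated values toward initialization, person/side
#' perseveration, state reset at block boundaries). Confidence reports are
#' not part of the likelihood; when `params$meta_gain != 0` the recorded
#' confidence modulates the next trial's effective MB weight exactly as in
#' the simulator. Computed in the log domain.
#'
#' @param session A `bandit_session`.
#' @param structure Its `task_structure`.
#' @param params An [agent_params()] (or a list with the same elements).
#' @return The negative log-likelihood (a single number).
#' @export
nll_hybrid <- function(session, structure, params) {
  persons <- structure$persons
  vegs <- structure$vegetables
  grows_idx <- matrix(match(structure$grows, vegs), ncol = 2)
  li <- match(session$left, persons)
  ri <- match(session$right, persons)
  ci <- match(session$choice, persons)
  if (anyNA(li) || anyNA(ri) || anyNA(ci))
    stop("session contains persons unknown to the structure")
  side <- ifelse(session$side == "left", 1L, 2L)
  v1 <- grows_idx[ci, 1]; v2 <- grows_idx[ci, 2]
  r1 <- session$out1; r2 <- session$out2
  blk <- session$block
  conf <- session$confidence
  n <- nrow(session)

  alpha <- params$alpha; w_mf <- params$w_mf; w_mb <- params$w_mb
  keep <- 1 - params$forget; pr <- params$pr; pz <- params$pz
  mg <- if (is.null(params$meta_gain)) 0 else params$meta_gain

  q_mf <- rep(Q_MF_INIT, 4)
  v_mb <- rep(V_MB_INIT, 4)
  prev_person <- 0L; prev_side <- 0L; prev_conf <- NA_real_
  cur_block <- -1L
  nll <- 0
  for (t in seq_len(n)) {
    if (blk[t] != cur_block) {
      cur_block <- blk[t]
      q_mf[1] <- Q_MF_INIT; q_mf[2] <- Q_MF_INIT
      q_mf[3] <- Q_MF_INIT; q_mf[4] <- Q_MF_INIT
      v_mb[1] <- V_MB_INIT; v_mb[2] <- V_MB_INIT
      v_mb[3] <- V_MB_INIT; v_mb[4] <- V_MB_INIT
      prev_person <- 0L; prev_side <- 0L; prev_conf <- NA_real_
    }
    l <- li[t]; r <- ri[t]
    q_mb_l <- v_mb[grows_idx[l, 1]] + v_mb[grows_idx[l, 2]]
    q_mb_r <- v_mb[grows_idx[r, 1]] + v_mb[grows_idx[r, 2]]
    w_mb_eff <- if (mg != 0 && prev_person > 0L)
      w_mb * exp(mg * (prev_conf - 75) / 25) else w_mb
    logit <- w_mf * (q_mf[l] - q_mf[r]) + w_mb_eff * (q_mb_l - q_mb_r)
    if (prev_person > 0L) {
      logit <- logit + pr * ((prev_person == l) - (prev_person == r)) +
        pz * ((prev_side == 1L) - (prev_side == 2L))
    }
    nll <- nll - stats::plogis(if (side[t] == 1L) logit else -logit,
                               log.p = TRUE)
    ch <- ci[t]
    q_mf[ch] <- q_mf[ch] + alpha * ((r1[t] + r2[t]) - q_mf[ch])
    va <- v1[t]; vb <- v2[t]
    v_mb[va] <- v_mb[va] + alpha * (r1[t] - v_mb[va])
    v_mb[vb] <- v_mb[vb] + alpha * (r2[t] - v_mb[vb])
    for (k in 1:4) {
      if (k != ch) q_mf[k] <- Q_MF_INIT + keep * (q_mf[k] - Q_MF_INIT)
      if (k != va && k != vb) v_mb[k] <- V_MB_INIT + keep * (v_mb[k] - V_MB_INIT)
    }
    prev_person <- ch; prev_side <- side[t]; prev_conf <- conf[t]
  }
  nll
}

#' Fit the hybrid model to a session by maximum likelihood
#'
#' Bounded multi-start local optimization (L-BFGS-B from Latin-hypercube
#' starting points) of the six choice parameters: `alpha`, `forget` in
#' `[0, 1]`, `w_mf`, `w_mb` in `[0, 20]`, `pr`, `pz` in `[-5, 5]`. Pure
#' maximum likelihood, no prior or penalty.
#'
#' @param session A `bandit_session`.
#' @param structure Its `task_structure`.
#' @param n_restarts Number of optimizer starts (default 10).
#' @param seed Optional integer seed (controls the start points).
#' @param meta_gain Fixed meta-control gain passed through to the
#'   likelihood (not estimated).
#' @param ridge Optional L2 penalty weight on `w_mf`, `w_mb`, `pr`, `pz`
#'   (default 0 = pure maximum likelihood). Useful for degenerate sessions
#'   where the likelihood is flat along a weight direction (e.g. data from
#'   a non-learning chooser, where `alpha = 0` makes the weights
#'   unidentified); a small ridge selects the null point of the ridge.
#' @return List of class `rl_fit`: `params` (an [agent_params()]), `nll`
#'   (of the unpenalized likelihood at the optimum), `n_restarts`,
#'   `converged`, `bounds`.
#' @export
fit_subject <- function(session, structure, n_restarts = 10, seed = NULL,
                        meta_gain = 0, ridge = 0) {
  if (!is.null(seed)) set.seed(seed)
  lower <- c(alpha = 0, w_mf = 0, w_mb = 0, forget = 0, pr = -5, pz = -5)
  upper <- c(alpha = 1, w_mf = 20, w_mb = 20, forget = 1, pr = 5, pz = 5)
  # start weights in a moderate subrange; extreme weights give flat likelihoods
  s_lower <- c(0.05, 0.1, 0.1, 0, -1, -1)
  s_upper <- c(0.95, 8, 8, 0.8, 1, 1)
  starts <- lhs::randomLHS(n_restarts, 6)
  starts <- sweep(sweep(starts, 2, s_upper - s_lower, "*"), 2, s_lower, "+")
  obj <- function(th) {
    p <- list(alpha = th[1], w_mf = th[2], w_mb = th[3], forget = th[4],
              pr = th[5], pz = th[6], meta_gain = meta_gain)
    nll_hybrid(session, structure, p) +
      ridge * sum(th[c(2, 3, 5, 6)]^2)
  }
  best <- NULL; any_ok <- FALSE
  for (i in seq_len(n_restarts)) {
    fit <- try(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 200, factr = 1e9)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    any_ok <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!any_ok) stop("all optimizer restarts failed")
  th <- best$par
  p_hat <- agent_params(alpha = th[1], w_mf = th[2], w_mb = th[3],
                        forget = th[4], pr = th[5], pz = th[6],
                        meta_gain = meta_gain)
  structure(list(
    params = p_hat,
    nll = nll_hybrid(session, structure, p_hat), n_restarts = n_restarts,
    converged = best$convergence == 0,
    bounds = list(lower = lower, upper = upper)),
    class = "rl_fit")
}

#' Simulate-then-regress closure of the hybrid model
#'
#' Given fitted parameters per subject, repeatedly regenerates cohorts of
#' synthetic sessions from those parameters (fresh reward walks and offer
#' sequences each time), reruns the MB signature regression (optionally
#' also MF) on each simulated cohort, and averages the per-subject total
#' Common effects across simulations. This asks whether the fitted
#' generative model reproduces the regression-based behavioral signatures.
#'
#' @param fits List of `rl_fit` (or `agent_params`) objects, one per
#'   subject.
#' @param structure A `task_structure` (used for all simulated subjects).
#' @param n_sims Number of simulate-regress repetitions (default 1000;
#'   reduce for quick checks).
#' @param n_blocks,trials_per_block Layout of each simulated session.
#' @param seed Optional integer seed.
#' @param systems Which signature regressions to run, subset of
#'   `c("MB", "MF")`.
#' @return List of class `sim_regress_result`: `n_sims`, `per_subject`
#'   (data frame of per-subject mean and sd of total effects per system),
#'   `n_failed` (simulations excluded for regression non-convergence).
#' @export
simulate_and_regress <- function(fits, structure, n_sims = 1000,
                                 n_blocks = 5, trials_per_block = 60,
                                 seed = NULL, systems = "MB") {
  stopifnot(length(fits) >= 2, all(systems %in% c("MB", "MF")))
  if (!is.null(seed)) set.seed(seed)
  par_list <- lapply(fits, function(f)
    if (inherits(f, "rl_fit")) f$params else f)
  S <- length(par_list)
  ids <- sprintf("s%02d", seq_len(S))
  eff <- list(MB = vector("list", n_sims), MF = vector("list", n_sims))
  n_failed <- 0L
  for (i in seq_len(n_sims)) {
    recs <- do.call(rbind, lapply(seq_len(S), function(s) {
      sch <- simulate_session_schedule(n_blocks, trials_per_block)
      off <- make_offer_sequence(structure, n_blocks, trials_per_block)
      sess <- simulate_bandit_agent(structure, sch, off, par_list[[s]])
      classify_transitions(sess, structure, subject = ids[s])
    }))
    ok <- TRUE
    for (sys in systems) {
      fit <- try(if (sys == "MB") mb_regression(recs) else mf_regression(recs),
                 silent = TRUE)
      if (inherits(fit, "try-error") || !fit$converged) { ok <- FALSE; break }
      eff[[sys]][[i]] <- stats::setNames(fit$subject_total$total,
                                         fit$subject_total$subject)
    }
    if (!ok) {
      n_failed <- n_failed + 1L
      for (sys in systems) eff[[sys]][i] <- list(NULL)
    }
  }
  per_subject <- do.call(rbind, lapply(systems, function(sys) {
    m <- do.call(rbind, eff[[sys]][!vapply(eff[[sys]], is.null, TRUE)])
    if (is.null(m)) stop("all simulations failed for system ", sys)
    data.frame(subject = colnames(m), system = sys,
               mean_effect = colMeans(m), sd_effect = apply(m, 2, stats::sd),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(n_sims = n_sims, per_subject = per_subject,
                 n_failed = n_failed),
            class = "sim_regress_result")
}
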
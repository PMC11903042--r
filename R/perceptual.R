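#' Parameters of the SDT observer for the dot-density task
#'
#' @param k Evidence gain: a dot difference of `delta` yields decision
#'   evidence `x ~ Normal(s * k * delta, 1)` with `s = +-1` the stimulus
#'   side. Type-1 sensitivity at a fixed level is `d' = 2 * k * delta`. The
#'   default places the one-up two-down staircase equilibrium
#'   (`Phi(k * delta) = 0.707`) at the 20-dot starting level, so the 1-dot
#'   step is a small relative perturbation of difficulty.
#' @param meta_noise Standard deviation of additional Gaussian noise on the
#'   confidence evidence `y = x + Normal(0, meta_noise)`. At 0 the
#'   confidence report uses the identical sample as the choice, so the
#'   observer is metacognitively ideal (M-ratio 1).
#' @return A list of class `sdt_observer`.
#' @export
sdt_observer <- function(k = 0.027, meta_noise = 0) {
  stopifnot(k >= 0, meta_noise >= 0)
  structure(list(k = k, meta_noise = meta_noise), class = "sdt_observer")
}

#' Simulate the dot-density task with a one-up two-down staircase
#'
#' Each trial shows a dot-difference `delta` (the staircase level) on a
#' random side; the observer chooses the side of the sign of its evidence
#' sample and reports confidence as its posterior probability of being
#' correct given the (possibly noisier) confidence sample, on the 50-100
#' scale. The posterior is computed under the observer's *belief* about the
#' task's difficulty — the trained level it reached when the recorded
#' session starts — rather than the exact current dot difference, which the
#' observer cannot count; this keeps confidence a monotone function of the
#' confidence evidence. Difficulty follows a one-up two-down staircase: one
#' error makes the task easier (`delta + step`), two consecutive correct
#' responses make it harder (`delta - step`), which converges to
#' approximately 70.7% accuracy.
#'
#' @param n_blocks,trials_per_block Session layout (default 8 x 25).
#' @param obs An [sdt_observer()].
#' @param start_level,step,min_level Staircase: initial dot difference, step
#'   size, and level floor (all in dots, positive).
#' @param n_practice Staircase-only practice trials run (and discarded)
#'   before the recorded session, mirroring the task's training phase that
#'   establishes a personalized difficulty level; the recorded session then
#'   starts near the staircase's convergence point. Default 0.
#' @param staircase If `FALSE`, the level is held fixed at `start_level`
#'   for the whole session (constant-difficulty variant).
#' @param seed Optional integer seed.
#'
#' @return A `perceptual_session` data frame, one row per trial: `block`,
#'   `trial`, `level` (pre-trial staircase level), `stim` (+1 right /
#'   -1 left), `choice` (+1/-1), `correct` (0/1), `confidence` (in
#'   `[50, 100]`).
#' @export
simulate_perceptual <- function(n_blocks = 8, trials_per_block = 25,
                                obs = sdt_observer(),
                                start_level = 20, step = 1, min_level = 1,
                                n_practice = 0, staircase = TRUE,
                                seed = NULL) {
  stopifnot(inherits(obs, "sdt_observer"),
            start_level > 0, step > 0, min_level > 0, n_practice >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_rec <- n_blocks * trials_per_block
  n <- n_practice + n_rec
  level <- numeric(n); stim <- integer(n); choice <- integer(n)
  correct <- integer(n); yev <- numeric(n)
  cur <- start_level
  streak <- 0L   # consecutive correct since last level change
  tau2 <- obs$meta_noise^2
  for (t in seq_len(n)) {
    level[t] <- cur
    s <- if (stats::runif(1) < 0.5) -1L else 1L
    x <- stats::rnorm(1, s * obs$k * cur, 1)
    a <- if (x >= 0) 1L else -1L
    yev[t] <- x + if (tau2 > 0) stats::rnorm(1, 0, obs$meta_noise) else 0
    stim[t] <- s; choice[t] <- a
    ok <- as.integer(a == s)
    correct[t] <- ok
    if (staircase) {
      if (ok == 1L) {
        streak <- streak + 1L
        if (streak == 2L) { cur <- max(cur - step, min_level); streak <- 0L }
      } else {
        cur <- cur + step
        streak <- 0L
      }
    }
  }
  rec <- seq.int(n_practice + 1L, n)
  # posterior P(stimulus = choice | y) under the observer's difficulty
  # belief (the trained level entering the session): log-likelihood ratio
  # of the marginal y ~ Normal(s * mu_belief, 1 + tau2)
  mu_belief <- obs$k * level[rec][1]
  p_correct <- stats::plogis(2 * mu_belief * choice[rec] * yev[rec] / (1 + tau2))
  out <- data.frame(block = rep(seq_len(n_blocks), each = trials_per_block),
                    trial = seq_len(n_rec), level = level[rec],
                    stim = stim[rec], choice = choice[rec],
                    correct = correct[rec],
                    confidence = 100 * pmin(pmax(p_correct, 0.5), 1))
  class(out) <- c("perceptual_session", "data.frame")
  out
}
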
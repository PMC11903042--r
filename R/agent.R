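#' Parameters of the hybrid MF/MB agent
#'
#' The agent mixes a model-free controller (cached person values updated
#' from the summed two-vegetable payoff) and a model-based controller
#' (vegetable values combined through the known person-vegetable structure),
#' with forgetting, person- and side-perseveration, and a confidence report.
#'
#' @param alpha Learning rate in `[0, 1]` shared by both systems.
#' @param w_mf,w_mb Nonnegative weights of the MF and MB value differences in
#'   the choice logit (inverse-temperature-like). `w_mf = 0` gives a pure-MB
#'   agent, `w_mb = 0` a pure-MF agent.
#' @param forget Per-trial decay in `[0, 1]` of all values *not* updated on a
#'   trial, toward their initialization.
#' @param pr,pz Perseveration weights for repeating the previous person
#'   (`pr`) and the previous response side (`pz`).
#' @param conf_gain Gain mapping the absolute value-difference evidence to
#'   the confidence report.
#' @param conf_noise Standard deviation of Gaussian noise on the confidence
#'   evidence (on the logit scale).
#' @param meta_gain Meta-control hook: the effective MB weight on a trial is
#'   `w_mb * exp(meta_gain * (conf_prev - 75) / 25)`, so positive values make
#'   high previous-trial confidence boost model-based control. Default 0
#'   (confidence-independent agent).
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.5, w_mf = 3, w_mb = 3, forget = 0.1,
                         pr = 0.3, pz = 0.1,
                         conf_gain = 1.5, conf_noise = 1, meta_gain = 0) {
  stopifnot(alpha >= 0, alpha <= 1, w_mf >= 0, w_mb >= 0,
            forget >= 0, forget <= 1, conf_noise >= 0)
  structure(list(alpha = alpha, w_mf = w_mf, w_mb = w_mb, forget = forget,
                 pr = pr, pz = pz, conf_gain = conf_gain,
                 conf_noise = conf_noise, meta_gain = meta_gain),
            class = "agent_params")
}

# Initialization constants of the value systems: the MF person value starts
# at the expected two-outcome sum under p = 0.5; MB vegetable values at 0.5.
Q_MF_INIT <- 1.0
V_MB_INIT <- 0.5

#' Simulate a hybrid agent on the two-outcome task
#'
#' Plays the offered pairs against a reward schedule. Per trial: the choice
#' logit is `w_mf * dQmf + w_mb_eff * dQmb + pr * drep + pz * dside` (left
#' minus right); both of the chosen person's vegetables pay out Bernoulli at
#' their current generating probabilities; MF values of the chosen person
#' and MB values of both observed vegetables are delta-rule updated while
#' everything else decays toward initialization by `(1 - forget)`;
#' confidence is `50 + 50 * logistic(conf_gain * |value evidence| + noise)`.
#' All value and perseveration state resets at block boundaries (the task's
#' reward probabilities are reset between blocks).
#'
#' @param structure A [make_structure()] task structure.
#' @param schedule A [simulate_schedule()] (or session) schedule with at
#'   least as many rows as there are offers.
#' @param offers An offer sequence from [make_offer_sequence()].
#' @param params An [agent_params()] object.
#' @param seed Optional integer seed.
#'
#' @return A `bandit_session` data frame, one row per trial: `block`,
#'   `trial`, `left`, `right`, `choice`, `side`, `confidence`, `veg_c`
#'   (common vegetable of the offer), `veg1`/`veg2` (the chosen person's
#'   vegetables), `out1`/`out2` (their payoffs in 0/1), and `prob_<veg>`
#'   columns with the generating probabilities of all four vegetables.
#' @export
simulate_bandit_agent <- function(structure, schedule, offers, params,
                                  seed = NULL) {
  stopifnot(inherits(structure, "task_structure"),
            inherits(params, "agent_params"))
  n <- nrow(offers)
  if (nrow(schedule$probs) < n) stop("schedule shorter than offer sequence")
  if (!is.null(seed)) set.seed(seed)

  persons <- structure$persons
  vegs <- structure$vegetables
  grows_idx <- matrix(match(structure$grows, vegs), ncol = 2)  # person x 2
  li <- match(offers$left, persons)
  ri <- match(offers$right, persons)

  q_mf <- rep(Q_MF_INIT, 4)
  v_mb <- rep(V_MB_INIT, 4)
  prev_person <- NA_integer_
  prev_side <- NA_integer_   # 1 = left, 2 = right
  prev_conf <- NA_real_

  choice <- integer(n); side <- integer(n); conf <- numeric(n)
  out1 <- integer(n); out2 <- integer(n)
  cur_block <- 0L
  for (t in seq_len(n)) {
    if (offers$block[t] != cur_block) {   # block reset
      cur_block <- offers$block[t]
      q_mf[] <- Q_MF_INIT; v_mb[] <- V_MB_INIT
      prev_person <- NA_integer_; prev_side <- NA_integer_; prev_conf <- NA_real_
    }
    l <- li[t]; r <- ri[t]
    q_mb_l <- v_mb[grows_idx[l, 1]] + v_mb[grows_idx[l, 2]]
    q_mb_r <- v_mb[grows_idx[r, 1]] + v_mb[grows_idx[r, 2]]
    w_mb_eff <- if (params$meta_gain != 0 && !is.na(prev_conf))
      params$w_mb * exp(params$meta_gain * (prev_conf - 75) / 25) else params$w_mb
    dval <- params$w_mf * (q_mf[l] - q_mf[r]) + w_mb_eff * (q_mb_l - q_mb_r)
    drep <- if (is.na(prev_person)) 0 else (prev_person == l) - (prev_person == r)
    dside <- if (is.na(prev_side)) 0 else (prev_side == 1L) - (prev_side == 2L)
    logit <- dval + params$pr * drep + params$pz * dside
    pick_left <- stats::runif(1) < stats::plogis(logit)
    ch <- if (pick_left) l else r
    choice[t] <- ch
    side[t] <- if (pick_left) 1L else 2L

    conf[t] <- 50 + 50 * stats::plogis(params$conf_gain * abs(dval) +
                                       stats::rnorm(1, 0, params$conf_noise))

    vg <- grows_idx[ch, ]
    p_now <- schedule$probs[t, ]
    r1 <- as.integer(stats::runif(1) < p_now[vg[1]])
    r2 <- as.integer(stats::runif(1) < p_now[vg[2]])
    out1[t] <- r1; out2[t] <- r2

    # delta-rule updates, then decay of everything untouched
    q_mf[ch] <- q_mf[ch] + params$alpha * ((r1 + r2) - q_mf[ch])
    v_mb[vg[1]] <- v_mb[vg[1]] + params$alpha * (r1 - v_mb[vg[1]])
    v_mb[vg[2]] <- v_mb[vg[2]] + params$alpha * (r2 - v_mb[vg[2]])
    keep <- 1 - params$forget
    q_mf[-ch] <- Q_MF_INIT + keep * (q_mf[-ch] - Q_MF_INIT)
    v_mb[-vg] <- V_MB_INIT + keep * (v_mb[-vg] - V_MB_INIT)

    prev_person <- ch; prev_side <- side[t]; prev_conf <- conf[t]
  }

  sess <- data.frame(
    block = offers$block, trial = offers$trial,
    left = offers$left, right = offers$right,
    choice = persons[choice], side = c("left", "right")[side],
    confidence = conf, veg_c = offers$common,
    veg1 = structure$grows[choice, 1], veg2 = structure$grows[choice, 2],
    out1 = out1, out2 = out2, stringsAsFactors = FALSE)
  pm <- schedule$probs[seq_len(n), , drop = FALSE]
  colnames(pm) <- paste0("prob_", vegs)
  sess <- cbind(sess, as.data.frame(pm))
  class(sess) <- c("bandit_session", "data.frame")
  sess
}
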
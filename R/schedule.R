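#' Simulate reward-probability random walks
#'
#' Each vegetable's probability of paying out follows an independent
#' Gaussian random walk (default step sd 0.03 per trial) with reflecting
#' boundaries at 0.2 and 0.8: a proposed value x above `hi` reflects to
#' `2*hi - x`, below `lo` to `2*lo - x`, applied iteratively until inside
#' the bounds.
#'
#' @param T Number of trials (rows).
#' @param sigma Per-trial Gaussian step standard deviation.
#' @param lo,hi Reflecting bounds, `0 <= lo < hi <= 1`.
#' @param init Either `"random"` (each walk starts uniformly in `[lo, hi]`)
#'   or a numeric vector of starting probabilities, one per vegetable.
#' @param vegetables Vegetable labels (columns).
#' @param seed Optional integer seed.
#'
#' @return An object of class `reward_schedule`: a list with `probs`
#'   (T x n matrix of probabilities, columns named by vegetable), `sigma`,
#'   `lo`, `hi`.
#' @examples
#' sch <- simulate_schedule(T = 300, seed = 1)
#' range(sch$probs)  # within [0.2, 0.8]
#' @export
simulate_schedule <- function(T, sigma = 0.03, lo = 0.2, hi = 0.8,
                              init = "random",
                              vegetables = c("garlic", "lettuce", "onion", "carrot"),
                              seed = NULL) {
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("invalid bounds: need 0 <= lo < hi <= 1")
  if (sigma < 0) stop("sigma must be nonnegative")
  if (T < 1) stop("T must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(vegetables)
  if (identical(init, "random")) {
    x0 <- stats::runif(n, lo, hi)
  } else {
    stopifnot(is.numeric(init))
    x0 <- rep_len(init, n)
    if (any(x0 < lo | x0 > hi)) stop("init outside [lo, hi]")
  }
  probs <- matrix(NA_real_, T, n, dimnames = list(NULL, vegetables))
  probs[1, ] <- x0
  if (T > 1) {
    for (t in 2:T) {
      probs[t, ] <- reflect_into(probs[t - 1, ] + stats::rnorm(n, 0, sigma), lo, hi)
    }
  }
  structure(list(probs = probs, sigma = sigma, lo = lo, hi = hi),
            class = "reward_schedule")
}

# Iterated reflection into [lo, hi]; vectorized.
reflect_into <- function(x, lo, hi) {
  while (any(bad <- (x < lo | x > hi))) {
    x[bad & x > hi] <- 2 * hi - x[bad & x > hi]
    bad <- x < lo | x > hi
    x[bad & x < lo] <- 2 * lo - x[bad & x < lo]
  }
  x
}

#' Concatenate independently initialized schedule segments
#'
#' Between blocks of the two-outcome task the reward probabilities are reset
#' to fresh values; this builds a full-session schedule as `n_blocks`
#' independent walks of `trials_per_block` rows each.
#'
#' @inheritParams simulate_schedule
#' @param n_blocks,trials_per_block Session layout.
#' @return A `reward_schedule` with `n_blocks * trials_per_block` rows and a
#'   `block` attribute on `probs` giving each row's block index.
#' @export
simulate_session_schedule <- function(n_blocks, trials_per_block, sigma = 0.03,
                                      lo = 0.2, hi = 0.8, init = "random",
                                      vegetables = c("garlic", "lettuce", "onion", "carrot"),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- lapply(seq_len(n_blocks), function(b)
    simulate_schedule(trials_per_block, sigma, lo, hi, init, vegetables)$probs)
  probs <- do.call(rbind, segs)
  attr(probs, "block") <- rep(seq_len(n_blocks), each = trials_per_block)
  structure(list(probs = probs, sigma = sigma, lo = lo, hi = hi),
            class = "reward_schedule")
}
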
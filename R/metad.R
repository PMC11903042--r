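#' Bin continuous confidence into rating counts
#'
#' The confidence slider is continuous on `[50, 100]`; signal-detection
#' metacognition models need discrete ratings. Confidence is cut at
#' per-subject quantile edges (default 4 bins), ties going to the lower bin,
#' and tabulated into a 2 (stimulus) x 2 (response) x K count array.
#'
#' @param session A `perceptual_session` (or any data frame with `stim`,
#'   `choice` in \{-1, +1\} and `confidence`).
#' @param K Number of confidence bins (>= 2).
#' @return An object of class `rating_counts`: list with `counts`
#'   (2 x 2 x K array, stimulus S1/S2 by response R1/R2 by rating) and
#'   `n_bins`.
#' @export
bin_confidence <- function(session, K = 4) {
  stopifnot(K >= 2, nrow(session) > 0)
  conf <- session$confidence
  n_distinct <- length(unique(conf))
  if (n_distinct < K) {
    warning(sprintf("only %d distinct confidence values; collapsing to %d bin(s)",
                    n_distinct, n_distinct))
    K <- max(n_distinct, 1L)
  }
  if (K == 1L) {
    bins <- rep(1L, length(conf))
  } else {
    edges <- unique(stats::quantile(conf, probs = seq(0, 1, length.out = K + 1),
                                    type = 7, names = FALSE))
    if (length(edges) == K + 1L) {
      # right-closed intervals: a value equal to an interior edge falls in
      # the lower bin
      bins <- as.integer(cut(conf, breaks = edges, include.lowest = TRUE,
                             right = TRUE))
    } else {
      # a point mass (e.g. reports pinned at the 50 end of the scale) has
      # collapsed some quantile edges; fall back to equal-count binning on
      # ranks, splitting the tied mass deterministically by trial order
      bins <- as.integer(ceiling(rank(conf, ties.method = "first") *
                                   K / length(conf)))
    }
  }
  counts <- array(0L, dim = c(2, 2, K),
                  dimnames = list(stim = c("S1", "S2"),
                                  resp = c("R1", "R2"),
                                  rating = seq_len(K)))
  si <- ifelse(session$stim > 0, 2L, 1L)
  ri <- ifelse(session$choice > 0, 2L, 1L)
  for (t in seq_along(bins))
    counts[si[t], ri[t], bins[t]] <- counts[si[t], ri[t], bins[t]] + 1L
  structure(list(counts = counts, n_bins = K), class = "rating_counts")
}

#' Type-1 signal-detection fit
#'
#' `d' = z(HR) - z(FAR)` and criterion `c = -0.5 * (z(HR) + z(FAR))`, with a
#' `1/(2N)` correction pulling perfect or empty rates off 0/1.
#'
#' @param counts A [bin_confidence()] `rating_counts` object.
#' @return List of class `type1_fit` with `d_prime`, `c`, `hr`, `far`.
#' @export
fit_type1 <- function(counts) {
  stopifnot(inherits(counts, "rating_counts"))
  tab <- apply(counts$counts, c(1, 2), sum)  # stim x resp
  n1 <- sum(tab["S1", ]); n2 <- sum(tab["S2", ])
  if (n1 == 0 || n2 == 0) stop("a stimulus class has zero trials")
  hr <- rate_corrected(tab["S2", "R2"], n2)
  far <- rate_corrected(tab["S1", "R2"], n1)
  structure(list(d_prime = stats::qnorm(hr) - stats::qnorm(far),
                 c = -0.5 * (stats::qnorm(hr) + stats::qnorm(far)),
                 hr = hr, far = far),
            class = "type1_fit")
}

rate_corrected <- function(x, n) {
  r <- x / n
  if (r == 0) r <- 1 / (2 * n)
  if (r == 1) r <- 1 - 1 / (2 * n)
  r
}

#' Maximum-likelihood meta-d'
#'
#' Fits the metacognitive sensitivity meta-d' of Maniscalco & Lau: the
#' type-1 sensitivity that an SDT observer would need to produce the
#' observed response-conditional confidence-rating distributions, holding
#' the relative type-1 criterion fixed (`c' = c * meta_d / d'`). Type-2
#' criteria (K-1 per response side) are estimated jointly by maximizing the
#' multinomial likelihood of the rating counts conditional on stimulus and
#' response.
#'
#' @param counts A `rating_counts` object with at least 2 bins.
#' @param t1 The [fit_type1()] fit of the same counts (computed if missing).
#' @param n_starts Number of optimizer restarts.
#' @return List of class `meta_fit`: `meta_d`, `m_ratio`
#'   (`meta_d / d_prime`), `c2_minus`, `c2_plus` (type-2 criteria, ordered
#'   outward from the rescaled type-1 criterion), `nll`, `converged`.
#' @export
fit_meta_d <- function(counts, t1 = fit_type1(counts), n_starts = 3) {
  stopifnot(inherits(counts, "rating_counts"), counts$n_bins >= 2)
  K <- counts$n_bins
  nS1 <- counts$counts["S1", , ]  # resp x rating
  nS2 <- counts$counts["S2", , ]
  c_rel <- t1$c / t1$d_prime  # relative criterion, preserved under rescaling

  nll_fun <- function(theta) {
    md <- theta[1]
    u <- theta[2:K]; v <- theta[(K + 1):(2 * K - 1)]
    meta_d_nll(md, cumsum(exp(u)), cumsum(exp(v)), c_rel, nS1, nS2)
  }
  best <- NULL
  starts <- list(c(max(t1$d_prime, 0.1), rep(log(0.4), 2 * (K - 1))),
                 c(0.5, rep(log(0.2), 2 * (K - 1))),
                 c(2, rep(log(0.7), 2 * (K - 1))))
  for (s in seq_len(min(n_starts, length(starts)))) {
    fit <- try(stats::optim(starts[[s]], nll_fun, method = "L-BFGS-B",
                            lower = c(0, rep(-8, 2 * (K - 1))),
                            upper = c(10, rep(3, 2 * (K - 1))),
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("meta-d' estimation failed for all restarts")
  md <- best$par[1]
  cprime <- c_rel * md
  d_plus <- cumsum(exp(best$par[2:K]))
  d_minus <- cumsum(exp(best$par[(K + 1):(2 * K - 1)]))
  structure(list(meta_d = md, m_ratio = md / t1$d_prime,
                 c2_plus = cprime + d_plus, c2_minus = cprime - d_minus,
                 nll = best$value, converged = best$convergence == 0),
            class = "meta_fit")
}

# Negative log-likelihood of response-conditional rating counts under an
# SDT observer with sensitivity md, relative type-1 criterion c_rel and
# type-2 criterion offsets d_plus/d_minus (> 0, increasing) outward from
# c' = c_rel * md. nS1, nS2 are resp x rating count matrices.
meta_d_nll <- function(md, d_plus, d_minus, c_rel, nS1, nS2) {
  cprime <- c_rel * md
  bp <- c(cprime, cprime + d_plus, Inf)    # R2 boundaries, ascending
  bm <- c(-Inf, rev(cprime - d_minus), cprime)  # R1 boundaries, ascending
  ll <- 0
  for (stim in 1:2) {
    mu <- if (stim == 1) -md / 2 else md / 2
    n <- if (stim == 1) nS1 else nS2
    # R2: rating j occupies (bp[j], bp[j+1])
    aR2 <- diff(stats::pnorm(bp - mu))
    pR2 <- sum(aR2)
    # R1: rating j occupies the j-th interval below c', counted outward
    aR1 <- rev(diff(stats::pnorm(bm - mu)))
    pR1 <- sum(aR1)
    pj2 <- pmax(aR2 / max(pR2, 1e-300), 1e-12)
    pj1 <- pmax(aR1 / max(pR1, 1e-300), 1e-12)
    ll <- ll + sum(n[2, ] * log(pj2)) + sum(n[1, ] * log(pj1))
  }
  -ll
}

#' Quadratic scoring rule for confidence reports
#'
#' The proper score `1 - (confidence/100 - correct)^2`, averaged over
#' trials; 1 for perfectly calibrated certainty, 0.75 for uninformative
#' reports at 50.
#'
#' @param confidence Per-trial confidence in `[50, 100]`.
#' @param correct Per-trial correctness in \{0, 1\}.
#' @return Mean score in `[0, 1]`.
#' @export
qsr <- function(confidence, correct) {
  if (length(confidence) != length(correct))
    stop("confidence and correctness lengths differ")
  stopifnot(all(confidence >= 50 & confidence <= 100),
            all(correct %in% c(0, 1)))
  mean(1 - (confidence / 100 - correct)^2)
}
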
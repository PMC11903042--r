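#' MCMC settings for the hierarchical M-ratio model
#'
#' @param chains Number of chains (rhat needs >= 2).
#' @param draws Total samples per chain, *including* warm-up. The full-scale
#'   default is 3 chains x 12,000 draws with 2,000 warm-up; tests and quick
#'   analyses typically reduce to 2,000/500.
#' @param warmup Warm-up (burn-in) iterations per chain.
#' @param seed Integer seed; chain RNGs are derived from it.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 3, draws = 12000, warmup = 2000, seed = 1) {
  stopifnot(chains >= 2, draws > warmup, warmup >= 0)
  structure(list(chains = chains, draws = draws, warmup = warmup, seed = seed),
            class = "mcmc_control")
}

#' Hierarchical Bayesian estimation of M-ratio across correlated conditions
#'
#' Fits a hierarchical signal-detection model of metacognitive efficiency:
#' each subject's log M-ratio in each condition is a draw from a
#' multivariate Gaussian over conditions with free condition means
#' (`mu ~ N(0, 1)`), condition standard deviations (`1/sigma^2 ~
#' Gamma(0.001, 0.001)`), and pairwise correlations (`rho ~ Uniform(-1, 1)`,
#' non-positive-definite combinations rejected), matching a within-subject
#' design. Subject-level type-1 parameters (d', c) are fixed at their
#' maximum-likelihood estimates; type-2 criteria are estimated per subject
#' and condition with weakly informative priors. Sampling is by MCMC in
#' JAGS.
#'
#' @param counts Either a list of `rating_counts` (one per subject; a single
#'   condition) or a named list of conditions, each itself a list with one
#'   `rating_counts` per subject (same subjects, same order, same bin count
#'   across conditions).
#' @param mcmc An [mcmc_control()].
#' @return An object of class `meta_posterior`: list with `samples` (a
#'   `coda::mcmc.list` over group parameters and subject log M-ratios),
#'   `rhat` (named vector), `converged` (all rhat < 1.1), `conditions`,
#'   `n_subjects`, `d_prime` and `c1` matrices, and `mcmc` settings.
#' @examples
#' \dontrun{
#' sess <- lapply(1:8, function(s) simulate_perceptual(seed = s))
#' cnt <- lapply(sess, bin_confidence)
#' post <- fit_hierarchical(cnt, mcmc_control(draws = 1500, warmup = 500))
#' mean(group_mratio(post))
#' }
#' @export
fit_hierarchical <- function(counts, mcmc = mcmc_control()) {
  stopifnot(inherits(mcmc, "mcmc_control"))
  if (inherits(counts[[1]], "rating_counts")) counts <- list(cond1 = counts)
  C <- length(counts)
  if (is.null(names(counts))) names(counts) <- paste0("cond", seq_len(C))
  conditions <- names(counts)
  if (C > 3) stop("at most 3 conditions supported")
  S <- length(counts[[1]])
  if (S < 2) stop("need at least 2 subjects")
  if (!all(vapply(counts, length, 1L) == S))
    stop("same subjects required across conditions")
  K <- counts[[1]][[1]]$n_bins
  if (K < 3) stop("need at least 3 confidence bins for the hierarchical fit")

  nR1 <- array(0L, c(S, C, 2, K)); nR2 <- array(0L, c(S, C, 2, K))
  d1 <- matrix(NA_real_, S, C); crel <- matrix(NA_real_, S, C)
  for (cc in seq_len(C)) for (s in seq_len(S)) {
    rc <- counts[[cc]][[s]]
    stopifnot(inherits(rc, "rating_counts"))
    if (rc$n_bins != K) stop("bin counts differ across subjects/conditions")
    if (any(apply(rc$counts, c(1, 2), sum) == 0))
      stop("every stimulus x response cell needs at least one trial")
    t1 <- fit_type1(rc)
    if (t1$d_prime <= 0.05)
      warning(sprintf("subject %d condition %s: d' = %.3f is near zero; ",
                      s, conditions[cc], t1$d_prime),
              "M-ratio is unstable")
    d1[s, cc] <- t1$d_prime
    crel[s, cc] <- t1$c / t1$d_prime
    nR1[s, cc, , ] <- rc$counts[, 1, ]  # stim x rating, response R1
    nR2[s, cc, , ] <- rc$counts[, 2, ]
  }

  data <- list(S = S, C = C, K = K, nR1 = nR1, nR2 = nR2,
               NR1 = apply(nR1, 1:3, sum), NR2 = apply(nR2, 1:3, sum),
               d1 = d1, crel = crel)
  if (C == 3) data$zeros <- rep(0, S)

  model_str <- hmeta_model_string(C, K)
  set.seed(mcmc$seed)
  inits <- lapply(seq_len(mcmc$chains), function(i) {
    ini <- list(logM = matrix(0, S, C),
                gP = array(-1, c(S, C, K - 1)), gM = array(-1, c(S, C, K - 1)),
                muM = rep(0, C), lamM = rep(4, C),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = sample.int(2^31 - 2, 1))
    if (C == 2) ini$rho <- 0
    if (C == 3) ini$rho <- rep(0, 3)
    ini
  })
  monitors <- c("muM", "sigmaM", "logM", if (C >= 2) "rho")

  jm <- withCallingHandlers(
    rjags::jags.model(textConnection(model_str), data = data,
                      inits = inits, n.chains = mcmc$chains,
                      n.adapt = min(500, mcmc$warmup), quiet = TRUE),
    warning = function(w) {
      # at sharply reduced draw counts JAGS reports incomplete adaptation;
      # convergence is judged by rhat instead
      if (grepl("Adaptation incomplete", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  extra_burn <- mcmc$warmup - min(500, mcmc$warmup)
  if (extra_burn > 0) update(jm, extra_burn, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitors, n.iter = mcmc$draws - mcmc$warmup,
                                 progress.bar = "none")

  gd <- try(coda::gelman.diag(samples, multivariate = FALSE, autoburnin = FALSE),
            silent = TRUE)
  rhat <- if (inherits(gd, "try-error")) {
    stats::setNames(rep(NA_real_, ncol(samples[[1]])), colnames(samples[[1]]))
  } else stats::setNames(gd$psrf[, 1], rownames(gd$psrf))
  structure(list(samples = samples, rhat = rhat,
                 converged = all(rhat < 1.1, na.rm = TRUE),
                 conditions = conditions, n_subjects = S,
                 d_prime = d1, c1 = crel * d1, mcmc = mcmc),
            class = "meta_posterior")
}

# JAGS model text for the hierarchical M-ratio model with C in 1:3
# conditions and K >= 3 rating bins. Subject type-1 parameters enter as
# data (d1, crel = c/d'); the Maniscalco-Lau convention rescales the
# type-1 criterion by M-ratio so that c'/meta-d' = c/d'. The likelihood
# block is shared; only the group-level prior over log M-ratios differs
# by number of conditions.
hmeta_model_string <- function(C, K) {
  lik <- paste0(
    "  for (s in 1:S) {\n",
    "  for (c in 1:C) {\n",
    "    metad[s,c] <- exp(logM[s,c]) * d1[s,c]\n",
    "    cprime[s,c] <- crel[s,c] * metad[s,c]\n",
    "    cS2[s,c,1] <- cprime[s,c] + exp(gP[s,c,1])\n",
    "    cS1[s,c,1] <- cprime[s,c] - exp(gM[s,c,1])\n",
    "    for (j in 2:(K-1)) {\n",
    "      cS2[s,c,j] <- cS2[s,c,j-1] + exp(gP[s,c,j])\n",
    "      cS1[s,c,j] <- cS1[s,c,j-1] - exp(gM[s,c,j])\n",
    "    }\n",
    "    for (j in 1:(K-1)) {\n",
    "      gP[s,c,j] ~ dnorm(-1, 1)\n",
    "      gM[s,c,j] ~ dnorm(-1, 1)\n",
    "    }\n",
    "    for (i in 1:2) {\n",
    "      mus[s,c,i] <- (2*i - 3) * metad[s,c] / 2\n",
    "      aR2[s,c,i,1] <- phi(cS2[s,c,1] - mus[s,c,i]) - phi(cprime[s,c] - mus[s,c,i])\n",
    "      aR1[s,c,i,1] <- phi(cprime[s,c] - mus[s,c,i]) - phi(cS1[s,c,1] - mus[s,c,i])\n",
    "      for (j in 2:(K-1)) {\n",
    "        aR2[s,c,i,j] <- phi(cS2[s,c,j] - mus[s,c,i]) - phi(cS2[s,c,j-1] - mus[s,c,i])\n",
    "        aR1[s,c,i,j] <- phi(cS1[s,c,j-1] - mus[s,c,i]) - phi(cS1[s,c,j] - mus[s,c,i])\n",
    "      }\n",
    "      aR2[s,c,i,K] <- 1 - phi(cS2[s,c,K-1] - mus[s,c,i])\n",
    "      aR1[s,c,i,K] <- phi(cS1[s,c,K-1] - mus[s,c,i])\n",
    "      for (j in 1:K) {\n",
    "        pR2[s,c,i,j] <- (aR2[s,c,i,j] + 1.0E-8) / (sum(aR2[s,c,i,1:K]) + K * 1.0E-8)\n",
    "        pR1[s,c,i,j] <- (aR1[s,c,i,j] + 1.0E-8) / (sum(aR1[s,c,i,1:K]) + K * 1.0E-8)\n",
    "      }\n",
    "      nR1[s,c,i,1:K] ~ dmulti(pR1[s,c,i,1:K], NR1[s,c,i])\n",
    "      nR2[s,c,i,1:K] ~ dmulti(pR2[s,c,i,1:K], NR2[s,c,i])\n",
    "    }\n",
    "  }\n",
    "  }\n")

  group <- if (C == 1) {
    paste0(
      "  for (s in 1:S) {\n",
      "    logM[s, 1] ~ dnorm(muM[1], lamM[1])\n",
      "  }\n")
  } else if (C == 2) {
    paste0(
      "  SigmaM[1,1] <- sigmaM[1]^2\n",
      "  SigmaM[2,2] <- sigmaM[2]^2\n",
      "  SigmaM[1,2] <- rho * sigmaM[1] * sigmaM[2]\n",
      "  SigmaM[2,1] <- SigmaM[1,2]\n",
      "  TauM <- inverse(SigmaM)\n",
      "  rho ~ dunif(-1, 1)\n",
      "  for (s in 1:S) {\n",
      "    logM[s, 1:2] ~ dmnorm(muM[1:2], TauM[1:2, 1:2])\n",
      "  }\n")
  } else {
    paste0(
      # Uniform(-1,1) pairwise correlations with rejection of
      # non-positive-definite matrices: explicit 3x3 Gaussian log-density
      # through the zeros trick, -1e6 outside the PD region.
      "  for (p in 1:3) { rho[p] ~ dunif(-1, 1) }\n",
      "  detR <- 1 - rho[1]^2 - rho[2]^2 - rho[3]^2 + 2*rho[1]*rho[2]*rho[3]\n",
      "  pd <- step(detR - 1.0E-6)\n",
      "  detRs <- max(detR, 1.0E-6)\n",
      "  a11 <- (1 - rho[3]^2) / detRs\n",
      "  a22 <- (1 - rho[2]^2) / detRs\n",
      "  a33 <- (1 - rho[1]^2) / detRs\n",
      "  a12 <- (rho[2]*rho[3] - rho[1]) / detRs\n",
      "  a13 <- (rho[1]*rho[3] - rho[2]) / detRs\n",
      "  a23 <- (rho[1]*rho[2] - rho[3]) / detRs\n",
      "  for (s in 1:S) {\n",
      "    for (c in 1:3) {\n",
      "      logM[s, c] ~ dunif(-20, 20)\n",
      "      zz[s, c] <- (logM[s, c] - muM[c]) / sigmaM[c]\n",
      "    }\n",
      "    Qf[s] <- a11*zz[s,1]^2 + a22*zz[s,2]^2 + a33*zz[s,3]^2 +\n",
      "             2*a12*zz[s,1]*zz[s,2] + 2*a13*zz[s,1]*zz[s,3] +\n",
      "             2*a23*zz[s,2]*zz[s,3]\n",
      "    ld[s] <- ifelse(pd > 0.5,\n",
      "      -2.756815599614018 - log(sigmaM[1]*sigmaM[2]*sigmaM[3])\n",
      "      - 0.5*log(detRs) - 0.5*Qf[s],\n",
      "      -1.0E6)\n",
      "    zeros[s] ~ dpois(1.0E4 - ld[s])\n",
      "  }\n")
  }

  paste0(
    "model {\n",
    "  for (c in 1:C) {\n",
    "    muM[c] ~ dnorm(0, 1)\n",
    "    lamM[c] ~ dgamma(0.001, 0.001)\n",
    "    sigmaM[c] <- 1 / sqrt(lamM[c])\n",
    "  }\n",
    group,
    lik,
    "}\n")
}

#' Group-level M-ratio posterior draws
#'
#' @param post A [fit_hierarchical()] `meta_posterior`.
#' @param condition Condition label or index (default first).
#' @return Numeric vector of `exp(mu)` draws, pooled across chains in
#'   iteration order.
#' @export
group_mratio <- function(post, condition = 1) {
  stopifnot(inherits(post, "meta_posterior"))
  cc <- cond_index(post, condition)
  par <- sprintf("muM[%d]", cc)
  if (!par %in% colnames(post$samples[[1]])) par <- "muM"  # single condition
  exp(unlist(lapply(post$samples, function(m) as.numeric(m[, par]))))
}

#' Per-subject posterior mean M-ratios
#'
#' @inheritParams group_mratio
#' @return Matrix subjects x conditions of posterior means of
#'   `exp(log M-ratio)`.
#' @export
subject_mratio <- function(post) {
  stopifnot(inherits(post, "meta_posterior"))
  S <- post$n_subjects; C <- length(post$conditions)
  out <- matrix(NA_real_, S, C, dimnames = list(NULL, post$conditions))
  for (cc in seq_len(C)) for (s in seq_len(S)) {
    par <- sprintf("logM[%d,%d]", s, cc)
    out[s, cc] <- mean(exp(unlist(lapply(post$samples, function(m)
      as.numeric(m[, par])))))
  }
  out
}

cond_index <- function(post, condition) {
  if (is.character(condition)) {
    cc <- match(condition, post$conditions)
    if (is.na(cc)) stop("unknown condition: ", condition)
    cc
  } else {
    stopifnot(condition >= 1, condition <= length(post$conditions))
    as.integer(condition)
  }
}

#' Fraction of posterior draws with group M-ratio(a) < M-ratio(b)
#'
#' Draws are paired by iteration within chain, mirroring the reporting of
#' "what fraction of group posterior samples is lower in one condition than
#' another".
#'
#' @param post A `meta_posterior` fitted on >= 2 conditions (or 1, comparing
#'   a condition with itself).
#' @param a,b Condition labels or indices.
#' @return Fraction in `[0, 1]` (strict inequality).
#' @export
posterior_fraction <- function(post, a, b) {
  da <- group_mratio(post, a)
  db <- group_mratio(post, b)
  mean(da < db)
}

#' Repeated subsample Wilcoxon rank-sum comparison of two posteriors
#'
#' Draws `n_sub` samples from each of two posterior sample sets, compares
#' them with a two-sided Wilcoxon rank-sum test, and repeats `reps` times;
#' summarizes how often p < 0.05. A paired signed-rank variant is available
#' for within-subject comparisons.
#'
#' @param post_a,post_b Numeric sample vectors (e.g. [group_mratio()]
#'   draws).
#' @param n_sub Subsample size per set (default 30).
#' @param reps Repetitions (default 1000).
#' @param paired Use the signed-rank test on paired subsamples.
#' @param seed Optional integer seed.
#' @return List of class `subsample_wilcoxon`: `reps`, `frac_sig`
#'   (fraction of repetitions with p < 0.05), `mean_p`, `sd_p`.
#' @export
subsample_wilcoxon <- function(post_a, post_b, n_sub = 30, reps = 1000,
                               paired = FALSE, seed = NULL) {
  if (n_sub > length(post_a) || n_sub > length(post_b))
    stop("n_sub exceeds the available samples")
  if (!is.null(seed)) set.seed(seed)
  p <- vapply(seq_len(reps), function(i) {
    xa <- sample(post_a, n_sub)
    xb <- sample(post_b, n_sub)
    suppressWarnings(stats::wilcox.test(xa, xb, paired = paired,
                                        exact = FALSE)$p.value)
  }, numeric(1))
  structure(list(reps = reps, frac_sig = mean(p < 0.05),
                 mean_p = mean(p), sd_p = stats::sd(p)),
            class = "subsample_wilcoxon")
}
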
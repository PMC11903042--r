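# Shared fixtures built in code.

# permutation index -> permutation of 1:4
perm4 <- function(i) {
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  perms[i, ]
}

# A fixed 8-cycle structure: P1 {garlic, lettuce}, P2 {lettuce, onion},
# P3 {onion, carrot}, P4 {carrot, garlic}.
fixed_structure <- function() {
  persons <- paste0("P", 1:4)
  vegetables <- c("garlic", "lettuce", "onion", "carrot")
  grows <- matrix(c("garlic", "lettuce",
                    "lettuce", "onion",
                    "onion", "carrot",
                    "carrot", "garlic"),
                  ncol = 2, byrow = TRUE,
                  dimnames = list(persons, c("veg1", "veg2")))
  inc <- matrix(FALSE, 4, 4, dimnames = list(persons, vegetables))
  for (p in persons) inc[p, grows[p, ]] <- TRUE
  structure(list(persons = persons, vegetables = vegetables,
                 grows = grows, incidence = inc),
            class = "task_structure")
}

# Build a bandit_session data frame by hand from parallel vectors.
hand_session <- function(structure, block, left, right, choice, out1, out2,
                         confidence = rep(75, length(left)),
                         probs = NULL) {
  n <- length(left)
  side <- ifelse(choice == left, "left", "right")
  veg1 <- structure$grows[choice, 1]
  veg2 <- structure$grows[choice, 2]
  common <- mapply(function(a, b) shared_vegetable(structure, a, b), left, right)
  d <- data.frame(block = block, trial = seq_len(n), left = left, right = right,
                  choice = choice, side = side, confidence = confidence,
                  veg_c = unname(common), veg1 = unname(veg1),
                  veg2 = unname(veg2), out1 = out1, out2 = out2,
                  stringsAsFactors = FALSE)
  if (is.null(probs)) probs <- matrix(0.5, n, 4)
  colnames(probs) <- paste0("prob_", structure$vegetables)
  d <- cbind(d, as.data.frame(probs))
  class(d) <- c("bandit_session", "data.frame")
  d
}

# Construct a rating_counts object from a 2 x 2 x K array.
hand_counts <- function(arr) {
  dimnames(arr) <- list(stim = c("S1", "S2"), resp = c("R1", "R2"),
                        rating = seq_len(dim(arr)[3]))
  structure(list(counts = arr, n_bins = dim(arr)[3]), class = "rating_counts")
}

# Fake meta_posterior with given group log M-ratio draw matrices (one
# column per condition), for testing posterior summaries in isolation.
fake_posterior <- function(mu_draws, conditions = colnames(mu_draws)) {
  colnames(mu_draws) <- sprintf("muM[%d]", seq_len(ncol(mu_draws)))
  ml <- coda::mcmc.list(coda::mcmc(mu_draws))
  structure(list(samples = ml, rhat = NULL, converged = TRUE,
                 conditions = conditions, n_subjects = 0),
            class = "meta_posterior")
}

# Independent dense grid-search oracle for meta-d' with K = 2 rating bins:
# parameters are meta_d and one type-2 criterion offset per response side.
# Likelihood written from scratch (response-conditional multinomials).
# For fixed meta_d the two response sides separate (R2 cells depend only on
# the upper criterion offset dp, R1 cells only on dm), so the joint grid
# reduces to two dense 1-D profiles per meta_d value.
grid_meta_d_oracle <- function(counts, md_grid = seq(0, 4, by = 0.0025),
                               off_grid = seq(0.005, 4, by = 0.005)) {
  stopifnot(counts$n_bins == 2)
  t1 <- fit_type1(counts)
  crel <- t1$c / t1$d_prime
  n <- counts$counts
  best <- c(Inf, NA, NA, NA)
  for (md in md_grid) {
    cp <- crel * md
    ll2 <- 0; ll1 <- 0
    for (stim in 1:2) {
      mu <- c(-md / 2, md / 2)[stim]
      # response R2: low rating in (cp, cp+dp), high in (cp+dp, Inf)
      pR2 <- 1 - pnorm(cp - mu)
      a_hi2 <- 1 - pnorm(cp + off_grid - mu)
      a_lo2 <- pR2 - a_hi2
      # response R1: low rating in (cp-dm, cp), high in (-Inf, cp-dm)
      pR1 <- pnorm(cp - mu)
      a_hi1 <- pnorm(cp - off_grid - mu)
      a_lo1 <- pR1 - a_hi1
      ll2 <- ll2 + n[stim, 2, 1] * log(pmax(a_lo2 / pR2, 1e-12)) +
        n[stim, 2, 2] * log(pmax(a_hi2 / pR2, 1e-12))
      ll1 <- ll1 + n[stim, 1, 1] * log(pmax(a_lo1 / pR1, 1e-12)) +
        n[stim, 1, 2] * log(pmax(a_hi1 / pR1, 1e-12))
    }
    nll <- -(max(ll2) + max(ll1))
    if (nll < best[1])
      best <- c(nll, md, off_grid[which.max(ll2)], off_grid[which.max(ll1)])
  }
  list(nll = best[1], meta_d = best[2], d_plus = best[3], d_minus = best[4])
}
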
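#' Build the offered-pair sequence for a session
#'
#' Every trial offers two people who grow one vegetable in common. There are
#' exactly four such pairs; within each block of `trials_per_block` trials
#' each pair appears `trials_per_block / 4` times (15 times in a standard
#' 60-trial block), in a random order, with random left/right placement.
#'
#' @param structure A [make_structure()] task structure.
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block; must be divisible by 4.
#' @param seed Optional integer seed.
#'
#' @return A data frame with one row per trial: `block`, `trial` (global
#'   index), `left`, `right` (person labels), `common` (their shared
#'   vegetable).
#' @examples
#' st <- make_structure(seed = 1)
#' offers <- make_offer_sequence(st, n_blocks = 5, trials_per_block = 60, seed = 2)
#' table(offers$common[offers$block == 1])  # 15 each
#' @export
make_offer_sequence <- function(structure, n_blocks = 5, trials_per_block = 60,
                                seed = NULL) {
  stopifnot(inherits(structure, "task_structure"))
  if (trials_per_block %% 4 != 0)
    stop("trials_per_block must be divisible by 4 (one quarter per common pair)")
  if (!is.null(seed)) set.seed(seed)
  cp <- common_pairs(structure)
  reps <- trials_per_block / 4
  blocks <- lapply(seq_len(n_blocks), function(b) {
    idx <- sample(rep(seq_len(4), reps))          # pair order within block
    flip <- stats::runif(trials_per_block) < 0.5  # side assignment
    data.frame(block = b,
               left = ifelse(flip, cp$person_b[idx], cp$person_a[idx]),
               right = ifelse(flip, cp$person_a[idx], cp$person_b[idx]),
               common = cp$common[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out$trial <- seq_len(nrow(out))
  out[, c("block", "trial", "left", "right", "common")]
}
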
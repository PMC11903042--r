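#' Simulate a cohort of bandit subjects
#'
#' Simulates `n_subjects` independent sessions of the two-outcome task.
#' Each subject gets their own randomized person-vegetable mapping (as in
#' the task, where the mapping is created per participant), fresh reward
#' walks per block, and an offer sequence balanced within blocks.
#'
#' @param n_subjects Number of subjects.
#' @param params A single [agent_params()] shared by the cohort, or a list
#'   of one per subject.
#' @param n_blocks,trials_per_block Session layout (default 5 x 60).
#' @param seed Optional integer seed for the whole cohort.
#' @return List of class `bandit_cohort` with one element per subject:
#'   `id`, `structure`, `session`, `params`.
#' @export
simulate_bandit_cohort <- function(n_subjects, params = agent_params(),
                                   n_blocks = 5, trials_per_block = 60,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "agent_params"))
    params <- rep(list(params), n_subjects)
  stopifnot(length(params) == n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    st <- make_structure()
    sch <- simulate_session_schedule(n_blocks, trials_per_block)
    off <- make_offer_sequence(st, n_blocks, trials_per_block)
    sess <- simulate_bandit_agent(st, sch, off, params[[s]])
    list(id = sprintf("s%02d", s), structure = st, session = sess,
         params = params[[s]])
  })
  structure(subjects, class = "bandit_cohort")
}

#' Pool the transition records of a bandit cohort
#'
#' @param cohort A [simulate_bandit_cohort()] result.
#' @return Stacked [classify_transitions()] records with subject ids.
#' @export
cohort_transitions <- function(cohort) {
  stopifnot(inherits(cohort, "bandit_cohort"))
  do.call(rbind, lapply(cohort, function(su)
    classify_transitions(su$session, su$structure, subject = su$id)))
}

#' Simulate a cohort of perceptual-task subjects
#'
#' @param n_subjects Number of subjects.
#' @param obs A single [sdt_observer()] or a list of one per subject.
#' @param n_blocks,trials_per_block Session layout (default 8 x 25).
#' @param seed Optional integer seed.
#' @param ... Passed to [simulate_perceptual()] (staircase settings).
#' @return List of class `perceptual_cohort` of `perceptual_session`s.
#' @export
simulate_perceptual_cohort <- function(n_subjects, obs = sdt_observer(),
                                       n_blocks = 8, trials_per_block = 25,
                                       seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(obs, "sdt_observer")) obs <- rep(list(obs), n_subjects)
  stopifnot(length(obs) == n_subjects)
  structure(lapply(seq_len(n_subjects), function(s)
    simulate_perceptual(n_blocks, trials_per_block, obs[[s]], ...)),
    class = "perceptual_cohort")
}
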
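#' Default pipeline configuration
#'
#' A fully serializable (YAML/JSON) configuration for the end-to-end
#' pipeline. The `"study"` profile uses the study-scale settings (30
#' subjects, 5 x 60-trial bandit blocks, 8 x 25-trial perceptual blocks,
#' walk sd 0.03 in [0.2, 0.8], 3 MCMC chains x 12,000 draws with 2,000
#' warm-up, 1000 simulate-then-regress runs); the `"test"` profile scales
#' everything down for smoke runs.
#'
#' @param profile `"study"` or `"test"`.
#' @param seed Integer master seed.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(profile = c("study", "test"), seed = 1) {
  profile <- match.arg(profile)
  full <- profile == "study"
  structure(list(
    profile = profile, seed = seed,
    bandit = list(n_subjects = if (full) 30 else 4,
                  n_blocks = if (full) 5 else 2,
                  trials_per_block = if (full) 60 else 20,
                  sigma = 0.03, lo = 0.2, hi = 0.8,
                  agent = unclass(agent_params())),
    perceptual = list(n_subjects = if (full) 30 else 6,
                      n_blocks = if (full) 8 else 4,
                      trials_per_block = 25,
                      k = 0.027, meta_noise = 0,
                      start_level = 20, step = 1),
    metad = list(n_bins = 4,
                 chains = 3,
                 draws = if (full) 12000 else 2000,
                 warmup = if (full) 2000 else 500),
    rlfit = list(n_restarts = if (full) 10 else 3,
                 n_sims = if (full) 1000 else 20)),
    class = "run_config")
}

#' Load a configuration from a YAML (or JSON) file
#'
#' @param path File path; fields missing from the file keep their
#'   [default_config()] values.
#' @param profile Base profile for defaults.
#' @return A `run_config`.
#' @export
read_config <- function(path, profile = "study") {
  user <- yaml::read_yaml(path)
  cfg <- default_config(profile = user$profile %||% profile,
                        seed = user$seed %||% 1)
  for (sec in intersect(names(user), c("bandit", "perceptual", "metad", "rlfit")))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a synthetic cohort and write it out
#'
#' Writes per-subject bandit and perceptual session CSVs, the per-subject
#' task structures as JSON, and a provenance file with the full
#' configuration and seed.
#'
#' @param config A [default_config()] `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  b <- config$bandit
  agent <- do.call(agent_params, b$agent)
  cohort <- simulate_bandit_cohort(b$n_subjects, agent, b$n_blocks,
                                   b$trials_per_block)
  p <- config$perceptual
  pc <- simulate_perceptual_cohort(p$n_subjects,
                                   sdt_observer(p$k, p$meta_noise),
                                   p$n_blocks, p$trials_per_block,
                                   start_level = p$start_level, step = p$step)
  paths <- character(0)
  for (su in cohort) {
    f1 <- file.path(out_dir, sprintf("bandit_%s.csv", su$id))
    f2 <- file.path(out_dir, sprintf("structure_%s.json", su$id))
    write_session_csv(su$session, f1, seed = config$seed)
    write_structure_json(su$structure, f2)
    paths <- c(paths, f1, f2)
  }
  for (s in seq_along(pc)) {
    f <- file.path(out_dir, sprintf("perceptual_s%02d.csv", s))
    write_session_csv(pc[[s]], f, seed = config$seed)
    paths <- c(paths, f)
  }
  prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(list(config = unclass(config),
                            written = basename(paths)),
                       prov, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, prov))
}

#' Analyze simulated (or recorded) sessions
#'
#' Runs the metacognition pipeline on the perceptual sessions (quantile
#' binning, type-1 fits, hierarchical M-ratio posterior) and the signature
#' pipeline on the bandit sessions (transition classification, MF/MB
#' regressions, confidence interactions, hybrid-model fits), writing a
#' machine-readable results bundle. A failure in one stage is reported in
#' the bundle without aborting the others.
#'
#' @param config A `run_config`.
#' @param in_dir Directory produced by [run_simulate()].
#' @param out_file Path of the JSON results bundle.
#' @return Invisibly, the results list.
#' @export
run_analyze <- function(config = default_config(), in_dir, out_file) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  results <- list()

  pfiles <- sort(list.files(in_dir, "^perceptual_.*\\.csv$", full.names = TRUE))
  if (length(pfiles) >= 2) {
    results$metad <- tryCatch({
      sessions <- lapply(pfiles, read_session_csv)
      counts <- lapply(sessions, bin_confidence, K = config$metad$n_bins)
      post <- fit_hierarchical(counts,
        mcmc_control(chains = config$metad$chains, draws = config$metad$draws,
                     warmup = config$metad$warmup, seed = config$seed))
      g <- group_mratio(post)
      list(group_mratio_mean = mean(g),
           group_mratio_ci = as.numeric(stats::quantile(g, c(0.025, 0.975))),
           rhat_max = max(post$rhat, na.rm = TRUE),
           converged = post$converged,
           mean_d_prime = mean(post$d_prime),
           qsr = vapply(sessions, function(s) qsr(s$confidence, s$correct),
                        numeric(1)))
    }, error = function(e) list(error = conditionMessage(e)))
  }

  bfiles <- sort(list.files(in_dir, "^bandit_.*\\.csv$", full.names = TRUE))
  if (length(bfiles) >= 2) {
    results$signatures <- tryCatch({
      recs <- do.call(rbind, lapply(bfiles, function(f) {
        id <- sub("^bandit_(.*)\\.csv$", "\\1", basename(f))
        st <- read_structure_json(file.path(in_dir,
                                            sprintf("structure_%s.json", id)))
        classify_transitions(read_session_csv(f), st, subject = id)
      }))
      mf <- mf_regression(recs)
      mb <- mb_regression(recs)
      ci_mf <- confidence_interaction(recs, "MF")
      ci_mb <- confidence_interaction(recs, "MB")
      list(mf_fixed = mf$fixed, mb_fixed = mb$fixed,
           mf_interaction = ci_mf$fixed[ci_mf$fixed$term == "C:conf", ],
           mb_interaction = ci_mb$fixed[ci_mb$fixed$term == "C:conf", ])
    }, error = function(e) list(error = conditionMessage(e)))
    results$rlfit <- tryCatch({
      fits <- lapply(bfiles, function(f) {
        id <- sub("^bandit_(.*)\\.csv$", "\\1", basename(f))
        st <- read_structure_json(file.path(in_dir,
                                            sprintf("structure_%s.json", id)))
        fit_subject(read_session_csv(f), st,
                    n_restarts = config$rlfit$n_restarts)
      })
      list(params = do.call(rbind, lapply(fits, function(f)
             as.data.frame(unclass(f$params)[1:6]))),
           nll = vapply(fits, function(f) f$nll, numeric(1)))
    }, error = function(e) list(error = conditionMessage(e)))
  }

  jsonlite::write_json(results, out_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  failed <- any(vapply(results, function(r) !is.null(r$error), logical(1)))
  if (failed) warning("one or more analysis stages failed; see ", out_file)
  invisible(results)
}

#' Parameter-recovery and simulate-then-regress report
#'
#' Simulates a cohort with dispersed known parameters, refits each subject
#' by maximum likelihood, reports recovered-vs-true correlations, and runs
#' the simulate-then-regress procedure from the fitted parameters.
#'
#' @param config A `run_config`.
#' @param out_file Optional JSON report path.
#' @return The report list: `true`, `fitted`, `recovery_r` (per-parameter
#'   correlation), `sim_regress` summary.
#' @export
run_recover <- function(config = default_config(), out_file = NULL) {
  stopifnot(inherits(config, "run_config"))
  b <- config$bandit
  if (b$n_subjects < 2) stop("recovery needs at least 2 subjects")
  set.seed(config$seed)
  true <- replicate(b$n_subjects, draw_agent_params(), simplify = FALSE)
  cohort <- simulate_bandit_cohort(b$n_subjects, true, b$n_blocks,
                                   b$trials_per_block)
  fits <- lapply(cohort, function(su)
    fit_subject(su$session, su$structure, n_restarts = config$rlfit$n_restarts))
  pmat <- function(ps) do.call(rbind, lapply(ps, function(p)
    unlist(unclass(p)[c("alpha", "w_mf", "w_mb", "forget", "pr", "pz")])))
  tm <- pmat(true); fm <- pmat(lapply(fits, function(f) f$params))
  recovery_r <- vapply(colnames(tm), function(nm)
    stats::cor(tm[, nm], fm[, nm]), numeric(1))
  sr <- simulate_and_regress(fits, cohort[[1]]$structure,
                             n_sims = config$rlfit$n_sims,
                             n_blocks = b$n_blocks,
                             trials_per_block = b$trials_per_block)
  report <- list(true = as.data.frame(tm), fitted = as.data.frame(fm),
                 recovery_r = recovery_r,
                 sim_regress = sr$per_subject, n_failed = sr$n_failed)
  if (!is.null(out_file))
    jsonlite::write_json(report, out_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  report
}

# Dispersed but realistic agent parameters for recovery studies.
draw_agent_params <- function() {
  agent_params(alpha = stats::runif(1, 0.2, 0.8),
               w_mf = stats::runif(1, 0.5, 6),
               w_mb = stats::runif(1, 0.5, 6),
               forget = stats::runif(1, 0, 0.5),
               pr = stats::runif(1, -0.5, 1),
               pz = stats::runif(1, -0.5, 0.5))
}
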
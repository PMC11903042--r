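#' @importFrom lme4 glmer glmerControl VarCorr fixef ranef
NULL

# Fit a hierarchical logistic regression and package the result.
fit_hier_logit <- function(formula, data, total_term) {
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
  fit <- suppressMessages(lme4::glmer(formula, data = data,
                                      family = stats::binomial(), control = ctrl))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- length(msgs) == 0L
  sm <- summary(fit)$coefficients
  fixed <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4],
                      ci_lo = sm[, 1] - stats::qnorm(0.975) * sm[, 2],
                      ci_hi = sm[, 1] + stats::qnorm(0.975) * sm[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  random_sd <- stats::setNames(vc$sdcor[is.na(vc$var2)], vc$var1[is.na(vc$var2)])
  # total (fixed + empirical-Bayes random) effect per subject
  cf <- stats::coef(fit)$subject
  subject_total <- NULL
  if (!is.null(total_term) && total_term %in% colnames(cf)) {
    subject_total <- data.frame(subject = rownames(cf),
                                term = total_term,
                                total = cf[[total_term]],
                                row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(fixed = fixed, random_sd = random_sd,
                 subject_total = subject_total, converged = converged,
                 messages = msgs, model = fit),
            class = "hier_logit_fit")
}

#' @export
print.hier_logit_fit <- function(x, ...) {
  cat("Hierarchical logistic fit", if (!x$converged) "(NOT converged)", "\n")
  print(x$fixed, digits = 3)
  invisible(x)
}

#' Model-free signature regression
#'
#' On MF-type transitions, regresses the probability of repeating the
#' trial-n choice on the Common and Unique trial-n outcomes and their
#' interaction, with a per-subject random intercept and random Common
#' slope: `repeat ~ C * U + (1 + C | subject)`. A positive Common effect
#' (controlling for the Unique outcome) is the model-free signature: the
#' model-based system values both offered people equally after a common
#' reward.
#'
#' @param records Transition records from [classify_transitions()] (rows of
#'   other kinds are dropped) from at least 2 subjects.
#' @return A `hier_logit_fit`: fixed-effect table, random-effect sds, and
#'   per-subject total (fixed + random) Common effects.
#' @export
mf_regression <- function(records) {
  d <- records[records$kind == "MF", , drop = FALSE]
  check_records(d, "MF")
  fit_hier_logit(y ~ C * U + (1 + C | subject), d, total_term = "C")
}

#' Model-based signature regression
#'
#' On MB-type transitions, regresses the probability of generalizing (on
#' trial n+1 choosing the person who shares a vegetable with the now-absent
#' trial-n choice) on the Common outcome, the generating reward probability
#' of the common vegetable (standardized) and their interaction, with a
#' per-subject random intercept and random Common slope:
#' `generalize ~ C * prob_C + (1 + C | subject)`. A positive Common effect
#' after controlling for the generating probability is the model-based
#' signature.
#'
#' @inheritParams mf_regression
#' @return A `hier_logit_fit` with per-subject total Common effects.
#' @export
mb_regression <- function(records) {
  d <- records[records$kind == "MB", , drop = FALSE]
  check_records(d, "MB")
  psd <- stats::sd(d$prob_C)
  if (is.na(psd) || psd == 0) {
    warning("prob_C is constant; dropping the probability regressor")
    return(fit_hier_logit(y ~ C + (1 + C | subject), d, total_term = "C"))
  }
  d$prob_C <- (d$prob_C - mean(d$prob_C)) / psd
  fit_hier_logit(y ~ C * prob_C + (1 + C | subject), d, total_term = "C")
}

#' Confidence x signature interaction regression
#'
#' The meta-control analysis: does the previous trial's confidence modulate
#' the Common-outcome effect on repetition (MF) or generalization (MB)?
#' Fits `y ~ C * conf + (1 + C:conf | subject)` where `conf` is the
#' within-subject median-split code (+-0.5) or the standardized continuous
#' confidence. The per-subject total (fixed + random) interaction effect is
#' the subject's meta-control measure.
#'
#' @inheritParams mf_regression
#' @param system `"MF"` (repeat outcome) or `"MB"` (generalize outcome).
#' @param confidence_coding `"split"` (median split, default) or
#'   `"continuous"`.
#' @return A `hier_logit_fit` with per-subject total `C:conf` interaction
#'   effects.
#' @export
confidence_interaction <- function(records, system = c("MF", "MB"),
                                   confidence_coding = c("split", "continuous")) {
  system <- match.arg(system)
  confidence_coding <- match.arg(confidence_coding)
  d <- records[records$kind == system, , drop = FALSE]
  check_records(d, system)
  d$conf <- if (confidence_coding == "split") d$conf_hl else d$conf_cont
  fit_hier_logit(y ~ C * conf + (1 + C:conf | subject), d,
                 total_term = "C:conf")
}

check_records <- function(d, kind) {
  if (nrow(d) == 0) stop("no ", kind, "-type records")
  if (length(unique(d$subject)) < 2)
    stop(kind, " regression needs records from at least 2 subjects")
  invisible(TRUE)
}

#' Compare per-subject effects across conditions
#'
#' Contrasts each condition against a reference condition (the first factor
#' level) for a subject x condition table of effects, using a linear
#' mixed-effects model with a random subject intercept, a paired Wilcoxon
#' signed-rank test, or an unpaired rank-sum test.
#'
#' @param effects Data frame with columns `subject`, `condition`, `effect`;
#'   every subject must appear in every condition.
#' @param test `"mixed-linear"` (default), `"signed-rank"`, or
#'   `"rank-sum"`.
#' @param reference Reference condition (default: first level).
#' @return Data frame, one row per non-reference condition: `contrast`,
#'   `estimate`, `ci_lo`, `ci_hi` (mixed-linear only), `statistic`, `p`.
#' @export
compare_conditions <- function(effects,
                               test = c("mixed-linear", "signed-rank", "rank-sum"),
                               reference = NULL) {
  test <- match.arg(test)
  stopifnot(all(c("subject", "condition", "effect") %in% names(effects)))
  tab <- table(effects$subject, effects$condition)
  if (any(tab != 1))
    stop("missing or duplicated subject x condition cells: ",
         paste(rownames(tab)[rowSums(tab != 1) > 0], collapse = ", "))
  effects$condition <- factor(effects$condition)
  if (!is.null(reference))
    effects$condition <- stats::relevel(effects$condition, ref = reference)
  lev <- levels(effects$condition)
  ref <- lev[1]

  if (test == "mixed-linear") {
    fit <- lmerTest::lmer(effect ~ condition + (1 | subject), data = effects)
    sm <- summary(fit)$coefficients
    rows <- grep("^condition", rownames(sm), value = TRUE)
    out <- data.frame(
      contrast = paste(sub("^condition", "", rows), "vs", ref),
      estimate = sm[rows, "Estimate"],
      ci_lo = sm[rows, "Estimate"] - stats::qnorm(0.975) * sm[rows, "Std. Error"],
      ci_hi = sm[rows, "Estimate"] + stats::qnorm(0.975) * sm[rows, "Std. Error"],
      statistic = sm[rows, "t value"],
      p = sm[rows, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE)
    return(out)
  }
  paired <- test == "signed-rank"
  x_ref <- effects$effect[effects$condition == ref][
    order(effects$subject[effects$condition == ref])]
  out <- lapply(lev[-1], function(l) {
    x <- effects$effect[effects$condition == l][
      order(effects$subject[effects$condition == l])]
    w <- suppressWarnings(stats::wilcox.test(x, x_ref, paired = paired,
                                             exact = FALSE))
    data.frame(contrast = paste(l, "vs", ref),
               estimate = stats::median(x - x_ref),
               ci_lo = NA_real_, ci_hi = NA_real_,
               statistic = unname(w$statistic), p = w$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
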
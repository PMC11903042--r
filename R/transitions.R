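#' Median-split coding of confidence
#'
#' Codes values strictly above the (per-subject) median as +0.5 and the
#' rest as -0.5, the dichotomous confidence regressor of the one-trial-back
#' interaction analyses. Ties at the median go to -0.5.
#'
#' @param x Per-trial values.
#' @param subject Optional per-trial subject ids; the median is computed
#'   within subject.
#' @return Numeric vector of +0.5 / -0.5 codes.
#' @export
median_split <- function(x, subject = NULL) {
  stopifnot(length(x) > 0)
  split_one <- function(v) {
    if (length(unique(v)) == 1L)
      warning("constant values: median split is degenerate (all -0.5)")
    ifelse(v > stats::median(v), 0.5, -0.5)
  }
  if (is.null(subject)) return(split_one(x))
  stopifnot(length(subject) == length(x))
  out <- numeric(length(x))
  for (s in unique(subject)) {
    i <- subject == s
    out[i] <- split_one(x[i])
  }
  out
}

#' Classify one-trial-back transitions of a bandit session
#'
#' Splits consecutive within-block trial pairs into the two signature
#' types. A transition is MF-type when trial n+1 re-offers the person
#' chosen on trial n (outcome measure: repeating that choice), and MB-type
#' when it does not, in which case exactly one offered person shares a
#' vegetable with the trial-n chosen person (outcome measure: generalizing
#' to that neighbor). In both cases C is the vegetable the trial-n chosen
#' person shares with the comparison person and U is their other vegetable;
#' rewards are the trial-n outcomes coded +-0.5.
#'
#' @param session A `bandit_session` from [simulate_bandit_agent()].
#' @param structure The `task_structure` the session was played on.
#' @param subject Subject identifier attached to every record.
#' @return A data frame of transition records: `subject`, `kind`
#'   (`"MF"`/`"MB"`), `y` (repeat or generalize, 0/1), `C`, `U` (coded
#'   +-0.5), `prob_C` (generating reward probability of the common
#'   vegetable at trial n; used by the MB regression), `conf_prev` (raw
#'   trial-n confidence), `conf_hl` (+-0.5 within-subject median split),
#'   `conf_cont` (within-subject standardized confidence).
#' @export
classify_transitions <- function(session, structure, subject = "s1") {
  stopifnot(inherits(structure, "task_structure"))
  persons <- structure$persons
  if (!all(session$choice %in% persons) ||
      !all(session$left %in% persons) || !all(session$right %in% persons))
    stop("session contains persons unknown to the structure")
  n <- nrow(session)
  recs <- vector("list", n - 1L)
  conf_hl <- median_split(session$confidence)
  conf_sd <- stats::sd(session$confidence)
  conf_cont <- if (is.na(conf_sd) || conf_sd == 0) rep(0, n) else
    (session$confidence - mean(session$confidence)) / conf_sd
  for (t in seq_len(n - 1L)) {
    if (session$block[t] != session$block[t + 1L]) next  # values reset
    chosen <- session$choice[t]
    off <- c(session$left[t + 1L], session$right[t + 1L])
    if (chosen %in% off) {
      kind <- "MF"
      other <- off[off != chosen]
      y <- as.integer(session$choice[t + 1L] == chosen)
    } else {
      kind <- "MB"
      sh <- !is.na(vapply(off, function(p) shared_vegetable(structure, chosen, p),
                          character(1)))
      if (sum(sh) != 1L)
        stop("offer does not share exactly one person with the previous choice")
      other <- off[sh]
      y <- as.integer(session$choice[t + 1L] == other)
    }
    veg_c <- shared_vegetable(structure, chosen, other)
    veg_u <- setdiff(structure$grows[chosen, ], veg_c)
    r_c <- if (session$veg1[t] == veg_c) session$out1[t] else session$out2[t]
    r_u <- if (session$veg1[t] == veg_u) session$out1[t] else session$out2[t]
    recs[[t]] <- data.frame(
      subject = subject, kind = kind, y = y,
      C = r_c - 0.5, U = r_u - 0.5,
      prob_C = session[[paste0("prob_", veg_c)]][t],
      conf_prev = session$confidence[t],
      conf_hl = conf_hl[t], conf_cont = conf_cont[t],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
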
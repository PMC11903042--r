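#' Write a session table as CSV with a provenance header
#'
#' One row per trial; the first line is a `#`-prefixed comment recording
#' the generator and seed so a file can be traced back to its
#' configuration.
#'
#' @param session A `bandit_session` or `perceptual_session` data frame.
#' @param path Output file.
#' @param seed Seed recorded in the provenance line (optional).
#' @export
write_session_csv <- function(session, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metacontrol %s generated %s seed=%s",
                     class(session)[1], format(Sys.time(), "%Y-%m-%d"),
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.csv(session, con, row.names = FALSE)
  invisible(path)
}

#' Read a session CSV written by [write_session_csv()]
#'
#' @param path Input file.
#' @return The session data frame (class restored from the provenance
#'   line when present).
#' @export
read_session_csv <- function(path) {
  first <- readLines(path, n = 1)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cls <- regmatches(first, regexpr("(bandit|perceptual)_session", first))
  if (length(cls) == 1) class(d) <- c(cls, "data.frame")
  d
}

#' Write a reward schedule as trial x vegetable CSV
#'
#' @param schedule A `reward_schedule`.
#' @param path Output file.
#' @export
write_schedule_csv <- function(schedule, path) {
  d <- data.frame(trial = seq_len(nrow(schedule$probs)), schedule$probs)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a task structure as JSON
#'
#' @param structure A `task_structure`.
#' @param path Output file.
#' @export
write_structure_json <- function(structure, path) {
  grows <- stats::setNames(lapply(seq_len(4), function(i)
    unname(structure$grows[i, ])), structure$persons)
  jsonlite::write_json(list(persons = structure$persons,
                            vegetables = structure$vegetables,
                            grows = grows),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a task structure from JSON
#'
#' @param path Input file.
#' @return A `task_structure`.
#' @export
read_structure_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  grows <- do.call(rbind, j$grows[j$persons])
  dimnames(grows) <- list(j$persons, c("veg1", "veg2"))
  inc <- matrix(FALSE, 4, 4, dimnames = list(j$persons, j$vegetables))
  for (p in j$persons) inc[p, grows[p, ]] <- TRUE
  out <- structure(list(persons = j$persons, vegetables = j$vegetables,
                        grows = grows, incidence = inc),
                   class = "task_structure")
  if (!is_valid_structure(out)) stop("invalid structure in ", path)
  out
}

#' Export posterior draws in tidy long format
#'
#' @param post A [fit_hierarchical()] `meta_posterior`.
#' @param path Output CSV (columns `chain`, `draw`, `parameter`, `value`).
#' @export
write_posterior_csv <- function(post, path) {
  stopifnot(inherits(post, "meta_posterior"))
  rows <- lapply(seq_along(post$samples), function(ch) {
    m <- as.matrix(post$samples[[ch]])
    data.frame(chain = ch, draw = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.numeric(m), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
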
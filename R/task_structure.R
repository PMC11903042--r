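#' Task structure of the two-outcome bandit
#'
#' Four people each grow a unique unordered pair out of four vegetables, and
#' each vegetable is grown by exactly two people. These constraints force the
#' person-vegetable incidence graph to be a single 8-cycle, so that exactly
#' four unordered person pairs share exactly one vegetable (the "common
#' pairs" offered on every trial) and the remaining two pairs share none.
#'
#' @param seed Integer seed; the mapping is randomized per participant.
#' @param persons,vegetables Character vectors of length 4 giving labels.
#'
#' @return An object of class `task_structure`: a list with elements
#'   `persons`, `vegetables`, `grows` (4 x 2 character matrix, one row per
#'   person), and `incidence` (4 x 4 logical matrix, persons x vegetables).
#' @examples
#' st <- make_structure(seed = 1)
#' common_pairs(st)
#' @export
make_structure <- function(seed = NULL,
                           persons = paste0("P", 1:4),
                           vegetables = c("garlic", "lettuce", "onion", "carrot")) {
  stopifnot(length(persons) == 4, length(vegetables) == 4,
            !anyDuplicated(persons), !anyDuplicated(vegetables))
  if (!is.null(seed)) set.seed(seed)
  # Random alternating 8-cycle: person at cycle position i grows the
  # vegetables at positions i and i+1 (mod 4). Randomizing both orderings
  # reaches every valid labelled structure.
  pp <- sample.int(4)
  vv <- sample.int(4)
  grows_idx <- cbind(vv, vv[c(2:4, 1)])[order(pp), , drop = FALSE]
  grows <- matrix(vegetables[grows_idx], ncol = 2,
                  dimnames = list(persons, c("veg1", "veg2")))
  incidence <- matrix(FALSE, 4, 4, dimnames = list(persons, vegetables))
  for (i in 1:4) incidence[i, grows[i, ]] <- TRUE
  structure(list(persons = persons, vegetables = vegetables,
                 grows = grows, incidence = incidence),
            class = "task_structure")
}

#' Validate the invariants of a task structure
#'
#' @param x A candidate `task_structure` (or a list with an `incidence`
#'   matrix).
#' @return `TRUE` if every invariant holds, else `FALSE`.
#' @export
is_valid_structure <- function(x) {
  inc <- x$incidence
  if (is.null(inc) || !all(dim(inc) == c(4, 4))) return(FALSE)
  if (!all(rowSums(inc) == 2)) return(FALSE)          # each person: 2 vegetables
  if (!all(colSums(inc) == 2)) return(FALSE)          # each vegetable: 2 growers
  pair_key <- apply(inc, 1, function(r) paste(which(r), collapse = "-"))
  if (anyDuplicated(pair_key)) return(FALSE)          # pairs are unique
  shared <- tcrossprod(inc * 1L)
  diag(shared) <- 0L
  n_common <- sum(shared[upper.tri(shared)] == 1L)
  n_common == 4L && all(shared[upper.tri(shared)] %in% c(0L, 1L))
}

#' Person pairs sharing exactly one vegetable
#'
#' @param structure A `task_structure`.
#' @return A data frame with columns `person_a`, `person_b`, `common`
#'   (the shared vegetable), one row per common pair (always 4 rows).
#' @export
common_pairs <- function(structure) {
  stopifnot(inherits(structure, "task_structure"))
  inc <- structure$incidence
  out <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    shared <- which(inc[i, ] & inc[j, ])
    if (length(shared) == 1L) {
      out[[length(out) + 1L]] <- data.frame(
        person_a = structure$persons[i], person_b = structure$persons[j],
        common = structure$vegetables[shared], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Vegetable shared by two persons
#'
#' @param structure A `task_structure`.
#' @param a,b Person labels.
#' @return The shared vegetable label, or `NA_character_` if they share none.
#' @export
shared_vegetable <- function(structure, a, b) {
  inc <- structure$incidence
  shared <- which(inc[a, ] & inc[b, ])
  if (length(shared) == 1L) structure$vegetables[shared] else NA_character_
}

#' Enumerate all valid labelled task structures
#'
#' Brute-force enumeration over all 6^4 assignments of vegetable pairs to
#' persons, filtered by the structure invariants. Used as an independent
#' check that the generator's support is exactly the valid set.
#'
#' @param persons,vegetables Labels as in [make_structure()].
#' @return A list of `task_structure` objects (one per valid assignment).
#' @export
enumerate_structures <- function(persons = paste0("P", 1:4),
                                 vegetables = c("garlic", "lettuce", "onion", "carrot")) {
  pairs <- utils::combn(4, 2)  # 6 unordered vegetable pairs
  out <- list()
  for (a in 1:6) for (b in 1:6) for (d in 1:6) for (e in 1:6) {
    idx <- cbind(pairs[, a], pairs[, b], pairs[, d], pairs[, e])
    inc <- matrix(FALSE, 4, 4, dimnames = list(persons, vegetables))
    for (i in 1:4) inc[i, idx[, i]] <- TRUE
    cand <- structure(list(persons = persons, vegetables = vegetables,
                           grows = matrix(vegetables[t(idx)], ncol = 2,
                                          dimnames = list(persons, c("veg1", "veg2"))),
                           incidence = inc),
                      class = "task_structure")
    if (is_valid_structure(cand)) out[[length(out) + 1L]] <- cand
  }
  out
}

#' @export
print.task_structure <- function(x, ...) {
  cat("Two-outcome task structure (4 persons x 4 vegetables, 8-cycle)\n")
  for (p in x$persons)
    cat(sprintf("  %s grows %s + %s\n", p, x$grows[p, 1], x$grows[p, 2]))
  invisible(x)
}
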
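#' Shift tallies
#'
#' A tally counts the exclusive presence categories of a set of shifts for
#' one cadre. Categories never overlap, and their counts sum to at most
#' `n_shifts`; any slack is made up of neutral shifts (provider off site,
#' no emergency call arose) that count in the denominator but in no scored
#' category.
#'
#' `doctor_tally()` holds the four scored doctor-style categories:
#' `a` shifts with a provider on site more than half the shift, `b` on site
#' less than half, `c` off site but responded to an emergency call, `d` an
#' emergency call unanswered.
#'
#' `graded_tally()` holds headcount categories relative to a minimum
#' requirement: `at_min` shifts at or above the minimum (top-coded), `below`
#' a vector of counts for shifts with exactly `1 .. min_required - 1`
#' providers (element `k` is the count of shifts with exactly `k` on site),
#' `absent` shifts scored as total absence, and for on-call cadres
#' `oncall_at_min` / `oncall_below` mirroring the on-site categories for
#' providers who arrived on emergency call.
#'
#' `support_tally()` is the pooled-support special case: minimum 2, so
#' `s2` shifts with at least two support staff, `s1` with exactly one and
#' `s0` with none.
#'
#' @param a,b,c,d Doctor-style category counts.
#' @param n_shifts Total observed shifts `N`; defaults to the category sum.
#' @return A tally object (class `doctor_tally`, `graded_tally` or
#'   `support_tally` + `graded_tally`).
#' @seealso [doctor_index()], [build_tally()]
#' @export
#' @examples
#' doctor_tally(a = 27, c = 2, n_shifts = 30)
#' graded_tally(at_min = 29, below = c(`1` = 0, `2` = 1), min_required = 3)
#' support_tally(s2 = 24, s1 = 6)
doctor_tally <- function(a = 0, b = 0, c = 0, d = 0,
                         n_shifts = a + b + c + d) {
  counts <- c(a = a, b = b, c = c, d = d)
  check_tally_counts(counts, n_shifts)
  structure(list(a = a, b = b, c = c, d = d, n_shifts = n_shifts),
            class = "doctor_tally")
}

#' @rdname doctor_tally
#' @param at_min Shifts with headcount at or above `min_required`.
#' @param below Integer vector of shifts with exactly `k` providers for
#'   `k = 1 .. min_required - 1`; element names (or positions) give `k`.
#' @param absent Shifts counted as total absence (the penalty category).
#' @param oncall_at_min,oncall_below On-call mirrors of `at_min` / `below`.
#' @param min_required Minimum headcount defining the top category.
#' @export
graded_tally <- function(at_min = 0, below = integer(), absent = 0,
                         oncall_at_min = 0, oncall_below = integer(),
                         min_required = 3,
                         n_shifts = NULL) {
  min_required <- as.integer(min_required)
  if (min_required < 1) abort("min_required must be positive",
                              class = "emoncavail_bad_tally")
  below <- normalize_below(below, min_required)
  oncall_below <- normalize_below(oncall_below, min_required)
  counts <- c(at_min, below, absent, oncall_at_min, oncall_below)
  if (is.null(n_shifts)) n_shifts <- sum(counts)
  check_tally_counts(counts, n_shifts)
  structure(
    list(at_min = at_min, below = below, absent = absent,
         oncall_at_min = oncall_at_min, oncall_below = oncall_below,
         min_required = min_required, n_shifts = n_shifts),
    class = "graded_tally"
  )
}

#' @rdname doctor_tally
#' @param s2,s1,s0 Support-pool category counts (at least two / exactly one /
#'   none present).
#' @export
support_tally <- function(s2 = 0, s1 = 0, s0 = 0, n_shifts = s2 + s1 + s0) {
  out <- graded_tally(at_min = s2, below = c(`1` = s1), absent = s0,
                      min_required = 2, n_shifts = n_shifts)
  class(out) <- c("support_tally", class(out))
  out
}

normalize_below <- function(below, min_required) {
  full <- integer(max(min_required - 1L, 0L))
  if (min_required > 1) names(full) <- as.character(seq_len(min_required - 1L))
  if (length(below) == 0) return(full)
  if (is.null(names(below))) {
    if (length(below) > length(full)) {
      abort("below has more categories than min_required - 1",
            class = "emoncavail_bad_tally")
    }
    full[seq_along(below)] <- as.integer(below)
    return(full)
  }
  bad <- setdiff(names(below), names(full))
  if (length(bad) > 0) {
    abort(sprintf("below counts named for headcounts outside 1..%d: %s",
                  min_required - 1L, paste(bad, collapse = ", ")),
          class = "emoncavail_bad_tally")
  }
  full[names(below)] <- as.integer(below)
  full
}

check_tally_counts <- function(counts, n_shifts) {
  if (any(counts < 0) || n_shifts < 0) {
    abort("tally counts must be non-negative",
          class = "emoncavail_bad_tally")
  }
  if (sum(counts) > n_shifts) {
    abort(sprintf("category counts (%d) exceed n_shifts (%d)",
                  sum(counts), n_shifts),
          class = "emoncavail_bad_tally")
  }
  invisible(TRUE)
}

#' @export
print.doctor_tally <- function(x, ...) {
  cat(sprintf(
    "<doctor_tally> a=%d b=%d c=%d d=%d (neutral=%d) N=%d\n",
    x$a, x$b, x$c, x$d, x$n_shifts - x$a - x$b - x$c - x$d, x$n_shifts))
  invisible(x)
}

#' @export
print.graded_tally <- function(x, ...) {
  below <- paste(sprintf("%s:%d", names(x$below), x$below), collapse = " ")
  cat(sprintf(
    "<graded_tally> min=%d  >=min:%d %s absent:%d oncall>=min:%d N=%d\n",
    x$min_required, x$at_min, below, x$absent, x$oncall_at_min, x$n_shifts))
  invisible(x)
}
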
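#' Availability index formulas
#'
#' Each index maps a tally of exclusive shift categories to a percentage on
#' the \[-100, 100\] scale: full presence scores +1, partial presence a
#' fraction, total absence in the face of an emergency call -1, and neutral
#' shifts 0; the index is the mean per-shift score times 100. All arithmetic
#' is kept at full precision — rounding happens only at presentation time
#' (see [format_index_report()]), because chained rounding distorts day
#' averages.
#'
#' * `doctor_index()`: `(a + b/2 + c - d) / N * 100`.
#' * `graded_index_morning()`: ward nurses/FWVs against a morning minimum of
#'   three, `(m3 + 2 m2/3 + m1/3 - m0) / N * 100` — a short-staffed shift
#'   earns credit in proportion to the fraction of the minimum present.
#' * `graded_index_offpeak()`: evening/night minimum of two,
#'   `(m2 + m1/2 - m0) / N * 100`.
#' * `ot_index()`: operating-theatre nurses, minimum two in every shift, with
#'   on-call arrivals credited like on-site presence:
#'   `(m2 + m1/2 + m2a + m1a/2 - m0) / N * 100`.
#' * `support_index()`: pooled support staff, minimum two,
#'   `(s2 + s1/2 - s0) / N * 100`.
#' * `availability_index()`: dispatches on the tally to the matching formula
#'   (the generic used by [index_report()]).
#'
#' An empty tally (`N = 0`) has no defined index and raises an
#' `emoncavail_undefined_index` error; it is never silently reported as 0.
#'
#' @param t A tally from [doctor_tally()], [graded_tally()] or
#'   [support_tally()].
#' @return A single numeric index value in percent, full precision. Negative
#'   values are possible when penalty categories dominate.
#' @export
#' @examples
#' doctor_index(doctor_tally(a = 10, b = 10, c = 5, d = 5))        # 50
#' graded_index_morning(
#'   graded_tally(at_min = 29, below = c(`1` = 0, `2` = 1),
#'                min_required = 3))                               # 98.888...
#' support_index(support_tally(s2 = 24, s1 = 6))                   # 90
doctor_index <- function(t) {
  stopifnot(inherits(t, "doctor_tally"))
  check_defined(t)
  (t$a + t$b / 2 + t$c - t$d) / t$n_shifts * 100
}

#' @rdname doctor_index
#' @export
graded_index_morning <- function(t) {
  stopifnot(inherits(t, "graded_tally"))
  check_defined(t)
  if (t$min_required != 3) {
    abort("morning ward formula requires a minimum of 3",
          class = "emoncavail_bad_tally")
  }
  (t$at_min + 2 * t$below[["2"]] / 3 + t$below[["1"]] / 3 - t$absent) /
    t$n_shifts * 100
}

#' @rdname doctor_index
#' @export
graded_index_offpeak <- function(t) {
  stopifnot(inherits(t, "graded_tally"))
  check_defined(t)
  if (t$min_required != 2) {
    abort("off-peak formula requires a minimum of 2",
          class = "emoncavail_bad_tally")
  }
  (t$at_min + t$below[["1"]] / 2 - t$absent) / t$n_shifts * 100
}

#' @rdname doctor_index
#' @export
ot_index <- function(t) {
  stopifnot(inherits(t, "graded_tally"))
  check_defined(t)
  if (t$min_required != 2) {
    abort("operating-theatre formula requires a minimum of 2",
          class = "emoncavail_bad_tally")
  }
  (t$at_min + t$below[["1"]] / 2 +
      t$oncall_at_min + t$oncall_below[["1"]] / 2 - t$absent) /
    t$n_shifts * 100
}

#' @rdname doctor_index
#' @export
support_index <- function(t) {
  stopifnot(inherits(t, "graded_tally"))
  graded_index_offpeak(t)
}

#' @rdname doctor_index
#' @export
availability_index <- function(t) {
  if (inherits(t, "doctor_tally")) return(doctor_index(t))
  if (inherits(t, "support_tally")) return(support_index(t))
  if (inherits(t, "graded_tally")) {
    has_oncall <- t$oncall_at_min > 0 || any(t$oncall_below > 0)
    if (t$min_required == 3 && !has_oncall) return(graded_index_morning(t))
    if (t$min_required == 2) {
      if (has_oncall) return(ot_index(t))
      return(graded_index_offpeak(t))
    }
    # general weighted form for non-study minimums
    check_defined(t)
    k <- seq_len(t$min_required - 1)
    return((t$at_min + sum(k * t$below / t$min_required) +
              t$oncall_at_min + sum(k * t$oncall_below / t$min_required) -
              t$absent) / t$n_shifts * 100)
  }
  abort("not a tally object", class = "emoncavail_bad_tally")
}

check_defined <- function(t) {
  if (is.null(t$n_shifts) || t$n_shifts == 0) {
    abort("index undefined: tally covers zero shifts",
          class = "emoncavail_undefined_index")
  }
  invisible(TRUE)
}

#' Day average of the three per-shift indices
#'
#' The unweighted arithmetic mean of the morning, evening and night index
#' values at full precision. Shift lengths are deliberately not weighted.
#' Any undefined (`NA`) input makes the average undefined and raises an
#' error.
#'
#' @param morning,evening,night Per-shift index values in percent.
#' @return The mean of the three values.
#' @export
#' @examples
#' day_average(83.3, 21.7, 16.7)  # 40.566...
day_average <- function(morning, evening, night) {
  vals <- c(morning, evening, night)
  if (length(vals) != 3 || anyNA(vals)) {
    abort("day average undefined: needs three defined shift indices",
          class = "emoncavail_undefined_index")
  }
  mean(vals)
}

#' Round half away from zero
#'
#' Presentation rounding used throughout reports: ties go away from zero
#' (98.85 -> 98.9, -0.05 -> -0.1), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
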
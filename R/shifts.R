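#' Duty shifts and provider cadre modes
#'
#' Facilities run three daily duty shifts: morning (8 AM-2 PM, 6 h), evening
#' (2 PM-9 PM, 7 h) and night (9 PM-8 AM, 11 h). All index arithmetic weights
#' the three shifts equally despite their unequal lengths; the nominal hours
#' are carried as metadata only.
#'
#' @return `shift_labels()` returns the three shift labels in day order.
#'   `shift_hours()` returns a named numeric vector of nominal shift durations
#'   in hours.
#' @export
#' @examples
#' shift_labels()
#' shift_hours()
shift_labels <- function() c("morning", "evening", "night")

#' @rdname shift_labels
#' @export
shift_hours <- function() c(morning = 6, evening = 7, night = 11)

#' Presence-payload modes for provider cadres
#'
#' Each cadre is observed in one of four modes, which determines the payload a
#' shift observation must carry:
#'
#' * `doctor_style` — a single exclusive classification of the shift
#'   (see [doctor_classifications()]). Used for consultants, medical officers,
#'   anesthetists, and also for medical technologists and assistant nursing
#'   attendants, which are scored with the same algorithm as doctors.
#' * `graded_headcount` — a headcount of providers on site (ward nurses, FWVs).
#' * `graded_headcount_with_oncall` — a headcount plus a count of providers who
#'   arrived in response to an emergency call (operating-theatre nurses).
#' * `support_pool` — a pooled headcount across the support categories
#'   (peon/ward boy/aya/sweeper/guard).
#'
#' @return Character vector of mode names.
#' @export
cadre_modes <- function() {
  c("doctor_style", "graded_headcount", "graded_headcount_with_oncall",
    "support_pool")
}

#' Exclusive shift classifications for doctor-style cadres
#'
#' A doctor-style shift is classified into exactly one of five states:
#'
#' * `present_majority` — at least one provider on site for more than 50% of
#'   the shift (full credit, +1).
#' * `present_minority` — on site for less than 50% of the shift (+1/2).
#' * `offsite_responded` — off site but came to the facility in response to an
#'   emergency call (+1; arrival delay is not discounted).
#' * `offsite_no_response` — an emergency call went unanswered (-1).
#' * `offsite_no_call` — off site and no emergency call arose; the shift
#'   carries no information about responsiveness and scores 0 while still
#'   counting in the denominator.
#'
#' @return Character vector of classification labels.
#' @export
doctor_classifications <- function() {
  c("present_majority", "present_minority", "offsite_responded",
    "offsite_no_response", "offsite_no_call")
}

headcount_modes <- function() {
  c("graded_headcount", "graded_headcount_with_oncall", "support_pool")
}
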
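#' Classify one observed shift into its exclusive presence category
#'
#' Every observed shift falls into exactly one category (the partition that
#' tallies and distribution tables are built from):
#'
#' * doctor-style rows keep their classification label (see
#'   [doctor_classifications()]);
#' * headcount rows with `n_present >= min_required` are top-coded `"ge_min"`;
#' * headcounts between 1 and `min_required - 1` become the exact-count
#'   category `"1"`, `"2"`, ...;
#' * a zero headcount is `"absent"` for plain ward/support cadres (staff are
#'   rostered on site, so absence is a straight penalty), while for on-call
#'   cadres the on-call response is classified instead: `"oncall_ge_min"` /
#'   `"oncall_1"` ... when providers arrived on emergency call, and the
#'   neutral `"none"` when nobody was on site and no call response was
#'   recorded (scored 0 but counted in the denominator).
#'
#' A headcount at the minimum is always the top category (`>=` semantics).
#'
#' @param mode Cadre payload mode (see [cadre_modes()]).
#' @param min_required Minimum headcount for the shift.
#' @param classification Doctor-style classification label (doctor rows).
#' @param n_present,n_oncall_responded Headcounts (headcount rows).
#' @return A single category label.
#' @export
#' @examples
#' classify_shift("graded_headcount", 3, n_present = 3)   # "ge_min"
#' classify_shift("graded_headcount", 3, n_present = 2)   # "2"
#' classify_shift("graded_headcount_with_oncall", 2,
#'                n_present = 0, n_oncall_responded = 1)  # "oncall_1"
classify_shift <- function(mode, min_required, classification = NA,
                           n_present = NA, n_oncall_responded = NA) {
  if (mode == "doctor_style") {
    if (!classification %in% doctor_classifications()) {
      abort(sprintf("unknown doctor classification '%s'", classification),
            class = "emoncavail_payload_mismatch")
    }
    return(classification)
  }
  n <- as.integer(n_present)
  if (is.na(n) || n < 0) {
    abort("headcount cadre observation needs a non-negative n_present",
          class = "emoncavail_payload_mismatch")
  }
  if (n >= min_required) return("ge_min")
  if (n > 0) return(as.character(n))
  if (mode == "graded_headcount_with_oncall") {
    k <- as.integer(n_oncall_responded)
    if (is.na(k)) k <- 0L
    if (k >= min_required) return("oncall_ge_min")
    if (k > 0) return(paste0("oncall_", k))
    return("none")
  }
  "absent"
}

classify_rows <- function(rows, standards) {
  vapply(seq_len(nrow(rows)), function(i) {
    min_req <- lookup_min_required(standards, rows$department[[i]],
                                   rows$cadre[[i]], rows$shift[[i]],
                                   rows$mode[[i]])
    classify_shift(rows$mode[[i]], min_req,
                   classification = rows$classification[[i]],
                   n_present = rows$n_present[[i]],
                   n_oncall_responded = rows$n_oncall_responded[[i]])
  }, character(1))
}

#' Build a tally for one facility/department/cadre/shift cell
#'
#' Filters the records to the requested cell, classifies every observed
#' shift with [classify_shift()] and counts the categories. `N` is the
#' number of observed shifts in the selection: shifts with no observation
#' are simply absent from the denominator rather than imputed.
#'
#' @param records Validated observation tibble.
#' @param facility,department,cadre Cell identifiers.
#' @param shift A shift label, or several that share the same minimum
#'   requirement (doctor-style cadres may always be pooled across shifts).
#' @param standards Staffing standards tibble (default
#'   [default_standards()]).
#' @return A [doctor_tally()], [graded_tally()] or [support_tally()].
#' @export
build_tally <- function(records, facility, department, cadre, shift,
                        standards = default_standards()) {
  rows <- records[records$facility == facility &
                    records$department == department &
                    records$cadre == cadre &
                    records$shift %in% shift, ]
  if (nrow(rows) == 0) {
    abort(sprintf("no observations for %s/%s/%s in shift(s) %s",
                  facility, department, cadre, paste(shift, collapse = ",")),
          class = "emoncavail_undefined_tally")
  }
  mode <- unique(rows$mode)
  if (length(mode) != 1) {
    abort("mixed payload modes within one cadre selection",
          class = "emoncavail_payload_mismatch")
  }
  n_total <- nrow(rows)

  if (mode == "doctor_style") {
    cls <- classify_rows(rows, standards)
    return(doctor_tally(
      a = sum(cls == "present_majority"),
      b = sum(cls == "present_minority"),
      c = sum(cls == "offsite_responded"),
      d = sum(cls == "offsite_no_response"),
      n_shifts = n_total
    ))
  }

  mins <- vapply(unique(rows$shift), function(s)
    lookup_min_required(standards, department, cadre, s, mode), integer(1))
  if (length(unique(mins)) != 1) {
    abort("selected shifts have different minimum requirements; tally them separately",
          class = "emoncavail_bad_tally")
  }
  min_req <- mins[[1]]
  cls <- classify_rows(rows, standards)
  ks <- as.character(seq_len(min_req - 1))
  below <- setNames(vapply(ks, function(k) sum(cls == k), numeric(1)), ks)
  oncall_below <- setNames(
    vapply(ks, function(k) sum(cls == paste0("oncall_", k)), numeric(1)), ks)
  out <- graded_tally(
    at_min = sum(cls == "ge_min"), below = below,
    absent = sum(cls == "absent"),
    oncall_at_min = sum(cls == "oncall_ge_min"),
    oncall_below = oncall_below,
    min_required = min_req, n_shifts = n_total
  )
  if (mode == "support_pool" && min_req == 2) {
    class(out) <- c("support_tally", class(out))
  }
  out
}

category_grid <- function(mode, min_required) {
  if (mode == "doctor_style") return(doctor_classifications())
  below <- rev(as.character(seq_len(min_required - 1)))
  base <- c("ge_min", below, "absent")
  if (mode == "graded_headcount_with_oncall") {
    base <- c("ge_min", below,
              "oncall_ge_min", paste0("oncall_", rev(seq_len(min_required - 1))),
              "absent", "none")
  }
  base
}

#' Presence-distribution tables
#'
#' The percentage of observed shifts in each exclusive presence category,
#' per facility, department, cadre and shift — the tabular view that the
#' per-shift indices are computed from. Every category of the cadre's grid
#' is reported, including empty ones (0.0), and percentages are presented
#' rounded half-away-from-zero to one decimal, so each column sums to
#' 100 within rounding slack.
#'
#' @inheritParams build_tally
#' @return A tibble with columns `facility`, `department`, `cadre`, `shift`,
#'   `category`, `n`, `pct`.
#' @export
presence_distribution <- function(records, standards = default_standards()) {
  cells <- dplyr::distinct(records, .data$facility, .data$department,
                           .data$cadre, .data$mode, .data$shift)
  cells$shift <- factor(cells$shift, levels = shift_labels())
  cells <- dplyr::arrange(cells, .data$facility, .data$department,
                          .data$cadre, .data$shift)
  cells$shift <- as.character(cells$shift)
  out <- purrr::pmap(cells, function(facility, department, cadre, mode,
                                     shift) {
    rows <- records[records$facility == facility &
                      records$department == department &
                      records$cadre == cadre & records$shift == shift, ]
    min_req <- lookup_min_required(standards, department, cadre, shift, mode)
    cls <- classify_rows(rows, standards)
    grid <- category_grid(mode, min_req)
    n <- vapply(grid, function(g) sum(cls == g), numeric(1))
    tibble::tibble(
      facility = facility, department = department, cadre = cadre,
      shift = shift, category = grid, n = as.integer(n),
      pct = round_half_up(n / nrow(rows) * 100, 1)
    )
  })
  dplyr::bind_rows(out)
}

#' Per-shift availability index matrix with day averages
#'
#' Runs the full tabulation pipeline for every (facility, department, cadre)
#' in the records: per shift, [build_tally()] then [availability_index()];
#' then the unweighted [day_average()] of the three shifts. Values are kept
#' at full precision — use [format_index_report()] for presentation. A cell
#' whose index is undefined (no observed shifts) is reported as `NA` with a
#' warning and leaves the other cells intact; its day average is also `NA`.
#'
#' @inheritParams build_tally
#' @return A tibble with columns `facility`, `department`, `cadre`,
#'   `morning`, `evening`, `night`, `day_average` (full-precision percent).
#' @export
index_report <- function(records, standards = default_standards()) {
  groups <- dplyr::distinct(records, .data$facility, .data$department,
                            .data$cadre)
  out <- purrr::pmap(groups, function(facility, department, cadre) {
    vals <- setNames(rep(NA_real_, 3), shift_labels())
    for (s in shift_labels()) {
      vals[[s]] <- tryCatch(
        availability_index(build_tally(records, facility, department, cadre,
                                       s, standards)),
        emoncavail_undefined_tally = function(e) {
          warn(sprintf("index undefined for %s/%s/%s %s: %s",
                       facility, department, cadre, s, conditionMessage(e)))
          NA_real_
        }
      )
    }
    avg <- if (anyNA(vals)) NA_real_ else day_average(vals[["morning"]],
                                                      vals[["evening"]],
                                                      vals[["night"]])
    tibble::tibble(facility = facility, department = department,
                   cadre = cadre,
                   morning = vals[["morning"]], evening = vals[["evening"]],
                   night = vals[["night"]], day_average = avg)
  })
  dplyr::bind_rows(out)
}

#' Format an index report for presentation
#'
#' Rounds the full-precision index columns half-away-from-zero to the
#' requested number of decimals; optionally clamps negative indices to 0
#' for audiences expecting a 0-100 scale (the raw, possibly negative value
#' is the faithful default).
#'
#' @param report Tibble from [index_report()].
#' @param decimals Decimal places (default 1).
#' @param clamp_negative Clamp negative values to 0 before rounding.
#' @return The report with rounded numeric index columns.
#' @export
format_index_report <- function(report, decimals = 1,
                                clamp_negative = FALSE) {
  cols <- c("morning", "evening", "night", "day_average")
  for (cl in cols) {
    v <- report[[cl]]
    if (clamp_negative) v <- pmax(v, 0)
    report[[cl]] <- round_half_up(v, decimals)
  }
  report
}

#' Collapse a two-pool support standard to a pooled headcount
#'
#' Some facilities split support staff into two sub-pools (e.g. peon/guard
#' vs sweeper/aya) and require at least one person from each. This helper
#' maps the two sub-pool headcounts to an effective pooled count for the
#' standard observation schema: both pools covered counts as fully staffed
#' (the combined headcount, necessarily >= 2); anyone present but a pool
#' uncovered counts as a single-provider shift; nobody present is 0.
#'
#' @param n_pool_a,n_pool_b Headcounts of the two sub-pools (vectorised).
#' @return Integer vector of effective pooled headcounts.
#' @export
#' @examples
#' classify_support_pools(1, 1)  # 2: both pools covered
#' classify_support_pools(3, 0)  # 1: second pool uncovered
classify_support_pools <- function(n_pool_a, n_pool_b) {
  both <- n_pool_a >= 1 & n_pool_b >= 1
  any_ <- n_pool_a + n_pool_b >= 1
  as.integer(ifelse(both, n_pool_a + n_pool_b, ifelse(any_, 1L, 0L)))
}
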
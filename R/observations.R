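#' Shift observation records
#'
#' Observations are long-format: one row per (facility, department, day,
#' shift, cadre). The exact column set is:
#'
#' * `facility`, `department`, `cadre` — identifiers.
#' * `date` — integer day index, 1-based and contiguous within an observation
#'   phase.
#' * `shift` — one of `morning`, `evening`, `night`.
#' * `mode` — the cadre's payload mode; see [cadre_modes()].
#' * `classification` — for `doctor_style` rows, one of
#'   [doctor_classifications()]; `NA` otherwise.
#' * `n_present` — for headcount rows, providers on site; `NA` for doctor
#'   rows.
#' * `n_oncall_responded` — providers who arrived on emergency call
#'   (`graded_headcount_with_oncall` rows); 0 or `NA` otherwise.
#' * `provenance` — `observed` or `interview` (night shifts are often
#'   reconstructed by interviewing the staff who worked them); treated
#'   identically in computation.
#'
#' @param ... Column values passed to [tibble::tibble()]; missing payload
#'   columns are filled with `NA`.
#' @return A tibble in the observation schema.
#' @export
observation_tbl <- function(...) {
  x <- tibble::tibble(...)
  defaults <- list(
    facility = NA_character_, department = NA_character_,
    date = NA_integer_, shift = NA_character_, cadre = NA_character_,
    mode = NA_character_, classification = NA_character_,
    n_present = NA_integer_, n_oncall_responded = NA_integer_,
    provenance = "observed"
  )
  for (col in names(defaults)) {
    if (!col %in% names(x)) x[[col]] <- defaults[[col]]
  }
  x[names(defaults)]
}

observation_cols <- function() {
  readr::cols(
    facility = readr::col_character(),
    department = readr::col_character(),
    date = readr::col_integer(),
    shift = readr::col_character(),
    cadre = readr::col_character(),
    mode = readr::col_character(),
    classification = readr::col_character(),
    n_present = readr::col_integer(),
    n_oncall_responded = readr::col_integer(),
    provenance = readr::col_character()
  )
}

#' Read and write observation CSV files
#'
#' @param path CSV path.
#' @return `read_observations()` returns an observation tibble;
#'   `write_observations()` returns `path` invisibly. Writing then reading a
#'   set of records reproduces it value-for-value.
#' @export
read_observations <- function(path) {
  x <- readr::read_csv(path, col_types = observation_cols())
  missing <- setdiff(names(observation_cols()$cols), names(x))
  if (length(missing) > 0) {
    abort(sprintf("observation file missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "emoncavail_bad_input")
  }
  if (nrow(x) == 0) {
    abort("no observations", class = "emoncavail_bad_input")
  }
  observation_tbl(!!!as.list(x))
}

#' @rdname read_observations
#' @param records Observation tibble.
#' @export
write_observations <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Validate shift observation records
#'
#' Checks structural integrity before tabulation:
#'
#' * duplicate (facility, department, date, shift, cadre) keys — hard error;
#' * payload/mode mismatches (a doctor-style row carrying a headcount, a
#'   headcount row carrying a classification, unknown shift/mode/
#'   classification labels, negative counts, simultaneous on-site and on-call
#'   headcounts) — hard error;
#' * day-index gaps within a (facility, department, cadre) series and
#'   implausibly large headcounts — recorded as warnings in the report.
#'
#' Validation is idempotent: validating the records of a validation report
#' yields an identical report.
#'
#' @param records Observation tibble (see [observation_tbl()]).
#' @param max_headcount Sanity bound above which a headcount is flagged as
#'   suspicious (default 20).
#' @return An object of class `validation_report`: a list with `records`
#'   (the validated rows, unchanged), `issues` (tibble with `row`, `type`,
#'   `message`) and `n_valid`.
#' @export
validate_observations <- function(records, max_headcount = 20) {
  records <- observation_tbl(!!!as.list(records))
  issues <- list()
  note <- function(row, type, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      row = as.integer(row), type = type, message = message)
  }

  key <- paste(records$facility, records$department, records$date,
               records$shift, records$cadre, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    rows <- which(dup)
    abort(
      paste0("duplicate observation keys (facility, department, date, shift,",
             " cadre) at rows: ", paste(rows, collapse = ", ")),
      class = "emoncavail_duplicate_key"
    )
  }

  bad_shift <- !records$shift %in% shift_labels()
  bad_mode <- !records$mode %in% cadre_modes()
  if (any(bad_shift) || any(bad_mode)) {
    abort(sprintf("unknown shift or mode labels at rows: %s",
                  paste(which(bad_shift | bad_mode), collapse = ", ")),
          class = "emoncavail_payload_mismatch")
  }

  is_doc <- records$mode == "doctor_style"
  mismatch <- (is_doc & (is.na(records$classification) |
                           !is.na(records$n_present))) |
    (is_doc & !is.na(records$classification) &
       !records$classification %in% doctor_classifications()) |
    (!is_doc & (is.na(records$n_present) | !is.na(records$classification))) |
    (!is_doc & !is.na(records$n_present) & records$n_present < 0) |
    (!is_doc & !is.na(records$n_oncall_responded) &
       records$n_oncall_responded < 0) |
    (records$mode != "graded_headcount_with_oncall" &
       !is.na(records$n_oncall_responded) & records$n_oncall_responded > 0) |
    (records$mode == "graded_headcount_with_oncall" &
       !is.na(records$n_present) & !is.na(records$n_oncall_responded) &
       records$n_present > 0 & records$n_oncall_responded > 0)
  if (any(mismatch, na.rm = TRUE)) {
    abort(sprintf("payload does not match cadre mode at rows: %s",
                  paste(which(mismatch), collapse = ", ")),
          class = "emoncavail_payload_mismatch")
  }

  big <- !is.na(records$n_present) & records$n_present > max_headcount
  for (r in which(big)) {
    note(r, "suspicious_headcount",
         sprintf("headcount %d exceeds sanity bound %d",
                 records$n_present[[r]], max_headcount))
  }

  series <- split(seq_len(nrow(records)),
                  paste(records$facility, records$department, records$cadre,
                        sep = "\r"))
  for (idx in series) {
    days <- sort(unique(records$date[idx]))
    gaps <- setdiff(seq(min(days), max(days)), days)
    if (length(gaps) > 0) {
      note(idx[[1]], "day_gap",
           sprintf("%s/%s/%s: missing day indices %s",
                   records$facility[[idx[[1]]]],
                   records$department[[idx[[1]]]],
                   records$cadre[[idx[[1]]]],
                   paste(gaps, collapse = ", ")))
    }
  }

  structure(
    list(
      records = records,
      issues = if (length(issues) > 0) dplyr::bind_rows(issues) else
        tibble::tibble(row = integer(), type = character(),
                       message = character()),
      n_valid = nrow(records)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d records, %d issue(s)\n",
              x$n_valid, nrow(x$issues)))
  if (nrow(x$issues) > 0) print(x$issues, ...)
  invisible(x)
}
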
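#' Synthetic roster scenarios
#'
#' A scenario describes, for each (facility, department, cadre, shift) cell,
#' how to produce `n_days` shift observations. Three specifications are
#' supported per entry:
#'
#' * `counts` — exact-count mode: a named tally of category keys summing to
#'   `n_days`; days are assigned by stratified enumeration, so generation is
#'   fully deterministic (independent of the seed). This is how observed
#'   presence distributions are replayed through the pipeline.
#' * `probs` — sampled mode: a named category-probability vector (summing to
#'   1); each day's category is drawn independently.
#' * `pool` + `attend_prob` — binomial headcount mode: each of `pool` staff
#'   attends independently with probability `attend_prob`.
#'
#' Category keys are doctor classifications for `doctor_style` entries, and
#' headcount values (`"0"`, `"1"`, `"2"`, ...) for headcount entries, plus
#' `"oncall_<k>"` (k providers arrived on emergency call) and the neutral
#' `"none"` for `graded_headcount_with_oncall` entries.
#'
#' @param facility,department,cadre,shift,mode Cell identifiers and payload
#'   mode.
#' @param counts,probs Named numeric vectors keyed by category.
#' @param pool,attend_prob Binomial headcount parameters.
#' @return `scenario_entry()` returns one entry; `roster_scenario()` a
#'   validated scenario object of class `roster_scenario`.
#' @seealso [generate_roster()], [read_scenario()]
#' @export
scenario_entry <- function(facility, department, cadre, mode, shift,
                           counts = NULL, probs = NULL,
                           pool = NULL, attend_prob = NULL) {
  spec <- c(!is.null(counts), !is.null(probs), !is.null(pool))
  if (sum(spec) != 1) {
    abort("exactly one of counts, probs or pool/attend_prob must be given",
          class = "emoncavail_bad_scenario")
  }
  list(facility = facility, department = department, cadre = cadre,
       mode = mode, shift = shift, counts = counts, probs = probs,
       pool = pool, attend_prob = attend_prob)
}

#' @rdname scenario_entry
#' @param n_days Number of observation days (default 30, the three
#'   10-day observation phases of the study design).
#' @param entries List of [scenario_entry()] objects.
#' @param seed Integer seed governing all sampled entries.
#' @export
roster_scenario <- function(n_days = 30, entries, seed = 1L) {
  n_days <- as.integer(n_days)
  if (n_days < 1) abort("n_days must be positive",
                        class = "emoncavail_bad_scenario")
  for (e in entries) validate_entry(e, n_days)
  structure(list(n_days = n_days, entries = entries, seed = as.integer(seed)),
            class = "roster_scenario")
}

valid_keys <- function(mode) {
  if (mode == "doctor_style") return(doctor_classifications())
  keys <- as.character(0:50)
  if (mode == "graded_headcount_with_oncall") {
    keys <- c(keys, paste0("oncall_", 1:50), "none")
  }
  keys
}

validate_entry <- function(e, n_days) {
  req <- c("facility", "department", "cadre", "mode", "shift")
  if (!all(req %in% names(e))) {
    abort("scenario entry missing identifier fields",
          class = "emoncavail_bad_scenario")
  }
  if (!e$mode %in% cadre_modes()) {
    abort(sprintf("unknown mode '%s'", e$mode),
          class = "emoncavail_bad_scenario")
  }
  if (!e$shift %in% shift_labels()) {
    abort(sprintf("unknown shift '%s'", e$shift),
          class = "emoncavail_bad_scenario")
  }
  if (!is.null(e$counts)) {
    if (sum(e$counts) != n_days) {
      abort(sprintf("entry %s/%s/%s/%s: counts sum to %d, not n_days = %d",
                    e$facility, e$department, e$cadre, e$shift,
                    sum(e$counts), n_days),
            class = "emoncavail_bad_scenario")
    }
    check_keys(names(e$counts), e$mode)
  } else if (!is.null(e$probs)) {
    if (abs(sum(e$probs) - 1) > 1e-9 || any(e$probs < 0)) {
      abort(sprintf("entry %s/%s/%s/%s: probabilities must be non-negative and sum to 1",
                    e$facility, e$department, e$cadre, e$shift),
            class = "emoncavail_bad_scenario")
    }
    check_keys(names(e$probs), e$mode)
  } else {
    if (e$mode == "doctor_style") {
      abort("binomial headcount entries need a headcount mode",
            class = "emoncavail_bad_scenario")
    }
    if (is.null(e$attend_prob) || e$attend_prob < 0 || e$attend_prob > 1 ||
        e$pool < 0) {
      abort("binomial entry needs pool >= 0 and attend_prob in [0, 1]",
            class = "emoncavail_bad_scenario")
    }
  }
  invisible(TRUE)
}

check_keys <- function(keys, mode) {
  if (is.null(keys)) {
    abort("category vectors must be named by category key",
          class = "emoncavail_bad_scenario")
  }
  bad <- setdiff(keys, valid_keys(mode))
  if (length(bad) > 0) {
    abort(sprintf("invalid category keys for mode %s: %s", mode,
                  paste(bad, collapse = ", ")),
          class = "emoncavail_bad_scenario")
  }
  invisible(TRUE)
}

key_to_payload <- function(key, mode) {
  if (mode == "doctor_style") {
    return(list(classification = key, n_present = NA_integer_,
                n_oncall_responded = NA_integer_))
  }
  if (key == "none") {
    return(list(classification = NA_character_, n_present = 0L,
                n_oncall_responded = 0L))
  }
  if (startsWith(key, "oncall_")) {
    return(list(classification = NA_character_, n_present = 0L,
                n_oncall_responded = as.integer(sub("oncall_", "", key))))
  }
  list(classification = NA_character_, n_present = as.integer(key),
       n_oncall_responded = 0L)
}

payload_to_key <- function(mode, classification, n_present,
                           n_oncall_responded) {
  if (mode == "doctor_style") return(classification)
  k <- if (is.na(n_oncall_responded)) 0L else n_oncall_responded
  if (n_present == 0 && mode == "graded_headcount_with_oncall") {
    if (k > 0) return(paste0("oncall_", k))
    return("none")
  }
  as.character(n_present)
}

entry_order <- function(entries) {
  keys <- vapply(entries, function(e) {
    paste(e$facility, e$department, e$cadre,
          match(e$shift, shift_labels()), sep = "\r")
  }, character(1))
  order(keys)
}

#' Generate a synthetic observation roster
#'
#' Produces `n_days` x entries shift observations following the scenario.
#' Exact-count entries are enumerated deterministically; sampled and
#' binomial entries draw from a single RNG stream seeded with `seed`, with
#' entries processed in a canonical sort order, so a given seed always
#' yields a byte-identical roster. Night-shift rows are marked
#' `provenance = "interview"` (they are typically reconstructed
#' retrospectively); the flag does not affect computation.
#'
#' @param scenario A [roster_scenario()].
#' @param seed Optional seed overriding the scenario's own.
#' @return An observation tibble that passes [validate_observations()].
#' @export
generate_roster <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "roster_scenario"))
  if (is.null(seed)) seed <- scenario$seed
  set.seed(as.integer(seed))
  n <- scenario$n_days
  entries <- scenario$entries[entry_order(scenario$entries)]
  rows <- purrr::map(entries, function(e) {
    keys <- if (!is.null(e$counts)) {
      rep(names(e$counts), times = e$counts)
    } else if (!is.null(e$probs)) {
      sample(names(e$probs), n, replace = TRUE, prob = e$probs)
    } else {
      as.character(rbinom(n, e$pool, e$attend_prob))
    }
    payload <- purrr::map(keys, key_to_payload, mode = e$mode)
    observation_tbl(
      facility = e$facility, department = e$department,
      date = seq_len(n), shift = e$shift, cadre = e$cadre, mode = e$mode,
      classification = purrr::map_chr(payload, "classification"),
      n_present = purrr::map_int(payload, "n_present"),
      n_oncall_responded = purrr::map_int(payload, "n_oncall_responded"),
      provenance = if (e$shift == "night") "interview" else "observed"
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare empirical category proportions with scenario targets
#'
#' For every scenario entry specified by `counts` or `probs`, tabulates the
#' empirical category proportions in the generated records and their
#' absolute deviation from the scenario's target proportions. Exact-count
#' entries recover their targets exactly; sampled entries converge at the
#' usual root-n rate.
#'
#' @param records Roster generated from `scenario`.
#' @param scenario The generating [roster_scenario()].
#' @return Tibble with columns `facility`, `department`, `cadre`, `shift`,
#'   `category`, `expected`, `observed`, `abs_dev`.
#' @export
recover_proportions <- function(records, scenario) {
  stopifnot(inherits(scenario, "roster_scenario"))
  out <- purrr::map(scenario$entries, function(e) {
    target <- if (!is.null(e$counts)) e$counts / sum(e$counts) else e$probs
    if (is.null(target)) return(NULL)
    rows <- records[records$facility == e$facility &
                      records$department == e$department &
                      records$cadre == e$cadre & records$shift == e$shift, ]
    keys <- vapply(seq_len(nrow(rows)), function(i) {
      payload_to_key(e$mode, rows$classification[[i]], rows$n_present[[i]],
                     rows$n_oncall_responded[[i]])
    }, character(1))
    emp <- vapply(names(target), function(k) mean(keys == k), numeric(1))
    tibble::tibble(
      facility = e$facility, department = e$department, cadre = e$cadre,
      shift = e$shift, category = names(target),
      expected = as.numeric(target), observed = emp,
      abs_dev = abs(emp - as.numeric(target))
    )
  })
  dplyr::bind_rows(purrr::compact(out))
}

#' Expected index value of a sampled scenario entry
#'
#' The index is linear in the per-shift scores, so its expectation under a
#' category-probability vector is the probability-weighted mean score times
#' 100. Useful for calibrating sampled scenarios and for Monte-Carlo checks.
#'
#' @param probs Named category-probability vector (entry keys).
#' @param mode Cadre payload mode.
#' @param min_required Minimum headcount for the shift.
#' @return Expected index in percent.
#' @export
expected_index <- function(probs, mode, min_required = 2) {
  scores <- vapply(names(probs), shift_score, numeric(1),
                   mode = mode, min_required = min_required)
  sum(probs * scores) * 100
}

shift_score <- function(key, mode, min_required) {
  if (mode == "doctor_style") {
    return(switch(key,
                  present_majority = 1, present_minority = 0.5,
                  offsite_responded = 1, offsite_no_response = -1,
                  offsite_no_call = 0,
                  abort(sprintf("unknown classification '%s'", key),
                        class = "emoncavail_bad_scenario")))
  }
  if (key == "none") return(0)
  oncall <- startsWith(key, "oncall_")
  k <- as.integer(sub("oncall_", "", key))
  if (k >= min_required) return(1)
  if (k > 0) return(k / min_required)
  -1
}

#' Read and write roster scenarios as YAML
#'
#' The file carries `n_days`, `seed` and a list of entries; each entry gives
#' the cell identifiers plus one of `counts`, `probs` or
#' `pool`/`attend_prob` (see [scenario_entry()]).
#'
#' @param path YAML path.
#' @return `read_scenario()` returns a [roster_scenario()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$entries)) {
    abort("scenario file has no entries", class = "emoncavail_bad_scenario")
  }
  entries <- purrr::map(raw$entries, function(e) {
    scenario_entry(
      facility = e$facility, department = e$department, cadre = e$cadre,
      mode = e$mode, shift = e$shift,
      counts = if (!is.null(e$counts)) unlist(e$counts),
      probs = if (!is.null(e$probs)) unlist(e$probs),
      pool = e$pool, attend_prob = e$attend_prob
    )
  })
  roster_scenario(n_days = raw$n_days %||% 30, entries = entries,
                  seed = raw$seed %||% 1L)
}

#' @rdname read_scenario
#' @param scenario Scenario to serialise.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "roster_scenario"))
  entries <- purrr::map(scenario$entries, function(e) {
    out <- e[c("facility", "department", "cadre", "mode", "shift")]
    if (!is.null(e$counts)) out$counts <- as.list(e$counts)
    if (!is.null(e$probs)) out$probs <- as.list(e$probs)
    if (!is.null(e$pool)) {
      out$pool <- e$pool
      out$attend_prob <- e$attend_prob
    }
    out
  })
  yaml::write_yaml(
    list(n_days = scenario$n_days, seed = scenario$seed, entries = entries),
    path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
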
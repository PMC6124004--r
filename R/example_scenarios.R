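#' Bundled example rosters: district-hospital and MCWC staffing
#'
#' Exact-count scenarios encoding 30-day presence distributions of the kind
#' observed in district-level EmONC facilities in Bangladesh: a district
#' hospital (DH) with ob/gyn and pediatric wards, an operating theatre, an
#' emergency department, a laboratory and a pooled support-staff roster; and
#' a mother and child welfare centre (MCWC) staffed by family welfare
#' visitors (FWVs), assistant nursing attendants (ANAs) and support staff.
#'
#' Because the scenarios are exact-count, regenerating and tabulating them
#' reproduces the same presence distributions and index matrix every time,
#' making them convenient end-to-end fixtures and worked examples. The same
#' scenarios ship as YAML under `inst/extdata/` for the command-line tools.
#'
#' @param seed Seed stored in the scenario (exact-count generation does not
#'   consume randomness; the seed only matters if entries are replaced by
#'   sampled ones).
#' @return A [roster_scenario()].
#' @export
#' @examples
#' roster <- generate_roster(dh_example_scenario())
#' index_report(roster)
dh_example_scenario <- function(seed = 1L) {
  e <- function(department, cadre, mode, shift, ...) {
    scenario_entry("DH", department, cadre, mode, shift, counts = c(...))
  }
  roster_scenario(n_days = 30, seed = seed, entries = list(
    e("obgyn_ward", "nurse", "graded_headcount", "morning",
      "3" = 29, "2" = 1),
    e("obgyn_ward", "nurse", "graded_headcount", "evening",
      "3" = 8, "2" = 21, "1" = 1),
    e("obgyn_ward", "nurse", "graded_headcount", "night",
      "3" = 2, "2" = 22, "1" = 6),
    e("pediatric_ward", "nurse", "graded_headcount", "morning",
      "3" = 4, "2" = 20, "1" = 6),
    e("pediatric_ward", "nurse", "graded_headcount", "evening",
      "2" = 7, "1" = 23),
    e("pediatric_ward", "nurse", "graded_headcount", "night",
      "2" = 12, "1" = 18),
    e("operating_theatre", "nurse", "graded_headcount_with_oncall",
      "morning", "2" = 25, "1" = 2, "none" = 3),
    e("operating_theatre", "nurse", "graded_headcount_with_oncall",
      "evening", "oncall_1" = 4, "none" = 26),
    e("operating_theatre", "nurse", "graded_headcount_with_oncall",
      "night", "none" = 30),
    e("laboratory", "med_technologist", "doctor_style", "morning",
      "present_majority" = 27, "offsite_responded" = 2,
      "offsite_no_call" = 1),
    e("laboratory", "med_technologist", "doctor_style", "evening",
      "offsite_responded" = 25, "offsite_no_call" = 5),
    e("laboratory", "med_technologist", "doctor_style", "night",
      "offsite_responded" = 22, "offsite_no_call" = 8),
    e("emergency", "doctor", "doctor_style", "morning",
      "present_majority" = 30),
    e("emergency", "doctor", "doctor_style", "evening",
      "present_majority" = 30),
    e("emergency", "doctor", "doctor_style", "night",
      "present_majority" = 30),
    e("facility", "support", "support_pool", "morning", "2" = 30),
    e("facility", "support", "support_pool", "evening", "2" = 30),
    e("facility", "support", "support_pool", "night", "2" = 24, "1" = 6)
  ))
}

#' @rdname dh_example_scenario
#' @export
mcwc_example_scenario <- function(seed = 1L) {
  e <- function(department, cadre, mode, shift, ...) {
    scenario_entry("MCWC", department, cadre, mode, shift, counts = c(...))
  }
  roster_scenario(n_days = 30, seed = seed, entries = list(
    e("obgyn_ward", "fwv", "graded_headcount", "morning",
      "3" = 27, "2" = 2, "1" = 1),
    e("obgyn_ward", "fwv", "graded_headcount", "evening",
      "3" = 5, "2" = 15, "1" = 10),
    e("obgyn_ward", "fwv", "graded_headcount", "night",
      "3" = 1, "2" = 11, "1" = 17, "0" = 1),
    e("operating_theatre", "ana", "doctor_style", "morning",
      "present_majority" = 27, "offsite_no_call" = 3),
    e("operating_theatre", "ana", "doctor_style", "evening",
      "present_majority" = 13, "offsite_no_call" = 17),
    e("operating_theatre", "ana", "doctor_style", "night",
      "present_majority" = 17, "offsite_no_call" = 13),
    e("facility", "support", "support_pool", "morning", "2" = 30),
    e("facility", "support", "support_pool", "evening", "2" = 22, "1" = 8),
    e("facility", "support", "support_pool", "night", "2" = 27, "1" = 3)
  ))
}
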
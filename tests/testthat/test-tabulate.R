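test_that("shift classification is exclusive with >= semantics at the minimum", {
  expect_equal(classify_shift("graded_headcount", 3, n_present = 3), "ge_min")
  expect_equal(classify_shift("graded_headcount", 3, n_present = 5), "ge_min")
  expect_equal(classify_shift("graded_headcount", 3, n_present = 2), "2")
  # the same headcount of two is the top category against an evening minimum
  expect_equal(classify_shift("graded_headcount", 2, n_present = 2), "ge_min")
  expect_equal(classify_shift("graded_headcount", 2, n_present = 0), "absent")
  expect_equal(
    classify_shift("graded_headcount_with_oncall", 2, n_present = 0,
                   n_oncall_responded = 1), "oncall_1")
  expect_equal(
    classify_shift("graded_headcount_with_oncall", 2, n_present = 0,
                   n_oncall_responded = 3), "oncall_ge_min")
  # no presence and no recorded call response: neutral, not a penalty
  expect_equal(
    classify_shift("graded_headcount_with_oncall", 2, n_present = 0,
                   n_oncall_responded = 0), "none")
  expect_equal(classify_shift("doctor_style", 1,
                              classification = "offsite_responded"),
               "offsite_responded")
  expect_error(classify_shift("doctor_style", 1, classification = "late"),
               class = "emoncavail_payload_mismatch")
})

test_that("build_tally counts classifications over the observed shifts", {
  ward <- headcount_records(c(rep(3, 29), 2))
  t <- build_tally(ward, "F", "obgyn_ward", "nurse", "morning")
  expect_s3_class(t, "graded_tally")
  expect_equal(t$at_min, 29)
  expect_equal(t$below, c(`1` = 0L, `2` = 1L))
  expect_equal(t$absent, 0)
  expect_equal(t$n_shifts, 30)

  er <- doctor_records(rep("present_majority", 30),
                       department = "emergency")
  td <- build_tally(er, "F", "emergency", "doctor", "morning")
  expect_s3_class(td, "doctor_tally")
  expect_equal(td$a, 30)
  expect_equal(td$n_shifts, 30)

  single <- build_tally(ward[30, ], "F", "obgyn_ward", "nurse", "morning")
  expect_equal(single$n_shifts, 1)
  expect_equal(single$below[["2"]], 1)

  expect_error(build_tally(ward, "F", "obgyn_ward", "nurse", "night"),
               class = "emoncavail_undefined_tally")
})

test_that("presence distributions print every category and sum to 100", {
  fwv_night <- headcount_records(
    c(rep(3, 1), rep(2, 11), rep(1, 17), rep(0, 1)),
    shift = "night", facility = "MCWC", cadre = "fwv")
  dist <- presence_distribution(fwv_night)
  expect_equal(dist$category, c("ge_min", "1", "absent"))
  expect_equal(dist$pct, c(36.7 + 3.3, 56.7, 3.3))
  expect_equal(sum(dist$pct), 100, tolerance = 0.2 / 100)

  # morning against a minimum of three keeps the exact-count layout
  fwv_morning <- headcount_records(
    c(rep(3, 1), rep(2, 11), rep(1, 17), rep(0, 1)),
    shift = "morning", facility = "MCWC", cadre = "fwv")
  dm <- presence_distribution(fwv_morning)
  expect_equal(dm$category, c("ge_min", "2", "1", "absent"))
  expect_equal(dm$pct, c(3.3, 36.7, 56.7, 3.3))

  # empty categories are printed as 0.0, never omitted
  full <- presence_distribution(headcount_records(rep(3, 30)))
  expect_equal(full$pct, c(100, 0, 0, 0))
})

test_that("index_report cells equal the formulas applied to their tallies", {
  records <- generate_roster(dh_example_scenario())
  report <- index_report(records)
  std <- default_standards()
  for (i in seq_len(nrow(report))) {
    for (s in shift_labels()) {
      t <- build_tally(records, report$facility[[i]],
                       report$department[[i]], report$cadre[[i]], s, std)
      expect_equal(report[[s]][[i]], availability_index(t))
    }
    expect_equal(report$day_average[[i]],
                 day_average(report$morning[[i]], report$evening[[i]],
                             report$night[[i]]))
  }
})

test_that("recomputing from emitted distribution counts reproduces indices", {
  records <- generate_roster(dh_example_scenario())
  dist <- presence_distribution(records)
  report <- index_report(records)
  # rebuild one observation per counted shift from the distribution rows
  rebuilt <- dplyr::bind_rows(purrr::pmap(
    dplyr::filter(dist, n > 0),
    function(facility, department, cadre, shift, category, n, pct) {
      mode <- unique(records$mode[records$cadre == cadre &
                                    records$department == department])
      if (mode == "doctor_style") {
        return(doctor_records(rep(category, n), shift = shift,
                              facility = facility, department = department,
                              cadre = cadre))
      }
      min_req <- lookup_min_required(default_standards(), department, cadre,
                                     shift, mode)
      present <- 0L
      oncall <- 0L
      if (category == "ge_min") present <- min_req
      else if (category == "oncall_ge_min") oncall <- min_req
      else if (category == "absent" || category == "none") present <- 0L
      else if (grepl("^oncall_", category)) {
        oncall <- as.integer(sub("oncall_", "", category))
      } else present <- as.integer(category)
      headcount_records(rep(present, n), shift = shift, facility = facility,
                        department = department, cadre = cadre, mode = mode,
                        n_oncall = oncall)
    }))
  rebuilt$date <- as.integer(stats::ave(
    rebuilt$date, rebuilt$facility, rebuilt$department, rebuilt$cadre,
    rebuilt$shift, FUN = seq_along))
  report2 <- index_report(validate_observations(rebuilt)$records)
  merged <- dplyr::arrange(report, facility, department, cadre)
  merged2 <- dplyr::arrange(report2, facility, department, cadre)
  expect_equal(merged2, merged, tolerance = 1e-12)
})

test_that("an unobserved shift shrinks only its own denominator", {
  records <- generate_roster(dh_example_scenario())
  drop_row <- which(records$department == "obgyn_ward" &
                      records$shift == "morning" & records$date == 1)
  trimmed <- records[-drop_row, ]
  t <- build_tally(trimmed, "DH", "obgyn_ward", "nurse", "morning")
  expect_equal(t$n_shifts, 29)
  report <- index_report(trimmed)
  row <- report[report$department == "obgyn_ward", ]
  expect_equal(row$morning, 8600 / 87)  # (28 + 2/3) / 29 * 100
  full <- index_report(records)
  expect_equal(row$evening, full$evening[full$department == "obgyn_ward"])
  expect_equal(row$night, full$night[full$department == "obgyn_ward"])
})

test_that("a wholly unobserved shift leaves other cells intact as NA", {
  records <- generate_roster(mcwc_example_scenario())
  trimmed <- records[!(records$cadre == "fwv" & records$shift == "night"), ]
  expect_warning(report <- index_report(trimmed), "undefined")
  row <- report[report$cadre == "fwv", ]
  expect_true(is.na(row$night))
  expect_true(is.na(row$day_average))
  expect_equal(row$morning, (27 + 4 / 3 + 1 / 3) / 30 * 100)
  expect_false(anyNA(report[report$cadre != "fwv",
                            c("morning", "evening", "night")]))
})

test_that("two-pool support staffing collapses to the pooled headcount", {
  expect_equal(classify_support_pools(1, 1), 2L)
  expect_equal(classify_support_pools(3, 2), 5L)
  expect_equal(classify_support_pools(3, 0), 1L)
  expect_equal(classify_support_pools(0, 2), 1L)
  expect_equal(classify_support_pools(0, 0), 0L)
  expect_equal(classify_support_pools(c(1, 0), c(1, 0)), c(2L, 0L))
})

test_that("negative indices can be clamped at presentation only", {
  records <- headcount_records(rep(0, 30), shift = "evening")
  t <- build_tally(records, "F", "obgyn_ward", "nurse", "evening")
  expect_equal(availability_index(t), -100)
  rep <- tibble::tibble(facility = "F", department = "obgyn_ward",
                        cadre = "nurse", morning = -12.34, evening = -100,
                        night = 50.25, day_average = -20.6966667)
  expect_equal(format_index_report(rep)$morning, -12.3)
  expect_equal(format_index_report(rep, clamp_negative = TRUE)$morning, 0)
  expect_equal(format_index_report(rep, clamp_negative = TRUE)$night, 50.3)
  expect_equal(format_index_report(rep, decimals = 2)$day_average, -20.70)
})
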
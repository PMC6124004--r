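# Shared helpers: hand-built record constructors and an independent
# per-shift-score oracle for the index formulas.

doctor_records <- function(classifications, shift = "morning",
                           facility = "F", department = "dept",
                           cadre = "doctor") {
  observation_tbl(
    facility = facility, department = department,
    date = seq_along(classifications), shift = shift, cadre = cadre,
    mode = "doctor_style", classification = classifications
  )
}

headcount_records <- function(n_present, shift = "morning",
                              facility = "F", department = "obgyn_ward",
                              cadre = "nurse", mode = "graded_headcount",
                              n_oncall = 0L) {
  observation_tbl(
    facility = facility, department = department,
    date = seq_along(n_present), shift = shift, cadre = cadre, mode = mode,
    n_present = as.integer(n_present),
    n_oncall_responded = as.integer(rep_len(n_oncall, length(n_present)))
  )
}

# Independent oracle: expand a tally into one score per shift (including
# neutral shifts at 0) and average. Score tables written out by hand; no
# reuse of package formulas.
oracle_index <- function(t) {
  if (inherits(t, "doctor_tally")) {
    scores <- c(rep(1, t$a), rep(0.5, t$b), rep(1, t$c), rep(-1, t$d),
                rep(0, t$n_shifts - t$a - t$b - t$c - t$d))
  } else {
    m <- t$min_required
    scores <- c(rep(1, t$at_min), rep(1, t$oncall_at_min))
    for (k in seq_len(m - 1)) {
      scores <- c(scores,
                  rep(k / m, t$below[[as.character(k)]]),
                  rep(k / m, t$oncall_below[[as.character(k)]]))
    }
    scores <- c(scores, rep(-1, t$absent),
                rep(0, t$n_shifts - length(scores) - t$absent))
  }
  mean(scores) * 100
}

random_graded_tally <- function(min_required = sample(2:3, 1),
                                oncall = FALSE) {
  n <- sample(1:60, 1)
  ncat <- min_required + 2 + if (oncall) min_required else 0
  counts <- as.vector(stats::rmultinom(1, n, rep(1, ncat)))
  below <- setNames(counts[2:min_required],
                    as.character(seq_len(min_required - 1)))
  oncall_below <- if (oncall) {
    setNames(counts[(min_required + 3):(2 * min_required + 1)],
             as.character(seq_len(min_required - 1)))
  } else {
    integer()
  }
  graded_tally(
    at_min = counts[1], below = below, absent = counts[min_required + 1],
    oncall_at_min = if (oncall) counts[min_required + 2] else 0,
    oncall_below = oncall_below,
    min_required = min_required, n_shifts = n
  )
}

random_doctor_tally <- function() {
  n <- sample(1:60, 1)
  counts <- as.vector(stats::rmultinom(1, n, rep(1, 5)))
  doctor_tally(a = counts[1], b = counts[2], c = counts[3], d = counts[4],
               n_shifts = n)
}
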
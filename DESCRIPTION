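Package: emoncavail
Title: Human Resource Availability Indices for Round-the-Clock Emergency
    Obstetric and Newborn Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes shift-level availability indices for the health
    workforce needed to keep emergency obstetric and newborn care (EmONC)
    running around the clock. From long-format observation records of
    provider presence (one row per facility, department, day, shift and
    cadre), the package tallies exclusive presence categories against
    minimum staffing standards, applies closed-form weighted scoring
    formulas for medical doctors, nurses, operating-theatre nurses and
    support staff, and summarises them as per-shift indices and day
    averages on a -100 to 100 percentage scale. A synthetic roster
    generator produces deterministic or sampled observation sets with
    known presence probabilities so the whole pipeline can be exercised
    and calibrated without access to facility data. Command-line entry
    points wrap the compute and simulate paths for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
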
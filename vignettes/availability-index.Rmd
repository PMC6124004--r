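---
title: "Measuring round-the-clock staffing: the availability index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring round-the-clock staffing: the availability index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emoncavail)
```

## The measurement problem

Emergency obstetric and newborn care (EmONC) must be deliverable 24 hours a
day, but district-level facilities in low-resource settings routinely have
the right providers only during the morning shift. Head counts of sanctioned
posts do not capture this: a ward can be fully staffed on paper and still
have no nurse at 3 AM. The availability index summarises, per provider
cadre and department, how close a facility comes to its own minimum staffing
standard across every shift of an observation period, on a scale where 100
means the standard was met in every shift, 0 means presence and absence
balanced out, and negative values mean unanswered emergencies dominated.

The unit of observation is the *shift*: each day contributes a morning
(8 AM–2 PM), evening (2 PM–9 PM) and night (9 PM–8 AM) shift. All three
shifts are weighted equally even though their durations differ; the index
measures coverage of duty periods, not person-hours. Night-shift information
is often reconstructed the next morning by interviewing the staff who worked
it; such rows carry `provenance = "interview"` but enter the arithmetic
identically.

## Presence classification

Two observation styles exist, reflecting how different cadres work:

**Doctor-style cadres** (consultants, medical officers, anesthetists — and
also medical technologists and assistant nursing attendants, which use the
same algorithm) get one exclusive classification per shift:

| classification       | meaning                                      | score |
|----------------------|----------------------------------------------|------:|
| `present_majority`   | on site more than 50% of the shift           | +1    |
| `present_minority`   | on site less than 50% of the shift           | +1/2  |
| `offsite_responded`  | off site, came in when called                 | +1    |
| `offsite_no_response`| an emergency call went unanswered            | −1    |
| `offsite_no_call`    | off site, no emergency arose                 | 0     |

The fifth, neutral state matters. Doctors not assigned to the emergency
department are expected to cover evenings, nights and holidays off-site
until called in. A shift in which nobody called them carries no information
about their responsiveness: it must count in the denominator (the service
was not demonstrably available) without counting as a failure. Treating
those shifts as `offsite_no_response` would systematically understate
availability wherever emergencies are rare; dropping them from the
denominator would overstate it.

**Headcount cadres** (nurses, FWVs, pooled support staff) are recorded as
the number of providers on site, classified against the minimum standard for
that department and shift into *exclusive, top-coded* categories: at or
above the minimum; exactly `k` for each `k` below the minimum; and absent.
A headcount exactly at the minimum is always the top category (`>=`
semantics). Operating-theatre nurses additionally carry an on-call count,
classified into mirror categories that earn the same credit as on-site
presence at the same headcount, and the neutral `none` when nobody was on
site and no call response was recorded.

The exclusive/top-coded reading is a deliberate design choice. Category
definitions written as "at least two" and "at least one" are only consistent
with a partition of the observed shifts if each shift lands in its highest
applicable category; the scoring formulas below assume exactly that, and the
bundled example rosters only reproduce their published index values under
this interpretation.

## Staffing standards

`default_standards()` encodes the minimums negotiated with district-level
facility staff against their typical caseload:

* ob/gyn and pediatric wards (nurses/FWVs): 3 in the morning, 2 in the
  evening and night;
* operating theatre (nurses): 2 in every shift;
* pooled support staff (peon/ward boy/aya/sweeper/guard): 2 in every shift,
  any combination;
* doctor-style cadres: at least one provider per discipline per shift.

Standards are configurable per department × cadre × shift through a small
YAML file; the department wildcard `"*"` supplies cadre-level defaults. Some
facilities split support staff into two sub-pools and require one person
from each (e.g. at least one peon/guard *and* one sweeper/aya);
`classify_support_pools()` collapses the two sub-pool headcounts into an
effective pooled count (both covered → fully staffed; anyone present but a
pool uncovered → a single-provider shift) so the standard single-headcount
schema applies downstream.

## The index formulas

Write `N` for the number of observed shifts in a cell. For doctor-style
cadres with `a, b, c, d` shifts in the four scored classifications:

\[ I_{doc} = \frac{a + b/2 + c - d}{N} \times 100. \]

For ward nurses/FWVs against the morning minimum of three (`m3` shifts at or
above three, `m2` with exactly two, `m1` with exactly one, `m0` with none):

\[ I_{morning} = \frac{m_3 + 2m_2/3 + m_1/3 - m_0}{N} \times 100, \]

i.e. a short-staffed shift earns credit proportional to the fraction of the
minimum present. Evening and night use the minimum of two:

\[ I_{offpeak} = \frac{m_2 + m_1/2 - m_0}{N} \times 100, \]

operating-theatre nurses add the on-call mirror categories,

\[ I_{OT} = \frac{m_2 + m_1/2 + m_{2a} + m_{1a}/2 - m_0}{N} \times 100, \]

and pooled support staff use the same minimum-of-two form
\((s_2 + s_1/2 - s_0)/N \times 100\). Every formula is equivalently the mean
over shifts of a per-shift score times 100 — the property the test suite
exploits with a brute-force per-shift oracle — which immediately gives the
invariants: values lie in \([-100, 100]\) whenever the categories partition
`N`, equal 100 exactly when every shift is in a top category, and never
decrease when a shift's headcount rises or a doctor classification upgrades.

The **day average** is the unweighted arithmetic mean of the three
full-precision per-shift values. No skill weighting or provider-type
prioritisation is applied within or across shifts.

## Numerical choices

* **Full precision, late rounding.** All arithmetic is double precision;
  rounding to one decimal (half away from zero, `round_half_up()`) happens
  only at presentation. Averaging pre-rounded cells can change the printed
  day average by a tenth, so `day_average()` always consumes unrounded shift
  values.
* **Undefined is an error.** A cell with zero observed shifts has no index;
  the package raises a classed error rather than reporting 0. In a full
  report such a cell becomes `NA` with a warning and leaves every other cell
  intact.
* **Missing shifts shrink `N`.** A day without an observation for some cell
  is simply absent from that cell's denominator; nothing is imputed. How
  partially observed days should be handled is not fixed by the measurement
  design, and drop-and-renormalise is the least-assumption choice.
* **Negative values are reported raw.** The penalty terms can drive an index
  below zero; `format_index_report(clamp_negative = TRUE)` offers a clamped
  presentation for audiences expecting 0–100, but raw values are the
  faithful default since clamping loses the distinction between "never
  present" and "present but ignored emergencies".
* **Pooling before classification.** Consultants and medical officers of one
  discipline are pooled, and a shift takes the best classification any
  pooled provider achieves; support categories are pooled into one
  headcount. Pooling is an input-preparation step — records arrive already
  pooled per cadre.

## The synthetic roster generator

`roster_scenario()` describes, per facility/department/cadre/shift, how to
produce `n_days` observations (default 30, matching a three-phase, 10-day
observation design). Two generation modes serve different purposes:

* **Exact-count mode** fixes the number of shifts per category and
  enumerates them deterministically. It exists so that a known presence
  distribution — such as the bundled district-hospital and MCWC example
  scenarios — can be replayed through the *entire* pipeline (generate →
  validate → tabulate → index → report) and reproduce its index matrix
  exactly, every time, independent of the seed.
* **Sampled mode** draws each day independently from a category-probability
  vector (or a binomial headcount: `pool` staff attending independently with
  probability `attend_prob`). Because the index is linear in per-shift
  scores, its expectation is the probability-weighted mean score
  (`expected_index()`); Monte-Carlo runs at the study scale (30 days, 1,000
  replicates) recover that expectation within sampling error, and long
  rosters (10,000 days in the tests) recover the category proportions to
  within 0.02.

A single integer seed governs all sampled draws; entries are processed in a
canonical sort order from one RNG stream, so a scenario file plus a seed
fully determines the roster byte-for-byte.

What the generator deliberately does **not** emulate: day-to-day correlation
in absenteeism (each day is independent), delays in on-call arrival (an
answered call is full credit regardless of delay), within-shift timing
beyond the 50% split, and competence or quality of the providers present.
Passing tests on synthetic rosters therefore demonstrate the arithmetic and
plumbing, not that real rosters satisfy independence.

## Problem sizes in the test suite

The suite exercises tallies up to 60 shifts in the property checks
(500–1,000 random tallies per invariant), 30-day rosters for the end-to-end
reproductions, one 10,000-day roster for proportion recovery, and 1,000
Monte-Carlo replicates of a 30-day scenario for expectation recovery —
sizes chosen to make sampling error negligible relative to the assertions
while keeping a full run under a minute.

## Known limitations

The index measures presence, not competence or caseload adequacy; one
provider per shift may be insufficient where demand is high. Shift coverage
is split only at the 50% mark. All cadres within a formula are
interchangeable (no skill prioritisation). Combining two cadres that
compensate for each other (e.g. paramedics and nurse aides covering the
same ward) has no canonical formula here; pooling their headcounts before
classification is supported but is a modelling choice the analyst must own.
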
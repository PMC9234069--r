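---
title: "Phenotyping methods: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping methods: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortpheno)
library(data.table)
```

# The problem

Ascertaining a binary health outcome in a biobank cohort means reconciling
evidence of very different provenance: questionnaire answers and
nurse-interview self-reports collected at the assessment centre, hospital
inpatient episodes, primary-care events and prescriptions, and death
registrations, each with its own coding system and its own notion of an
event date. `cohortpheno` factors this into three stages — definition
parsing, episode harmonization, ascertainment — each with an explicit,
testable contract. This vignette records the modelling decisions, why they
were made, and what a green test suite does and does not establish.

# Definition tables

A definition table has one row per trait. Code cells are comma-separated
lists; an annotation in parentheses (`E11(type 2 code)`) documents a code
and is never matched against data. For hierarchical systems a parent code
implies all descendants by prefix. Two dialect rules matter:

* **READ2/CTV3 dot padding.** Primary-care codes are padded to five
  characters with dots (`G573.`). Trailing dots are stripped on *both*
  sides before prefix comparison, so `G573.` covers `G5730`, `G573z` and
  `G573.` itself, while output strings always stay in the map's original
  form. Matching is case-sensitive by default (READ distinguishes `G573z`
  from `X202R`-style codes); a per-source `ignore_case` flag exists in the
  data-settings file.
* **Bare self-report fields.** A field specification without codes
  (`20003`) means "any non-missing, non-negative value counts as a
  record". Negative values are the cohort's special answer codes ("do not
  know", "prefer not to answer") and never count as clinical content —
  also not under `!=` conditions.

Expansion happens once, at parse time. This makes downstream matching a
set lookup and makes the validation report complete: every entered code
either expands to at least one map code or is dropped with a warning and
listed in `report$dropped_codes`. Composite phenotypes reference other
traits through four columns (`Study_population`, `Include_definitions`,
`Exclude_from_cases`, `Exclude_from_controls`); `plan_composite()` produces
a dependency-ordered evaluation plan and rejects cycles.

The serializer `write_definition_table()` emits the normalized table form;
parse → serialize → parse is an exact identity (unmatched codes and
annotations included), which the test suite asserts.

# The episode model

Every source harmonizes to seven columns: source id, participant, code,
event date, event flag, hospitalization days, classification. The event
flag records *date provenance*, not severity:

| flag | meaning | typical sources |
|------|---------|-----------------|
| 1 | true event date from linked records; self-reported operations | hospital, GP, prescriptions, death, field 20004 |
| 2 | self-reported event date (interpolated year/age) | fields 20001/20002, touchscreen with age field |
| 0 | no true date; assessment-centre visit date imputed | timing missing or special-coded |

Numerical conventions, chosen where the source material is silent:

* **Year → date**: July 1 of the reported year (unbiased within-year
  placement). **Age → date**: birth date + age × 365.25 days, where the
  birth date is year + mid-month day 15 when the month is known, else
  July 1. Timing values that are negative, before 1900 or after 2100 are
  treated as missing (flag 0).
* **Hospital episodes**: event date is the episode start, falling back to
  the admission date; `epidur` is end − start in days, missing when either
  bound is absent or the difference is negative. Diagnosis/operation rows
  without a master row are dropped with a logged count.
* **GP rows carrying both `read_2` and `read_3`** emit two episodes, one
  per coding system. (Whether the original tool emits one or two is not
  documented; two keeps the per-system sources self-contained.)
* Withdrawn participants are removed from every component; episodes of
  identifiers absent from the main dataset are discarded, so the container
  invariant "every episode identifier is in the identifier vector" holds by
  construction.

# Ascertainment semantics

Given reference dates (typically the baseline visit), matched events yield
a 16-field summary per participant. The boundary and status conventions:

* **Events dated exactly on the reference date count as prevalent**
  (`Hx = 2`), and `Ref` flags events within a symmetric window (default 0
  days). Inclusive-prevalent is the conservative choice for baseline
  ascertainment; the alternative would silently reclassify same-day
  diagnoses as incident.
* **`Fu = 2` (incident) only when the first event is strictly after the
  reference date**; `Fu_days` is then the days to that first event.
  Participants with both pre- and post-reference events are prevalent.
* **Flag-0 episodes count toward ascertainment** (`Hx`/`Fu`/`Any` and
  `count`): a self-reported prevalent disease must produce a case even
  without a usable date. Only the per-year timeline excludes them, since
  an imputed visit date says nothing about when the event happened.
* **Status encoding**: the summary has exactly the 16 canonical columns;
  exclusion negates the `Hx`/`Fu`/`Ref`/`Any` indicators, so `Any` is the
  overall status (2/1/−2/−1) and downstream code can keep filtering on
  `Hx > 0` as established practice does.
* **Composite algebra**: candidate cases = own matches ∪ (recursive)
  include-trait matches, restricted to the study population when given;
  case exclusion then control exclusion follow. The test suite checks this
  against an independently written set-algebra oracle on randomized
  composite definitions.
* **Minimum-instance filter**: a per-source threshold (`min_instances`)
  drops a participant's episodes from a source unless that source supplies
  at least the threshold — a crude but useful reliability weight for noisy
  sources such as single GP mentions.

Follow-up derivation is deliberately separate: for non-events, observed
time runs to the earlier of death and the region's secondary-care
censoring date (both configuration; defaults are the England/Scotland
2021-03-31 and Wales 2018-02-28 dates with the standard centre-to-region
map). A non-event who dies before censoring is censored at death; events
keep their `Fu_days`.

# The synthetic world

`generate_cohort()` emits every input format with ground truth. What it
emulates: per-trait baseline prevalence and post-baseline incidence;
evidence scattered over a configurable subset of sources with at least one
source forced; duplicate records; self-report timing missingness (special
code −1, 15% by default); dot-padded primary-care codes; noise episodes
drawn from map codes no definition uses; deaths with primary/contributory
causes; a withdrawal list (`round(n × fraction)` identifiers).

Defaults are fixed once: 500 participants, visits 2008–2010, births
1940–1965 (ages ≈ 43–70 at baseline), censoring 2021-03-31, five traits
with prevalences 1–5% and incidences 2–5 per 1000 person-years — orders of
magnitude a cardiometabolic phenotyping study would recognise, scaled so a
desk-size cohort still contains cases.

Two generator choices protect truth recovery and are worth knowing:
self-reported timing is withheld (flag 0) when mid-year imputation could
cross the visit date, and touchscreen age-of-diagnosis values are floored
so the interpolated date cannot overshoot the onset. Incident cases never
carry self-report or touchscreen evidence (one cannot report a future
diagnosis at baseline).

What the generator does *not* emulate — and hence what a green end-to-end
test does **not** establish: disease co-occurrence and confounding
structure, coding-practice drift over calendar time, regionally varying
primary-care coverage, contradictory records (e.g. simultaneous type 1 and
type 2 specific codes arise only via the explicit exclusion-injection
knob), free-text or mis-coded entries beyond flat noise, and genuine
date errors. Recovery being exact on this world validates the *plumbing
and the algebra*, not the clinical validity of any particular codelist.

# Numerical and degenerate-input choices

* Dates are ISO-8601 only; anything else fails loudly. Silent locale
  guessing is a correctness hazard in multi-source data.
* An empty withdrawal list, missing optional record files, and a
  main-dataset-only invocation are all valid; missing *definition* fields
  in the main dataset are fatal unless `allow_missing = TRUE` (then warned
  and skipped).
* Ties in the individual timeline sort by source id then code, making
  output byte-stable; identical inputs give byte-identical status tables.
* `median.epidur` is numeric (a median of an even count of days is
  fractional); `sum.epidur ≥ max.epidur ≥ median.epidur` whenever any
  hospital episode matched.

# Known limitations

* Status is presence-based: contradictory diagnoses produce participants
  excluded from cases rather than adjudicated ones; refinement is left to
  the analyst, as in the source protocol.
* Weighting is per source (minimum instances), not per code.
* Cancer-registry fields, COVID-19 results and cross-system code mapping
  are out of scope, as are figure aesthetics (the reporting layer renders
  plain base-graphics conveniences; all numbers live in the tables).
* The html metadata parser targets the simple table layout the generator
  emits; the TSV catalog is the stable contract for other layouts.
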
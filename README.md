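# cohortpheno

Phenotype ascertainment for biobank-scale cohorts from harmonized clinical
records.

Large population cohorts (the UK Biobank being the archetype) scatter the
evidence for a single health outcome across many places: self-reported
illnesses, medications and operations from a nurse interview, touchscreen
questionnaire answers, hospital inpatient episodes coded in ICD-9/ICD-10 and
OPCS-4, primary-care events in READ2/CTV3, prescriptions, and the death
register. `cohortpheno` turns a *machine-actionable definition table* — one
row per trait, with per-coding-system codelists, self-report field
specifications, touchscreen conditions and composite references — into
case/control status for every participant, with prevalent/incident/
time-to-event semantics. Everything is testable offline: a synthetic cohort
generator emits every input format with known ground truth.

## The model in brief

1. **Codelist expansion.** For hierarchical systems, a parent code stands
   for all its descendants by prefix (`E11` → `E11, E110, E119`; READ
   dot-padding `G573.` ≡ `G573*`). Expansion happens once at parse time
   against per-system code maps; unknown codes are dropped with a warning.
2. **Episode harmonization.** Every source is converted to one schema —
   `.id, identifier, code, eventdate, event, epidur, classification` — with
   the `event` flag recording date provenance: `1` true date from linked
   records (or a self-reported operation), `2` self-reported event date
   (year/age of diagnosis, interpolated), `0` imputed assessment-centre
   visit date. `epidur` is days hospitalized (hospital episodes only).
3. **Ascertainment.** For a trait *T* with reference dates *r(i)*:
   candidate cases are participants matching *T*'s codes or any
   `Include_definitions` trait; `Exclude_from_cases` / `Exclude_from_controls`
   remove candidates / controls carrying the named traits;
   `Study_population` restricts the base population. Each participant gets
   the 16-field summary (episode count, hospitalization aggregates, death
   indicators, `Hx`/`Fu`/`Ref`/`Any` indicators, signed days to first
   diagnosis). Status is carried in the indicators: included case/control
   `2`/`1`, excluded `-2`/`-1` (read it off the `Any` column or
   `cc_status()`).
4. **Follow-up.** Observed time for survival analysis runs to the event,
   or for non-events to the earlier of death and the region's
   secondary-care censoring date (England/Scotland 2021-03-31, Wales
   2018-02-28 by default; both configurable).

## Worked example (fully synthetic)

```r
library(cohortpheno)
library(data.table)

settings <- read_data_settings(example_data_settings())
defset   <- read_definition_table(example_definitions(), settings,
                                  example_codemap_dir())

f <- as.list(generate_cohort(synth_config(n = 500, seed = 1),
                             file.path(tempdir(), "demo"))$files)
hz <- harmonize_all(f$main, f$metadata_html, defset, settings,
                    f.hesin = f$hesin, f.hesin_diag = f$hesin_diag,
                    f.hesin_oper = f$hesin_oper,
                    f.gp_clinical = f$gp_clinical,
                    f.gp_scripts = f$gp_scripts,
                    f.death = f$death, f.death_cause = f$death_cause,
                    f.withdrawal = f$withdrawal)
hz
#> <harmonized_data> 495 participants, 12 episode source(s)
#>   hesin_icd10                      257 episodes
#>   hesin_icd9                        66 episodes
#>   hesin_oper                        31 episodes
#>   gpclinical.read2                 178 episodes
#>   ...
```

495 of 500 participants remain: the 5 on the generated withdrawal list are
purged from every table. Ascertain type 2 diabetes with the composite
definition `DmRxT2` (own T2D codes, oral antidiabetic users included as
cases, type 1 diabetics excluded from cases, any antidiabetic-medication
user excluded from controls), using each participant's baseline visit as
the reference date:

```r
refs <- hz$dfukb[, .(identifier, f.53.0.0)]
res  <- get_cases_controls(defset, "DmRxT2", hz, settings, refs)
res
#> <case_control_result> 495 participants: 93 cases (0 excluded),
#>                       402 controls (12 excluded)

res$df.casecontrol[Any == 2][1:3,
  .(identifier, count, Hx, Fu, Hx_days, first_diagnosis_days, Any)]
#>    identifier count    Hx    Fu Hx_days first_diagnosis_days   Any
#> 1:    1000016     4     1     2      NA                 1112     2
#> 2:    1000019     5     2     1     760                 -760     2
#> 3:    1000025     4     1     2      NA                 1703     2
```

Participant `1000019` is a *prevalent* case (`Hx = 2`): their first
diagnosis was 760 days before the baseline visit (negative
`first_diagnosis_days`). `1000016` is *incident* (`Fu = 2`), first
diagnosed 1112 days after baseline. The 12 excluded controls (`Any = -1`)
carry antidiabetic-medication evidence without a type-2-specific code. Code
frequencies among case events:

```r
head(event_stats(res$all_event_dt.Include_in_cases), 3)
#>    classification     code n_events n_participants frac_cases
#> 1:           icd9    25002       36             27  0.2903226
#> 2:           icd9    25000       30             26  0.2795699
#> 3:            dmd met00001       29             25  0.2688172
```

## Command line

```sh
cohortpheno synth --n 500 --seed 1 --out fixtures/
cohortpheno codes extract --records gp_clinical.txt --columns read_2,read_3 --out maps/
cohortpheno harmonize --main main.tab --metadata metadata.html --out harmonized/
cohortpheno phenotype --trait DmRxT2 --main main.tab --metadata metadata.html \
    --hesin hesin.txt --hesin-diag hesin_diag.txt --out pheno/
```

See the methods vignette (`vignettes/phenotyping-methods.Rmd`) for the
modelling choices, generator assumptions and known limitations.
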
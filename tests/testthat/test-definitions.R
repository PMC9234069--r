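test_that("parse_code_entry handles commas, annotations and errors", {
  p <- parse_code_entry("K621, K622, K623")
  expect_identical(p$code, c("K621", "K622", "K623"))
  expect_true(all(is.na(p$annotation)))

  p2 <- parse_code_entry("E11(type 2 code)")
  expect_identical(p2$code, "E11")
  expect_identical(p2$annotation, "type 2 code")

  expect_identical(nrow(parse_code_entry("")), 0L)
  expect_identical(nrow(parse_code_entry(NA)), 0L)
  expect_error(parse_code_entry("E11(oops"), "unbalanced")
})

test_that("parse_field_spec: coded and bare field forms", {
  fs <- parse_field_spec("20002(1471, 1483)")
  expect_identical(fs$field_id, 20002L)
  expect_identical(fs$codes, c("1471", "1483"))
  expect_false(fs$any)

  bare <- parse_field_spec("20003")
  expect_true(bare$any)
  expect_identical(bare$codes, character())

  expect_identical(parse_field_spec("20004(1070, 1095, 1523)")$codes,
                   c("1070", "1095", "1523"))
  expect_error(parse_field_spec("abc(1)"), "malformed")
})

test_that("parse_condition: comparators, age field, aliases", {
  c1 <- parse_condition("6177=3(insulin)")
  expect_identical(c1[c("field_id", "comparator", "value", "annotation")],
                   list(field_id = 6177L, comparator = "=", value = "3",
                        annotation = "insulin"))
  expect_identical(c1$canonical, "6177=3")

  c2 <- parse_condition("4041=1[2976](Gestational diabetes)")
  expect_identical(c2$age_field, 2976L)
  expect_identical(c2$canonical, "4041=1[2976]")

  expect_identical(parse_condition("21003>=40")$comparator, ">=")
  expect_identical(parse_condition("21003≥40")$comparator, ">=")
  expect_identical(parse_condition("21003≤40")$comparator, "<=")
  expect_error(parse_condition("6177~3"), "=")
})

test_that("read_definition_table expands codes and reports problems", {
  w <- example_world()
  d <- w$defset$definitions$DmT2
  expect_setequal(d$code_sets$icd10, c("E11", "E110", "E119"))
  expect_setequal(d$code_sets$read2, c("C10F.", "C10F9", "C10FJ"))

  ## misspelled code: dropped with warning, kept in the report
  bad <- tmpfile(c("TRAIT\tICD10\tSR\tTS",
                   "X1\tE11, I2X5\t\t"))
  expect_warning(ds <- read_definition_table(bad, w$settings,
                                             example_codemap_dir()),
                 "I2X5")
  expect_identical(ds$report$dropped_codes$code, "I2X5")
  expect_setequal(ds$definitions$X1$code_sets$icd10, c("E11", "E110", "E119"))

  dup <- tmpfile(c("TRAIT\tICD10", "Af\tI48", "Af\tI50"))
  expect_error(read_definition_table(dup, w$settings, example_codemap_dir()),
               "duplicate TRAIT")

  unk <- tmpfile(c("TRAIT\tICD10\tInclude_definitions", "A\tE11\tNoSuch"))
  expect_error(read_definition_table(unk, w$settings, example_codemap_dir()),
               "NoSuch")

  extra <- tmpfile(c("TRAIT\tICD10\tBOGUS", "A\tE11\tx"))
  expect_warning(read_definition_table(extra, w$settings,
                                       example_codemap_dir()),
                 "BOGUS")
})

test_that("plan_composite orders dependencies and detects cycles", {
  w <- example_world()
  plan <- plan_composite(w$defset, "DmRxT2")
  expect_identical(tail(plan, 1), "DmRxT2")
  expect_true(all(c("DmT1", "RxDm", "RxDmOr") %in% head(plan, -1)))
  ## every edge points backwards in the plan
  for (t in plan) {
    d <- w$defset$definitions[[t]]
    refs <- c(d$include_definitions, d$exclude_from_cases,
              d$exclude_from_controls,
              if (!is.na(d$study_population)) d$study_population)
    for (r in refs) expect_lt(match(r, plan), match(t, plan))
  }
  expect_identical(plan_composite(w$defset, "Af"), "Af")

  cyc <- tmpfile(c("TRAIT\tICD10\tInclude_definitions",
                   "A\tE11\tB", "B\tE10\tA"))
  ds <- read_definition_table(cyc, w$settings, example_codemap_dir())
  expect_error(plan_composite(ds, "A"), "cyclic")
  expect_error(plan_composite(ds, "Nope"), "unknown trait")
})

test_that("definition sets round-trip through serialization", {
  w <- example_world()
  p <- tempfile(fileext = ".tsv")
  write_definition_table(w$defset, p)
  again <- suppressWarnings(read_definition_table(p, w$settings,
                                                  example_codemap_dir()))
  expect_equal(again$definitions, w$defset$definitions)
  expect_identical(again$traits, w$defset$traits)
})
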
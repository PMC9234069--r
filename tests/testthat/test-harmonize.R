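st_example <- function() example_world()$settings

test_that("harmonize_hesin joins, dates and epidur behave", {
  master <- data.frame(
    eid = c("1", "1", "2"), ins_index = c("0", "1", "0"),
    epistart = c("2010-01-01", "", "2012-03-01"),
    epiend = c("2010-01-11", "", "2012-03-04"),
    admidate = c("2010-01-01", "2011-05-01", "2012-03-01"),
    disdate = c("2010-01-11", "2011-05-06", "2012-03-04"))
  diag <- data.frame(eid = c("1", "1", "2", "3"),
                     ins_index = c("0", "1", "0", "0"),
                     level = c("1", "2", "1", "1"),
                     diag_icd9 = c("", "", "4273", ""),
                     diag_icd10 = c("I480", "I50", "", "E11"))
  oper <- data.frame(eid = "2", ins_index = "0", level = "1", oper4 = "K621")
  eps <- suppressMessages(harmonize_hesin(master, diag, oper, st_example()))

  e1 <- eps[.id == "hesin_icd10" & code == "I480"]
  expect_identical(as.character(e1$eventdate), "2010-01-01")
  expect_identical(e1$epidur, 10L)
  expect_identical(e1$event, 1L)

  ## missing episode start falls back to admission date
  e2 <- eps[code == "I50"]
  expect_identical(as.character(e2$eventdate), "2011-05-01")
  expect_identical(e2$epidur, 5L)

  expect_identical(eps[.id == "hesin_icd9", code], "4273")
  expect_identical(eps[.id == "hesin_oper", classification], "opcs4")
  ## orphan diagnosis (eid 3) dropped with a message
  expect_false("E11" %in% eps$code)
  expect_message(harmonize_hesin(master, diag, NULL, st_example()), "orphan")
})

test_that("harmonize_gp emits one episode per filled code column", {
  clin <- data.frame(eid = c("1", "1", "2"),
                     event_dt = c("2001-02-03", "2002-03-04", "2003-04-05"),
                     read_2 = c("G573.", "", ""),
                     read_3 = c("XaEga", "X40J5", ""))
  eps <- harmonize_gp(clin, NULL, st_example())
  expect_identical(nrow(eps), 3L)          # row 3 has no codes
  both <- eps[identifier == "1" & as.character(eventdate) == "2001-02-03"]
  expect_identical(nrow(both), 2L)         # read_2 + read_3 on one row
  expect_setequal(both$classification, c("read2", "read3"))
  expect_true(all(eps$event == 1L))

  scr <- data.frame(eid = "2", issue_date = "2010-06-07",
                    dmd_code = "met00001")
  eps2 <- harmonize_gp(NULL, scr, st_example())
  expect_identical(eps2$.id, "gpscripts")
  expect_identical(eps2$classification, "dmd")

  nodate <- data.frame(eid = "1", event_dt = "", read_2 = "G573.",
                       read_3 = "")
  expect_message(out <- harmonize_gp(nodate, NULL, st_example()), "no event date")
  expect_identical(nrow(out), 0L)
})

test_that("harmonize_death splits primary and contributory causes", {
  death <- data.frame(eid = c("1", "2"),
                      date_of_death = c("2020-03-01", "2019-01-01"))
  cause <- data.frame(eid = c("1", "1", "3"), level = c("1", "2", "1"),
                      cause_icd10 = c("I50", "E119", "I21"))
  expect_warning(eps <- harmonize_death(death, cause, st_example()),
                 "no death date")
  expect_identical(eps[.id == "tte.death.icd10.primary", code], "I50")
  expect_identical(eps[.id == "tte.death.icd10.secondary", code], "E119")
  expect_identical(as.character(eps$eventdate), rep("2020-03-01", 2))
  expect_false("I21" %in% eps$code)
})

sr_fixture <- function() {
  rows <- data.frame(
    column = c("f.eid", "f.53.0.0", "f.34.0.0", "f.52.0.0",
               "f.20002.0.0", "f.20008.0.0", "f.20004.0.0", "f.20010.0.0",
               "f.20003.0.0", "f.6177.0.0", "f.4041.0.0", "f.2976.0.0"),
    type = c("text", "date", "integer", "integer", "integer", "real",
             "integer", "integer", "integer", "integer", "integer", "real"))
  meta <- tmpfile(c("column_label\ttype",
                    paste(rows$column, rows$type, sep = "\t")))
  cat <- read_field_catalog(meta)
  tab <- tmpfile(c(
    paste(rows$column, collapse = "\t"),
    "1\t2009-06-15\t1950\t\t1223\t2005\t1095\t2010\t1140884600\t3\t1\t40",
    "2\t2010-01-10\t1960\t4\t1471\t-1\t\t\t\t-3\t0\t"))
  list(participants = read_main_dataset(
    tab, cat, c(53, 34, 52, 20002, 20008, 20004, 20010, 20003, 6177, 4041,
                2976)), catalog = cat)
}

test_that("self-report episodes: timing interpolation and event flags", {
  fx <- sr_fixture()
  eps <- harmonize_self_report(fx$participants, fx$catalog, st_example())

  ## illness with a year: July 1 of that year, flag 2
  e <- eps[.id == "sr_20002" & identifier == "1"]
  expect_identical(as.character(e$eventdate), "2005-07-01")
  expect_identical(e$event, 2L)
  ## operation with a year: flag 1
  op <- eps[.id == "sr_20004" & identifier == "1"]
  expect_identical(op$event, 1L)
  expect_identical(as.character(op$eventdate), "2010-07-01")
  ## medication has no timing wiring: visit date, flag 0
  med <- eps[.id == "sr_20003" & identifier == "1"]
  expect_identical(med$event, 0L)
  expect_identical(as.character(med$eventdate), "2009-06-15")
  ## timing -1 means missing: visit date, flag 0
  e2 <- eps[.id == "sr_20002" & identifier == "2"]
  expect_identical(e2$event, 0L)
  expect_identical(as.character(e2$eventdate), "2010-01-10")
})

test_that("touchscreen conditions: comparisons, ages, special codes", {
  fx <- sr_fixture()
  ## 6177=3 holds for participant 1 only (-3 is a special code, not a 3)
  eps <- evaluate_touchscreen(fx$participants, parse_condition("6177=3"),
                              fx$catalog)
  expect_identical(eps$identifier, "1")
  expect_identical(eps$event, 0L)
  expect_identical(as.character(eps$eventdate), "2009-06-15")
  expect_identical(eps$code, "6177=3")

  ## age interpolation: birth 1950 (no month -> July 1) + 40 * 365.25 days
  ep2 <- evaluate_touchscreen(fx$participants,
                              parse_condition("4041=1[2976]"), fx$catalog)
  expect_identical(ep2$identifier, "1")
  expect_identical(as.character(ep2$eventdate), "1990-07-01")
  expect_identical(ep2$event, 2L)

  ## negative special answers never satisfy a condition, even "!="
  ep3 <- evaluate_touchscreen(fx$participants, parse_condition("6177!=0"),
                              fx$catalog)
  expect_identical(ep3$identifier, "1")

  expect_error(evaluate_touchscreen(fx$participants,
                                    parse_condition("6177=abc"), fx$catalog),
               "not numeric")
})

test_that("harmonize_all: container shape, withdrawals, minimal inputs", {
  co <- shared_cohort()
  hz <- co$hz
  expect_s3_class(hz, "harmonized_data")
  expect_identical(names(hz), c("lst.data", "dfukb", "vct.identifiers"))
  expect_gte(length(hz$lst.data), 6L)
  ## every episode belongs to a known participant, none withdrawn
  withdrawn <- read_withdrawals(co$files$withdrawal)
  expect_gt(length(withdrawn), 0L)
  for (src in names(hz$lst.data)) {
    eps <- hz$lst.data[[src]]
    expect_true(all(eps$identifier %in% hz$vct.identifiers))
    expect_identical(intersect(eps$identifier, withdrawn), character())
    expect_true(all(eps$event %in% 0:2))
    expect_true(all(is.na(eps$epidur) | eps$epidur >= 0))
    expect_false(any(is.na(eps$eventdate)))
  }
  expect_identical(intersect(hz$vct.identifiers, withdrawn), character())
  ## epidur only on hospital episodes
  for (src in setdiff(names(hz$lst.data),
                      c("hesin_icd10", "hesin_icd9", "hesin_oper"))) {
    expect_true(all(is.na(hz$lst.data[[src]]$epidur)))
  }

  ## minimal invocation: main + metadata only
  w <- example_world()
  hz0 <- suppressWarnings(harmonize_all(co$files$main,
                                        co$files$metadata_tsv,
                                        w$defset, w$settings))
  expect_identical(names(hz0), c("lst.data", "dfukb", "vct.identifiers"))
  record_srcs <- c("hesin_icd10", "hesin_icd9", "hesin_oper",
                   "gpclinical.read2", "gpclinical.read3", "gpscripts",
                   "tte.death.icd10.primary", "tte.death.icd10.secondary")
  expect_identical(intersect(names(hz0$lst.data), record_srcs), character())
})

test_that("event flags follow the per-source date-provenance rule", {
  hz <- shared_cohort()$hz
  flag_rule <- list(hesin_icd10 = 1L, hesin_icd9 = 1L, hesin_oper = 1L,
                    gpclinical.read2 = 1L, gpclinical.read3 = 1L,
                    gpscripts = 1L, tte.death.icd10.primary = 1L,
                    tte.death.icd10.secondary = 1L)
  for (src in intersect(names(flag_rule), names(hz$lst.data))) {
    expect_true(all(hz$lst.data[[src]]$event == flag_rule[[src]]),
                label = src)
  }
  ## self-report illness: 2 with a true date, else 0; operations: 1 or 0
  if ("sr_20002" %in% names(hz$lst.data)) {
    expect_true(all(hz$lst.data$sr_20002$event %in% c(0L, 2L)))
  }
  if ("sr_20004" %in% names(hz$lst.data)) {
    expect_true(all(hz$lst.data$sr_20004$event %in% c(0L, 1L)))
  }
  if ("ts" %in% names(hz$lst.data)) {
    expect_true(all(hz$lst.data$ts$event %in% c(0L, 2L)))
  }
})
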
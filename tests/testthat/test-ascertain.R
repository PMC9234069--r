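mk_events <- function(id, dates, src = "hesin_icd10", code = "E110",
                      event = 1L, epidur = NA_integer_, cls = "icd10") {
  data.table::data.table(
    .id = src, identifier = id, code = code,
    eventdate = data.table::as.IDate(dates), event = event,
    epidur = as.integer(epidur), classification = cls)
}

test_that("match_episodes: set lookup, min-instance filter, field specs", {
  w <- example_world()
  lst <- list(
    hesin_icd10 = mk_events(c("a", "b"), c("2010-01-01", "2011-01-01"),
                            code = c("E110", "J450")),
    gpclinical.read2 = mk_events(c("a", "c"), c("2009-01-01", "2009-06-01"),
                                 src = "gpclinical.read2",
                                 code = c("C10F9", "C10F9"), cls = "read2"),
    sr_20002 = mk_events(c("d"), "2008-07-01", src = "sr_20002",
                         code = "1223", event = 2L, cls = "sr"))
  m <- match_episodes(w$defset$definitions$DmT2, lst, w$settings)
  expect_setequal(unique(m$identifier), c("a", "c", "d"))
  expect_false("J450" %in% m$code)        # not a diabetes code

  ## raising min_instances for the GP source removes single-episode carriers
  st2 <- data.table::copy(w$settings)
  st2[source_id == "gpclinical.read2", min_instances := 2L]
  m2 <- match_episodes(w$defset$definitions$DmT2, lst, st2)
  expect_false("c" %in% m2$identifier)    # only 1 GP episode
  expect_true("a" %in% m2$identifier)     # still matched via hospital

  ## READ2 dot-padding matches across dialects
  lstd <- list(gpclinical.read2 = mk_events("z", "2009-01-01",
                                            src = "gpclinical.read2",
                                            code = "C10F", cls = "read2"))
  expect_identical(match_episodes(w$defset$definitions$DmT2, lstd,
                                  w$settings)$identifier, "z")
})

test_that("summarize_participant computes the 16-field record", {
  ref <- data.table::as.IDate("2010-01-01")
  ## single event one year before reference
  s1 <- summarize_participant(mk_events("p", "2009-01-01"), ref)
  expect_identical(ncol(s1), 16L)
  expect_identical(s1$Hx, 2L)
  expect_identical(s1$Hx_days, 365L)
  expect_identical(s1$first_diagnosis_days, -365L)
  expect_identical(s1$Any, 2L)
  expect_identical(s1$Fu, 1L)
  expect_true(is.na(s1$Fu_days))

  ## events only after reference: incident
  s2 <- summarize_participant(
    mk_events("p", c("2010-04-11", "2010-07-20")), ref)
  expect_identical(s2$Fu, 2L)
  expect_identical(s2$Fu_days, 100L)
  expect_identical(s2$Hx, 1L)
  expect_identical(s2$first_diagnosis_days, 100L)

  ## hospitalization aggregates
  s3 <- summarize_participant(
    mk_events("p", c("2009-01-01", "2009-02-01", "2009-03-01"),
              epidur = c(3L, 5L, 10L)), ref)
  expect_identical(s3$sum.epidur, 18L)
  expect_identical(s3$median.epidur, 5)
  expect_identical(s3$max.epidur, 10L)

  ## event on the reference date: prevalent and Ref-flagged
  s4 <- summarize_participant(mk_events("p", "2010-01-01"), ref)
  expect_identical(s4$Hx, 2L)
  expect_identical(s4$Ref, 2L)

  ## death-source events fill the death fields
  s5 <- summarize_participant(
    mk_events("p", "2012-01-01", src = "tte.death.icd10.primary"), ref)
  expect_identical(s5$Death_primary, 2L)
  expect_identical(s5$Death_any, 2L)
  expect_identical(s5$survival_days, 730L)

  expect_error(summarize_participant(mk_events("p", character()), ref),
               "at least one")
  expect_error(summarize_participant(
    mk_events(c("p", "q"), c("2009-01-01", "2009-01-01")), ref),
    "single participant")
})

## hand-built mini-cohort exercising the composite algebra end to end
mini_world <- function() {
  w <- example_world()
  lst <- list(
    hesin_icd10 = mk_events(
      c("case1", "case1", "case2", "t1dm", "ctrl_rx"),
      c("2005-01-01", "2006-01-01", "2012-05-01", "2004-01-01", "2001-01-01"),
      code = c("E110", "E119", "E11", "E100", "J450"),
      epidur = c(3L, 7L, 1L, 2L, 1L)),
    gpscripts = mk_events(c("oralmed", "ctrl_rx"),
                          c("2007-03-01", "2007-04-01"), src = "gpscripts",
                          code = c("met00001", "ins00001"), cls = "dmd"),
    sr_20002 = mk_events("t1dm", "2008-07-01", src = "sr_20002",
                         code = "1222", event = 2L, cls = "sr"))
  ## t1dm also carries a type 2 code, so they are a candidate to exclude
  lst$hesin_icd10 <- rbind(lst$hesin_icd10,
                           mk_events("t1dm", "2006-06-01", code = "E119"))
  ids <- c("case1", "case2", "t1dm", "oralmed", "ctrl_rx", "clean")
  hz <- structure(list(lst.data = lst,
                       dfukb = data.table::data.table(identifier = ids),
                       vct.identifiers = ids),
                  class = "harmonized_data")
  list(w = w, hz = hz, ids = ids,
       refs = data.table::data.table(
         identifier = ids, reference_date = data.table::as.IDate("2010-01-01")))
}

test_that("get_cases_controls applies the composite algebra", {
  mw <- mini_world()
  res <- get_cases_controls(mw$w$defset, "DmRxT2", mw$hz, mw$w$settings,
                            mw$refs)
  expect_s3_class(res, "case_control_result")
  expect_identical(names(res),
                   c("df.casecontrol", "all_event_dt.Include_in_cases",
                     "all_event_dt.Include_in_cases.summary"))
  st <- cc_status(res)
  expect_identical(st[["case1"]], 2L)     # own T2D codes
  expect_identical(st[["case2"]], 2L)     # incident T2D
  expect_identical(st[["oralmed"]], 2L)   # included via RxDmOr
  expect_identical(st[["t1dm"]], -2L)     # excluded case (T1D evidence)
  expect_identical(st[["ctrl_rx"]], -1L)  # control on insulin, excluded
  expect_identical(st[["clean"]], 1L)

  cc <- res$df.casecontrol
  expect_identical(ncol(cc), 16L)
  expect_identical(sort(cc$identifier), sort(mw$ids))
  ## prevalent vs incident split
  expect_identical(cc[identifier == "case1", Hx], 2L)
  expect_identical(cc[identifier == "case2", Fu], 2L)
  expect_identical(cc[identifier == "case1", count], 2L)
  expect_identical(cc[identifier == "case1", sum.epidur], 10L)
  ## control rows carry the no-evidence defaults
  expect_identical(cc[identifier == "clean", count], 0L)
  expect_true(is.na(cc[identifier == "clean", Hx_days]))

  ## event table: included cases only; summary: all cases incl. excluded
  expect_false("t1dm" %in% res$all_event_dt.Include_in_cases$identifier)
  expect_setequal(res$all_event_dt.Include_in_cases.summary$identifier,
                  c("case1", "case2", "oralmed", "t1dm"))

  ## study-population restriction: heart failure within diabetes
  resp <- get_cases_controls(mw$w$defset, "HfInDm", mw$hz, mw$w$settings,
                             mw$refs)
  expect_true(all(resp$df.casecontrol$identifier %in%
                    c("case1", "case2", "t1dm", "oralmed")))

  expect_error(get_cases_controls(mw$w$defset, "NoSuch", mw$hz,
                                  mw$w$settings, mw$refs), "unknown trait")
})

test_that("statuses equal the set-algebra oracle on the mini cohort", {
  mw <- mini_world()
  for (trait in c("DmRxT2", "DmT2", "RxDm", "Dm", "HfInDm")) {
    res <- get_cases_controls(mw$w$defset, trait, mw$hz, mw$w$settings,
                              mw$refs)
    st <- cc_status(res)
    or <- oracle_statuses(mw$w$defset, trait, mw$hz$lst.data, mw$w$settings,
                          mw$refs$identifier)
    expect_identical(st[sort(names(st))], or[sort(names(or))], label = trait)
  }
})

test_that("ascertainment is deterministic and internally consistent", {
  co <- shared_cohort()
  w <- example_world()
  r1 <- get_cases_controls(w$defset, "DmRxT2", co$hz, w$settings, co$refs)
  r2 <- get_cases_controls(w$defset, "DmRxT2", co$hz, w$settings, co$refs)
  f1 <- tempfile(); f2 <- tempfile()
  data.table::fwrite(r1$df.casecontrol, f1)
  data.table::fwrite(r2$df.casecontrol, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  cc <- r1$df.casecontrol
  ## status partition
  expect_identical(anyDuplicated(cc$identifier), 0L)
  expect_true(all(cc$Any %in% c(2L, 1L, -1L, -2L)))
  ## count >= 1 iff case
  expect_identical(cc$count >= 1L, abs(cc$Any) == 2L)
  ## Hx_days mirrors first_diagnosis_days for prevalent cases
  prev <- cc[!is.na(Hx_days)]
  expect_identical(prev$Hx_days, -prev$first_diagnosis_days)
  ## epidur aggregate ordering
  hosp <- cc[!is.na(sum.epidur)]
  expect_true(all(hosp$sum.epidur >= hosp$max.epidur))
  expect_true(all(hosp$max.epidur >= hosp$median.epidur))
})

test_that("event_stats, timelines and overlaps", {
  ev <- mk_events(c("a", "a", "a", "b"),
                  c("2010-01-01", "2010-06-01", "2011-01-01", "2010-03-01"),
                  code = c("E119", "E119", "E119", "E110"))
  st <- event_stats(ev)
  expect_identical(st$code[1], "E119")
  expect_identical(st$n_events[1], 3L)
  expect_identical(st$n_participants[1], 1L)
  expect_true(all(st$n_participants <= 2L))
  expect_identical(nrow(event_stats(ev[0])), 0L)

  ## timeline: event-flag-0 episodes are excluded, grid spans years
  w <- example_world()
  lst <- list(
    hesin_icd10 = mk_events(c("a", "a", "b"),
                            c("2010-02-01", "2010-11-01", "2012-01-01")),
    sr_20002 = mk_events("c", "2011-01-01", src = "sr_20002", code = "1223",
                         event = 0L, cls = "sr"))
  tc <- timeline_counts(w$defset$definitions$DmT2, lst, w$settings)
  expect_identical(tc[year == 2010 & source_id == "hesin_icd10", n], 2L)
  expect_false("sr_20002" %in% tc$source_id)
  expect_identical(sort(unique(tc$year)), 2010:2012)
  empty <- timeline_counts(w$defset$definitions$DmT2,
                           list(hesin_icd10 = mk_events("a", "2010-01-01")[0]),
                           w$settings)
  expect_identical(nrow(empty), 0L)

  ## overlap matrix: pre-reference evidence only, row sums >= 1
  mw <- mini_world()
  om <- source_overlap_matrix(mw$w$defset$definitions$DmRxT2, mw$hz,
                              mw$w$settings, mw$refs)
  expect_true("case1" %in% om$identifier)
  expect_false("case2" %in% om$identifier)   # incident only
  mat <- as.matrix(om[, -1, with = FALSE])
  expect_true(all(rowSums(mat) >= 1))
})

test_that("individual_timeline sorts by date with stable tie-breaks", {
  lst <- list(
    b_src = mk_events(c("p", "p"), c("2010-01-01", "2009-01-01"),
                      src = "b_src"),
    a_src = mk_events("p", "2010-01-01", src = "a_src", code = "A1"))
  tl <- individual_timeline(lst, "p")
  expect_identical(nrow(tl), 3L)
  expect_identical(as.character(tl$eventdate[1]), "2009-01-01")
  ## tie on date: source id a_src before b_src
  expect_identical(tl$.id[2:3], c("a_src", "b_src"))
  expect_identical(nrow(individual_timeline(lst, "nobody")), 0L)
})

test_that("batch mode prefixes columns per trait", {
  mw <- mini_world()
  wide <- get_cases_controls_batch(mw$w$defset, c("DmT2", "Af"), mw$hz,
                                   mw$w$settings, mw$refs)
  expect_true(all(c("DmT2_0_Any", "DmT2_0_Hx", "Af_0_Any") %in% names(wide)))
  expect_identical(nrow(wide), length(mw$ids))
})
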
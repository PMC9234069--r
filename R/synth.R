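## Synthetic cohort generator: emits every input format the pipeline reads
## (main dataset + metadata, hospital inpatient trio, primary-care events and
## prescriptions, death register, withdrawal list) with a ground-truth table,
## so harmonization and ascertainment are testable end to end without
## restricted data. Codes are drawn from the bundled toy code maps through
## the bundled definition table, which guarantees that definitions mirror the
## generative code sets exactly.

#' Synthetic-cohort configuration
#'
#' @param n number of participants.
#' @param seed RNG seed; the same seed yields byte-identical output files.
#' @param visit_range baseline-visit date range (ISO strings).
#' @param birth_year_range inclusive birth-year range.
#' @param cohort_start earliest possible onset date for prevalent disease.
#' @param censor_date last date record-level sources are complete.
#' @param traits list of per-trait settings: each a list with `name` (a trait
#'   in the bundled definition table), `prevalence` (baseline probability),
#'   `incidence` (annual post-baseline hazard) and `sources` (episode sources
#'   that may carry evidence).
#' @param source_prob probability each eligible source carries evidence for a
#'   case (at least one source is always forced).
#' @param extra_record_prob probability a case gets a second, later record
#'   from the same source.
#' @param date_missing_prob probability a self-report timing value is a
#'   special code (-1), forcing visit-date imputation (event flag 0).
#' @param noise_rate per-source probability of one non-matching (noise)
#'   episode per participant.
#' @param death_rate probability of death between visit and censoring.
#' @param withdrawal_fraction fraction of participants on the withdrawal
#'   list (count = `round(n * fraction)`).
#' @param n_exclusion number of prevalent cases of `exclusion_target` that
#'   additionally receive hospital evidence of `exclusion_trait` (to test
#'   case exclusion); 0 disables.
#' @param exclusion_target,exclusion_trait trait names for the injection.
#' @param centre_probs sampling weights for England/Scotland/Wales centres.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n = 500, seed = 1,
                         visit_range = c("2008-01-01", "2010-12-31"),
                         birth_year_range = c(1940, 1965),
                         cohort_start = "1995-01-01",
                         censor_date = "2021-03-31",
                         traits = list(
                           list(name = "DmT2", prevalence = 0.05,
                                incidence = 0.005,
                                sources = c("hesin_icd10", "hesin_icd9",
                                            "gpclinical.read2",
                                            "gpclinical.read3", "sr_20002")),
                           list(name = "Af", prevalence = 0.02,
                                incidence = 0.003,
                                sources = c("hesin_icd10", "hesin_oper",
                                            "gpclinical.read2", "sr_20002")),
                           list(name = "Hf", prevalence = 0.015,
                                incidence = 0.004,
                                sources = c("hesin_icd10", "sr_20002",
                                            "sr_20004")),
                           list(name = "RxDmOr", prevalence = 0.03,
                                incidence = 0.004,
                                sources = c("gpscripts", "sr_20003")),
                           list(name = "RxDmIns", prevalence = 0.01,
                                incidence = 0.002,
                                sources = c("gpscripts", "ts"))),
                         source_prob = 0.6, extra_record_prob = 0.5,
                         date_missing_prob = 0.15, noise_rate = 0.25,
                         death_rate = 0.04, withdrawal_fraction = 0.01,
                         n_exclusion = 0, exclusion_target = "DmT2",
                         exclusion_trait = "DmT1",
                         centre_probs = c(england = 0.8, scotland = 0.1,
                                          wales = 0.1)) {
  stopifnot(n >= 1)
  cfg <- as.list(environment())
  probs <- c(vapply(cfg$traits, `[[`, numeric(1), "prevalence"),
             cfg$date_missing_prob, cfg$noise_rate, cfg$death_rate,
             cfg$withdrawal_fraction, cfg$source_prob)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(cfg, class = "synth_config")
}

runif_dates <- function(n, from, to) {
  from <- as.integer(data.table::as.IDate(from))
  to <- as.integer(data.table::as.IDate(to))
  data.table::as.IDate(from + floor(runif(n) * (to - from + 1L)))
}

## noise pools: map codes used by no definition of the bundled set
noise_pools <- function(defset, maps) {
  used <- list()
  for (d in defset$definitions) {
    for (cls in names(d$code_sets)) {
      used[[cls]] <- union(used[[cls]], d$code_sets[[cls]])
    }
  }
  lapply(setNames(names(maps), names(maps)), function(cls)
    setdiff(maps[[cls]]$codes, used[[cls]]))
}

#' Generate a complete synthetic cohort on disk
#'
#' Writes `main.tab`, `metadata.html`, `metadata.tsv`, `hesin.txt`,
#' `hesin_diag.txt`, `hesin_oper.txt`, `gp_clinical.txt`, `gp_scripts.txt`,
#' `death.txt`, `death_cause.txt`, `withdrawals.csv` and `truth.tsv` into
#' `out_dir`, all in the dialects the readers expect. Identical
#' configurations (including the seed) produce byte-identical files.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with `files` (named paths) and `truth`
#'   (data.table: identifier, trait, prevalent, incident, onset_date,
#'   sources, injected_exclusion, withdrawn).
#' @export
generate_cohort <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir),
                                 call. = FALSE)
  set.seed(config$seed)
  settings <- read_data_settings(example_data_settings())
  defset <- suppressWarnings(
    read_definition_table(example_definitions(), settings,
                          example_codemap_dir()))
  maps <- load_settings_codemaps(settings, example_codemap_dir())
  noise <- noise_pools(defset, maps)

  n <- config$n
  ids <- sprintf("1%06d", seq_len(n))
  sex <- rbinom(n, 1L, 0.5)
  birth_year <- sample(seq(config$birth_year_range[1],
                           config$birth_year_range[2]), n, replace = TRUE)
  birth_month <- sample(1:12, n, replace = TRUE)
  visit <- runif_dates(n, config$visit_range[1], config$visit_range[2])
  birth <- data.table::as.IDate(sprintf("%04d-%02d-15", birth_year,
                                        birth_month))
  age <- as.integer(floor(as.numeric(visit - birth) / 365.25))
  cfg_centres <- default_censor_config()$centre_region
  region <- sample(names(config$centre_probs), n, replace = TRUE,
                   prob = config$centre_probs)
  centre <- vapply(region, function(r)
    sample(names(cfg_centres)[cfg_centres == r], 1L), character(1))
  censor <- data.table::as.IDate(config$censor_date)

  ## record accumulators
  hes_master <- list(); hes_diag <- list(); hes_oper <- list()
  gp_clin <- list(); gp_scr <- list()
  sr_rows <- list()       # id, field, code, timing_field, timing_value
  ts_vals <- list()       # field -> numeric vector (length n)
  ts_age <- list()        # age_field -> numeric vector
  truth <- list()
  ins_counter <- setNames(rep(0L, n), ids)

  add_hes <- function(id, code, cls, date) {
    ins_counter[id] <<- ins_counter[id] + 1L
    idx <- ins_counter[id]
    dur <- sample(0:14, 1L)
    hes_master[[length(hes_master) + 1L]] <<- list(
      eid = id, ins_index = idx, epistart = as.character(date),
      epiend = as.character(date + dur), admidate = as.character(date),
      disdate = as.character(date + dur))
    if (cls == "opcs4") {
      hes_oper[[length(hes_oper) + 1L]] <<- list(
        eid = id, ins_index = idx, level = sample(1:2, 1L), oper4 = code)
    } else {
      hes_diag[[length(hes_diag) + 1L]] <<- list(
        eid = id, ins_index = idx, level = sample(1:2, 1L),
        diag_icd9 = if (cls == "icd9") code else "",
        diag_icd10 = if (cls == "icd10") code else "")
    }
  }
  add_gp <- function(id, code, cls, date) {
    gp_clin[[length(gp_clin) + 1L]] <<- list(
      eid = id, data_provider = sample(1:4, 1L),
      event_dt = as.character(date),
      read_2 = if (cls == "read2") code else "",
      read_3 = if (cls == "read3") code else "")
  }
  add_script <- function(id, code, date) {
    gp_scr[[length(gp_scr) + 1L]] <<- list(
      eid = id, data_provider = sample(1:4, 1L),
      issue_date = as.character(date), dmd_code = code)
  }
  sr_timing <- function(src) {
    row <- settings[source_id == src]
    list(field = row$field_id[1], timing = row$timing_field[1])
  }
  add_sr <- function(id, i, src, code, onset) {
    wire <- sr_timing(src)
    tv <- NA_real_
    if (!is.na(wire$timing)) {
      if (runif(1) < config$date_missing_prob ||
          data.table::year(onset) >= data.table::year(visit[i])) {
        ## timing withheld (special code) when missing or when mid-year
        ## imputation could cross the visit date
        tv <- -1
      } else {
        tv <- as.numeric(data.table::year(onset))
      }
    }
    sr_rows[[length(sr_rows) + 1L]] <<- list(
      identifier = id, field = wire$field, code = code,
      timing_field = wire$timing, timing_value = tv)
  }

  pool_for <- function(def, src) {
    switch(src,
      hesin_icd10 = def$code_sets[["icd10"]],
      hesin_icd9 = def$code_sets[["icd9"]],
      hesin_oper = def$code_sets[["opcs4"]],
      gpclinical.read2 = def$code_sets[["read2"]],
      gpclinical.read3 = def$code_sets[["read3"]],
      gpscripts = def$code_sets[["dmd"]],
      sr_20001 = , sr_20002 = , sr_20003 = , sr_20004 = {
        fid <- as.integer(sub("^sr_", "", src))
        unlist(lapply(def$field_specs,
                      function(fs) if (fs$field_id == fid) fs$codes))
      },
      ts = NULL)
  }

  emit_evidence <- function(i, def, src, onset, prevalent) {
    id <- ids[i]
    dmax <- if (prevalent) visit[i] else censor
    extra_date <- runif_dates(1L, onset, dmax)
    ## c() would strip the IDate class; re-wrap
    dates <- data.table::as.IDate(
      c(onset, if (runif(1) < config$extra_record_prob) extra_date))
    if (src == "ts") {
      eqs <- Filter(function(cd) cd$comparator == "=", def$conditions)
      if (length(eqs) == 0L) return(invisible())
      cond <- eqs[[1]]
      f <- as.character(cond$field_id)
      if (is.null(ts_vals[[f]])) ts_vals[[f]] <<- rep(NA_real_, n)
      ts_vals[[f]][i] <<- as.numeric(cond$value)
      if (!is.na(cond$age_field)) {
        af <- as.character(cond$age_field)
        if (is.null(ts_age[[af]])) ts_age[[af]] <<- rep(NA_real_, n)
        ts_age[[af]][i] <<- floor(as.numeric(onset - birth[i]) / 365.25)
      }
      return(invisible())
    }
    pool <- pool_for(def, src)
    if (length(pool) == 0L) return(invisible())
    for (k in seq_along(dates)) {
      d <- dates[k]
      code <- sample(pool, 1L)
      if (startsWith(src, "hesin")) {
        cls <- c(hesin_icd10 = "icd10", hesin_icd9 = "icd9",
                 hesin_oper = "opcs4")[src]
        add_hes(ids[i], code, cls, d)
      } else if (startsWith(src, "gpclinical")) {
        add_gp(ids[i], code, sub("^gpclinical\\.", "", src), d)
      } else if (src == "gpscripts") {
        add_script(ids[i], code, d)
      } else if (startsWith(src, "sr_")) {
        add_sr(ids[i], i, src, code, onset)
        break   # one self-report slot per trait is enough
      }
    }
    invisible()
  }

  for (tc in config$traits) {
    def <- defset$definitions[[tc$name]]
    if (is.null(def)) stop(sprintf("synth trait '%s' not in bundled definitions",
                                   tc$name), call. = FALSE)
    prevalent <- runif(n) < tc$prevalence
    yrs <- as.numeric(censor - visit) / 365.25
    incident <- !prevalent & runif(n) < pmin(1, tc$incidence * yrs)
    onset <- data.table::as.IDate(rep(NA_integer_, n))
    onset[prevalent] <- runif_dates(sum(prevalent), config$cohort_start,
                                    config$visit_range[1])
    ## clamp prevalent onsets to each participant's own visit
    onset[prevalent] <- pmin(onset[prevalent], visit[prevalent])
    onset[incident] <- data.table::as.IDate(
      as.integer(visit[incident]) + 1L +
        floor(runif(sum(incident)) *
                pmax(1, as.integer(censor - visit[incident]) - 1L)))
    for (i in which(prevalent | incident)) {
      elig <- tc$sources
      if (incident[i]) {
        elig <- elig[!startsWith(elig, "sr_") & elig != "ts"]
      }
      if (length(elig) == 0L) elig <- "hesin_icd10"
      use <- elig[runif(length(elig)) < config$source_prob]
      if (length(use) == 0L) use <- sample(elig, 1L)
      for (src in use) emit_evidence(i, def, src, onset[i], prevalent[i])
      truth[[length(truth) + 1L]] <- list(
        identifier = ids[i], trait = tc$name,
        prevalent = as.integer(prevalent[i]),
        incident = as.integer(incident[i]),
        onset_date = as.character(onset[i]),
        sources = paste(use, collapse = ","),
        injected_exclusion = 0L)
    }
  }

  ## exclusion injection: hospital evidence of the exclusion trait
  truth_dt <- data.table::rbindlist(truth)
  injected <- character()
  if (config$n_exclusion > 0) {
    pool_ids <- truth_dt[trait == config$exclusion_target & prevalent == 1L,
                         unique(identifier)]
    if (length(pool_ids) < config$n_exclusion) {
      stop("n_exclusion exceeds the number of prevalent target cases",
           call. = FALSE)
    }
    injected <- sort(sample(pool_ids, config$n_exclusion))
    exdef <- defset$definitions[[config$exclusion_trait]]
    for (id in injected) {
      i <- match(id, ids)
      d <- runif_dates(1L, config$cohort_start, visit[i])
      add_hes(id, sample(exdef$code_sets[["icd10"]], 1L), "icd10", d)
      truth_dt <- rbind(truth_dt, data.table::data.table(
        identifier = id, trait = config$exclusion_trait, prevalent = 1L,
        incident = 0L, onset_date = as.character(d),
        sources = "hesin_icd10", injected_exclusion = 1L))
    }
  }

  ## noise episodes (codes no definition uses)
  for (i in seq_len(n)) {
    if (length(noise$icd10) && runif(1) < config$noise_rate) {
      add_hes(ids[i], sample(noise$icd10, 1L), "icd10",
              runif_dates(1L, config$cohort_start, censor))
    }
    if (length(noise$read2) && runif(1) < config$noise_rate) {
      add_gp(ids[i], sample(noise$read2, 1L), "read2",
             runif_dates(1L, config$cohort_start, censor))
    }
    if (length(noise$dmd) && runif(1) < config$noise_rate) {
      add_script(ids[i], sample(noise$dmd, 1L),
                 runif_dates(1L, config$cohort_start, censor))
    }
  }

  ## deaths
  died <- runif(n) < config$death_rate
  death_date <- data.table::as.IDate(rep(NA_integer_, n))
  death_date[died] <- data.table::as.IDate(
    as.integer(visit[died]) + 1L +
      floor(runif(sum(died)) * pmax(1, as.integer(censor - visit[died]) - 1L)))
  death_rows <- list(); cause_rows <- list()
  dm_cases <- truth_dt[trait == config$traits[[1]]$name, unique(identifier)]
  primary_pool <- defset$definitions[[config$traits[[1]]$name]]$code_sets[["icd10"]]
  for (i in which(died)) {
    id <- ids[i]
    death_rows[[length(death_rows) + 1L]] <- list(
      eid = id, date_of_death = as.character(death_date[i]))
    primary <- if (id %in% dm_cases && length(primary_pool) &&
                   runif(1) < 0.5) sample(primary_pool, 1L)
      else sample(noise$icd10 %||% "R99", 1L)
    cause_rows[[length(cause_rows) + 1L]] <- list(
      eid = id, level = 1L, cause_icd10 = primary)
    if (length(noise$icd10) && runif(1) < 0.3) {
      cause_rows[[length(cause_rows) + 1L]] <- list(
        eid = id, level = 2L, cause_icd10 = sample(noise$icd10, 1L))
    }
  }

  ## assemble the main dataset
  main <- data.table::data.table(
    f.eid = ids, `f.31.0.0` = sex, `f.34.0.0` = birth_year,
    `f.52.0.0` = birth_month, `f.53.0.0` = as.character(visit),
    `f.54.0.0` = centre, `f.21003.0.0` = age)
  ## touchscreen defaults, then case overrides
  base_ts <- list(`2443` = rep(0, n), `4041` = rep(0, n),
                  `6177` = sample(c(-7, 1, 2), n, replace = TRUE,
                                  prob = c(0.6, 0.2, 0.2)))
  for (f in names(base_ts)) {
    v <- base_ts[[f]]
    if (!is.null(ts_vals[[f]])) {
      v[!is.na(ts_vals[[f]])] <- ts_vals[[f]][!is.na(ts_vals[[f]])]
    }
    data.table::set(main, j = sprintf("f.%s.0.0", f), value = v)
  }
  for (f in names(ts_age)) {
    data.table::set(main, j = sprintf("f.%s.0.0", f), value = ts_age[[f]])
  }
  ## age-of-diagnosis field referenced by the bundled touchscreen
  ## conditions: always present, NA unless a condition filled it
  if (!"f.2976.0.0" %in% names(main)) {
    data.table::set(main, j = "f.2976.0.0", value = rep(NA_real_, n))
  }
  ## self-report arrays: slots assigned in emission order per (id, field)
  slots <- list(`20001` = 4L, `20002` = 4L, `20003` = 4L, `20004` = 2L)
  sr_dt <- data.table::rbindlist(sr_rows)
  if (nrow(sr_dt)) {
    sr_dt[, arr_index := seq_len(.N) - 1L, by = .(identifier, field)]
  }
  for (f in names(slots)) {
    fid <- as.integer(f)
    wire <- settings[field_id == fid & classification == "sr"]
    for (a in seq_len(slots[[f]]) - 1L) {
      codev <- rep(NA_character_, n)
      timev <- rep(NA_real_, n)
      if (nrow(sr_dt)) {
        rows <- sr_dt[field == fid & arr_index == a]
        if (nrow(rows)) {
          ix <- match(rows$identifier, ids)
          codev[ix] <- rows$code
          timev[ix] <- rows$timing_value
        }
      }
      data.table::set(main, j = sprintf("f.%d.0.%d", fid, a), value = codev)
      if (nrow(wire) && !is.na(wire$timing_field[1])) {
        data.table::set(main, j = sprintf("f.%d.0.%d", wire$timing_field[1], a),
                        value = timev)
      }
    }
  }

  ## metadata (html + TSV fallback)
  meta <- data.table::data.table(column_label = names(main))
  meta[column_label == "f.eid", type := "text"]
  type_of <- function(lbl) {
    p <- parse_column_label(lbl)
    if (is.null(p)) return("text")
    if (p$field_id %in% c(53)) "date"
    else if (p$field_id %in% c(54)) "text"
    else if (p$field_id %in% c(20008, 2976, 20006)) "real"
    else if (p$field_id %in% c(20001, 20002, 20003, 20004)) "integer"
    else "integer"
  }
  meta[column_label != "f.eid",
       type := vapply(column_label, type_of, character(1))]

  files <- c(main = "main.tab", metadata_html = "metadata.html",
             metadata_tsv = "metadata.tsv", hesin = "hesin.txt",
             hesin_diag = "hesin_diag.txt", hesin_oper = "hesin_oper.txt",
             gp_clinical = "gp_clinical.txt", gp_scripts = "gp_scripts.txt",
             death = "death.txt", death_cause = "death_cause.txt",
             withdrawal = "withdrawals.csv", truth = "truth.tsv")
  files <- setNames(file.path(out_dir, files), names(files))

  fw <- function(lst, template, path) {
    dt <- if (length(lst)) data.table::rbindlist(lst) else template
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "")
    dt
  }
  data.table::fwrite(main, files["main"], sep = "\t", quote = FALSE, na = "")
  data.table::fwrite(meta, files["metadata_tsv"], sep = "\t", quote = FALSE)
  html <- c("<html><body><table>",
            "<tr><th>column</th><th>type</th></tr>",
            sprintf("<tr><td>%s</td><td>%s</td></tr>",
                    meta$column_label, meta$type),
            "</table></body></html>")
  writeLines(html, files["metadata_html"])
  fw(hes_master, data.table::data.table(eid = character(),
     ins_index = integer(), epistart = character(), epiend = character(),
     admidate = character(), disdate = character()), files["hesin"])
  fw(hes_diag, data.table::data.table(eid = character(), ins_index = integer(),
     level = integer(), diag_icd9 = character(), diag_icd10 = character()),
     files["hesin_diag"])
  fw(hes_oper, data.table::data.table(eid = character(), ins_index = integer(),
     level = integer(), oper4 = character()), files["hesin_oper"])
  fw(gp_clin, data.table::data.table(eid = character(),
     data_provider = integer(), event_dt = character(), read_2 = character(),
     read_3 = character()), files["gp_clinical"])
  fw(gp_scr, data.table::data.table(eid = character(),
     data_provider = integer(), issue_date = character(),
     dmd_code = character()), files["gp_scripts"])
  fw(death_rows, data.table::data.table(eid = character(),
     date_of_death = character()), files["death"])
  fw(cause_rows, data.table::data.table(eid = character(), level = integer(),
     cause_icd10 = character()), files["death_cause"])

  n_withdraw <- round(n * config$withdrawal_fraction)
  withdrawn <- if (n_withdraw > 0) sort(sample(ids, n_withdraw)) else character()
  writeLines(withdrawn, files["withdrawal"])
  if (nrow(truth_dt)) {
    truth_dt[, withdrawn := as.integer(identifier %in% withdrawn)]
  } else {
    truth_dt <- data.table::data.table(identifier = character(),
      trait = character(), prevalent = integer(), incident = integer(),
      onset_date = character(), sources = character(),
      injected_exclusion = integer(), withdrawn = integer())
  }
  data.table::setorder(truth_dt, trait, identifier)
  data.table::fwrite(truth_dt, files["truth"], sep = "\t", quote = FALSE)
  invisible(list(files = files, truth = truth_dt[]))
}
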
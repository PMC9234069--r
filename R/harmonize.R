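## Harmonization: every data source (hospital inpatient, primary care,
## death register, nurse-interview self-report, touchscreen) is converted
## into the unified episode schema:
##   .id, identifier, code, eventdate, event, epidur, classification
## with the event flag documenting date provenance:
##   1 = true event date from linked records (or self-reported operation)
##   2 = self-reported event date (illness year / age of diagnosis)
##   0 = not a true event date (assessment-centre visit date imputed)

as_record <- function(x, id_col = c("eid", "identifier")) {
  if (is.character(x) && length(x) == 1L) return(read_record_table(x, id_col))
  dt <- data.table::as.data.table(x)
  idc <- intersect(id_col, names(dt))[1]
  if (is.na(idc)) stop("record table lacks an identifier column", call. = FALSE)
  data.table::setnames(dt, idc, "identifier")
  for (col in names(dt)) if (!is.character(dt[[col]]) &&
                             !inherits(dt[[col]], "IDate"))
    data.table::set(dt, j = col, value = as.character(dt[[col]]))
  dt
}

default_flag <- function(settings, source) {
  v <- settings[source_id == source, default_event_flag]
  if (length(v) == 0L) 1L else v[1]
}

#' Harmonize hospital inpatient episodes
#'
#' Joins the diagnosis and operation tables to the master episode table on
#' (identifier, record index) and emits one episode per code. The event date
#' is the episode start, falling back to the admission date; `epidur` is the
#' episode length in days (end minus start). Diagnosis/operation rows with no
#' matching master row, and master rows with no usable date, are dropped with
#' a logged count.
#'
#' @param hesin master table (columns `eid`/`identifier`, `ins_index`,
#'   `epistart`, `epiend`, `admidate`, `disdate`; ISO dates) or a path.
#' @param hesin_diag diagnosis table (`ins_index`, `level`, `diag_icd10`,
#'   `diag_icd9`) or a path; may be `NULL`.
#' @param hesin_oper operation table (`ins_index`, `level`, `oper4`) or a
#'   path; may be `NULL`.
#' @param settings a [read_data_settings()] table.
#' @return episode `data.table` with sources `hesin_icd10`, `hesin_icd9`,
#'   `hesin_oper`.
#' @export
harmonize_hesin <- function(hesin, hesin_diag = NULL, hesin_oper = NULL,
                            settings) {
  master <- as_record(hesin)
  for (col in intersect(c("epistart", "epiend", "admidate", "disdate"),
                        names(master))) {
    data.table::set(master, j = col, value = parse_iso_date(master[[col]], col))
  }
  getcol <- function(dt, col) if (col %in% names(dt)) dt[[col]] else
    data.table::as.IDate(rep(NA_integer_, nrow(dt)))
  master[, eventdate := data.table::fifelse(is.na(getcol(master, "epistart")),
                                            getcol(master, "admidate"),
                                            getcol(master, "epistart"))]
  st <- getcol(master, "epistart"); en <- getcol(master, "epiend")
  st2 <- data.table::fifelse(is.na(st), getcol(master, "admidate"), st)
  en2 <- data.table::fifelse(is.na(en), getcol(master, "disdate"), en)
  master[, epidur := {
    d <- as.integer(en2 - st2)
    data.table::fifelse(!is.na(d) & d >= 0L, d, NA_integer_)
  }]
  n_nodate <- master[is.na(eventdate), .N]
  if (n_nodate > 0L) {
    message(sprintf("hesin: dropped %d master row(s) with no usable date",
                    n_nodate))
    master <- master[!is.na(eventdate)]
  }
  key <- c("identifier", "ins_index")
  data.table::setkeyv(master, key)

  emit <- function(detail, code_col, source, cls) {
    if (is.null(detail) || !code_col %in% names(detail)) return(empty_episodes())
    d <- detail[nzchar(trimws2(detail[[code_col]]))]
    if (nrow(d) == 0L) return(empty_episodes())
    j <- master[d, on = key, nomatch = NULL]
    orphans <- nrow(d) - nrow(j)
    if (orphans > 0L) {
      message(sprintf("%s: dropped %d orphan row(s) with no master episode",
                      source, orphans))
    }
    if (nrow(j) == 0L) return(empty_episodes())
    as_episode_table(j[, .(
      .id = source, identifier, code = trimws2(get(code_col)),
      eventdate, event = default_flag(settings, source), epidur,
      classification = cls)])
  }
  diag <- if (!is.null(hesin_diag)) as_record(hesin_diag) else NULL
  oper <- if (!is.null(hesin_oper)) as_record(hesin_oper) else NULL
  data.table::rbindlist(list(
    emit(diag, "diag_icd10", "hesin_icd10", "icd10"),
    emit(diag, "diag_icd9", "hesin_icd9", "icd9"),
    emit(oper, "oper4", "hesin_oper", "opcs4")))
}

#' Harmonize primary-care events and prescriptions
#'
#' Clinical rows emit one episode per filled code column (`read_2`,
#' `read_3`), so a row carrying both yields two episodes in two sources.
#' Prescription rows emit `gpscripts` episodes from the drug-code column.
#' Rows with no code, or no event date, are dropped.
#'
#' @param gp_clinical clinical-events table (`event_dt`, `read_2`, `read_3`)
#'   or path; may be `NULL`.
#' @param gp_scripts prescriptions table (`issue_date`, `dmd_code`) or path;
#'   may be `NULL`.
#' @param settings a [read_data_settings()] table.
#' @return episode `data.table` with sources `gpclinical.read2`,
#'   `gpclinical.read3`, `gpscripts`.
#' @export
harmonize_gp <- function(gp_clinical = NULL, gp_scripts = NULL, settings) {
  out <- list()
  if (!is.null(gp_clinical)) {
    gc <- as_record(gp_clinical)
    gc[, eventdate := parse_iso_date(event_dt, "event_dt")]
    n_nodate <- gc[is.na(eventdate), .N]
    if (n_nodate > 0L) {
      message(sprintf("gp_clinical: dropped %d row(s) with no event date",
                      n_nodate))
      gc <- gc[!is.na(eventdate)]
    }
    for (spec in list(list(col = "read_2", src = "gpclinical.read2", cls = "read2"),
                      list(col = "read_3", src = "gpclinical.read3", cls = "read3"))) {
      if (!spec$col %in% names(gc)) next
      d <- gc[nzchar(trimws2(get(spec$col)))]
      if (nrow(d) == 0L) next
      out[[spec$src]] <- as_episode_table(d[, .(
        .id = spec$src, identifier, code = trimws2(get(spec$col)), eventdate,
        event = default_flag(settings, spec$src), epidur = NA_integer_,
        classification = spec$cls)])
    }
  }
  if (!is.null(gp_scripts)) {
    gs <- as_record(gp_scripts)
    gs[, eventdate := parse_iso_date(issue_date, "issue_date")]
    gs <- gs[!is.na(eventdate) & nzchar(trimws2(dmd_code))]
    if (nrow(gs)) {
      out[["gpscripts"]] <- as_episode_table(gs[, .(
        .id = "gpscripts", identifier, code = trimws2(dmd_code), eventdate,
        event = default_flag(settings, "gpscripts"), epidur = NA_integer_,
        classification = "dmd")])
    }
  }
  if (length(out) == 0L) return(empty_episodes())
  data.table::rbindlist(out)
}

#' Harmonize the death register
#'
#' Cause rows are joined to death dates per participant: primary causes
#' (level 1) feed the `tte.death.icd10.primary` source, contributory causes
#' the `tte.death.icd10.secondary` source. Cause rows with no corresponding
#' death date are dropped with a warning.
#'
#' @param death date table (`date_of_death`) or path.
#' @param death_cause cause table (`level`, `cause_icd10`) or path.
#' @param settings a [read_data_settings()] table.
#' @return episode `data.table`.
#' @export
harmonize_death <- function(death, death_cause = NULL, settings) {
  dd <- as_record(death)
  dd[, eventdate := parse_iso_date(date_of_death, "date_of_death")]
  dd <- unique(dd[!is.na(eventdate), .(identifier, eventdate)], by = "identifier")
  if (is.null(death_cause)) return(empty_episodes())
  dc <- as_record(death_cause)
  dc <- dc[nzchar(trimws2(cause_icd10))]
  j <- dd[dc, on = "identifier"]
  n_orphan <- j[is.na(eventdate), .N]
  if (n_orphan > 0L) {
    warning(sprintf("death_cause: dropped %d cause row(s) with no death date",
                    n_orphan), call. = FALSE)
    j <- j[!is.na(eventdate)]
  }
  if (nrow(j) == 0L) return(empty_episodes())
  j[, .id := data.table::fifelse(trimws2(level) == "1",
                                 "tte.death.icd10.primary",
                                 "tte.death.icd10.secondary")]
  out <- j[, .(.id, identifier, code = trimws2(cause_icd10), eventdate,
               epidur = NA_integer_, classification = "icd10")]
  out[, event := vapply(.id, function(s) default_flag(settings, s), integer(1))]
  as_episode_table(out)
}

## participant birth dates: year field 34, optional month field 52.
## Day is mid-month (15th) when the month is known, July 1 otherwise.
birth_dates <- function(participants) {
  yr <- if ("f.34.0.0" %in% names(participants))
    as.integer(participants[["f.34.0.0"]]) else rep(NA_integer_, nrow(participants))
  mo <- if ("f.52.0.0" %in% names(participants))
    as.integer(participants[["f.52.0.0"]]) else rep(NA_integer_, nrow(participants))
  d <- rep(NA_character_, length(yr))
  ok <- !is.na(yr) & yr >= 1900
  hasmo <- ok & !is.na(mo) & mo >= 1 & mo <= 12
  d[hasmo] <- sprintf("%04d-%02d-15", yr[hasmo], mo[hasmo])
  d[ok & !hasmo] <- sprintf("%04d-07-01", yr[ok & !hasmo])
  data.table::as.IDate(d)
}

visit_date_column <- function(instance) sprintf("f.53.%d.0", instance)

## year -> July 1 of that (floored) year; implausible values -> NA
year_to_date <- function(y) {
  y <- suppressWarnings(as.numeric(y))
  y[!is.na(y) & (y < 1900 | y > 2100)] <- NA
  data.table::as.IDate(ifelse(is.na(y), NA_character_,
                              sprintf("%04d-07-01", floor(y))))
}

## age -> birth date + age * 365.25 days; non-positive ages -> NA
age_to_date <- function(age, birth) {
  age <- suppressWarnings(as.numeric(age))
  age[!is.na(age) & age <= 0] <- NA
  out <- birth + as.integer(round(age * 365.25))
  out[is.na(age) | is.na(birth)] <- NA
  data.table::as.IDate(out)
}

#' Harmonize nurse-interview self-report fields
#'
#' Every settings row with classification `sr` names a self-report code field
#' (illness 20002, medication 20003, operation 20004, ...). One episode is
#' emitted per non-missing code cell per instance/array. When the companion
#' timing field (same instance/array) holds a valid year or age, the event
#' date is interpolated (year to July 1; age to birth date + age x 365.25
#' days) and the event flag is the source default (2 for illnesses, 1 for
#' operations). Otherwise the visit date of that instance is imputed with
#' event flag 0. Negative timing values (special codes such as -1 "do not
#' know" and -3 "prefer not to answer") are treated as missing timing.
#'
#' @param participants main-dataset subset (needs the code, timing, visit
#'   and birth-date columns).
#' @param catalog a [read_field_catalog()] result.
#' @param settings a [read_data_settings()] table.
#' @return episode `data.table` with sources `sr_<field>`.
#' @export
harmonize_self_report <- function(participants, catalog, settings) {
  sr <- settings[classification == "sr"]
  if (nrow(sr) == 0L) return(empty_episodes())
  birth <- birth_dates(participants)
  out <- list()
  for (i in seq_len(nrow(sr))) {
    fid <- sr$field_id[i]
    if (is.na(fid)) {
      fid <- suppressWarnings(as.integer(sub("^sr_", "", sr$source_id[i])))
    }
    if (is.na(fid)) next
    cols <- catalog[field_id == fid & column_label %in% names(participants)]
    if (nrow(cols) == 0L) next
    for (k in seq_len(nrow(cols))) {
      cl <- cols$column_label[k]
      inst <- cols$instance[k]
      arr <- cols$array_index[k]
      v <- participants[[cl]]
      keep <- !is.na(v) & nzchar(as.character(v))
      if (!any(keep)) next
      code <- format(v, scientific = FALSE, trim = TRUE)
      ## companion timing value at the same instance/array
      tdate <- data.table::as.IDate(rep(NA_integer_, nrow(participants)))
      if (!is.na(sr$timing_field[i])) {
        tcol <- sprintf("f.%d.%d.%d", sr$timing_field[i], inst, arr)
        if (tcol %in% names(participants)) {
          tv <- suppressWarnings(as.numeric(participants[[tcol]]))
          tv[!is.na(tv) & tv < 0] <- NA          # -1 / -3 special codes
          tdate <- if (identical(sr$timing_type[i], "age"))
            age_to_date(tv, birth) else year_to_date(tv)
        }
      }
      vcol <- visit_date_column(inst)
      vdate <- if (vcol %in% names(participants)) participants[[vcol]] else
        data.table::as.IDate(rep(NA_integer_, nrow(participants)))
      ed <- data.table::fifelse(is.na(tdate), vdate, tdate)
      ev <- data.table::fifelse(is.na(tdate), 0L, default_flag(settings, sr$source_id[i]))
      keep <- keep & !is.na(ed)
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.table::data.table(
        .id = sr$source_id[i], identifier = participants$identifier[keep],
        code = code[keep], eventdate = ed[keep], event = ev[keep],
        epidur = NA_integer_, classification = "sr")
    }
  }
  if (length(out) == 0L) return(empty_episodes())
  as_episode_table(data.table::rbindlist(out))
}

compare_values <- function(v, comparator, target) {
  num <- is.numeric(v)
  if (num) {
    t <- suppressWarnings(as.numeric(target))
    if (is.na(t)) {
      stop(sprintf("condition value '%s' is not numeric but the field is",
                   target), call. = FALSE)
    }
    v[!is.na(v) & v < 0] <- NA  # negative special codes never satisfy a condition
    switch(comparator,
           "=" = v == t, "!=" = v != t, "<" = v < t, "<=" = v <= t,
           ">" = v > t, ">=" = v >= t)
  } else {
    v <- as.character(v)
    v[!is.na(v) & !nzchar(v)] <- NA
    switch(comparator,
           "=" = v == target, "!=" = v != target,
           stop(sprintf("comparator '%s' requires a numeric field", comparator),
                call. = FALSE))
  }
}

#' Evaluate a touchscreen condition into episodes
#'
#' For every participant and instance where the comparison holds, one episode
#' is emitted with the condition's canonical text as the code and
#' classification `ts`. Negative field values (special answer codes) never
#' satisfy a condition. When the condition carries an age-of-diagnosis field
#' with a valid value, the event date is interpolated from the birth date
#' (event flag 2); otherwise the instance's visit date is used (event flag 0).
#'
#' @param participants main-dataset subset.
#' @param condition a [parse_condition()] result.
#' @param catalog a [read_field_catalog()] result.
#' @return episode `data.table` with source `ts`.
#' @export
evaluate_touchscreen <- function(participants, condition, catalog) {
  cols <- catalog[field_id == condition$field_id &
                    column_label %in% names(participants)]
  if (nrow(cols) == 0L) return(empty_episodes())
  birth <- birth_dates(participants)
  out <- list()
  for (k in seq_len(nrow(cols))) {
    cl <- cols$column_label[k]
    inst <- cols$instance[k]
    hold <- compare_values(participants[[cl]], condition$comparator,
                           condition$value)
    hold[is.na(hold)] <- FALSE
    if (!any(hold)) next
    adate <- data.table::as.IDate(rep(NA_integer_, nrow(participants)))
    if (!is.na(condition$age_field)) {
      acol <- sprintf("f.%d.%d.0", condition$age_field, inst)
      if (acol %in% names(participants)) {
        av <- suppressWarnings(as.numeric(participants[[acol]]))
        av[!is.na(av) & av < 0] <- NA
        adate <- age_to_date(av, birth)
      }
    }
    vcol <- visit_date_column(inst)
    vdate <- if (vcol %in% names(participants)) participants[[vcol]] else
      data.table::as.IDate(rep(NA_integer_, nrow(participants)))
    ed <- data.table::fifelse(is.na(adate), vdate, adate)
    ev <- data.table::fifelse(is.na(adate), 0L, 2L)
    keep <- hold & !is.na(ed)
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.table::data.table(
      .id = "ts", identifier = participants$identifier[keep],
      code = condition$canonical, eventdate = ed[keep], event = ev[keep],
      epidur = NA_integer_, classification = "ts")
  }
  if (length(out) == 0L) return(empty_episodes())
  as_episode_table(data.table::rbindlist(out))
}

fields_needed <- function(defset, settings) {
  fids <- integer()
  for (d in defset$definitions) {
    fids <- c(fids, vapply(d$field_specs, `[[`, integer(1), "field_id"))
    for (cond in d$conditions) {
      fids <- c(fids, cond$field_id,
                if (!is.na(cond$age_field)) cond$age_field)
    }
  }
  sr <- settings[classification == "sr"]
  sr_fields <- ifelse(is.na(sr$field_id),
                      suppressWarnings(as.integer(sub("^sr_", "", sr$source_id))),
                      sr$field_id)
  used_sr <- intersect(sr_fields, fids)
  timing <- sr$timing_field[match(used_sr, sr_fields)]
  sort(unique(c(fids, timing[!is.na(timing)], 53L, 34L, 52L)))
}

#' Harmonize all available data sources
#'
#' Loads the main dataset (restricted to the fields the definition set
#' needs), every provided record-level file and the withdrawal list, and
#' returns the harmonized container of exactly three components:
#' \describe{
#'   \item{lst.data}{named list of episode tables, grouped by source id}
#'   \item{dfukb}{the participant subset of the main dataset}
#'   \item{vct.identifiers}{all participant identifiers after withdrawal
#'     filtering}
#' }
#' Only the main dataset and metadata are mandatory; any record-level path
#' may be `NULL`. Withdrawn participants are removed from every table.
#'
#' @param f.main main dataset TSV path.
#' @param f.metadata metadata document path (html or TSV).
#' @param defset a [read_definition_table()] result.
#' @param settings a [read_data_settings()] table.
#' @param f.hesin,f.hesin_diag,f.hesin_oper hospital inpatient paths.
#' @param f.gp_clinical,f.gp_scripts primary-care paths.
#' @param f.death,f.death_cause death-register paths.
#' @param f.withdrawal withdrawal-list path.
#' @param allow_missing skip definition fields absent from the main dataset
#'   (warning) instead of halting.
#' @param extra_fields additional main-dataset field ids to carry in `dfukb`
#'   (e.g. 54 for assessment centre, 21003 for age).
#' @return a `harmonized_data` object (list of 3).
#' @export
harmonize_all <- function(f.main, f.metadata, defset, settings,
                          f.hesin = NULL, f.hesin_diag = NULL,
                          f.hesin_oper = NULL, f.gp_clinical = NULL,
                          f.gp_scripts = NULL, f.death = NULL,
                          f.death_cause = NULL, f.withdrawal = NULL,
                          allow_missing = TRUE, extra_fields = integer()) {
  catalog <- read_field_catalog(f.metadata)
  fields <- sort(unique(c(fields_needed(defset, settings),
                          as.integer(extra_fields))))
  dfukb <- read_main_dataset(f.main, catalog, fields,
                             allow_missing = allow_missing)
  withdrawn <- read_withdrawals(f.withdrawal)
  if (length(withdrawn)) {
    dfukb <- dfukb[!identifier %in% withdrawn]
  }
  ids <- dfukb$identifier

  episodes <- list()
  add <- function(eps) {
    if (is.null(eps) || nrow(eps) == 0L) return(invisible())
    eps <- eps[identifier %in% ids]
    for (src in unique(eps$.id)) {
      episodes[[src]] <<- data.table::rbindlist(
        list(episodes[[src]], eps[.id == src]))
    }
    invisible()
  }
  if (!is.null(f.hesin)) {
    add(harmonize_hesin(f.hesin, f.hesin_diag, f.hesin_oper, settings))
  } else if (!is.null(f.hesin_diag) || !is.null(f.hesin_oper)) {
    message("hesin master file missing; diagnosis/operation files skipped")
  }
  if (!is.null(f.gp_clinical) || !is.null(f.gp_scripts)) {
    add(harmonize_gp(f.gp_clinical, f.gp_scripts, settings))
  }
  if (!is.null(f.death)) {
    add(harmonize_death(f.death, f.death_cause, settings))
  }
  add(harmonize_self_report(dfukb, catalog, settings))
  ## touchscreen conditions come from the definition set
  conds <- unique(unlist(lapply(defset$definitions, function(d)
    lapply(d$conditions, `[[`, "canonical"))))
  for (cond_txt in conds) {
    add(evaluate_touchscreen(dfukb, parse_condition(cond_txt), catalog))
  }
  episodes <- lapply(episodes, function(e) {
    data.table::setkeyv(e, c("identifier", "eventdate")); e[]
  })
  structure(list(lst.data = episodes, dfukb = dfukb, vct.identifiers = ids),
            class = "harmonized_data")
}

#' @export
print.harmonized_data <- function(x, ...) {
  cat(sprintf("<harmonized_data> %d participants, %d episode source(s)\n",
              length(x$vct.identifiers), length(x$lst.data)))
  for (src in names(x$lst.data)) {
    cat(sprintf("  %-28s %7d episodes\n", src, nrow(x$lst.data[[src]])))
  }
  invisible(x)
}
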
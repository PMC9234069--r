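## Case/control ascertainment: match harmonized episodes against a
## definition, summarize per participant relative to a reference date
## (prevalent Hx / incident Fu / peri-reference Ref), and apply composite
## study-population / include / exclude logic.

.ccr_cols <- c("identifier", "reference_date", "count", "sum.epidur",
               "median.epidur", "max.epidur", "survival_days",
               "Death_primary", "Death_any", "Hx_days", "Fu_days",
               "Hx", "Fu", "Ref", "first_diagnosis_days", "Any")

settings_row <- function(settings, src) {
  i <- match(src, settings$source_id)
  if (is.na(i)) NULL else settings[i]
}

## codes that parse as negative numbers are special answer codes, never
## clinical content
is_negative_code <- function(code) {
  v <- suppressWarnings(as.numeric(code))
  !is.na(v) & v < 0
}

#' Match harmonized episodes against one phenotype definition
#'
#' Episodes match when their source's classification has a code set in the
#' definition and the episode code is in that (already expanded) set, or when
#' the source is a self-report field named by one of the definition's field
#' specifications, or a touchscreen episode generated by one of its
#' conditions. The per-source minimum-instance filter is then applied: a
#' participant's episodes from source *s* are kept only if there are at
#' least `min_instances(s)` of them.
#'
#' @param definition a `phenotype_definition`.
#' @param harmonized a [harmonize_all()] result (or a bare `lst.data` list).
#' @param settings a [read_data_settings()] table.
#' @return episode `data.table` of matched events (7 columns).
#' @export
match_episodes <- function(definition, harmonized, settings) {
  lst <- if (inherits(harmonized, "harmonized_data")) harmonized$lst.data
         else harmonized
  sr_fields <- vapply(definition$field_specs, `[[`, integer(1), "field_id")
  cond_codes <- vapply(definition$conditions, `[[`, character(1), "canonical")
  out <- list()
  for (src in names(lst)) {
    eps <- lst[[src]]
    if (nrow(eps) == 0L) next
    row <- settings_row(settings, src)
    cls <- if (!is.null(row)) row$classification else eps$classification[1]
    ic <- if (!is.null(row)) row$ignore_case else FALSE
    hit <- NULL
    if (cls == "sr") {
      fid <- if (!is.null(row) && !is.na(row$field_id)) row$field_id else
        suppressWarnings(as.integer(sub("^sr_", "", src)))
      specs <- definition$field_specs[sr_fields == fid]
      if (length(specs)) {
        if (any(vapply(specs, `[[`, logical(1), "any"))) {
          hit <- eps[!is_negative_code(code)]
        } else {
          codes <- unique(unlist(lapply(specs, `[[`, "codes")))
          hit <- eps[code %in% codes]
        }
      }
    } else if (cls == "ts") {
      if (length(cond_codes)) hit <- eps[code %in% cond_codes]
    } else if (cls %in% names(definition$code_sets)) {
      set_norm <- unique(normalize_code(definition$code_sets[[cls]], ic))
      hit <- eps[normalize_code(code, ic) %in% set_norm]
    }
    if (is.null(hit) || nrow(hit) == 0L) next
    min_inst <- if (!is.null(row)) row$min_instances else 1L
    if (min_inst > 1L) {
      hit <- hit[, if (.N >= min_inst) .SD, by = identifier]
      if (nrow(hit) == 0L) next
      data.table::setcolorder(hit, c(".id", "identifier"))
    }
    out[[src]] <- hit
  }
  if (length(out) == 0L) return(empty_episodes())
  as_episode_table(data.table::rbindlist(out))
}

## vectorized per-participant summary; `events` must already carry a
## reference_date column
summarize_events_by_participant <- function(events, window_days = 0) {
  events[, {
    ref <- reference_date[1]
    first <- min(eventdate)
    dur <- epidur[!is.na(epidur)]
    death_dt <- eventdate[grepl("^tte\\.death", .id)]
    hx <- first <= ref
    list(
      count = .N,
      sum.epidur = if (length(dur)) sum(dur) else NA_integer_,
      median.epidur = if (length(dur)) as.numeric(median(dur)) else NA_real_,
      max.epidur = if (length(dur)) max(dur) else NA_integer_,
      survival_days = if (length(death_dt))
        as.integer(min(death_dt) - ref) else NA_integer_,
      Death_primary = if (any(.id == "tte.death.icd10.primary")) 2L else 1L,
      Death_any = if (length(death_dt)) 2L else 1L,
      Hx_days = if (hx) as.integer(ref - first) else NA_integer_,
      Fu_days = if (!hx) as.integer(first - ref) else NA_integer_,
      Hx = if (hx) 2L else 1L,
      Fu = if (!hx) 2L else 1L,
      Ref = if (any(abs(as.integer(eventdate - ref)) <= window_days)) 2L else 1L,
      first_diagnosis_days = as.integer(first - ref),
      Any = 2L
    )
  }, by = .(identifier, reference_date)]
}

#' Summarize one participant's matched events
#'
#' Produces the 16-field per-participant case summary: episode counts,
#' hospitalization-duration aggregates, death indicators, prevalent (Hx) and
#' incident (Fu) indicators with durations, the peri-reference indicator and
#' the signed days from reference to first diagnosis. Events dated exactly on
#' the reference date count as prevalent.
#'
#' @param events matched episode table for a single participant (non-empty).
#' @param reference_date the participant's reference date.
#' @param window_days window for the `Ref` indicator (default 0 days).
#' @return one-row `data.table` with the 16 summary fields.
#' @export
summarize_participant <- function(events, reference_date, window_days = 0) {
  events <- data.table::as.data.table(events)
  if (nrow(events) == 0L) {
    stop("summarize_participant requires at least one matched event", call. = FALSE)
  }
  if (length(unique(events$identifier)) != 1L) {
    stop("events must belong to a single participant", call. = FALSE)
  }
  ev <- data.table::copy(events)
  ev[, reference_date := data.table::as.IDate(reference_date)]
  out <- summarize_events_by_participant(ev, window_days)
  data.table::setcolorder(out, .ccr_cols)
  out[]
}

normalize_reference_dates <- function(reference_dates, ids) {
  if (inherits(reference_dates, "Date") ||
      (is.character(reference_dates) && length(reference_dates) == 1L)) {
    return(data.table::data.table(
      identifier = ids,
      reference_date = data.table::as.IDate(reference_dates)))
  }
  rd <- data.table::as.data.table(reference_dates)
  data.table::setnames(rd, names(rd)[1:2], c("identifier", "reference_date"))
  rd[, identifier := as.character(identifier)]
  if (!inherits(rd$reference_date, "IDate")) {
    rd[, reference_date := data.table::as.IDate(as.character(reference_date))]
  }
  rd[identifier %in% ids, .(identifier, reference_date)]
}

## recursive match-set closure: participants matching a trait's own codes or
## (recursively) any Include_definitions trait
match_closure <- function(defset, trait, matched_by_trait) {
  seen <- character()
  recur <- function(t) {
    if (t %in% seen) return(character())
    seen <<- c(seen, t)
    d <- defset$definitions[[t]]
    own <- unique(matched_by_trait[[t]]$identifier)
    unique(c(own, unlist(lapply(d$include_definitions, recur))))
  }
  recur(trait)
}

events_closure <- function(defset, trait, matched_by_trait) {
  plan <- plan_composite(defset, trait)
  seen <- character()
  collect <- function(t) {
    if (t %in% seen) return(NULL)
    seen <<- c(seen, t)
    d <- defset$definitions[[t]]
    data.table::rbindlist(c(list(matched_by_trait[[t]]),
                            lapply(d$include_definitions, collect)))
  }
  collect(trait)
}

#' Ascertain case/control status for one phenotype
#'
#' Evaluation order: (1) if `Study_population` is set, restrict to
#' participants matching that trait; (2) participants matching the trait's
#' own codes or any `Include_definitions` trait become candidate cases
#' (status 2); (3) candidate cases also matching an `Exclude_from_cases`
#' trait are excluded (status -2); (4) the remaining participants are
#' controls (status 1), and controls matching an `Exclude_from_controls`
#' trait are excluded (status -1).
#'
#' The status is carried in the indicator columns: included case/control are
#' 2/1, excluded case/control -2/-1 (the `Hx`, `Fu`, `Ref` and `Any` columns
#' of excluded participants are negated, so `Any` is the overall status).
#'
#' @param defset a [read_definition_table()] result.
#' @param trait target trait identifier.
#' @param harmonized a [harmonize_all()] result.
#' @param settings a [read_data_settings()] table.
#' @param reference_dates a single date, or a two-column table
#'   (identifier, date); participants without a reference date are dropped
#'   with a warning.
#' @param window_days window for the `Ref` indicator (default 0).
#' @return a `case_control_result` with exactly three components:
#'   `df.casecontrol` (all participants, 16 columns),
#'   `all_event_dt.Include_in_cases` (episodes of included cases) and
#'   `all_event_dt.Include_in_cases.summary` (summary rows of all cases,
#'   included and excluded).
#' @export
get_cases_controls <- function(defset, trait, harmonized, settings,
                               reference_dates, window_days = 0) {
  stopifnot(inherits(defset, "definition_set"))
  if (!trait %in% defset$traits) {
    stop(sprintf("unknown trait '%s'", trait), call. = FALSE)
  }
  plan <- plan_composite(defset, trait)   # also detects cycles
  ids <- harmonized$vct.identifiers
  refs <- normalize_reference_dates(reference_dates, ids)
  n_missing <- length(ids) - sum(ids %in% refs[!is.na(reference_date), identifier])
  if (n_missing > 0L) {
    warning(sprintf("%d participant(s) without a reference date dropped",
                    n_missing), call. = FALSE)
  }
  refs <- refs[!is.na(reference_date)]
  matched_by_trait <- lapply(setNames(plan, plan), function(t)
    match_episodes(defset$definitions[[t]], harmonized, settings))

  d <- defset$definitions[[trait]]
  pop <- refs$identifier
  if (!is.na(d$study_population)) {
    pop <- intersect(pop, match_closure(defset, d$study_population,
                                        matched_by_trait))
  }
  cases <- intersect(pop, match_closure(defset, trait, matched_by_trait))
  excl_cases <- character()
  for (e in d$exclude_from_cases) {
    excl_cases <- union(excl_cases,
                        intersect(cases, match_closure(defset, e,
                                                       matched_by_trait)))
  }
  controls <- setdiff(pop, cases)
  excl_controls <- character()
  for (e in d$exclude_from_controls) {
    excl_controls <- union(excl_controls,
                           intersect(controls,
                                     match_closure(defset, e, matched_by_trait)))
  }

  case_events <- events_closure(defset, trait, matched_by_trait)
  case_events <- case_events[identifier %in% cases]
  ev <- refs[case_events, on = "identifier", nomatch = NULL]
  summ <- if (nrow(ev)) summarize_events_by_participant(ev, window_days) else
    data.table::data.table()

  cc <- refs[identifier %in% pop]
  if (nrow(summ)) {
    cc <- merge(cc, summ[, setdiff(names(summ), "reference_date"), with = FALSE],
                by = "identifier", all.x = TRUE)
  } else {
    cc[, `:=`(count = NA_integer_, sum.epidur = NA_integer_,
              median.epidur = NA_real_, max.epidur = NA_integer_,
              survival_days = NA_integer_, Death_primary = NA_integer_,
              Death_any = NA_integer_, Hx_days = NA_integer_,
              Fu_days = NA_integer_, Hx = NA_integer_, Fu = NA_integer_,
              Ref = NA_integer_, first_diagnosis_days = NA_integer_,
              Any = NA_integer_)]
  }
  cc[is.na(count), `:=`(count = 0L, Death_primary = 1L, Death_any = 1L,
                        Hx = 1L, Fu = 1L, Ref = 1L, Any = 1L)]
  excl <- c(excl_cases, excl_controls)
  if (length(excl)) {
    cc[identifier %in% excl,
       `:=`(Hx = -Hx, Fu = -Fu, Ref = -Ref, Any = -Any)]
  }
  data.table::setcolorder(cc, .ccr_cols)
  data.table::setkeyv(cc, "identifier")

  included_cases <- setdiff(cases, excl_cases)
  case_summary <- cc[identifier %in% cases]
  structure(list(
    df.casecontrol = cc[],
    all_event_dt.Include_in_cases =
      case_events[identifier %in% included_cases][order(identifier, eventdate)],
    all_event_dt.Include_in_cases.summary = case_summary[]
  ), class = "case_control_result")
}

#' @export
print.case_control_result <- function(x, ...) {
  st <- x$df.casecontrol$Any
  cat(sprintf(
    "<case_control_result> %d participants: %d cases (%d excluded), %d controls (%d excluded)\n",
    length(st), sum(abs(st) == 2), sum(st == -2), sum(abs(st) == 1),
    sum(st == -1)))
  invisible(x)
}

#' Status vector of a case/control result
#'
#' @param result a [get_cases_controls()] result.
#' @return named integer vector: 2 included case, -2 excluded case,
#'   1 included control, -1 excluded control.
#' @export
cc_status <- function(result) {
  setNames(result$df.casecontrol$Any, result$df.casecontrol$identifier)
}

#' Batch ascertainment over several traits
#'
#' Loops [get_cases_controls()] over traits and merges the per-participant
#' summaries into one wide table with columns prefixed `<trait>_0_<col>`.
#'
#' @param defset,harmonized,settings,reference_dates,window_days as in
#'   [get_cases_controls()].
#' @param traits character vector of trait identifiers.
#' @return a wide `data.table` keyed by `identifier`.
#' @export
get_cases_controls_batch <- function(defset, traits, harmonized, settings,
                                     reference_dates, window_days = 0) {
  out <- NULL
  for (tr in traits) {
    res <- get_cases_controls(defset, tr, harmonized, settings,
                              reference_dates, window_days)
    cc <- data.table::copy(res$df.casecontrol)
    data.table::setnames(cc, setdiff(names(cc), "identifier"),
                         paste(tr, "0", setdiff(names(cc), "identifier"),
                               sep = "_"))
    out <- if (is.null(out)) cc else
      merge(out, cc, by = "identifier", all = TRUE)
  }
  out
}

#' Per-code frequency statistics of a case event table
#'
#' @param events matched/case episode table.
#' @return `data.table` per (classification, code): `n_events`,
#'   `n_participants`, `frac_cases` (share of participants in `events`),
#'   sorted by descending event count.
#' @export
event_stats <- function(events) {
  events <- data.table::as.data.table(events)
  if (nrow(events) == 0L) {
    return(data.table::data.table(classification = character(),
                                  code = character(), n_events = integer(),
                                  n_participants = integer(),
                                  frac_cases = numeric()))
  }
  total <- length(unique(events$identifier))
  st <- events[, .(n_events = .N,
                   n_participants = length(unique(identifier))),
               by = .(classification, code)]
  st[, frac_cases := n_participants / total]
  st[order(-n_events, classification, code)]
}

#' Data-source overlap at baseline
#'
#' For every participant with at least one matched event on or before their
#' reference date, one logical column per episode source says whether that
#' source carries pre-reference evidence (the input for an UpSet-style plot).
#'
#' @param definition a `phenotype_definition`.
#' @param harmonized a [harmonize_all()] result.
#' @param settings a [read_data_settings()] table.
#' @param reference_dates single date or (identifier, date) table.
#' @return `data.table`: `identifier` + one logical column per source.
#' @export
source_overlap_matrix <- function(definition, harmonized, settings,
                                  reference_dates) {
  matched <- match_episodes(definition, harmonized, settings)
  refs <- normalize_reference_dates(reference_dates,
                                    harmonized$vct.identifiers)
  ev <- refs[matched, on = "identifier", nomatch = NULL]
  ev <- ev[eventdate <= reference_date]
  if (nrow(ev) == 0L) {
    return(data.table::data.table(identifier = character()))
  }
  wide <- data.table::dcast(ev, identifier ~ .id, fun.aggregate = length,
                            value.var = "code")
  for (col in setdiff(names(wide), "identifier")) {
    data.table::set(wide, j = col, value = wide[[col]] > 0L)
  }
  wide[]
}

#' Event counts per calendar year and data source
#'
#' Only episodes with a true event date (event flag 1 or 2) are counted;
#' imputed visit dates (flag 0) are excluded. The grid spans the full
#' observed year range for every source, with zero fills.
#'
#' @param definition a `phenotype_definition`.
#' @param harmonized a [harmonize_all()] result.
#' @param settings a [read_data_settings()] table.
#' @return `data.table` with columns `year`, `source_id`, `n`.
#' @export
timeline_counts <- function(definition, harmonized, settings) {
  matched <- match_episodes(definition, harmonized, settings)
  matched <- matched[event %in% c(1L, 2L)]
  if (nrow(matched) == 0L) {
    return(data.table::data.table(year = integer(), source_id = character(),
                                  n = integer()))
  }
  matched[, year := data.table::year(eventdate)]
  counts <- matched[, .(n = .N), by = .(year, source_id = .id)]
  grid <- data.table::CJ(year = seq(min(counts$year), max(counts$year)),
                         source_id = unique(counts$source_id))
  out <- counts[grid, on = c("year", "source_id")]
  out[is.na(n), n := 0L]
  out[order(year, source_id)]
}

#' Date-ordered event list for one participant
#'
#' All harmonized episodes of one participant across every source, sorted by
#' event date with ties broken by source id then code.
#'
#' @param harmonized a [harmonize_all()] result (or bare `lst.data` list).
#' @param identifier participant identifier.
#' @return episode `data.table` (possibly empty).
#' @export
individual_timeline <- function(harmonized, identifier) {
  lst <- if (inherits(harmonized, "harmonized_data")) harmonized$lst.data
         else harmonized
  id <- as.character(identifier)
  rows <- data.table::rbindlist(lapply(lst, function(e)
    e[e$identifier == id]))
  if (nrow(rows) == 0L) return(empty_episodes())
  as_episode_table(rows[order(eventdate, .id, code)])
}
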
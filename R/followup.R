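## Censoring-aware follow-up derivation for survival analyses. Hospital
## inpatient data completeness differs by nation, so the censoring date is
## looked up from the assessment-centre code a participant attended.

#' Default censoring configuration
#'
#' Secondary-care (hospital inpatient) censoring dates per region together
#' with the assessment-centre-to-region map. Censoring dates move with every
#' data release, so both are plain configuration: override by editing the
#' returned object or by loading a TSV with [read_censor_config()].
#'
#' Defaults: England and Scotland 2021-03-31, Wales 2018-02-28.
#'
#' @return a `censor_config`: list with `region_dates` (named IDate vector)
#'   and `centre_region` (named character vector, centre code -> region).
#' @export
default_censor_config <- function() {
  region_dates <- setNames(
    data.table::as.IDate(c("2021-03-31", "2021-03-31", "2018-02-28")),
    c("england", "scotland", "wales"))
  england <- c("10003", "11001", "11002", "11007", "11008", "11009", "11010",
               "11011", "11012", "11013", "11014", "11016", "11017", "11018",
               "11019", "11020", "11021")
  scotland <- c("11004", "11005")
  wales <- c("11003", "11022", "11006", "11023")
  centre_region <- c(setNames(rep("england", length(england)), england),
                     setNames(rep("scotland", length(scotland)), scotland),
                     setNames(rep("wales", length(wales)), wales))
  structure(list(region_dates = region_dates, centre_region = centre_region),
            class = "censor_config")
}

#' Read a censoring configuration from TSV
#'
#' Two-column tab-separated file with a header; rows are either
#' `region<TAB>ISO-date` or `centre<TAB>region`. Region rows are recognised
#' by their value parsing as a date.
#'
#' @param path TSV file.
#' @return a `censor_config`.
#' @export
read_censor_config <- function(path) {
  stop_missing_file(path, "censor config")
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          showProgress = FALSE)
  if (ncol(dt) < 2L) stop("censor config needs two columns", call. = FALSE)
  key <- trimws2(dt[[1]]); val <- trimws2(dt[[2]])
  is_date <- grepl("^\\d{4}-\\d{2}-\\d{2}$", val)
  region_dates <- setNames(data.table::as.IDate(val[is_date]), key[is_date])
  centre_region <- setNames(val[!is_date], key[!is_date])
  bad <- setdiff(unique(centre_region), names(region_dates))
  if (length(bad)) {
    stop(sprintf("centre(s) mapped to region(s) without a censor date: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(region_dates = region_dates, centre_region = centre_region),
            class = "censor_config")
}

#' Censoring date for an assessment-centre code
#'
#' @param centre_code character vector of centre codes (e.g. `"11003"`).
#' @param config a `censor_config` (default [default_censor_config()]).
#' @return IDate vector; unknown centres give `NA` with a warning.
#' @export
censor_date_for_centre <- function(centre_code, config = default_censor_config()) {
  centre_code <- as.character(centre_code)
  region <- config$centre_region[centre_code]
  unknown <- unique(centre_code[is.na(region) & !is.na(centre_code)])
  if (length(unknown)) {
    warning(sprintf("unknown assessment centre code(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out <- config$region_dates[region]
  data.table::as.IDate(unname(out))
}

#' Derive censoring-aware observed follow-up time
#'
#' Observed time runs from the baseline visit to the event, or for
#' non-events to the earliest of the death date and the region's
#' secondary-care censoring date:
#' \itemize{
#'   \item incident case (`fu_indicator == 2`): `(fu_days, "event")`;
#'   \item non-event who died on/before the censoring date:
#'     `(death - visit, "censored")`;
#'   \item non-event who died after censoring, or alive:
#'     `(censor - visit, "censored")`.
#' }
#'
#' @param fu_indicator integer vector; 2 = incident event, 1 = non-event
#'   (negative/NA entries, i.e. excluded or unascertained participants,
#'   yield NA).
#' @param fu_days days from visit to event (required where
#'   `fu_indicator == 2`).
#' @param death_date death date or NA.
#' @param visit_date baseline visit date.
#' @param censor_date per-participant censoring date (see
#'   [censor_date_for_centre()]).
#' @return `data.table` with `observed_days` (integer) and `outcome`
#'   (`"event"`/`"censored"`/NA).
#' @export
derive_followup <- function(fu_indicator, fu_days, death_date, visit_date,
                            censor_date) {
  n <- length(fu_indicator)
  recyc <- function(d) data.table::as.IDate(
    rep_len(as.integer(data.table::as.IDate(d)), n))
  visit_date <- recyc(visit_date)
  censor_date <- recyc(censor_date)
  death_date <- recyc(death_date)
  fu_days <- rep_len(fu_days, n)
  if (any(!is.na(visit_date) & !is.na(censor_date) & visit_date > censor_date)) {
    stop("visit_date after censor_date", call. = FALSE)
  }
  is_event <- !is.na(fu_indicator) & fu_indicator == 2L
  if (any(is_event & is.na(fu_days))) {
    stop("fu_days missing for incident case(s)", call. = FALSE)
  }
  observed <- rep(NA_integer_, n)
  outcome <- rep(NA_character_, n)
  observed[is_event] <- as.integer(fu_days[is_event])
  outcome[is_event] <- "event"
  nonev <- !is.na(fu_indicator) & fu_indicator == 1L
  died_pre <- nonev & !is.na(death_date) & death_date <= censor_date
  observed[died_pre] <- as.integer(death_date[died_pre] - visit_date[died_pre])
  alive <- nonev & !died_pre
  observed[alive] <- as.integer(censor_date[alive] - visit_date[alive])
  outcome[nonev] <- "censored"
  data.table::data.table(observed_days = observed, outcome = outcome)
}
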
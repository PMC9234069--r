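## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a

trimws2 <- function(x) trimws(x, which = "both")

#' Normalize a clinical code for comparison
#'
#' READ2/CTV3 codes are conventionally padded to 5 characters with trailing
#' dots (`"G573."`); padding is stripped before prefix comparison so that
#' `"G573."` and `"G5730"` are recognised as parent and child. The original
#' string is never altered in outputs, only in comparisons.
#'
#' @param x character vector of codes.
#' @param ignore_case fold case before comparison (READ codes are
#'   case-significant, so the default is `FALSE`).
#' @return normalized character vector, same length as `x`.
#' @export
normalize_code <- function(x, ignore_case = FALSE) {
  x <- trimws2(as.character(x))
  x <- sub("\\.+$", "", x)
  if (ignore_case) x <- toupper(x)
  x
}

## ISO-8601 date parsing; anything non-ISO fails loudly.
parse_iso_date <- function(x, what = "date") {
  x <- as.character(x)
  x[!is.na(x) & trimws2(x) == ""] <- NA_character_
  d <- data.table::as.IDate(rep(NA_integer_, length(x)))
  ok <- !is.na(x)
  if (any(ok)) {
    parsed <- suppressWarnings(data.table::as.IDate(x[ok], format = "%Y-%m-%d"))
    bad <- is.na(parsed) | !grepl("^\\d{4}-\\d{2}-\\d{2}$", x[ok])
    if (any(bad)) {
      stop(sprintf("non-ISO-8601 %s value(s): %s (expected YYYY-MM-DD)",
                   what, paste(unique(utils::head(x[ok][bad], 5)), collapse = ", ")),
           call. = FALSE)
    }
    d[which(ok)] <- parsed
  }
  d
}

stop_missing_file <- function(path, what = "file") {
  if (!file.exists(path)) {
    stop(sprintf("%s not found: '%s'", what, path), call. = FALSE)
  }
  invisible(path)
}

## canonical empty episode table (the 7-column episode schema)
empty_episodes <- function() {
  data.table::data.table(
    .id = character(), identifier = character(), code = character(),
    eventdate = data.table::as.IDate(integer()), event = integer(),
    epidur = integer(), classification = character()
  )
}

as_episode_table <- function(dt) {
  cols <- c(".id", "identifier", "code", "eventdate", "event", "epidur",
            "classification")
  stopifnot(all(cols %in% names(dt)))
  out <- dt[, cols, with = FALSE]
  out[, identifier := as.character(identifier)]
  out[, code := as.character(code)]
  out[, event := as.integer(event)]
  out[, epidur := as.integer(epidur)]
  out[]
}
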
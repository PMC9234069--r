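#' Read the data-settings table
#'
#' The data-settings file declares, per harmonizable data source, how that
#' source is read and matched: which definition-table column carries its
#' codes, the coding system, whether prefix hierarchy applies, case
#' sensitivity, how event dates are obtained, the default event flag and the
#' minimum number of matched episodes a participant needs before the source
#' counts. Optional columns wire self-report fields to their companion timing
#' fields and name the code-map file.
#'
#' Required columns: `source_id`, `definition_column`, `classification`,
#' `hierarchical`, `ignore_case`, `date_rule`, `default_event_flag`,
#' `min_instances`. Optional: `code_map`, `field_id`, `timing_field`,
#' `timing_type` (`year`/`age`).
#'
#' @param path tab-separated settings file with a header.
#' @return a `data.table`, one row per source, validated and typed.
#' @export
read_data_settings <- function(path) {
  stop_missing_file(path, "data-settings file")
  st <- data.table::fread(path, sep = "\t", colClasses = "character",
                          showProgress = FALSE)
  req <- c("source_id", "definition_column", "classification", "hierarchical",
           "ignore_case", "date_rule", "default_event_flag", "min_instances")
  missing <- setdiff(req, names(st))
  if (length(missing)) {
    stop(sprintf("data-settings file lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (opt in c("code_map", "timing_field", "timing_type", "field_id")) {
    if (!opt %in% names(st)) data.table::set(st, j = opt, value = NA_character_)
  }
  st[, hierarchical := toupper(hierarchical) %in% c("TRUE", "T", "1", "YES")]
  st[, ignore_case := toupper(ignore_case) %in% c("TRUE", "T", "1", "YES")]
  st[, default_event_flag := as.integer(default_event_flag)]
  st[, min_instances := as.integer(min_instances)]
  st[is.na(min_instances), min_instances := 1L]
  st[, code_map := ifelse(nzchar(trimws2(code_map)) & code_map != "NA",
                          trimws2(code_map), NA_character_)]
  st[, timing_field := suppressWarnings(as.integer(timing_field))]
  st[, field_id := suppressWarnings(as.integer(field_id))]
  st[, timing_type := ifelse(timing_type %in% c("year", "age"),
                             timing_type, NA_character_)]
  if (anyDuplicated(st$source_id)) {
    stop("duplicate source_id in data-settings file", call. = FALSE)
  }
  if (!all(st$default_event_flag %in% 0:2)) {
    stop("default_event_flag must be 0, 1 or 2", call. = FALSE)
  }
  st[]
}

#' Path to the bundled example data-settings file
#' @return file path within the installed package.
#' @export
example_data_settings <- function() {
  system.file("extdata", "data.settings.tsv", package = "cohortpheno")
}

#' Path to the bundled example definition table
#' @return file path within the installed package.
#' @export
example_definitions <- function() {
  system.file("extdata", "definitions_example.tsv", package = "cohortpheno")
}

#' Path to the bundled toy code-map directory
#' @return directory path within the installed package.
#' @export
example_codemap_dir <- function() {
  system.file("extdata", "codemaps", package = "cohortpheno")
}

## load one code_map per classification that declares a map file
load_settings_codemaps <- function(settings, codemap_dir) {
  cls <- unique(settings[!is.na(code_map),
                         .(classification, code_map, hierarchical, ignore_case)])
  if (anyDuplicated(cls$classification)) {
    stop("conflicting code_map/hierarchical settings within one classification",
         call. = FALSE)
  }
  maps <- list()
  for (i in seq_len(nrow(cls))) {
    p <- file.path(codemap_dir, cls$code_map[i])
    maps[[cls$classification[i]]] <- load_code_map(
      p, system_id = cls$classification[i],
      hierarchical = cls$hierarchical[i])
  }
  maps
}
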
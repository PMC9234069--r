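## Readers for the cohort's own file dialects: the wide main dataset
## (columns f.<field>.<instance>.<array>), its field-metadata document,
## record-level tables and the participant withdrawal list.

parse_column_label <- function(label) {
  m <- regmatches(label, regexec("^f\\.(\\d+)\\.(\\d+)\\.(\\d+)$", label))[[1]]
  if (length(m) == 0L) return(NULL)
  list(field_id = as.integer(m[2]), instance = as.integer(m[3]),
       array_index = as.integer(m[4]))
}

.catalog_types <- c("integer", "real", "text", "date", "categorical")

#' Read the field-metadata document into a field catalog
#'
#' Accepts either the html metadata document produced alongside the main
#' dataset (a table with columns `column`, `field_id`, `instance`, `array`,
#' `type`) or, as the stable fallback, a TSV with columns `column_label`,
#' `field_id`, `type` (instance/array are then recovered from the label).
#' The participant-identifier column `f.eid` is renamed to `identifier`.
#'
#' @param metadata_path path to the html or TSV metadata file.
#' @return a `field_catalog`: data.table with columns `column_label`,
#'   `field_id`, `instance`, `array_index`, `type`.
#' @export
read_field_catalog <- function(metadata_path) {
  stop_missing_file(metadata_path, "metadata file")
  is_html <- grepl("\\.x?html?$", metadata_path, ignore.case = TRUE) ||
    grepl("^\\s*<", readLines(metadata_path, n = 1L, warn = FALSE)[1] %||% "")
  if (is_html) {
    doc <- xml2::read_html(metadata_path)
    rows <- xml2::xml_find_all(doc, "//table//tr")
    cells <- lapply(rows, function(r)
      xml2::xml_text(xml2::xml_find_all(r, "./td|./th")))
    cells <- Filter(function(x) length(x) >= 2L, cells)
    if (length(cells) < 2L) {
      stop(sprintf("unparseable html metadata document: '%s'", metadata_path),
           call. = FALSE)
    }
    header <- tolower(trimws2(cells[[1]]))
    body <- cells[-1]
    col_i <- which(header %in% c("column", "column_label", "udi"))[1]
    type_i <- which(header == "type")[1]
    if (is.na(col_i) || is.na(type_i)) {
      stop("html metadata table lacks 'column'/'type' headers", call. = FALSE)
    }
    cat <- data.table::rbindlist(lapply(body, function(x)
      list(column_label = trimws2(x[col_i]), type = tolower(trimws2(x[type_i])))))
  } else {
    tsv <- data.table::fread(metadata_path, sep = "\t",
                             colClasses = "character", showProgress = FALSE)
    if (!all(c("column_label", "type") %in% names(tsv))) {
      stop("TSV metadata requires columns 'column_label' and 'type'",
           call. = FALSE)
    }
    cat <- tsv[, .(column_label, type = tolower(type))]
  }
  cat <- cat[nzchar(column_label)]
  parsed <- lapply(cat$column_label, parse_column_label)
  cat[, field_id := vapply(parsed, function(p) p$field_id %||% NA_integer_,
                           integer(1))]
  cat[, instance := vapply(parsed, function(p) p$instance %||% NA_integer_,
                           integer(1))]
  cat[, array_index := vapply(parsed, function(p) p$array_index %||% NA_integer_,
                              integer(1))]
  cat[column_label == "f.eid", column_label := "identifier"]
  bad <- setdiff(unique(cat$type), .catalog_types)
  if (length(bad)) {
    stop(sprintf("unknown value type(s) in metadata: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!"identifier" %in% cat$column_label) {
    stop("metadata document lacks the participant identifier column (f.eid)",
         call. = FALSE)
  }
  data.table::setattr(cat, "class", c("field_catalog", class(cat)))
  cat[]
}

catalog_columns_for_fields <- function(catalog, field_ids) {
  catalog[field_id %in% field_ids][order(field_id, instance, array_index),
                                   column_label]
}

#' Read selected fields from the main dataset
#'
#' Projects the wide tab-separated main dataset down to the participant
#' identifier plus every instance/array column of the requested fields,
#' parsed to their catalog types (dates must be ISO-8601).
#'
#' @param tab_path main dataset TSV (header `f.eid  f.53.0.0 ...`).
#' @param catalog a [read_field_catalog()] result.
#' @param fields_to_keep integer vector of field ids.
#' @param allow_missing if `TRUE`, requested fields absent from the dataset
#'   are skipped with a warning; if `FALSE` the read halts.
#' @return a `data.table` keyed by `identifier` (character).
#' @export
read_main_dataset <- function(tab_path, catalog, fields_to_keep,
                              allow_missing = TRUE) {
  stop_missing_file(tab_path, "main dataset")
  header <- names(data.table::fread(tab_path, nrows = 0L, sep = "\t",
                                    showProgress = FALSE))
  present_fields <- unique(catalog[column_label %in%
    sub("^f\\.eid$", "identifier", header)][!is.na(field_id), field_id])
  absent <- setdiff(fields_to_keep, present_fields)
  if (length(absent)) {
    msg <- sprintf("field(s) not present in main dataset: %s",
                   paste(absent, collapse = ", "))
    if (!allow_missing) stop(msg, call. = FALSE)
    warning(paste(msg, "(skipped)"), call. = FALSE)
  }
  want <- catalog_columns_for_fields(catalog, setdiff(fields_to_keep, absent))
  id_col <- intersect(c("f.eid", "identifier"), header)[1]
  if (is.na(id_col)) {
    stop("main dataset lacks the participant identifier column", call. = FALSE)
  }
  sel <- c(id_col, intersect(want, header))
  dt <- data.table::fread(tab_path, sep = "\t", select = sel,
                          colClasses = "character", showProgress = FALSE)
  data.table::setnames(dt, id_col, "identifier")
  if (anyDuplicated(dt$identifier)) {
    stop("duplicate participant identifiers in main dataset", call. = FALSE)
  }
  for (col in setdiff(names(dt), "identifier")) {
    ty <- catalog[column_label == col, type][1]
    data.table::set(dt, j = col, value = switch(ty,
      integer = suppressWarnings(as.integer(dt[[col]])),
      real = suppressWarnings(as.numeric(dt[[col]])),
      categorical = suppressWarnings(as.numeric(dt[[col]])),
      date = parse_iso_date(dt[[col]], what = col),
      dt[[col]]))
    if (ty == "text") {
      v <- dt[[col]]
      v[!is.na(v) & !nzchar(v)] <- NA_character_
      data.table::set(dt, j = col, value = v)
    }
  }
  data.table::setkeyv(dt, "identifier")
  dt[]
}

#' Read a participant withdrawal list
#'
#' One identifier per line; a non-numeric first line is treated as a header
#' and skipped. An empty file is allowed and yields an empty set.
#'
#' @param path withdrawal-list file, or `NULL`/`NA` for no list.
#' @return character vector of identifiers (possibly empty).
#' @export
read_withdrawals <- function(path) {
  if (is.null(path) || (length(path) == 1L && is.na(path))) return(character())
  stop_missing_file(path, "withdrawal list")
  lines <- trimws2(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(character())
  if (!grepl("^[0-9]+$", lines[1])) lines <- lines[-1]
  unique(lines)
}

## generic record-level table reader: TSV with header; identifier column
## renamed to "identifier"; returns character columns.
read_record_table <- function(path, id_col = c("eid", "identifier")) {
  stop_missing_file(path, "record-level file")
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          showProgress = FALSE)
  idc <- intersect(id_col, names(dt))[1]
  if (is.na(idc)) {
    stop(sprintf("record-level file '%s' lacks an identifier column (%s)",
                 path, paste(id_col, collapse = "/")), call. = FALSE)
  }
  data.table::setnames(dt, idc, "identifier")
  dt
}

#' Write/read harmonized episode tables as TSV
#'
#' Episodes serialize losslessly: dates as ISO-8601, missing values as empty
#' cells. `read_episodes` restores the exact 7-column schema and types.
#'
#' @param episodes an episode `data.table`.
#' @param path file path.
#' @return `write_episodes`: invisibly `path`; `read_episodes`: episode table.
#' @export
write_episodes <- function(episodes, path) {
  data.table::fwrite(as_episode_table(data.table::as.data.table(episodes)),
                     path, sep = "\t", quote = FALSE, dateTimeAs = "ISO")
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  stop_missing_file(path, "episode file")
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          showProgress = FALSE, na.strings = c("", "NA"))
  if (nrow(dt) == 0L) return(empty_episodes())
  dt[, eventdate := parse_iso_date(eventdate)]
  as_episode_table(dt)
}
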
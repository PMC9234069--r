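## Parsing of the phenotype definition table: codelists with annotations,
## self-report field specifications, touchscreen conditions and composite
## phenotype references.

## split a cell on commas that are not inside () or []; errors on unbalanced
## parentheses.
split_outside_parens <- function(text) {
  text <- as.character(text %||% "")
  if (is.na(text) || !nzchar(trimws2(text))) return(character())
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  buf <- character()
  out <- character()
  for (ch in chars) {
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- depth - 1L
    if (depth < 0L) {
      stop(sprintf("unbalanced parentheses in '%s'", text), call. = FALSE)
    }
    if (ch == "," && depth == 0L) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
  }
  if (depth != 0L) {
    stop(sprintf("unbalanced parentheses in '%s'", text), call. = FALSE)
  }
  out <- trimws2(c(out, paste(buf, collapse = "")))
  out[nzchar(out)]
}

#' Parse a comma-separated code list
#'
#' Codes are separated by commas; a free-text annotation in parentheses is
#' attached to the immediately preceding code and stripped from the code
#' string itself (`"E11(type 2 code)"` gives code `E11`). Annotations are
#' metadata only and are never matched against data.
#'
#' @param text one definition-table cell.
#' @return a `data.table` with columns `raw`, `code`, `annotation` (NA when
#'   absent), one row per code, input order preserved.
#' @export
parse_code_entry <- function(text) {
  frags <- split_outside_parens(text)
  if (length(frags) == 0L) {
    return(data.table::data.table(raw = character(), code = character(),
                                  annotation = character()))
  }
  ann <- rep(NA_character_, length(frags))
  m <- regmatches(frags, regexec("\\(([^()]*)\\)\\s*$", frags))
  has <- lengths(m) == 2L
  ann[has] <- vapply(m[has], `[[`, "", 2L)
  code <- trimws2(sub("\\(([^()]*)\\)\\s*$", "", frags))
  bad <- !nzchar(code)
  if (any(bad)) {
    stop(sprintf("code entry with empty code: '%s'", frags[bad][1]),
         call. = FALSE)
  }
  data.table::data.table(raw = frags, code = code, annotation = ann)
}

#' Parse a self-report field specification
#'
#' A specification is either a bare field number (`"20003"`), meaning any
#' non-missing, non-negative value in that field counts as a record, or a
#' field number with a code set in parentheses (`"20002(1471, 1483)"`).
#'
#' @param text one specification, e.g. from the SR column.
#' @return list with `raw`, `field_id` (integer), `codes` (character vector,
#'   empty when any value matches) and `any` (logical).
#' @export
parse_field_spec <- function(text) {
  text <- trimws2(text)
  m <- regmatches(text, regexec("^(\\d+)\\s*(?:\\((.*)\\))?$", text))[[1]]
  if (length(m) == 0L || !nzchar(m[2])) {
    stop(sprintf("malformed field specification: '%s' (expected 'field' or 'field(code,...)')",
                 text), call. = FALSE)
  }
  codes <- if (nzchar(m[3])) trimws2(strsplit(m[3], ",")[[1]]) else character()
  codes <- codes[nzchar(codes)]
  list(raw = text, field_id = as.integer(m[2]), codes = codes,
       any = length(codes) == 0L)
}

.comparators <- c("=", "!=", "<", "<=", ">", ">=")

#' Parse a touchscreen condition
#'
#' Syntax: `field <cmp> value [age_field] (annotation)`, the last two parts
#' optional; comparators are `=`, `!=`, `<`, `<=`, `>`, `>=` with the unicode
#' aliases `≥`/`≤` accepted for `>=`/`<=`. The optional bracketed
#' field gives the companion age-of-diagnosis field.
#'
#' @param text one condition, e.g. `"6177=3(insulin)"` or
#'   `"4041=1[2976](Gestational diabetes)"`.
#' @return list with `raw`, `field_id`, `comparator`, `value`, `age_field`
#'   (integer or NA), `annotation` (or NA) and `canonical` (annotation-free
#'   canonical text used as the episode code).
#' @export
parse_condition <- function(text) {
  raw <- trimws2(text)
  txt <- gsub("≥", ">=", gsub("≤", "<=", raw))
  pat <- "^(\\d+)\\s*(!=|>=|<=|=|<|>)\\s*([^\\[\\(]+?)\\s*(?:\\[(\\d+)\\])?\\s*(?:\\(([^()]*)\\))?$"
  m <- regmatches(txt, regexec(pat, txt))[[1]]
  if (length(m) == 0L) {
    stop(sprintf(
      "malformed condition '%s': expected field, one of {%s}, value, optional [age_field] and (annotation)",
      raw, paste(.comparators, collapse = " ")), call. = FALSE)
  }
  age_field <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  canonical <- paste0(m[2], m[3], m[4],
                      if (!is.na(age_field)) paste0("[", age_field, "]") else "")
  list(raw = raw, field_id = as.integer(m[2]), comparator = m[3],
       value = m[4], age_field = age_field,
       annotation = if (nzchar(m[6])) m[6] else NA_character_,
       canonical = canonical)
}

split_trait_refs <- function(text) {
  refs <- trimws2(strsplit(as.character(text %||% ""), ",")[[1]])
  refs[nzchar(refs)]
}

#' Read, validate and expand a phenotype definition table
#'
#' The definition table is a UTF-8 TSV with a header: one phenotype per row,
#' a unique case-sensitive `TRAIT` identifier, one code column per coding
#' system (named as declared in the data-settings file), an `SR` column of
#' self-report field specifications, a `TS` column of touchscreen conditions
#' and the four composite columns `Study_population`, `Include_definitions`,
#' `Exclude_from_cases`, `Exclude_from_controls`.
#'
#' Parent codes are expanded against the code maps at parse time; codes absent
#' from the map are dropped with a warning and listed in the validation
#' report, so downstream matching is a plain set lookup.
#'
#' @param path definition-table file.
#' @param settings a [read_data_settings()] table (or a path to one).
#' @param codemap_dir directory holding the code-map files named in
#'   `settings$code_map`.
#' @return a `definition_set`: list with `definitions` (named list), `traits`
#'   (character), `settings`, and `report` (dropped codes + warnings).
#' @export
read_definition_table <- function(path, settings, codemap_dir) {
  stop_missing_file(path, "definition table")
  if (is.character(settings)) settings <- read_data_settings(settings)
  df <- data.table::fread(path, sep = "\t", colClasses = "character",
                          showProgress = FALSE)
  if (!"TRAIT" %in% names(df)) {
    stop("definition table lacks the TRAIT column", call. = FALSE)
  }
  if (anyDuplicated(df$TRAIT)) {
    stop(sprintf("duplicate TRAIT identifier(s): %s",
                 paste(unique(df$TRAIT[duplicated(df$TRAIT)]), collapse = ", ")),
         call. = FALSE)
  }
  maps <- load_settings_codemaps(settings, codemap_dir)
  ## column -> classification for code columns backed by a map
  codecols <- unique(settings[!is.na(code_map),
                              .(definition_column, classification, ignore_case)])
  sr_col <- unique(settings[classification == "sr", definition_column])
  ts_col <- unique(settings[classification == "ts", definition_column])
  composite_cols <- c("Study_population", "Include_definitions",
                      "Exclude_from_cases", "Exclude_from_controls")
  known <- c("TRAIT", "DESCRIPTION", codecols$definition_column, sr_col,
             ts_col, composite_cols)
  unknown <- setdiff(names(df), known)
  warnings <- character()
  if (length(unknown)) {
    w <- sprintf("ignoring unknown definition-table column(s): %s",
                 paste(unknown, collapse = ", "))
    warning(w, call. = FALSE)
    warnings <- c(warnings, w)
  }
  dropped <- data.table::data.table(trait = character(), column = character(),
                                    code = character())
  defs <- list()
  for (i in seq_len(nrow(df))) {
    trait <- df$TRAIT[i]
    cell <- function(col) if (col %in% names(df)) df[[col]][i] else ""
    patterns <- list()
    code_sets <- list()
    for (j in seq_len(nrow(codecols))) {
      col <- codecols$definition_column[j]
      cls <- codecols$classification[j]
      pats <- parse_code_entry(cell(col))
      if (nrow(pats)) {
        map <- maps[[cls]]
        ic <- codecols$ignore_case[j]
        pats[, matched := vapply(code, function(cd)
          length(expand_codes(cd, map, ignore_case = ic)) > 0L, logical(1))]
        exp <- expand_codes(pats$code, map, ignore_case = ic)
        if (any(!pats$matched)) {
          bad <- pats$code[!pats$matched]
          w <- sprintf("trait %s, column %s: code(s) not in %s map, dropped: %s",
                       trait, col, cls, paste(bad, collapse = ", "))
          warning(w, call. = FALSE)
          warnings <- c(warnings, w)
          dropped <- rbind(dropped, data.table::data.table(
            trait = trait, column = col, code = bad))
        }
        patterns[[col]] <- pats
        if (length(exp)) {
          code_sets[[cls]] <- sort(unique(c(code_sets[[cls]], exp)))
        }
      }
    }
    field_specs <- lapply(split_outside_parens(cell(sr_col[1] %||% "SR")),
                          parse_field_spec)
    conditions <- lapply(split_outside_parens(cell(ts_col[1] %||% "TS")),
                         parse_condition)
    sp <- split_trait_refs(cell("Study_population"))
    if (length(sp) > 1L) {
      stop(sprintf("trait %s: Study_population must name a single trait", trait),
           call. = FALSE)
    }
    defs[[trait]] <- structure(list(
      trait = trait,
      description = cell("DESCRIPTION"),
      patterns = patterns,
      code_sets = code_sets,
      field_specs = field_specs,
      conditions = conditions,
      study_population = if (length(sp)) sp else NA_character_,
      include_definitions = split_trait_refs(cell("Include_definitions")),
      exclude_from_cases = split_trait_refs(cell("Exclude_from_cases")),
      exclude_from_controls = split_trait_refs(cell("Exclude_from_controls"))
    ), class = "phenotype_definition")
  }
  ## composite references must resolve
  for (d in defs) {
    refs <- c(if (!is.na(d$study_population)) d$study_population,
              d$include_definitions, d$exclude_from_cases,
              d$exclude_from_controls)
    bad <- setdiff(refs, names(defs))
    if (length(bad)) {
      stop(sprintf("trait %s references unknown trait(s): %s", d$trait,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(definitions = defs, traits = names(defs),
                 settings = settings,
                 report = list(dropped_codes = dropped, warnings = warnings)),
            class = "definition_set")
}

#' @export
print.definition_set <- function(x, ...) {
  cat(sprintf("<definition_set> %d trait(s): %s\n", length(x$traits),
              paste(x$traits, collapse = ", ")))
  if (nrow(x$report$dropped_codes)) {
    cat(sprintf("  %d code(s) dropped during validation\n",
                nrow(x$report$dropped_codes)))
  }
  invisible(x)
}

#' Serialize a definition set back to the normalized table format
#'
#' Writes a TSV that [read_definition_table()] parses back to an identical
#' definition set (given the same settings and code maps): annotations,
#' unmatched codes and composite references are all preserved verbatim.
#'
#' @param defset a `definition_set`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_definition_table <- function(defset, path) {
  stopifnot(inherits(defset, "definition_set"))
  settings <- defset$settings
  codecols <- unique(settings[!is.na(code_map), definition_column])
  sr_col <- unique(settings[classification == "sr", definition_column])[1] %||% "SR"
  ts_col <- unique(settings[classification == "ts", definition_column])[1] %||% "TS"
  cols <- c("TRAIT", "DESCRIPTION", codecols, sr_col, ts_col,
            "Study_population", "Include_definitions", "Exclude_from_cases",
            "Exclude_from_controls")
  rows <- lapply(defset$definitions, function(d) {
    vals <- setNames(rep("", length(cols)), cols)
    vals["TRAIT"] <- d$trait
    vals["DESCRIPTION"] <- d$description %||% ""
    for (col in names(d$patterns)) {
      vals[col] <- paste(d$patterns[[col]]$raw, collapse = ", ")
    }
    vals[sr_col] <- paste(vapply(d$field_specs, `[[`, "", "raw"), collapse = ", ")
    vals[ts_col] <- paste(vapply(d$conditions, `[[`, "", "raw"), collapse = ", ")
    vals["Study_population"] <- if (is.na(d$study_population)) "" else d$study_population
    vals["Include_definitions"] <- paste(d$include_definitions, collapse = ", ")
    vals["Exclude_from_cases"] <- paste(d$exclude_from_cases, collapse = ", ")
    vals["Exclude_from_controls"] <- paste(d$exclude_from_controls, collapse = ", ")
    as.list(vals)
  })
  out <- data.table::rbindlist(rows)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Dependency-ordered evaluation plan for a composite phenotype
#'
#' Returns the traits that must be evaluated, all referenced traits before
#' the target, following `Study_population`, `Include_definitions`,
#' `Exclude_from_cases` and `Exclude_from_controls` edges recursively.
#'
#' @param defset a `definition_set`.
#' @param trait target trait identifier.
#' @return character vector: a topological order ending in `trait`.
#' @export
plan_composite <- function(defset, trait) {
  stopifnot(inherits(defset, "definition_set"))
  if (!trait %in% defset$traits) {
    stop(sprintf("unknown trait '%s'", trait), call. = FALSE)
  }
  order <- character()
  onstack <- character()
  visit <- function(t) {
    if (t %in% order) return(invisible())
    if (t %in% onstack) {
      stop(sprintf("cyclic composite reference: %s",
                   paste(c(onstack[which(onstack == t):length(onstack)], t),
                         collapse = " -> ")), call. = FALSE)
    }
    onstack <<- c(onstack, t)
    d <- defset$definitions[[t]]
    refs <- c(if (!is.na(d$study_population)) d$study_population,
              d$include_definitions, d$exclude_from_cases,
              d$exclude_from_controls)
    for (r in unique(refs)) visit(r)
    onstack <<- setdiff(onstack, t)
    order <<- c(order, t)
    invisible()
  }
  visit(trait)
  order
}
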
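#' Load a classification-system code map
#'
#' A code map lists every code known to one coding system (ICD-10, ICD-9,
#' OPCS-4, READ2, CTV3, a drug dictionary, ...). Maps are plain text, UTF-8,
#' tab-separated, no header: either one code per line or two columns
#' (code, description). Hierarchical systems allow definition tables to name
#' only a parent code; [expand_codes()] then pulls in every descendant by
#' prefix.
#'
#' @param path file path to the map.
#' @param system_id short label for the coding system (e.g. `"icd10"`).
#' @param hierarchical does prefix hierarchy apply to this system?
#' @return an object of class `code_map`: list with `system_id`, `codes`
#'   (unique, whitespace-trimmed), `description` (named character, possibly
#'   empty) and `hierarchical`.
#' @export
load_code_map <- function(path, system_id, hierarchical = FALSE) {
  stop_missing_file(path, "code map")
  stopifnot(is.character(system_id), nzchar(system_id))
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           blank.lines.skip = TRUE,
                           stringsAsFactors = FALSE)
  codes <- trimws2(raw[[1]])
  keep <- nzchar(codes)
  codes <- codes[keep]
  if (length(codes) == 0L) {
    stop(sprintf("code map '%s' contains no parseable rows", path),
         call. = FALSE)
  }
  desc <- if (ncol(raw) >= 2L) trimws2(raw[[2]][keep]) else rep("", length(codes))
  dup <- duplicated(codes)
  codes_u <- codes[!dup]
  desc_u <- desc[!dup]
  description <- setNames(desc_u[nzchar(desc_u)], codes_u[nzchar(desc_u)])
  structure(
    list(system_id = system_id, codes = codes_u,
         description = description, hierarchical = isTRUE(hierarchical)),
    class = "code_map"
  )
}

#' @export
print.code_map <- function(x, ...) {
  cat(sprintf("<code_map> %s: %d codes (%s)\n", x$system_id, length(x$codes),
              if (x$hierarchical) "hierarchical" else "flat"))
  invisible(x)
}

#' Expand parent codes against a code map
#'
#' For hierarchical maps, every map code of which a pattern is a prefix is
#' returned (plus exact matches); for flat maps only exact matches. READ-style
#' trailing-dot padding is stripped on both sides before comparison, so the
#' pattern `"G573."` matches `"G5730"`, `"G573z"` and `"G573."` itself. The
#' returned strings are always the map's own (original) code strings, so the
#' result is a subset of `map$codes`.
#'
#' @param patterns character vector of code patterns (parents or leaves).
#' @param map a [load_code_map()] result.
#' @param ignore_case fold case before matching (default `FALSE`; READ codes
#'   are case-significant).
#' @return character vector of matched map codes, in map order.
#' @export
expand_codes <- function(patterns, map, ignore_case = FALSE) {
  stopifnot(inherits(map, "code_map"))
  if (length(patterns) == 0L) return(character())
  pat <- unique(normalize_code(patterns, ignore_case))
  pat <- pat[nzchar(pat)]
  if (length(pat) == 0L) return(character())
  norm <- normalize_code(map$codes, ignore_case)
  if (map$hierarchical) {
    hit <- rep(FALSE, length(norm))
    for (p in pat) {
      hit <- hit | startsWith(norm, p)
    }
  } else {
    hit <- norm %in% pat
  }
  map$codes[hit]
}

#' Extract flat code maps from a record-level table
#'
#' Builds one flat (non-hierarchical) code-map file per requested column by
#' collecting the sorted unique non-empty values of that column. Useful when
#' no curated map is available: the map then contains exactly the codes
#' observed in the data.
#'
#' @param record_path tab-separated record-level file with a header.
#' @param code_columns character vector of column names holding codes.
#' @param out_prefix path prefix for outputs; each map is written to
#'   `<out_prefix><column>.tsv`.
#' @return invisibly, the character vector of file paths written.
#' @export
extract_existing_codes <- function(record_path, code_columns, out_prefix) {
  stop_missing_file(record_path, "record file")
  dt <- data.table::fread(record_path, sep = "\t", colClasses = "character",
                          showProgress = FALSE)
  missing <- setdiff(code_columns, names(dt))
  if (length(missing)) {
    stop(sprintf("column(s) not present in '%s': %s", record_path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  paths <- character(0)
  for (col in code_columns) {
    codes <- sort(unique(trimws2(dt[[col]])))
    codes <- codes[nzchar(codes) & !is.na(codes)]
    out <- paste0(out_prefix, col, ".tsv")
    if (length(codes) == 0L) {
      warning(sprintf("column '%s' has no non-empty codes; writing empty map", col),
              call. = FALSE)
    }
    writeLines(codes, out)
    paths <- c(paths, out)
  }
  invisible(paths)
}
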
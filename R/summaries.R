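## Thin reporting layer: the acceptance-relevant numbers all live in the
## tables produced by the ascertainment module; figures here are best-effort
## conveniences rendered with base graphics.

#' Render report tables and figures
#'
#' Writes one file per requested format for each non-empty input table:
#' `tsv` writes the table itself, `png` renders a simple base-graphics
#' figure (frequency bar chart, per-year timeline, source-overlap counts,
#' individual timeline). Empty tables are skipped silently with a note in
#' the report. Input tables are never mutated.
#'
#' @param tables named list; recognised names: `frequency`
#'   ([event_stats()] output), `timeline` ([timeline_counts()]), `overlap`
#'   ([source_overlap_matrix()]), `individual` ([individual_timeline()]),
#'   `casecontrol` (the 16-column summary). Unrecognised names are written
#'   as TSV only.
#' @param out_dir output directory (created if absent).
#' @param formats subset of `c("tsv", "png")`.
#' @param dropped_codes optional validation report table of dropped codes;
#'   each row becomes one log line.
#' @return a `report_bundle`: list with `files` (paths written) and `report`
#'   (character log lines).
#' @export
render_reports <- function(tables, out_dir, formats = c("tsv"),
                           dropped_codes = NULL) {
  bad <- setdiff(formats, c("tsv", "png"))
  if (length(bad)) {
    stop(sprintf("unknown format(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  report <- character()
  if (!is.null(dropped_codes) && nrow(dropped_codes)) {
    report <- c(report, sprintf("dropped code %s (trait %s, column %s)",
                                dropped_codes$code, dropped_codes$trait,
                                dropped_codes$column))
  }
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.null(tb) || nrow(tb) == 0L) {
      report <- c(report, sprintf("table '%s' empty; skipped", nm))
      next
    }
    if ("tsv" %in% formats) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      data.table::fwrite(tb, p, sep = "\t", quote = FALSE)
      files <- c(files, p)
    }
    if ("png" %in% formats) {
      p <- file.path(out_dir, paste0(nm, ".png"))
      grDevices::png(p, width = 800, height = 500)
      tryCatch(plot_report_table(nm, tb), finally = grDevices::dev.off())
      files <- c(files, p)
    }
  }
  rp <- file.path(out_dir, "report.log")
  writeLines(report, rp)
  files <- c(files, rp)
  structure(list(files = files, report = report), class = "report_bundle")
}

plot_report_table <- function(nm, tb) {
  if (nm == "frequency" && all(c("code", "n_events") %in% names(tb))) {
    top <- utils::head(tb, 20)
    graphics::barplot(top$n_events, names.arg = top$code, las = 2,
                      main = "Event count per code", ylab = "events")
  } else if (nm == "timeline" && all(c("year", "source_id", "n") %in% names(tb))) {
    wide <- data.table::dcast(tb, source_id ~ year, value.var = "n",
                              fill = 0)
    m <- as.matrix(wide[, -1, with = FALSE])
    rownames(m) <- wide$source_id
    graphics::barplot(m, legend.text = rownames(m), las = 2,
                      main = "Events per year by source", ylab = "events")
  } else if (nm == "overlap") {
    srcs <- setdiff(names(tb), "identifier")
    counts <- vapply(srcs, function(s) sum(tb[[s]]), numeric(1))
    graphics::barplot(counts, names.arg = srcs, las = 2,
                      main = "Participants with baseline evidence by source")
  } else if (nm == "individual" && "eventdate" %in% names(tb)) {
    y <- as.integer(factor(tb$.id))
    graphics::plot(tb$eventdate, y, yaxt = "n", pch = 19,
                   xlab = "date", ylab = "", main = "Individual timeline")
    graphics::axis(2, at = seq_along(levels(factor(tb$.id))),
                   labels = levels(factor(tb$.id)), las = 2, cex.axis = 0.7)
    graphics::text(tb$eventdate, y, tb$code, pos = 3, cex = 0.6)
  } else {
    graphics::plot.new()
    graphics::title(main = sprintf("%s (%d rows)", nm, nrow(tb)))
  }
  invisible(NULL)
}
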
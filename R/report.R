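#' Write a scenario report
#'
#' Serialises a [scenario_grid()] result (or any scenario summary data frame,
#' e.g. the `summaries` of a [scan_p()]) to CSV or JSON with a deterministic
#' column order and, for CSV, percentages rendered to one decimal place in
#' the style of the published summary tables. Writing the same results twice
#' produces identical bytes; the JSON form round-trips to the in-memory
#' values.
#'
#' @param results A `minim_grid`, `minim_pscan`, `minim_scenario` or plain
#'   data frame of summary rows.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as_report_df(results)
  if (nrow(df) == 0L) stop("'results' is empty", call. = FALSE)
  if (format == "csv") {
    out <- df
    pct_cols <- grep("_pct$|^predictability", names(out), value = TRUE)
    for (cc in pct_cols) out[[cc]] <- sprintf("%.1f", out[[cc]])
    prob_cols <- grep("^prob_", names(out), value = TRUE)
    for (cc in prob_cols) out[[cc]] <- sprintf("%.3f", out[[cc]])
    utils::write.table(out, file = path, sep = ",", row.names = FALSE,
                       quote = TRUE, eol = "\n", na = "")
  } else {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA,
                         dataframe = "rows", pretty = TRUE, na = "null")
  }
  invisible(path)
}

as_report_df <- function(results) {
  if (inherits(results, "minim_scenario")) return(scenario_row(results))
  if (inherits(results, "minim_pscan")) return(results$summaries)
  if (inherits(results, "minim_grid") || is.data.frame(results))
    return(as.data.frame(results))
  stop("unsupported results object of class ",
       paste(class(results), collapse = "/"), call. = FALSE)
}

#' Read back a JSON scenario report
#'
#' Inverse of [render_report()] with `format = "json"`.
#'
#' @param path JSON file written by [render_report()].
#' @return A data frame of summary rows.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
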
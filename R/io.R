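# Delimited-text I/O: cohorts, fit reports, validation summaries.

#' Column dictionary for cohort files
#'
#' The canonical column names, units and meanings used by the delimited-text
#' cohort format (comma by default, tab accepted; decimal point only).
#'
#' @return a data frame with columns `name`, `unit`, `description`.
#' @export
cohort_dictionary <- function() {
  data.frame(
    name = .cohort_vars,
    unit = c("cm", "kg", "cm", "y", "y", "mm", "mm", "kg", "kg", "kg"),
    description = c(
      "stature", "body mass", "sitting height", "decimal age",
      "maturity offset (years from peak height velocity)",
      "suprailiac skinfold", "horizontal abdominal skinfold",
      "fat mass", "bone mineral content", "lean soft tissue"
    )
  )
}

.guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a cohort (or measurement) table from delimited text
#'
#' Reads a comma- or tab-delimited file with a header row of dictionary
#' names (see [cohort_dictionary()]). All data cells must be numeric; a
#' non-numeric cell aborts with the offending column and row index. A file
#' with a header but no data rows yields an empty data frame.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) guesses from the header line.
#' @return a data frame.
#' @export
read_cohort <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  sep <- sep %||% .guess_sep(path)
  df <- utils::read.table(path,
    header = TRUE, sep = sep, colClasses = "character",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (col in names(df)) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !(trimws(df[[col]]) %in% c("NA", "")))
    if (length(bad)) {
      stop_input(
        "non-numeric value in column `", col, "` at data row ",
        bad[1L], ": \"", df[[col]][bad[1L]], "\""
      )
    }
    df[[col]] <- x
  }
  df
}

#' Write a table as delimited text at full precision
#'
#' Numeric cells are written with 17 significant digits so that a
#' write/read round trip reproduces the values exactly.
#'
#' @param x data frame.
#' @param path file path.
#' @param sep field separator (`","` default, `"\t"` accepted).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, sep = ",") {
  df <- as.data.frame(x)
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path,
    sep = sep, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Export a fit (and optional cross-validation) report
#'
#' Writes a delimited report mirroring the published layout: the coefficient
#' block (one row per predictor, one column per response) followed by the
#' precision block (R^2, adjusted R^2, residual SEE) and, when a
#' [press_loo()] result is supplied, the cross-validation block (PRESS,
#' R^2_PRESS, RMSE_PRESS).
#'
#' @param fit a [fit_multivariate_ls()] result.
#' @param path file path.
#' @param press optional `press_result`.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
export_fit_report <- function(fit, path, press = NULL, sep = ",") {
  stopifnot(inherits(fit, "multivariate_fit"))
  rows <- rbind(
    fit$beta,
    `R2` = fit$r2, `Adj_R2` = fit$adj_r2, `SEE_residual` = fit$see_residual
  )
  if (!is.null(press)) {
    stopifnot(inherits(press, "press_result"))
    rows <- rbind(rows,
      `PRESS` = press$press, `R2_PRESS` = press$r2_press,
      `RMSE_PRESS` = press$rmse_press
    )
  }
  df <- data.frame(quantity = rownames(rows), rows, row.names = NULL, check.names = FALSE)
  write_cohort(df, path, sep = sep)
}

#' Export a machine-readable validation summary
#'
#' Key-value text (`key = value`, one per line) covering the per-response
#' PRESS, cross-validated R^2 and RMSE.
#'
#' @param press a `press_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
export_validation_summary <- function(press, path) {
  stopifnot(inherits(press, "press_result"))
  keys <- c(
    sprintf("n = %d", press$n),
    sprintf("press_%s = %.10g", names(press$press), press$press),
    sprintf("r2_press_%s = %.10g", names(press$r2_press), press$r2_press),
    sprintf("rmse_press_%s = %.10g", names(press$rmse_press), press$rmse_press)
  )
  writeLines(keys, path)
  invisible(path)
}
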
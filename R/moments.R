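# Population moments of the study sample, used to synthesize cohorts.

#' Bundle of population moments for cohort synthesis
#'
#' Per-variable mean, SD and (min, max) range, plus a pairwise correlation
#' matrix. The matrix as supplied (`correlation`) may be indefinite when it
#' mixes printed and imputed entries; a nearest positive-semidefinite repair
#' (`correlation_psd`, via [Matrix::nearPD()]) is stored alongside and is the
#' one the generators sample from.
#'
#' @param table data frame with columns `variable`, `mean`, `sd`, `min`,
#'   `max`.
#' @param correlation symmetric correlation matrix with unit diagonal, row
#'   and column names matching `table$variable`.
#' @param repair repair the matrix to nearest-PSD when indefinite (default);
#'   `FALSE` stores `correlation_psd = NULL` (used for sample summaries,
#'   which may contain undefined correlations).
#' @return an object of class `population_moments`.
#' @seealso [default_moments()] for the embedded study values.
#' @export
population_moments <- function(table, correlation, repair = TRUE) {
  need <- c("variable", "mean", "sd", "min", "max")
  if (!all(need %in% names(table))) {
    stop_input("moments table needs columns ", paste(need, collapse = ", "))
  }
  if (any(table$sd < 0, na.rm = TRUE)) stop_input("SDs must be non-negative")
  correlation <- as.matrix(correlation)
  v <- table$variable
  if (!identical(dim(correlation), c(length(v), length(v))) ||
    !identical(rownames(correlation), v) || !identical(colnames(correlation), v)) {
    stop_input("correlation matrix dimnames must match the variable set")
  }
  if (max(abs(correlation - t(correlation)), na.rm = TRUE) > 1e-12 ||
    any(abs(diag(correlation) - 1) > 1e-12)) {
    stop_input("correlation matrix must be symmetric with unit diagonal")
  }
  correlation_psd <- NULL
  if (repair) {
    if (anyNA(correlation)) stop_input("cannot repair a correlation matrix with NAs")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= 0) {
      correlation_psd <- correlation
    } else {
      correlation_psd <- as.matrix(Matrix::nearPD(correlation,
        corr = TRUE, keepDiag = TRUE
      )$mat)
      dimnames(correlation_psd) <- dimnames(correlation)
    }
  }
  structure(
    list(
      table = as.data.frame(table), correlation = correlation,
      correlation_psd = correlation_psd
    ),
    class = "population_moments"
  )
}

#' @export
print.population_moments <- function(x, digits = 3, ...) {
  cat("Population moments for", nrow(x$table), "variables\n")
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Moments of the development sample
#'
#' The embedded means, SDs and observed ranges of the ten modelled variables
#' (stature, body mass, sitting height, age, maturity offset, the two trunk
#' skinfolds, and the three DXA components), together with their correlation
#' structure. Pairs not published are filled by a documented completion rule
#' (the product of each variable's correlation with body mass, the strongest
#' shared covariate; sitting height enters through its correlation with
#' stature, set to 0.97) and the completed matrix is repaired to the nearest
#' positive-semidefinite matrix for sampling.
#'
#' @return a [population_moments()] object.
#' @examples
#' m <- default_moments()
#' m$table[m$table$variable == "fm", ]
#' @export
default_moments <- function() {
  if (!is.null(.anthro_cache$default_moments)) {
    return(.anthro_cache$default_moments)
  }
  tab <- data.frame(
    variable = .cohort_vars,
    mean = c(158.1, 50.2, 82.3, 13.7, -0.5, 13.3, 16.5, 9.3, 2.1, 38.1),
    sd = c(17.7, 17.4, 8.8, 2.99, 2.5, 10.2, 12.0, 7.5, 0.8, 12.7),
    min = c(120.3, 20.6, 61.5, 8, -4.7, 2.8, 1.5, 1.3, 0.7, 17.1),
    max = c(196.8, 119.4, 99.5, 18, 4.5, 64.5, 66.0, 41.8, 4.1, 72.6)
  )
  R <- diag(length(.cohort_vars))
  dimnames(R) <- list(.cohort_vars, .cohort_vars)
  set2 <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  # published pairwise correlations
  set2("height", "weight", .84)
  set2("height", "sk_suprailiac", .12)
  set2("height", "sk_horiz_abdominal", .11)
  set2("height", "phv", .94)
  set2("height", "age", .88)
  set2("height", "fm", .28)
  set2("height", "bmc", .91)
  set2("height", "lst", .95)
  set2("weight", "sk_suprailiac", .54)
  set2("weight", "sk_horiz_abdominal", .52)
  set2("weight", "phv", .87)
  set2("weight", "age", .78)
  set2("weight", "fm", .70)
  set2("weight", "bmc", .92)
  set2("weight", "lst", .91)
  set2("sk_suprailiac", "sk_horiz_abdominal", .90)
  set2("sk_suprailiac", "phv", .17)
  set2("sk_suprailiac", "age", .08)
  set2("sk_suprailiac", "fm", .92)
  set2("sk_suprailiac", "bmc", .24)
  set2("sk_suprailiac", "lst", .17)
  set2("sk_horiz_abdominal", "phv", .15)
  set2("sk_horiz_abdominal", "age", .05)
  set2("sk_horiz_abdominal", "fm", .92)
  set2("sk_horiz_abdominal", "bmc", .22)
  set2("sk_horiz_abdominal", "lst", .14)
  set2("phv", "age", .97)
  set2("phv", "fm", .32)
  set2("phv", "bmc", .93)
  set2("phv", "lst", .95)
  set2("age", "fm", .22)
  set2("age", "bmc", .87)
  set2("age", "lst", .89)
  # completion rule: unpublished response-response pairs through body mass
  set2("fm", "bmc", R["fm", "weight"] * R["bmc", "weight"])
  set2("fm", "lst", R["fm", "weight"] * R["lst", "weight"])
  set2("bmc", "lst", R["bmc", "weight"] * R["lst", "weight"])
  # sitting height: no published correlations; enters through stature
  set2("seating_height", "height", 0.97)
  for (v in setdiff(.cohort_vars, c("seating_height", "height"))) {
    set2("seating_height", v, 0.97 * R["height", v])
  }
  .anthro_cache$default_moments <- population_moments(tab, R)
  .anthro_cache$default_moments
}

#' Moments restricted to the five model predictors
#'
#' Convenience accessor: the subset of [default_moments()] (or any supplied
#' moments) covering height, weight, the two skinfolds and the maturity
#' offset, in the coefficient-matrix row order.
#'
#' @param moments a [population_moments()] object.
#' @return a [population_moments()] over the five predictors.
#' @export
predictor_moments <- function(moments = default_moments()) {
  stopifnot(inherits(moments, "population_moments"))
  keep <- match(.predictor_labels, moments$table$variable)
  if (anyNA(keep)) stop_input("moments must cover all five model predictors")
  population_moments(
    moments$table[keep, , drop = FALSE],
    moments$correlation[.predictor_labels, .predictor_labels]
  )
}
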
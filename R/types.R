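# Domain types: anthropometric record, body composition, coefficient matrix.

#' A single subject's anthropometric measurements
#'
#' Bundles the measured inputs of the multicomponent model. Units are fixed:
#' cm for lengths, kg for mass, mm for skinfolds, years for age and maturity
#' offset; no unit inference is performed. When `phv` is absent but `age` and
#' `seating_height` are given, the maturity offset is computed with
#' [maturity_offset()] at construction and tagged as derived.
#'
#' @param height stature, cm (> 0).
#' @param weight scale-measured body mass, kg (> 0).
#' @param sk_suprailiac suprailiac skinfold, mm (>= 0).
#' @param sk_horiz_abdominal horizontal abdominal skinfold, mm (>= 0).
#' @param seating_height sitting height, cm (optional; must be < `height`).
#' @param age decimal age, years (optional).
#' @param phv maturity offset, years from peak height velocity (optional).
#' @return an object of class `anthro_record`.
#' @examples
#' anthropometric_record(
#'   height = 148.3, weight = 40.0,
#'   sk_suprailiac = 18.7, sk_horiz_abdominal = 20.0, phv = -1.6
#' )
#' @export
anthropometric_record <- function(height, weight, sk_suprailiac, sk_horiz_abdominal,
                                  seating_height = NULL, age = NULL, phv = NULL) {
  check_finite_scalar(height, "height")
  check_finite_scalar(weight, "weight")
  check_finite_scalar(sk_suprailiac, "sk_suprailiac")
  check_finite_scalar(sk_horiz_abdominal, "sk_horiz_abdominal")
  if (height <= 0) stop_input("`height` must be positive")
  if (weight <= 0) stop_input("`weight` must be positive")
  if (sk_suprailiac < 0 || sk_horiz_abdominal < 0) {
    stop_input("skinfolds must be non-negative")
  }
  if (!is.null(seating_height)) {
    check_finite_scalar(seating_height, "seating_height")
    if (seating_height <= 0) stop_input("`seating_height` must be positive")
    if (seating_height >= height) {
      stop_input("`seating_height` must be smaller than `height`")
    }
  }
  if (!is.null(age)) check_finite_scalar(age, "age")
  phv_source <- "given"
  if (is.null(phv)) {
    if (!is.null(age) && !is.null(seating_height)) {
      phv <- maturity_offset(age, height, seating_height, weight)
      phv_source <- "computed"
    } else {
      phv_source <- "missing"
    }
  } else {
    check_finite_scalar(phv, "phv")
  }
  structure(
    list(
      height = height, weight = weight,
      sk_suprailiac = sk_suprailiac, sk_horiz_abdominal = sk_horiz_abdominal,
      seating_height = seating_height, age = age,
      phv = if (identical(phv_source, "missing")) NA_real_ else phv,
      phv_source = phv_source
    ),
    class = "anthro_record"
  )
}

#' @export
print.anthro_record <- function(x, ...) {
  cat("Anthropometric record\n")
  cat(sprintf("  height %.1f cm, weight %.1f kg\n", x$height, x$weight))
  cat(sprintf(
    "  skinfolds: suprailiac %.1f mm, horizontal abdominal %.1f mm\n",
    x$sk_suprailiac, x$sk_horiz_abdominal
  ))
  if (!is.na(x$phv)) {
    cat(sprintf("  maturity offset %.2f y (%s)\n", x$phv, x$phv_source))
  } else {
    cat("  maturity offset: missing\n")
  }
  invisible(x)
}

#' The three predicted body components
#'
#' Fat mass (FM), bone mineral content (BMC) and lean soft tissue (LST), all
#' in kg. Values must be finite but carry no sign constraint: the
#' intercept-free linear model can produce negative masses on out-of-range
#' inputs, which are flagged with a warning rather than clipped.
#'
#' @param fm fat mass, kg.
#' @param bmc bone mineral content, kg.
#' @param lst lean soft tissue, kg.
#' @return an object of class `body_composition`.
#' @export
body_composition <- function(fm, bmc, lst) {
  check_finite_scalar(fm, "fm")
  check_finite_scalar(bmc, "bmc")
  check_finite_scalar(lst, "lst")
  structure(
    list(fm = unname(fm), bmc = unname(bmc), lst = unname(lst)),
    class = "body_composition"
  )
}

#' @export
print.body_composition <- function(x, ...) {
  cat(sprintf(
    "Body composition (kg): FM %.2f | BMC %.2f | LST %.2f\n",
    x$fm, x$bmc, x$lst
  ))
  invisible(x)
}

#' @export
as.double.body_composition <- function(x, ...) {
  c(fm = x$fm, bmc = x$bmc, lst = x$lst)
}

#' Coefficient matrix of the multicomponent model
#'
#' A 5 x 3 matrix of regression coefficients mapping the five predictors
#' (height, weight, suprailiac skinfold, horizontal abdominal skinfold,
#' maturity offset) to the three responses (FM, BMC, LST). There is no
#' intercept row: the model is intercept-free.
#'
#' @param values numeric 5 x 3 matrix.
#' @param predictor_labels,response_labels row/column labels; defaults are the
#'   canonical ones and most users never change them.
#' @return an object of class `coef_matrix` (a labelled matrix).
#' @seealso [published_coefficients()] for the embedded published instance.
#' @export
coefficient_matrix <- function(values,
                               predictor_labels = .predictor_labels,
                               response_labels = .response_labels) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop_input("coefficient values must be finite numeric")
  }
  if (nrow(values) != 5L || ncol(values) != 3L) {
    stop_input(
      "coefficient matrix must be 5 x 3 (got ",
      nrow(values), " x ", ncol(values), ")"
    )
  }
  if (anyDuplicated(predictor_labels) || anyDuplicated(response_labels)) {
    stop_input("coefficient labels must be unique")
  }
  dimnames(values) <- list(predictor_labels, response_labels)
  class(values) <- c("coef_matrix", class(values))
  values
}

#' @export
print.coef_matrix <- function(x, ...) {
  cat("Multicomponent coefficient matrix (kg per predictor unit)\n")
  print(unclass(x), ...)
  invisible(x)
}
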
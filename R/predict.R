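# The published multicomponent predictor and its per-term breakdown.

.anthro_cache <- new.env(parent = emptyenv())

#' Published multicomponent coefficient matrix
#'
#' Returns the published 5 x 3 coefficient matrix of the intercept-free
#' multicomponent model for boys (e.g. height contributes -0.0857 kg of FM
#' per cm; weight contributes 0.6419 kg of LST per kg). The values are
#' shipped as a delimited-text resource inside the package and can be
#' overridden with a user file of identical shape via
#' [read_coefficient_matrix()].
#'
#' @return a [coefficient_matrix()].
#' @examples
#' published_coefficients()
#' @export
published_coefficients <- function() {
  if (is.null(.anthro_cache$published)) {
    path <- system.file("extdata", "multicomponent_coefficients.csv",
      package = "anthrocomp", mustWork = TRUE
    )
    .anthro_cache$published <- read_coefficient_matrix(path)
  }
  .anthro_cache$published
}

#' Read or write a coefficient matrix as delimited text
#'
#' The file format is a header `predictor,fm,bmc,lst` followed by five rows,
#' one per predictor, matching the published resource's shape.
#'
#' @param path file path.
#' @param x a [coefficient_matrix()] (for writing).
#' @param sep field separator (`","` or `"\t"`).
#' @return `read_coefficient_matrix()` returns a [coefficient_matrix()];
#'   `write_coefficient_matrix()` returns `path` invisibly.
#' @export
read_coefficient_matrix <- function(path, sep = ",") {
  if (!file.exists(path)) stop_input("coefficient file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("predictor", .response_labels)
  if (!all(need %in% names(tab))) {
    stop_input(
      "coefficient file must have columns ",
      paste(need, collapse = ", ")
    )
  }
  coefficient_matrix(as.matrix(tab[, .response_labels]),
    predictor_labels = tab$predictor
  )
}

#' @rdname read_coefficient_matrix
#' @export
write_coefficient_matrix <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "coef_matrix"))
  tab <- data.frame(predictor = rownames(x), unclass(x)[, , drop = FALSE])
  utils::write.table(tab, path,
    sep = sep, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Observed predictor ranges of the development sample; predictions outside
# them are extrapolations and are flagged, never refused.
.predictor_ranges <- matrix(
  c(
    120.3, 196.8,
    20.6, 119.4,
    2.8, 64.5,
    1.5, 66.0,
    -4.7, 4.5
  ),
  ncol = 2L, byrow = TRUE,
  dimnames = list(.predictor_labels, c("min", "max"))
)

# Coerce a record / data.frame to the n x 5 predictor matrix.
as_predictor_matrix <- function(record) {
  if (inherits(record, "anthro_record")) {
    if (is.na(record$phv)) {
      missing <- c(
        "phv",
        if (is.null(record$age)) "age",
        if (is.null(record$seating_height)) "seating_height"
      )
      stop_input(
        "maturity offset unavailable; missing fields: ",
        paste(missing, collapse = ", ")
      )
    }
    m <- matrix(
      c(
        record$height, record$weight, record$sk_suprailiac,
        record$sk_horiz_abdominal, record$phv
      ),
      nrow = 1L, dimnames = list(NULL, .predictor_labels)
    )
    return(m)
  }
  record <- as.data.frame(record)
  if (!("phv" %in% names(record)) || anyNA(record$phv)) {
    helpers <- c("age", "seating_height", "height", "weight")
    if (all(helpers %in% names(record))) {
      idx <- if ("phv" %in% names(record)) is.na(record$phv) else rep(TRUE, nrow(record))
      record$phv[idx] <- maturity_offset(
        record$age[idx], record$height[idx],
        record$seating_height[idx], record$weight[idx]
      )
    } else {
      stop_input(
        "maturity offset unavailable; missing fields: ",
        paste(setdiff(c("phv", helpers), names(record)), collapse = ", ")
      )
    }
  }
  miss <- setdiff(.predictor_labels, names(record))
  if (length(miss)) {
    stop_input("missing required columns: ", paste(miss, collapse = ", "))
  }
  as.matrix(record[, .predictor_labels, drop = FALSE])
}

#' Predict fat mass, bone mineral content and lean soft tissue
#'
#' Applies the intercept-free multicomponent model: each component is the
#' inner product of the predictor vector (height cm, weight kg, suprailiac
#' skinfold mm, horizontal abdominal skinfold mm, maturity offset y) with its
#' coefficient column.
#'
#' Inputs outside the development sample's observed ranges trigger an
#' extrapolation warning (class `anthrocomp_extrapolation`); negative
#' predicted masses are returned as-is with a warning, never clipped.
#'
#' @param record an [anthropometric_record()] or a data frame with columns
#'   `height`, `weight`, `sk_suprailiac`, `sk_horiz_abdominal` and either
#'   `phv` or (`age`, `seating_height`).
#' @param coeffs a [coefficient_matrix()]; defaults to the published one.
#' @param warn_extrapolation set to `FALSE` to silence range checks.
#' @return a [body_composition()] for a single record, otherwise a data frame
#'   with columns `fm`, `bmc`, `lst` (kg).
#' @examples
#' rec <- anthropometric_record(148.3, 40.0, 18.7, 20.0, phv = -1.6)
#' predict_components(rec)
#' @export
predict_components <- function(record, coeffs = published_coefficients(),
                               warn_extrapolation = TRUE) {
  stopifnot(inherits(coeffs, "coef_matrix"))
  X <- as_predictor_matrix(record)
  if (warn_extrapolation) {
    for (v in .predictor_labels) {
      out <- X[, v] < .predictor_ranges[v, "min"] | X[, v] > .predictor_ranges[v, "max"]
      if (any(out)) {
        warn_anthro(
          "`", v, "` outside the development range [",
          .predictor_ranges[v, "min"], ", ", .predictor_ranges[v, "max"],
          "] for ", sum(out), " record(s); prediction is an extrapolation",
          class = "anthrocomp_extrapolation"
        )
      }
    }
  }
  Yhat <- X %*% unclass(coeffs)
  if (any(Yhat < 0)) {
    warn_anthro(
      "negative predicted mass for ", sum(rowSums(Yhat < 0) > 0),
      " record(s); returned unclipped",
      class = "anthrocomp_negative_mass"
    )
  }
  if (inherits(record, "anthro_record")) {
    body_composition(Yhat[1L, "fm"], Yhat[1L, "bmc"], Yhat[1L, "lst"])
  } else {
    as.data.frame(Yhat)
  }
}

#' Per-term product breakdown of a prediction
#'
#' Expands a single prediction into the worked-example layout: for each
#' predictor, the measured value, the coefficient per response, and their
#' product (kg); column sums equal the [predict_components()] output.
#'
#' @inheritParams predict_components
#' @return an object of class `product_table`: a data frame with one row per
#'   predictor and attribute `totals` (named fm/bmc/lst sums, kg).
#' @export
product_breakdown <- function(record, coeffs = published_coefficients(),
                              warn_extrapolation = TRUE) {
  stopifnot(inherits(coeffs, "coef_matrix"))
  X <- as_predictor_matrix(record)
  if (nrow(X) != 1L) stop_input("`product_breakdown()` expects a single record")
  B <- unclass(coeffs)
  tab <- data.frame(
    predictor = rownames(B),
    measure = as.numeric(X[1L, ]),
    beta_fm = B[, "fm"], product_fm = X[1L, ] * B[, "fm"],
    beta_bmc = B[, "bmc"], product_bmc = X[1L, ] * B[, "bmc"],
    beta_lst = B[, "lst"], product_lst = X[1L, ] * B[, "lst"],
    row.names = NULL
  )
  pred <- predict_components(record, coeffs, warn_extrapolation = warn_extrapolation)
  structure(tab,
    totals = as.numeric(pred),
    class = c("product_table", class(tab))
  )
}

#' @export
print.product_table <- function(x, digits = 4, ...) {
  cat("Per-term products of the multicomponent prediction\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  tot <- attr(x, "totals")
  cat(sprintf(
    "Totals (kg): FM %.2f | BMC %.2f | LST %.2f\n",
    tot[["fm"]], tot[["bmc"]], tot[["lst"]]
  ))
  invisible(x)
}
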
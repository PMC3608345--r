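# PRESS leave-one-out cross-validation.

.press_result <- function(press, Y, n, labels) {
  tss_c <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  structure(
    list(
      press = stats::setNames(press, labels),
      r2_press = stats::setNames(1 - press / tss_c, labels),
      rmse_press = stats::setNames(sqrt(press / n), labels),
      n = n
    ),
    class = "press_result"
  )
}

#' PRESS statistic via the hat-matrix shortcut
#'
#' Leave-one-out prediction error: for least squares the deleted residual is
#' \eqn{e_i / (1 - h_{ii})}, so
#' \eqn{\mathrm{PRESS} = \sum_i e_i^2 / (1 - h_{ii})^2} per response without
#' refitting. `press_naive()` performs the literal n delete-one refits and is
#' kept as an independent cross-check; the two agree to numerical precision.
#'
#' The cross-validated \eqn{R^2_{PRESS} = 1 - \mathrm{PRESS} / \sum_i (y_i -
#' \bar y)^2} uses the centered total sum of squares and may be negative for
#' poor models. `rmse_press` is \eqn{\sqrt{\mathrm{PRESS}/n}} (kg).
#'
#' @param X numeric n x p design matrix (no intercept).
#' @param Y numeric n x m response matrix.
#' @param include_intercept passed to [fit_multivariate_ls()].
#' @param tol leverages above `1 - tol` abort with an error naming the point.
#' @return an object of class `press_result` with per-response `press` (kg^2),
#'   `r2_press`, `rmse_press` (kg).
#' @export
press_loo <- function(X, Y, include_intercept = FALSE, tol = 1e-8) {
  fit <- fit_multivariate_ls(X, Y, include_intercept = include_intercept)
  if (fit$n <= fit$p + 1L) stop_input("need n > p + 1 observations for leave-one-out")
  bad <- which(fit$hat >= 1 - tol)
  if (length(bad)) {
    stop_numeric(
      "leverage ~ 1 at observation(s) ",
      paste(bad, collapse = ", "), "; deleted residual undefined"
    )
  }
  press <- colSums((fit$residuals / (1 - fit$hat))^2)
  .press_result(press, fit$Y, fit$n, colnames(fit$Y))
}

#' @rdname press_loo
#' @export
press_naive <- function(X, Y, include_intercept = FALSE) {
  X <- as_design(X, "X")
  Y <- as_design(Y, "Y")
  n <- nrow(X)
  if (n <= ncol(X) + 1L + include_intercept) {
    stop_input("need n > p + 1 observations for leave-one-out")
  }
  err2 <- matrix(0, n, ncol(Y))
  Xfull <- if (include_intercept) cbind("(Intercept)" = 1, X) else X
  for (i in seq_len(n)) {
    fit_i <- fit_multivariate_ls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
      include_intercept = include_intercept
    )
    err2[i, ] <- (Y[i, ] - Xfull[i, , drop = FALSE] %*% fit_i$beta)^2
  }
  .press_result(colSums(err2), Y, n, colnames(Y))
}

#' @export
print.press_result <- function(x, digits = 4, ...) {
  cat(sprintf("PRESS leave-one-out cross-validation (n = %d)\n", x$n))
  print(round(rbind(
    PRESS = x$press, `R^2 PRESS` = x$r2_press, `RMSE PRESS` = x$rmse_press
  ), digits))
  invisible(x)
}

#' Cross-validated coefficient of determination from a PRESS value
#'
#' \eqn{R^2_{PRESS} = 1 - \mathrm{PRESS} / ((n - 1)\,\mathrm{Var}(y)}), i.e.
#' the centered total sum of squares in the denominator. Supply either the
#' response column `y` or its summary moments (`n`, `sd`).
#'
#' @param press PRESS value (squared response units).
#' @param y response column (alternative to `n` + `sd`).
#' @param n,sd sample size and standard deviation of the response.
#' @return the cross-validated R^2 (may be negative).
#' @examples
#' r2_press(1162.433, n = 408, sd = 7.5)
#' @export
r2_press <- function(press, y = NULL, n = NULL, sd = NULL) {
  check_finite_scalar(press, "press")
  if (!is.null(y)) {
    if (length(y) < 2L) stop_input("`y` must have at least two values")
    n <- length(y)
    sd <- stats::sd(y)
  } else if (is.null(n) || is.null(sd)) {
    stop_input("supply `y` or both `n` and `sd`")
  }
  if (sd <= 0) stop_input("response variance must be positive")
  1 - press / ((n - 1) * sd^2)
}
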
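# Pillai's trace for testing terms of the multivariate model.

#' Pillai trace kernel
#'
#' \eqn{V = \mathrm{tr}\,[H (H + E)^{-1}]} for a hypothesis
#' sum-of-products matrix H and an error matrix E.
#'
#' @param H,E symmetric m x m matrices.
#' @return the trace statistic V, bounded by `min(m, rank(H))`.
#' @export
pillai_trace <- function(H, E) {
  H <- as.matrix(H)
  E <- as.matrix(E)
  if (!all(dim(H) == dim(E))) stop_input("`H` and `E` must have the same dimensions")
  HE <- H + E
  if (!all(is.finite(HE)) || rcond(HE) < 1e-12) {
    stop_numeric("H + E is singular; Pillai trace undefined")
  }
  sum(diag(H %*% solve(HE)))
}

#' Pillai trace test for dropping a set of design columns
#'
#' Compares the fitted multivariate model with the model stripped of
#' `term_columns`: H is the increase in the residual sum-of-products matrix,
#' E the full model's residual sum-of-products. The approximate F uses the
#' standard transform with \eqn{s = \min(q, h)}, \eqn{m = (|h - q| - 1)/2},
#' \eqn{n^* = (\nu_e - q - 1)/2}, where q is the number of responses, h the
#' hypothesis degrees of freedom, and \eqn{\nu_e} the full model's error
#' degrees of freedom; for h = 1 the transform is exact.
#'
#' @param fit a [fit_multivariate_ls()] result.
#' @param term_columns character vector of design column labels to test.
#' @return an object of class `pillai_test` with `statistic` (V),
#'   `f_value`, `df1`, `df2`, `p_value`.
#' @export
pillai_trace_test <- function(fit, term_columns) {
  stopifnot(inherits(fit, "multivariate_fit"))
  if (length(term_columns) == 0L) stop_input("`term_columns` must be non-empty")
  labels <- colnames(fit$X)
  if (!all(term_columns %in% labels)) {
    stop_input(
      "unknown design column(s): ",
      paste(setdiff(term_columns, labels), collapse = ", ")
    )
  }
  keep <- setdiff(labels, term_columns)
  E <- crossprod(fit$residuals)
  if (length(keep) == 0L) {
    res0 <- fit$Y # null model: fitted values are zero (no intercept)
  } else {
    fit0 <- fit_multivariate_ls(fit$X[, keep, drop = FALSE], fit$Y,
      include_intercept = FALSE
    )
    res0 <- fit0$residuals
  }
  H <- crossprod(res0) - E
  # degenerate (noise-free) problems: H and E both vanish relative to Y'Y
  if (max(abs(H + E)) < 1e-10 * max(abs(crossprod(fit$Y)))) {
    stop_numeric("H + E is degenerate (residual scale ~ 0); Pillai trace undefined")
  }
  V <- pillai_trace(H, E)
  q <- ncol(fit$Y)
  h <- length(term_columns)
  nu_e <- fit$df_residual
  s <- min(q, h)
  m <- (abs(h - q) - 1) / 2
  nstar <- (nu_e - q - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nstar + s + 1)
  f_value <- (df2 / df1) * (V / s) / (1 - V / s)
  structure(
    list(
      statistic = V, f_value = f_value, df1 = df1, df2 = df2,
      p_value = stats::pf(f_value, df1, df2, lower.tail = FALSE),
      term_columns = term_columns, s = s
    ),
    class = "pillai_test"
  )
}

#' @export
print.pillai_test <- function(x, ...) {
  cat(sprintf(
    "Pillai trace test of {%s}: V = %.4f, F(%g, %g) = %.3f, p = %.4g\n",
    paste(x$term_columns, collapse = ", "),
    x$statistic, x$df1, x$df2, x$f_value, x$p_value
  ))
  invisible(x)
}
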
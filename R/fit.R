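# Simultaneous multivariate least squares and collinearity diagnostics.

as_design <- function(X, what = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X) || !all(is.finite(X))) {
    stop_input("`", what, "` must be a finite numeric matrix")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0(what, seq_len(ncol(X)))
  X
}

#' Fit the simultaneous multivariate regression Y = X B + E
#'
#' Solves the three-response (or generally m-response) least-squares problem
#' through the normal equations \eqn{B = (X'X)^{-1} X'Y}, which for full-rank
#' X is identical to stacking the per-response univariate fits column-wise.
#' The model is intercept-free by default, matching the published
#' multicomponent equations; an intercept column can be prepended for
#' comparison fits.
#'
#' Per response the fit reports \eqn{R^2} (against the uncentered total sum
#' of squares for intercept-free fits — the same convention `stats::lm`
#' prints — and the centered one when an intercept is included), the centered
#' \eqn{R^2} alongside, the adjusted \eqn{R^2}, and the residual standard
#' error of estimate \eqn{\sqrt{SSE/(n-p)}}.
#'
#' @param X numeric n x p design matrix (no intercept column).
#' @param Y numeric n x m response matrix (columns fm/bmc/lst in the intended
#'   application).
#' @param include_intercept prepend a column of ones before fitting.
#' @return an object of class `multivariate_fit` with elements `beta` (p x m),
#'   `residuals`, `fitted`, `r2`, `r2_centered`, `adj_r2`, `see_residual`,
#'   `hat` (leverages, summing to p), `df_residual`, and the data (`X`, `Y`)
#'   for downstream tests.
#' @examples
#' X <- cbind(x = c(1, 2, 3, 4))
#' Y <- cbind(y = c(2, 1, 4, 3))
#' fit_multivariate_ls(X, Y)$beta
#' @export
fit_multivariate_ls <- function(X, Y, include_intercept = FALSE) {
  X <- as_design(X, "X")
  Y <- as_design(Y, "Y")
  if (nrow(X) != nrow(Y)) stop_input("`X` and `Y` must have the same number of rows")
  if (include_intercept) {
    X <- cbind("(Intercept)" = 1, X)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop_input("need more observations than predictors (n > p)")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, p)]]
    stop_numeric(
      "design matrix is rank deficient; dependent column(s): ",
      paste(bad, collapse = ", ")
    )
  }
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, Y))
  dimnames(beta) <- list(colnames(X), colnames(Y))
  fitted <- X %*% beta
  res <- Y - fitted
  sse <- colSums(res^2)
  tss_c <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  tss_u <- colSums(Y^2)
  tss <- if (include_intercept) tss_c else tss_u
  r2 <- 1 - sse / tss
  adj_r2 <- 1 - (1 - r2) * (n - include_intercept) / (n - p)
  h <- rowSums(qr.Q(qx)^2)
  structure(
    list(
      beta = beta, residuals = res, fitted = fitted,
      r2 = r2, r2_centered = 1 - sse / tss_c, adj_r2 = adj_r2,
      see_residual = sqrt(sse / (n - p)),
      hat = h, df_residual = n - p, n = n, p = p,
      include_intercept = include_intercept,
      X = X, Y = Y
    ),
    class = "multivariate_fit"
  )
}

#' @export
print.multivariate_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Multivariate least-squares fit: n = %d, p = %d%s\n",
    x$n, x$p, if (x$include_intercept) " (with intercept)" else " (no intercept)"
  ))
  cat("Coefficients:\n")
  print(round(x$beta, digits))
  prec <- rbind(
    `R^2` = x$r2, `Adj R^2` = x$adj_r2,
    `SEE residual` = x$see_residual
  )
  cat("Precision:\n")
  print(round(prec, digits))
  invisible(x)
}

#' Eigenvalue-ratio multicollinearity diagnostic
#'
#' Computes the ratio of the largest to the smallest eigenvalue of X'X and
#' classifies it: below 100 weak, 100 to 1000 (inclusive at both ends)
#' moderate, above 1000 severe. A numerically null smallest eigenvalue is
#' reported as `severe` with an infinite ratio. By default the raw X'X is
#' used; `scale` allows centering or full correlation scaling for comparison,
#' since the classification bands were formulated for the raw matrix of this
#' model's predictors.
#'
#' @param X numeric design matrix.
#' @param scale `"none"` (raw X'X, default), `"center"` (covariance), or
#'   `"correlation"`.
#' @return an object of class `collinearity_report` with `lambda_ratio`,
#'   `category`, and the eigenvalues.
#' @export
collinearity_ratio <- function(X, scale = c("none", "center", "correlation")) {
  X <- as_design(X, "X")
  scale <- match.arg(scale)
  Xs <- switch(scale,
    none = X,
    center = sweep(X, 2L, colMeans(X)),
    correlation = {
      Xc <- sweep(X, 2L, colMeans(X))
      sweep(Xc, 2L, pmax(apply(Xc, 2L, stats::sd), .Machine$double.eps), "/")
    }
  )
  ev <- eigen(crossprod(Xs), symmetric = TRUE, only.values = TRUE)$values
  tol <- max(ev) * 1e-12
  if (min(ev) <= tol) {
    ratio <- Inf
    category <- "severe"
  } else {
    ratio <- max(ev) / min(ev)
    category <- if (ratio < 100) "weak" else if (ratio <= 1000) "moderate" else "severe"
  }
  structure(
    list(lambda_ratio = ratio, category = category, eigenvalues = ev, scale = scale),
    class = "collinearity_report"
  )
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf(
    "Collinearity (X'X eigenvalue ratio, scale = %s): lambda = %s -> %s\n",
    x$scale, format(x$lambda_ratio, digits = 6), x$category
  ))
  invisible(x)
}
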
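#' Technical error of measurement for duplicate measures
#'
#' Dahlberg's formula for m duplicate pairs:
#' \eqn{\mathrm{TEM} = \sqrt{\sum_i d_i^2 / (2m)}} with \eqn{d_i} the
#' within-pair difference, in the measurement's units; the relative error is
#' \eqn{\mathrm{TEM}\% = 100\,\mathrm{TEM}/\bar{x}} with \eqn{\bar{x}} the
#' grand mean over all 2m measurements. TEM is zero exactly when every pair
#' is identical, and scales with the data while TEM% is scale-free.
#'
#' @param first,second numeric vectors: first and repeat measurement per
#'   subject. Alternatively `first` may be a two-column matrix/data frame.
#' @return an object of class `tem_result` with `tem`, `tem_pct`, `m`.
#' @examples
#' technical_error(c(10, 20), c(11, 19))
#' @export
technical_error <- function(first, second = NULL) {
  if (is.null(second)) {
    pairs <- as.matrix(first)
    if (ncol(pairs) != 2L) stop_input("`first` must have two columns when `second` is missing")
    first <- pairs[, 1L]
    second <- pairs[, 2L]
  }
  if (length(first) != length(second) || length(first) < 1L) {
    stop_input("need at least one duplicate pair of equal length")
  }
  if (!all(is.finite(first)) || !all(is.finite(second))) {
    stop_input("duplicate measurements must be finite")
  }
  m <- length(first)
  tem <- sqrt(sum((first - second)^2) / (2 * m))
  grand <- mean(c(first, second))
  if (grand <= 0) stop_input("grand mean of duplicates must be positive for TEM%")
  structure(
    list(tem = tem, tem_pct = 100 * tem / grand, m = m),
    class = "tem_result"
  )
}

#' @export
print.tem_result <- function(x, ...) {
  cat(sprintf(
    "Technical error of measurement (m = %d pairs): TEM = %.4g, TEM%% = %.4g\n",
    x$m, x$tem, x$tem_pct
  ))
  invisible(x)
}
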
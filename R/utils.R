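# Internal helpers: classed conditions, logging, truncated-normal machinery.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_input <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("anthrocomp_input_error", "anthrocomp_error")))
}

#' @keywords internal
stop_numeric <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("anthrocomp_numeric_error", "anthrocomp_error")))
}

warn_anthro <- function(..., class = "anthrocomp_warning") {
  warning(warningCondition(paste0(...), class = c(class, "anthrocomp_warning")))
}

.log_levels <- c(quiet = 0L, info = 1L, debug = 2L)

#' Set or query the package logging verbosity
#'
#' @param level one of `"quiet"`, `"info"`, `"debug"`; missing returns the
#'   current level.
#' @return the current level, invisibly when setting.
#' @export
anthro_log_level <- function(level) {
  if (missing(level)) {
    return(getOption("anthrocomp.log_level", "info"))
  }
  level <- match.arg(level, names(.log_levels))
  options(anthrocomp.log_level = level)
  invisible(level)
}

vlog <- function(..., level = "info") {
  cur <- .log_levels[[getOption("anthrocomp.log_level", "info")]]
  if (.log_levels[[level]] <= cur && cur > 0L) {
    message("[anthrocomp] ", paste0(...))
  }
  invisible(NULL)
}

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`", name, "` must be a single finite number")
  }
  invisible(x)
}

# ---- doubly truncated normal ------------------------------------------------
# Moments and quantiles of N(mu, sigma^2) truncated to [a, b], computed in the
# numerically favourable tail (mirrored when the mass sits in the upper tail).

tn_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  if (al + be > 0) { # mirror into the lower tail
    m <- tn_moments(-mu, sigma, -b, -a)
    return(c(mean = -m[["mean"]], sd = m[["sd"]]))
  }
  pa <- stats::pnorm(al)
  pb <- stats::pnorm(be)
  z <- pb - pa
  if (z <= 0) {
    return(c(mean = NaN, sd = NaN))
  }
  da <- stats::dnorm(al)
  db <- stats::dnorm(be)
  m <- (da - db) / z
  v <- 1 + (al * da - be * db) / z - m^2
  c(mean = mu + sigma * m, sd = sigma * sqrt(max(v, 0)))
}

tn_quantile <- function(u, mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  if (al + be > 0) {
    return(-tn_quantile(1 - u, -mu, sigma, -b, -a))
  }
  pa <- stats::pnorm(al)
  pb <- stats::pnorm(be)
  q <- stats::qnorm(pa + u * (pb - pa))
  pmin(pmax(mu + sigma * q, a), b)
}

# Latent (mu, sigma) such that the [a, b]-truncated normal has the target
# mean/sd, or the closest attainable pair (the family's sd is bounded above by
# the uniform limit (b - a)/sqrt(12)).
tn_solve <- function(mean, sd, a, b) {
  target <- c(mean, sd)
  scale <- c(max(abs(mean), sd), sd)
  obj <- function(p) {
    m <- tn_moments(p[[1L]], exp(p[[2L]]), a, b)
    if (anyNA(m)) {
      return(1e6)
    }
    sum(((m - target) / scale)^2)
  }
  best <- NULL
  for (start in list(c(mean, log(sd)), c((a + b) / 2, log(b - a)))) {
    o <- stats::optim(start, obj,
      method = "Nelder-Mead",
      control = list(maxit = 5000L, reltol = 1e-14)
    )
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(
    mu = best$par[[1L]], sigma = exp(best$par[[2L]]),
    achieved = tn_moments(best$par[[1L]], exp(best$par[[2L]]), a, b)
  )
}

# Moment-matched lognormal parameters (used for the optional skinfold marginal).
lnorm_match <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}
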
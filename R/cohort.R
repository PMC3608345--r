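# Seeded synthetic cohorts with the study sample's moment structure.

new_cohort <- function(df, seed, provenance) {
  structure(df,
    seed = seed, provenance = provenance,
    class = c("synthetic_cohort", "data.frame")
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects (%s-driven, seed %s)\n",
    nrow(x), attr(x, "provenance"), format(attr(x, "seed"))
  ))
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 4)
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Generate a moments-driven synthetic cohort
#'
#' Samples n subjects from a Gaussian copula whose latent correlation is the
#' repaired (positive-semidefinite) study correlation matrix and whose
#' marginals are doubly truncated normals on each variable's observed range,
#' with latent location/scale solved numerically so the post-truncation mean
#' and SD equal the published targets. Every draw therefore lies inside the
#' configured ranges while the cohort's moments track the study sample's.
#' An optional lognormal marginal is available for the right-skewed
#' skinfolds.
#'
#' Output is a pure function of `(n, moments, seed, ...)`: the same seed
#' reproduces the cohort bit for bit, and the caller's RNG state is left
#' untouched.
#'
#' @param n number of subjects (>= 2).
#' @param moments a [population_moments()] with a repaired correlation.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   state, which is not reproducible.
#' @param lognormal_skinfolds use range-truncated lognormal marginals for the
#'   two skinfolds instead of truncated normals (off by default).
#' @param phv_from_equation replace the jointly drawn maturity offset by the
#'   value recomputed from age, stature, sitting height and body mass (off by
#'   default: the study treats the offset as a measured covariate).
#' @return a `synthetic_cohort` (data frame with one column per variable and
#'   attributes `seed`, `provenance = "moments"`).
#' @examples
#' coh <- generate_cohort(100, seed = 1)
#' colMeans(coh[, c("fm", "bmc", "lst")])
#' @export
generate_cohort <- function(n, moments = default_moments(), seed = NULL,
                            lognormal_skinfolds = FALSE,
                            phv_from_equation = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 2L) stop_input("`n` must be >= 2")
  stopifnot(inherits(moments, "population_moments"))
  if (is.null(moments$correlation_psd)) {
    stop_input("moments carry no repaired (PSD) correlation matrix")
  }
  n <- as.integer(n)
  tab <- moments$table
  R <- moments$correlation_psd
  draw <- function() {
    Z <- MASS::mvrnorm(n, mu = rep(0, nrow(tab)), Sigma = R)
    U <- stats::pnorm(Z)
    out <- matrix(NA_real_, n, nrow(tab), dimnames = list(NULL, tab$variable))
    for (j in seq_len(nrow(tab))) {
      v <- tab$variable[j]
      u <- U[, j]
      if (lognormal_skinfolds && v %in% c("sk_suprailiac", "sk_horiz_abdominal")) {
        lp <- lnorm_match(tab$mean[j], tab$sd[j])
        pa <- stats::plnorm(tab$min[j], lp$meanlog, lp$sdlog)
        pb <- stats::plnorm(tab$max[j], lp$meanlog, lp$sdlog)
        out[, j] <- stats::qlnorm(pa + u * (pb - pa), lp$meanlog, lp$sdlog)
      } else {
        sol <- tn_latent(v, tab$mean[j], tab$sd[j], tab$min[j], tab$max[j])
        out[, j] <- tn_quantile(u, sol$mu, sol$sigma, tab$min[j], tab$max[j])
      }
    }
    df <- as.data.frame(out)
    if (phv_from_equation && all(c("age", "height", "seating_height", "weight", "phv") %in% names(df))) {
      df$phv <- maturity_offset(df$age, df$height, df$seating_height, df$weight)
    }
    df
  }
  df <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_cohort(df, seed, "moments")
}

# Cache the per-variable latent truncated-normal parameters (deterministic).
tn_latent <- function(key, mean, sd, a, b) {
  id <- paste(key, mean, sd, a, b, sep = "|")
  if (is.null(.anthro_cache$tn[[id]])) {
    if (is.null(.anthro_cache$tn)) .anthro_cache$tn <- list()
    .anthro_cache$tn[[id]] <- tn_solve(mean, sd, a, b)
  }
  .anthro_cache$tn[[id]]
}

#' Generate a model-driven cohort from known coefficients
#'
#' Draws the five predictors from a multivariate normal with the supplied
#' moments (untruncated, so the design's second moments are exact) and
#' builds the responses as \eqn{Y = X B + \varepsilon} with independent
#' Gaussian noise of the given per-response SDs. Intended for parameter
#' recovery and cross-validation simulations against a known truth.
#'
#' @param n number of subjects (> 5).
#' @param beta a [coefficient_matrix()]; defaults to the published one.
#' @param noise_sd length-3 non-negative vector of response noise SDs (kg).
#' @param moments a [population_moments()] covering the five predictors.
#' @param seed integer seed (see [generate_cohort()]).
#' @return a `synthetic_cohort` with predictor and response columns and
#'   `provenance = "model"`.
#' @export
generate_from_coefficients <- function(n, beta = published_coefficients(),
                                       noise_sd = c(1.666, 0.192, 1.748),
                                       moments = default_moments(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n <= 5L) stop_input("`n` must be > 5")
  stopifnot(inherits(beta, "coef_matrix"))
  if (length(noise_sd) != 3L || any(!is.finite(noise_sd)) || any(noise_sd < 0)) {
    stop_input("`noise_sd` must be three non-negative values")
  }
  pm <- predictor_moments(moments)
  mu <- pm$table$mean
  S <- diag(pm$table$sd) %*% pm$correlation_psd %*% diag(pm$table$sd)
  n <- as.integer(n)
  draw <- function() {
    X <- MASS::mvrnorm(n, mu = mu, Sigma = S)
    colnames(X) <- pm$table$variable
    E <- vapply(noise_sd, function(s) stats::rnorm(n, 0, s), numeric(n))
    Y <- X %*% unclass(beta) + E
    as.data.frame(cbind(X, Y))
  }
  df <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_cohort(df, seed, "model")
}

#' Generate duplicate measurements with a target technical error
#'
#' For each requested variable, pairs the cohort's value (taken as the first
#' measurement) with a repeat equal to the first plus Gaussian error of SD
#' `tem * sqrt(2)`, so the expected Dahlberg [technical_error()] equals the
#' target.
#'
#' @param cohort a cohort data frame.
#' @param tem_targets named non-negative numeric vector: target TEM per
#'   variable (names must be cohort columns).
#' @param seed integer seed (see [generate_cohort()]).
#' @return a data frame with columns `variable`, `subject`, `first`,
#'   `second`.
#' @export
generate_duplicates <- function(cohort, tem_targets, seed = NULL) {
  if (is.null(names(tem_targets)) || !all(names(tem_targets) %in% names(cohort))) {
    stop_input("`tem_targets` must be named after cohort columns")
  }
  if (any(!is.finite(tem_targets)) || any(tem_targets < 0)) {
    stop_input("`tem_targets` must be non-negative")
  }
  draw <- function() {
    do.call(rbind, lapply(names(tem_targets), function(v) {
      x <- cohort[[v]]
      data.frame(
        variable = v, subject = seq_along(x), first = x,
        second = x + stats::rnorm(length(x), 0, tem_targets[[v]] * sqrt(2))
      )
    }))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Summarise a cohort in the moments layout
#'
#' Sample means, SDs, observed ranges and pairwise correlations of a cohort,
#' returned as a [population_moments()] (without PSD repair, since a sample
#' correlation may be undefined for constant columns, which are flagged).
#'
#' @param cohort a cohort data frame (>= 2 rows).
#' @return a [population_moments()] with the sample values.
#' @export
cohort_summary <- function(cohort) {
  df <- as.data.frame(cohort)
  df <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  if (nrow(df) < 2L) stop_input("need at least two rows to summarise")
  tab <- data.frame(
    variable = names(df),
    mean = vapply(df, mean, numeric(1)),
    sd = vapply(df, stats::sd, numeric(1)),
    min = vapply(df, min, numeric(1)),
    max = vapply(df, max, numeric(1)),
    row.names = NULL
  )
  if (any(tab$sd == 0)) {
    warn_anthro(
      "constant column(s): ", paste(tab$variable[tab$sd == 0], collapse = ", "),
      "; their correlations are undefined (NA)",
      class = "anthrocomp_degenerate_summary"
    )
  }
  R <- suppressWarnings(stats::cor(df))
  diag(R) <- 1
  population_moments(tab, R, repair = FALSE)
}
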
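# Common-predictor stepwise selection across the three responses.

# Residual sum of squares of the no-intercept least-squares fit of y on X[,S].
.sse <- function(X, y, S) {
  if (length(S) == 0L) {
    return(sum(y^2))
  }
  q <- qr(X[, S, drop = FALSE])
  sum(qr.resid(q, y)^2)
}

# One-response forward/backward stepwise with partial-F thresholds.
.stepwise_one <- function(X, y, entry_alpha, removal_alpha, response) {
  n <- nrow(X)
  cand <- colnames(X)
  sel <- character(0)
  log <- list()
  note <- function(action, variable, f, p) {
    log[[length(log) + 1L]] <<- data.frame(
      stage = "per-response", response = response, action = action,
      variable = variable, statistic = f, p_value = p
    )
  }
  repeat {
    changed <- FALSE
    # forward: best candidate by partial F
    rest <- setdiff(cand, sel)
    if (length(rest) && n - length(sel) - 1L > 0L) {
      sse0 <- .sse(X, y, sel)
      stats <- vapply(rest, function(v) {
        sse1 <- .sse(X, y, c(sel, v))
        df2 <- n - length(sel) - 1L
        f <- (sse0 - sse1) / (sse1 / df2)
        c(f, stats::pf(f, 1, df2, lower.tail = FALSE))
      }, numeric(2))
      best <- which.min(stats[2L, ])
      if (stats[2L, best] < entry_alpha) {
        sel <- c(sel, rest[best])
        note("enter", rest[best], stats[1L, best], stats[2L, best])
        changed <- TRUE
      }
    }
    # backward: weakest retained variable by partial F
    if (length(sel) > 1L) {
      sse_full <- .sse(X, y, sel)
      df2 <- n - length(sel)
      stats <- vapply(sel, function(v) {
        sse0 <- .sse(X, y, setdiff(sel, v))
        f <- (sse0 - sse_full) / (sse_full / df2)
        c(f, stats::pf(f, 1, df2, lower.tail = FALSE))
      }, numeric(2))
      worst <- which.max(stats[2L, ])
      if (stats[2L, worst] > removal_alpha) {
        note("remove", sel[worst], stats[1L, worst], stats[2L, worst])
        sel <- setdiff(sel, sel[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(selected = sel, log = log)
}

#' Select predictors common to all three responses
#'
#' Runs an intercept-free stepwise regression (forward entry, backward
#' removal, partial-F thresholds) separately for each response column,
#' intersects the three retained sets, and then prunes members of the
#' intersection whose Pillai trace test in the joint multivariate model is
#' non-significant at `removal_alpha`, provided their removal keeps the
#' collinearity category at `moderate` or better. The elimination order is
#' logged step by step so a selection can be replayed and audited.
#'
#' @param X_full numeric design matrix of candidate predictors (>= 2 columns).
#' @param Y numeric n x 3 response matrix.
#' @param entry_alpha,removal_alpha partial-F significance thresholds in
#'   (0, 1); both default to 0.05.
#' @param collinearity_scale passed to [collinearity_ratio()] for the joint
#'   pruning gate.
#' @return an object of class `selection_trace` with `final` (retained
#'   labels; possibly empty), `per_response` (per-response retained sets),
#'   `intersection`, and `steps` (a replayable log data frame).
#' @export
select_common_predictors <- function(X_full, Y,
                                     entry_alpha = 0.05, removal_alpha = 0.05,
                                     collinearity_scale = "none") {
  X <- as_design(X_full, "X")
  Y <- as_design(Y, "Y")
  if (ncol(X) < 2L) stop_input("need at least two candidate columns")
  if (!(entry_alpha > 0 && entry_alpha < 1) || !(removal_alpha > 0 && removal_alpha < 1)) {
    stop_input("alpha thresholds must lie in (0, 1)")
  }
  per <- lapply(seq_len(ncol(Y)), function(j) {
    .stepwise_one(X, Y[, j], entry_alpha, removal_alpha, colnames(Y)[j])
  })
  names(per) <- colnames(Y)
  steps <- do.call(rbind, c(
    unlist(lapply(per, `[[`, "log"), recursive = FALSE),
    make.row.names = FALSE
  ))
  sets <- lapply(per, `[[`, "selected")
  inter <- Reduce(intersect, sets)
  final <- inter
  if (length(inter) == 0L) {
    vlog("common-predictor selection is empty: no variable retained by all responses")
  } else {
    # joint pruning stage
    repeat {
      if (length(final) < 2L) break
      fit <- fit_multivariate_ls(X[, final, drop = FALSE], Y)
      tests <- vapply(final, function(v) {
        t <- pillai_trace_test(fit, v)
        c(t$statistic, t$p_value)
      }, numeric(2))
      ord <- order(tests[2L, ], decreasing = TRUE)
      dropped <- FALSE
      for (k in ord) {
        if (tests[2L, k] <= removal_alpha) break
        remaining <- setdiff(final, final[k])
        cat_after <- collinearity_ratio(X[, remaining, drop = FALSE],
          scale = collinearity_scale
        )$category
        if (cat_after %in% c("weak", "moderate")) {
          steps <- rbind(steps, data.frame(
            stage = "joint", response = "all", action = "remove",
            variable = final[k], statistic = tests[1L, k], p_value = tests[2L, k]
          ))
          final <- remaining
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
  }
  structure(
    list(
      candidates = colnames(X), per_response = sets,
      intersection = inter, final = final, steps = steps,
      entry_alpha = entry_alpha, removal_alpha = removal_alpha
    ),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf(
    "Common-predictor selection (entry %.3g, removal %.3g)\n",
    x$entry_alpha, x$removal_alpha
  ))
  for (r in names(x$per_response)) {
    cat(sprintf(
      "  %s: %s\n", r,
      if (length(x$per_response[[r]])) paste(x$per_response[[r]], collapse = ", ") else "(none)"
    ))
  }
  cat(sprintf(
    "  final: %s\n",
    if (length(x$final)) paste(x$final, collapse = ", ") else "(empty)"
  ))
  invisible(x)
}
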
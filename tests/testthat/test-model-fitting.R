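# Multivariate least squares, Pillai tests, collinearity, selection.

test_that("noise-free data is fitted exactly", {
  withr::with_seed(7, {
    X <- matrix(rnorm(40 * 4), 40, 4)
    B <- diag(4)[, 1:3]
    Y <- X %*% B
  })
  fit <- fit_multivariate_ls(X, Y)
  expect_equal(unname(fit$beta), B, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_equal(unname(fit$r2), rep(1, 3), tolerance = 1e-12)
})

test_that("single-column no-intercept slope equals the closed form", {
  fit <- fit_multivariate_ls(cbind(x = c(1, 2, 3, 4)), cbind(y = c(2, 1, 4, 3)))
  expect_equal(unname(fit$beta[1, 1]), 28 / 30, tolerance = 1e-12) # sum(xy)/sum(x^2)
  expect_equal(unname(fit$beta[1, 1]), 0.93333, tolerance = 1e-5)
})

test_that("multivariate solution equals column-wise univariate least squares", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      prob <- random_problem(n = 50, p = 4)
      fit <- fit_multivariate_ls(prob$X, prob$Y)
      for (j in 1:3) {
        uni <- stats::lm.fit(prob$X, prob$Y[, j]) # independent solver (QR)
        expect_equal(unname(fit$beta[, j]), unname(uni$coefficients),
          tolerance = 1e-10
        )
      }
    }
  })
})

test_that("normal-equation solution agrees with an orthogonal-decomposition solver", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      prob <- random_problem(n = 60, p = 5)
      fit <- fit_multivariate_ls(prob$X, prob$Y)
      qrsol <- qr.solve(prob$X, prob$Y)
      expect_equal(fit$beta, qrsol, tolerance = 1e-8, ignore_attr = TRUE)
    }
  })
})

test_that("leverages lie in [0, 1] and sum to the column count", {
  withr::with_seed(13, {
    prob <- random_problem(n = 80, p = 6)
  })
  fit <- fit_multivariate_ls(prob$X, prob$Y)
  expect_true(all(fit$hat >= 0 & fit$hat <= 1))
  expect_equal(sum(fit$hat), 6, tolerance = 1e-10)
  with_int <- fit_multivariate_ls(prob$X, prob$Y, include_intercept = TRUE)
  expect_equal(sum(with_int$hat), 7, tolerance = 1e-10)
})

test_that("intercept-free R^2 follows the lm convention, centered R^2 reported alongside", {
  withr::with_seed(14, {
    prob <- random_problem(n = 60, p = 3, noise = 2)
  })
  fit <- fit_multivariate_ls(prob$X, prob$Y)
  ref <- summary(stats::lm(prob$Y[, 2] ~ 0 + prob$X))
  expect_equal(unname(fit$r2["y2"]), ref$r.squared, tolerance = 1e-10)
  expect_equal(unname(fit$adj_r2["y2"]), ref$adj.r.squared, tolerance = 1e-10)
  expect_equal(unname(fit$see_residual["y2"]), ref$sigma, tolerance = 1e-10)
  sse <- sum(fit$residuals[, 2]^2)
  expect_equal(
    unname(fit$r2_centered["y2"]),
    1 - sse / sum((prob$Y[, 2] - mean(prob$Y[, 2]))^2),
    tolerance = 1e-12
  )
})

test_that("rank deficiency is reported with the dependent column", {
  X <- cbind(a = 1:10, b = (1:10) * 2)
  Y <- matrix(rnorm(30), 10, 3)
  expect_error(fit_multivariate_ls(X, Y), "b", class = "anthrocomp_numeric_error")
})

test_that("Pillai trace kernel handles the boundary cases", {
  expect_equal(pillai_trace(matrix(0, 2, 2), diag(2)), 0) # no-effect hypothesis
  expect_equal(pillai_trace(diag(2), diag(2)), 1.0)
  expect_error(
    pillai_trace(matrix(0, 2, 2), matrix(0, 2, 2)),
    class = "anthrocomp_numeric_error"
  )
})

test_that("Pillai test separates a real term from a null one", {
  withr::with_seed(15, {
    X <- cbind(a = rnorm(60), b = rnorm(60), junk = rnorm(60))
    Y <- X[, 1:2] %*% matrix(c(1, -1, 0.5, 1, 0.3, -0.7), 2, 3) +
      matrix(rnorm(180, sd = 0.5), 60, 3) # junk has exactly no effect
  })
  fit <- fit_multivariate_ls(X, Y)
  t_null <- pillai_trace_test(fit, "junk")
  t_real <- pillai_trace_test(fit, "a")
  expect_lt(t_null$statistic, t_real$statistic)
  expect_gt(t_null$p_value, 0.001)
  expect_gt(t_real$statistic, 0.5)
  expect_lt(t_real$p_value, 1e-10)
  # V is bounded by s = min(responses, hypothesis df)
  expect_true(t_real$statistic <= t_real$s)
  # noise-free data makes H + E degenerate for a null term: refused, not NaN
  Y0 <- X[, 1:2] %*% matrix(c(1, -1, 0.5, 1, 0.3, -0.7), 2, 3)
  fit0 <- fit_multivariate_ls(X, Y0)
  expect_error(pillai_trace_test(fit0, "junk"), class = "anthrocomp_numeric_error")
  expect_error(pillai_trace_test(fit, character(0)), class = "anthrocomp_input_error")
  expect_error(pillai_trace_test(fit, "nope"), class = "anthrocomp_input_error")
})

test_that("collinearity ratio matches constructions and classifies by the printed bands", {
  # orthonormal columns
  expect_equal(collinearity_ratio(diag(4))$lambda_ratio, 1)
  expect_identical(collinearity_ratio(diag(4))$category, "weak")
  # diagonal scaling 1 and 2 -> eigenvalues 1 and 4
  X <- diag(c(1, 2))
  rep <- collinearity_ratio(X)
  expect_equal(sort(rep$eigenvalues), c(1, 4))
  expect_equal(rep$lambda_ratio, 4)
  # boundary convention: 100 and 1000 are moderate
  expect_identical(collinearity_ratio(diag(c(10, 1)))$category, "moderate")
  expect_identical(collinearity_ratio(diag(c(sqrt(1000), 1)))$category, "moderate")
  expect_identical(collinearity_ratio(diag(c(sqrt(1001), 1)))$category, "severe")
  # duplicated column -> singular
  dup <- cbind(a = 1:5, b = 1:5)
  repd <- collinearity_ratio(dup)
  expect_identical(repd$category, "severe")
  expect_identical(repd$lambda_ratio, Inf)
})

test_that("selection retains the generating predictors and drops pure noise", {
  withr::with_seed(16, {
    X <- matrix(rnorm(500 * 6), 500, 6)
    colnames(X) <- paste0("x", 1:6)
    B <- matrix(0, 6, 3)
    B[2, ] <- c(1.0, 0.5, -0.8)
    B[5, ] <- c(-0.7, 1.2, 0.9)
    Y <- X %*% B + matrix(rnorm(500 * 3, sd = 0.5), 500, 3)
    colnames(Y) <- c("fm", "bmc", "lst")
  })
  sel <- select_common_predictors(X, Y)
  expect_setequal(sel$final, c("x2", "x5"))
  expect_true(all(sel$final %in% sel$candidates))
  # pure-noise candidates: empty or near-empty selection
  withr::with_seed(17, {
    Xn <- matrix(rnorm(300 * 5), 300, 5)
    colnames(Xn) <- paste0("n", 1:5)
    Yn <- matrix(rnorm(300 * 3), 300, 3)
    colnames(Yn) <- c("fm", "bmc", "lst")
  })
  seln <- select_common_predictors(Xn, Yn)
  expect_lte(length(seln$final), 1L)
  # single strongly predictive candidate is retained
  withr::with_seed(18, {
    X1 <- cbind(sig = rnorm(200), other = rnorm(200))
    Y1 <- X1[, 1, drop = FALSE] %*% matrix(c(1, 1, 1), 1, 3) + matrix(rnorm(600, sd = 0.3), 200, 3)
    colnames(Y1) <- c("fm", "bmc", "lst")
  })
  expect_true("sig" %in% select_common_predictors(X1, Y1)$final)
})

test_that("the selection trace is a replayable log", {
  withr::with_seed(19, {
    X <- matrix(rnorm(200 * 4), 200, 4)
    colnames(X) <- paste0("x", 1:4)
    Y <- X[, 1:2] %*% matrix(1, 2, 3) + matrix(rnorm(600, sd = 0.4), 200, 3)
    colnames(Y) <- c("fm", "bmc", "lst")
  })
  sel <- select_common_predictors(X, Y)
  expect_true(all(c("stage", "response", "action", "variable", "statistic", "p_value")
  %in% names(sel$steps)))
  # replaying the per-response entries reproduces the per-response sets
  for (r in names(sel$per_response)) {
    log_r <- sel$steps[sel$steps$response == r, ]
    replay <- character(0)
    for (i in seq_len(nrow(log_r))) {
      replay <- if (log_r$action[i] == "enter") {
        c(replay, log_r$variable[i])
      } else {
        setdiff(replay, log_r$variable[i])
      }
    }
    expect_setequal(replay, sel$per_response[[r]])
  }
})

test_that("coefficients recovered from a known-truth cohort stay within sampling error", {
  B <- unclass(published_coefficients())
  coh <- generate_from_coefficients(400, seed = 21)
  fit <- fit_multivariate_ls(as.matrix(coh[, rownames(B)]), as.matrix(coh[, colnames(B)]))
  # each coefficient within 3 standard errors of truth
  XtXi <- solve(crossprod(as.matrix(coh[, rownames(B)])))
  for (j in 1:3) {
    se <- sqrt(diag(XtXi)) * fit$see_residual[j]
    expect_true(all(abs(fit$beta[, j] - B[, j]) < 3 * se))
  }
})
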
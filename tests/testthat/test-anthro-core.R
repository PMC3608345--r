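# Domain types, maturity offset, published predictor, product breakdown.

test_that("maturity offset matches independent term-by-term evaluation", {
  # hand-derived cases
  expect_equal(maturity_offset(13, 150, 80, 45), -1.04061, tolerance = 1e-6)
  expect_equal(maturity_offset(16, 175, 92, 65), 2.09663, tolerance = 1e-6)
  # randomized grid against the oracle
  withr::with_seed(42, {
    for (i in 1:50) {
      age <- runif(1, 8, 18)
      height <- runif(1, 121, 196)
      sh <- runif(1, 0.4, 0.6) * height
      wt <- runif(1, 21, 119)
      expect_equal(
        maturity_offset(age, height, sh, wt),
        phv_oracle(age, height, sh, wt),
        tolerance = 1e-9
      )
    }
  })
})

test_that("maturity offset rejects out-of-domain geometry by name", {
  expect_error(maturity_offset(13, -150, 80, 45), "height", class = "anthrocomp_input_error")
  expect_error(maturity_offset(13, 150, 150, 45), "seating_height", class = "anthrocomp_input_error")
  expect_error(maturity_offset(13, 150, 0, 45), "seating_height", class = "anthrocomp_input_error")
  expect_error(maturity_offset(0, 150, 80, 45), "age", class = "anthrocomp_input_error")
})

test_that("record construction validates fields and derives the maturity offset", {
  rec <- anthropometric_record(150, 45, 10, 12, seating_height = 80, age = 13)
  expect_identical(rec$phv_source, "computed")
  expect_equal(rec$phv, maturity_offset(13, 150, 80, 45))
  expect_error(anthropometric_record(-1, 45, 10, 12), "height", class = "anthrocomp_input_error")
  expect_error(anthropometric_record(150, 45, -3, 12), "skinfold", class = "anthrocomp_input_error")
  expect_error(
    anthropometric_record(150, 45, 10, 12, seating_height = 151),
    "seating_height",
    class = "anthrocomp_input_error"
  )
})

test_that("published coefficients equal the printed matrix", {
  B <- published_coefficients()
  expect_s3_class(B, "coef_matrix")
  expect_equal(unclass(B)[, c("fm", "bmc", "lst")], published_beta_fixture(),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  expect_identical(rownames(B), c(
    "height", "weight", "sk_suprailiac",
    "sk_horiz_abdominal", "phv"
  ))
  # spot values and a derived row sum
  expect_equal(B["height", "fm"], -0.0857)
  expect_equal(B["phv", "lst"], 0.7047)
  expect_equal(sum(B["weight", ]), 0.9950)
})

test_that("coefficient matrices round-trip through delimited text and validate shape", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_coefficient_matrix(published_coefficients(), path)
  again <- read_coefficient_matrix(path)
  expect_equal(unclass(again), unclass(published_coefficients()))
  expect_error(coefficient_matrix(matrix(0, 4, 3)), "5 x 3", class = "anthrocomp_input_error")
  expect_error(
    coefficient_matrix(matrix(0, 5, 3), predictor_labels = rep("a", 5)),
    "unique",
    class = "anthrocomp_input_error"
  )
})

test_that("worked-example prediction reproduces the printed totals", {
  pred <- predict_components(worked_example_record())
  expect_equal(pred$fm, 9.28, tolerance = 0.01 / 9.28)
  expect_equal(pred$bmc, 1.57, tolerance = 0.01 / 1.57)
  expect_equal(pred$lst, 28.40, tolerance = 0.01 / 28.40)
  # mass closure: the three components nearly recover body mass
  expect_equal(pred$fm + pred$bmc + pred$lst, 39.25, tolerance = 0.05 / 39.25)
})

test_that("the predictor is an intercept-free linear map", {
  rec <- worked_example_record()
  base <- as.numeric(predict_components(rec))
  for (a in c(0.5, 2)) {
    scaled <- anthropometric_record(
      rec$height * a, rec$weight * a,
      rec$sk_suprailiac * a, rec$sk_horiz_abdominal * a,
      phv = rec$phv * a
    )
    got <- suppressWarnings(as.numeric(predict_components(scaled, warn_extrapolation = FALSE)))
    expect_equal(got, a * base, tolerance = 1e-12)
  }
  zero <- data.frame(
    height = 0, weight = 0, sk_suprailiac = 0,
    sk_horiz_abdominal = 0, phv = 0
  )
  expect_equal(
    unlist(predict_components(zero, warn_extrapolation = FALSE)),
    c(fm = 0, bmc = 0, lst = 0)
  )
  # single-term scaling picks out one coefficient column
  ht_only <- data.frame(
    height = 100, weight = 0, sk_suprailiac = 0,
    sk_horiz_abdominal = 0, phv = 0
  )
  got <- suppressWarnings(unlist(predict_components(ht_only, warn_extrapolation = FALSE)))
  expect_equal(got, c(fm = -8.57, bmc = 0.32, lst = 8.20), tolerance = 1e-9)
})

test_that("out-of-range and negative predictions warn instead of failing", {
  tall <- data.frame(
    height = 210, weight = 50, sk_suprailiac = 10,
    sk_horiz_abdominal = 10, phv = 1
  )
  expect_warning(predict_components(tall), class = "anthrocomp_extrapolation")
  neg <- data.frame(
    height = 196, weight = 21, sk_suprailiac = 3,
    sk_horiz_abdominal = 2, phv = 4
  )
  expect_warning(
    out <- predict_components(neg, warn_extrapolation = FALSE),
    class = "anthrocomp_negative_mass"
  )
  expect_lt(out$fm, 0) # returned unclipped
})

test_that("missing maturity offset is reported with the missing fields", {
  expect_error(
    predict_components(anthropometric_record(150, 45, 10, 12)),
    "phv",
    class = "anthrocomp_input_error"
  )
  expect_error(
    predict_components(data.frame(
      height = 150, weight = 45,
      sk_suprailiac = 10, sk_horiz_abdominal = 12
    )),
    "age|seating_height",
    class = "anthrocomp_input_error"
  )
})

test_that("product breakdown matches the printed per-term products and sums to the prediction", {
  pb <- product_breakdown(worked_example_record())
  row <- function(v) pb[pb$predictor == v, ]
  expect_equal(row("height")$product_fm, -12.71, tolerance = 0.005 / 12.71)
  expect_equal(row("weight")$product_fm, 12.56, tolerance = 0.005 / 12.56)
  expect_equal(row("height")$product_lst, 12.16, tolerance = 0.005 / 12.16)
  expect_equal(row("phv")$product_fm, 1.05, tolerance = 0.005 / 1.05)
  tot <- attr(pb, "totals")
  expect_equal(sum(pb$product_fm), tot[["fm"]], tolerance = 1e-9)
  expect_equal(sum(pb$product_bmc), tot[["bmc"]], tolerance = 1e-9)
  expect_equal(sum(pb$product_lst), tot[["lst"]], tolerance = 1e-9)
  expect_equal(tot, as.numeric(predict_components(worked_example_record())),
    tolerance = 1e-12
  )
  # zero record: all products vanish
  zb <- product_breakdown(
    data.frame(
      height = 0, weight = 0, sk_suprailiac = 0,
      sk_horiz_abdominal = 0, phv = 0
    ),
    warn_extrapolation = FALSE
  )
  expect_true(all(abs(zb[, grep("^product_", names(zb))]) == 0))
})
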
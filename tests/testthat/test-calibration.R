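test_that("exact exponential data are recovered to machine-level precision", {
  x <- seq(0, 1, length.out = 20)
  y <- 2 * exp(3 * x) + 1
  m <- fit_single_model(x, y, kind = "AC")
  expect_lt(max(abs(coef(m) - c(2, 3, 1)) / c(2, 3, 1)), 1e-6)
  expect_lt(m$fit_meta$sse, 1e-12)
  expect_true(m$fit_meta$converged)
})

test_that("degenerate predictors are refused", {
  expect_error(fit_single_model(rep(0.8, 10), runif(10, 0, 20), "AC"),
               class = "ueff_error_degenerate_input")
  expect_error(fit_single_model(1:3, c(1, 2, 3), "AC"),
               class = "ueff_error_invalid_input")
})

test_that("the fitted SSE matches a grid + polish search oracle", {
  set.seed(21)
  x <- runif(30, 0, 1)
  y <- 1.5 * exp(2.2 * x) - 0.5 + rnorm(30, 0, 0.4)
  m <- fit_single_model(x, y, kind = "AC")
  oracle <- nls_grid_polish_sse(x, y, b1_range = c(0.2, 5),
                                b2_range = c(0.5, 4), b3_range = c(-4, 3))
  expect_lt(abs(m$fit_meta$sse - oracle), 1e-6 * (1 + oracle))
})

test_that("combined model recovers its own noiseless generative form", {
  set.seed(2)
  ac <- runif(40, 0.5, 1.2)
  bscd <- runif(40, 60, 117)
  truth <- c(4, 2, 0.2, 0.04, -12)
  y <- truth[1] * exp(truth[2] * ac) + truth[3] * exp(truth[4] * bscd) +
    truth[5]
  m <- fit_combined_model(ac, bscd, y)
  expect_equal(m$n_predictors, 2L)
  expect_lt(max(abs(coef(m) - truth) / abs(truth)), 1e-5)
})

test_that("collinear predictors are flagged, nested SSE never worse than AC-only", {
  co <- generate_cohort(synthetic_config(n = 90, seed = 14))
  expect_warning(mc <- fit_combined_model(co$ac, co$ac, co$pdff),
                 "collinear")
  expect_true(mc$fit_meta$collinear)

  m1 <- fit_single_model(co$ac, co$pdff, "AC")
  m2 <- fit_combined_model(co$ac, co$bscd, co$pdff)
  expect_lte(m2$fit_meta$sse, m1$fit_meta$sse * (1 + 1e-8))
})

test_that("UEFF prediction is the closed form, unclipped, order-preserving", {
  m <- structure(list(kind = "AC", coefficients = c(b1 = 1, b2 = 2, b3 = 0.5),
                      n_predictors = 1L,
                      fit_meta = list(converged = TRUE)),
                 class = "calibration_model")
  # closed form at AC = 0: b1 + b3
  expect_equal(predict(m, data.frame(ac = 0)), 1.5)
  co <- make_cohort(6)
  out <- predict_ueff(m, co)
  expect_equal(out$ueff, 1 * exp(2 * co$ac) + 0.5)
  expect_equal(out$id, co$id)

  # a negative offset produces negative UEFF, returned unmodified
  m_neg <- structure(list(kind = "AC",
                          coefficients = c(b1 = 1, b2 = 2, b3 = -5),
                          n_predictors = 1L,
                          fit_meta = list(converged = TRUE)),
                     class = "calibration_model")
  expect_true(any(predict_ueff(m_neg, co)$ueff < 0))

  # permuting rows permutes predictions identically
  perm <- c(3, 1, 6, 2, 5, 4)
  co_p <- co[perm, , drop = FALSE]
  class(co_p) <- class(co)
  expect_equal(predict(m, co_p), predict(m, co)[perm])

  expect_error(predict(m, data.frame(bscd = 1)),
               class = "ueff_error_missing_predictor")
})

test_that("fit diagnostics equal the from-scratch formulas", {
  co <- generate_cohort(synthetic_config(n = 30, seed = 6))
  m <- fit_single_model(co$ac, co$pdff, "AC")
  d <- model_diagnostics(m, co)
  yhat <- coef(m)[["b1"]] * exp(coef(m)[["b2"]] * co$ac) + coef(m)[["b3"]]
  ss_res <- sum((co$pdff - yhat)^2)
  ss_tot <- sum((co$pdff - mean(co$pdff))^2)
  r2 <- 1 - ss_res / ss_tot
  expect_equal(d$r2, r2)
  expect_equal(d$adj_r2, 1 - (1 - r2) * (30 - 1) / (30 - 1 - 1))
  expect_equal(d$rmse, sqrt(ss_res / 30))

  # perfect predictions
  co_perfect <- co
  co_perfect$pdff <- yhat
  class(co_perfect) <- class(co)
  dp <- model_diagnostics(m, co_perfect)
  expect_equal(dp$r2, 1, tolerance = 1e-12)
  expect_equal(dp$adj_r2, 1, tolerance = 1e-12)
  expect_equal(dp$rmse, 0, tolerance = 1e-9)

  # predicting the mean everywhere: r2 = 0, adjusted r2 < 0
  m_const <- structure(list(kind = "AC",
                            coefficients = c(b1 = 0, b2 = 0,
                                             b3 = mean(co$pdff)),
                            n_predictors = 1L,
                            fit_meta = list(converged = TRUE)),
                       class = "calibration_model")
  d0 <- model_diagnostics(m_const, co)
  expect_equal(d0$r2, 0, tolerance = 1e-12)
  expect_lt(d0$adj_r2, 0)
})

test_that("refitting on a converged model's own predictions is idempotent", {
  co <- generate_cohort(synthetic_config(n = 90, seed = 31))
  m <- fit_single_model(co$ac, co$pdff, "AC")
  refit <- fit_single_model(co$ac, predict(m, co), "AC")
  expect_equal(coef(refit), coef(m), tolerance = 1e-6)
})

test_that("model JSON serialisation is bit-exact", {
  co <- generate_cohort(synthetic_config(n = 50, seed = 12))
  for (m in list(fit_single_model(co$ac, co$pdff, "AC"),
                 fit_combined_model(co$ac, co$bscd, co$pdff))) {
    back <- model_from_json(model_to_json(m))
    expect_identical(back$coefficients, m$coefficients)
    expect_identical(back$kind, m$kind)
    expect_equal(back$fit_meta$sse, m$fit_meta$sse)
    expect_equal(predict(back, co), predict(m, co))
  }
})

test_that("calibration curve is increasing and convex for positive b1, b2", {
  set.seed(77)
  m <- fit_single_model(seq(0.5, 1.2, length.out = 30),
                        5 * exp(2 * seq(0.5, 1.2, length.out = 30)) - 10 +
                          rnorm(30, 0, 0.1), "AC")
  grid <- data.frame(ac = seq(0.4, 1.3, length.out = 100))
  pred <- predict(m, grid)
  expect_true(all(diff(pred) > 0))
  expect_true(all(diff(diff(pred)) > 0))
})
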
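test_that("Fisher-z confidence intervals reproduce closed-form values", {
  ci <- function(rho, n) {
    tanh(atanh(rho) + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
  }
  # internal consistency against the closed form on real data
  set.seed(4)
  a <- rnorm(50)
  b <- a + rnorm(50)
  res <- pearson_with_ci(a, b)
  expect_equal(c(res$ci_low, res$ci_high), ci(res$rho, 50))
  tstat <- res$rho * sqrt(48 / (1 - res$rho^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 48))

  # perfectly linear data: degenerate interval
  lin <- pearson_with_ci(1:10, 2 * (1:10) + 1)
  expect_equal(lin$rho, 1)
  expect_equal(c(lin$ci_low, lin$ci_high), c(1, 1))

  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)),
               class = "ueff_error_degenerate_input")
})

test_that("Fisher CI shrinks with n and respects symmetry/affine invariance", {
  widths <- sapply(c(10, 30, 90, 300), function(n) {
    ci <- tanh(atanh(0.6) + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
    diff(ci)
  })
  expect_true(all(diff(widths) < 0))
  set.seed(8)
  x <- rnorm(40)
  y <- x + rnorm(40)
  r1 <- pearson_with_ci(x, y)
  r2 <- pearson_with_ci(y, x)
  r3 <- pearson_with_ci(3 * x - 7, 0.5 * y + 2)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$ci_low, r2$ci_low)
  expect_equal(r1$rho, r3$rho)
  expect_equal(r1$p_value, r3$p_value)
})

test_that("sub-range scan finds the linear regime below a saturation knee", {
  # linear to a knee at 12, flat above, small noise
  set.seed(15)
  pdff <- runif(80, 0, 20)
  ueff <- pmin(pdff, 12) + rnorm(80, 0, 0.3)
  res <- subrange_correlation_scan(pdff, ueff, min_fraction = 0.5)
  expect_lte(res$range_used[2], 14)  # knee + noise margin
  expect_gt(res$rho, 0.98)
  expect_gte(sum(pdff >= res$range_used[1] & pdff <= res$range_used[2]), 40)
})

test_that("sub-range scan degenerates correctly at the extremes", {
  set.seed(16)
  pdff <- runif(40, 0, 20)
  ueff <- 2 * pdff + 1
  # exactly linear throughout: every admissible interval ties at rho = 1,
  # and the tie-break selects the widest = the full range
  res <- subrange_correlation_scan(pdff, ueff, min_fraction = 0.5)
  expect_equal(res$range_used, range(pdff))
  # min_fraction = 1 reduces to the plain correlation on all data
  res_all <- subrange_correlation_scan(pdff, ueff, min_fraction = 1)
  plain <- pearson_with_ci(pdff, ueff)
  expect_equal(res_all$rho, plain$rho)
  expect_equal(res_all$n, plain$n)
})

test_that("simple linear regression matches the normal-equations closed form", {
  expect_equal(simple_linreg(1:10, 2 * (1:10))[c("slope", "intercept")],
               list(slope = 2, intercept = 0))
  expect_equal(simple_linreg(1:10, rep(3, 10))$slope, 0)
  set.seed(23)
  x <- rnorm(10)
  y <- 1 + 0.5 * x + rnorm(10)
  fit <- simple_linreg(x, y)
  slope <- cov(x, y) / var(x)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_error(simple_linreg(rep(1, 5), rnorm(5)),
               class = "ueff_error_degenerate_input")
})

test_that("linear screening reports per-predictor and joint models", {
  rec <- make_records(40, seed = 9)
  rec$pdff <- 3 + 2 * rec$ac  # exact univariable relation
  co <- cohort(rec)
  scr <- fit_linear_models(co)
  uni_ac <- scr[scr$analysis == "univariable" & scr$predictor == "ac", ]
  expect_equal(uni_ac$beta, 2, tolerance = 1e-8)
  expect_gt(uni_ac$adj_r2, 0.999)
  multi <- scr[scr$analysis == "multivariable", ]
  expect_equal(length(unique(multi$adj_r2)), 1)  # shared joint-model fit
  expect_equal(length(unique(multi$f_stat)), 1)

  # coefficients match the normal equations
  dat <- as.data.frame(co)
  X <- cbind(1, as.matrix(dat[, c("ac", "bscd", "ls", "bmi")]))
  beta_ne <- solve(t(X) %*% X, t(X) %*% dat$pdff)
  expect_equal(multi$beta, as.numeric(beta_ne[-1]), tolerance = 1e-10)

  rec$dup <- rec$ac
  co2 <- cohort(rec)
  expect_error(fit_linear_models(co2, predictors = c("ac", "dup")),
               class = "ueff_error_collinearity")
})

test_that("Kruskal-Wallis + Dunn matches hand-computed ranks", {
  # two groups, no ties: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1)
  res <- kruskal_wallis_dunn(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(res$H, 12 / (6 * 7) * (3 * 2^2 + 3 * 5^2) - 3 * 7)
  z_hand <- (2 - 5) / sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(res$pairwise$z, z_hand)
  expect_lt(res$pairwise$p_holm, 0.05)

  # all observations equal: degenerate by convention
  res0 <- kruskal_wallis_dunn(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(res0$H, 0)
  expect_equal(res0$p_value, 1)

  expect_error(kruskal_wallis_dunn(1:5, rep("a", 5)),
               class = "ueff_error_invalid_input")
})

test_that("Holm adjustment follows the step-down rule and is monotone", {
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
  set.seed(31)
  vals <- c(rnorm(10), rnorm(10, 2), rnorm(10, 4))
  res <- kruskal_wallis_dunn(vals, rep(c("a", "b", "c"), each = 10))
  expect_true(all(res$pairwise$p_holm >= res$pairwise$p_raw))
  ord <- order(res$pairwise$p_raw)
  expect_true(all(diff(res$pairwise$p_holm[ord]) >= 0))
})

test_that("Kruskal-Wallis H is invariant to strictly monotone transforms", {
  set.seed(32)
  vals <- c(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  grp <- rep(c("a", "b", "c"), each = 8)
  h0 <- kruskal_wallis_dunn(vals, grp)$H
  expect_equal(kruskal_wallis_dunn(exp(vals), grp)$H, h0)
  expect_equal(kruskal_wallis_dunn(vals^3, grp)$H, h0)
})
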
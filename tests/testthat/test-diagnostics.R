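test_that("AUC equals pair counting on canonical and random instances", {
  expect_equal(roc_auc(c(0.2, 0.4, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 8), rep(c(0, 1), 4))$auc, 0.5)  # all ties
  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force some ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_pair_counting(scores, labels))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), class = "ueff_error_single_class")
})

test_that("AUC is rank-invariant and label-swap maps to its complement", {
  set.seed(42)
  scores <- rnorm(30)
  labels <- sample(0:1, 30, replace = TRUE, prob = c(0.4, 0.6))
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
  expect_equal(roc_auc(scores, 1 - labels)$auc, 1 - a)
})

test_that("DeLong interval matches the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  scores <- c(rnorm(40, 1), rnorm(40))
  labels <- rep(c(1, 0), each = 40)
  mine <- roc_auc(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                direction = "<"), method = "delong")
  expect_equal(mine$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(mine$ci_low, as.numeric(ref[1]), tolerance = 1e-9)
  expect_equal(mine$ci_high, as.numeric(ref[3]), tolerance = 1e-9)
})

test_that("Youden cutoff equals brute-force enumeration with its tie-break", {
  # perfectly separated: the midpoint of the gap
  sep <- best_cutoff_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$cutoff, 6.5)
  expect_equal(sep$j, 1)

  set.seed(44)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    scores <- round(rnorm(n), 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    got <- best_cutoff_youden(scores, labels)
    want <- youden_brute_force(scores, labels)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$j, want$j)
  }

  # uninformative scores: deterministic result, stable under permutation
  scores <- rep(c(1, 2, 3), each = 4)
  labels <- rep(c(0, 1), 6)
  c1 <- best_cutoff_youden(scores, labels)
  perm <- sample(12)
  c2 <- best_cutoff_youden(scores[perm], labels[perm])
  expect_equal(c1, c2)
})

test_that("the literal J definition reduces to maximising sensitivity", {
  scores <- c(1, 2, 3, 4)
  labels <- c(0, 1, 0, 1)
  lit <- best_cutoff_youden(scores, labels, j_definition = "literal")
  # any cutoff with TPR = 1 attains J = 1; tie-break picks the highest
  expect_equal(lit$j, 1)
  expect_equal(lit$cutoff, 1.5)
})

test_that("confusion-table metrics follow their definitions", {
  # constructed 2x2: TP = 9, FN = 1, TN = 8, FP = 2 at cutoff 0.5
  scores <- c(rep(0.9, 9), 0.1, rep(0.2, 8), rep(0.7, 2))
  labels <- c(rep(1, 10), rep(0, 10))
  m <- classification_metrics(scores, labels, 0.5)
  expect_equal(m$sn, 0.9)
  expect_equal(m$sp, 0.8)
  expect_equal(m$ppv, 9 / 11, tolerance = 1e-12)
  expect_equal(m$npv, 8 / 9, tolerance = 1e-12)
  expect_equal(m$ta, 0.85)

  all_pos <- classification_metrics(scores, labels, -Inf)
  expect_equal(c(all_pos$sn, all_pos$sp), c(1, 0))
  all_neg <- classification_metrics(scores, labels, Inf)
  expect_equal(c(all_neg$sn, all_neg$sp), c(0, 1))
  expect_error(classification_metrics(scores, labels, NA_real_),
               class = "ueff_error_invalid_input")
})

test_that("at the Youden cutoff sn + sp - 1 equals the brute-force maximum", {
  set.seed(45)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    scores <- round(rnorm(n), 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    cut <- best_cutoff_youden(scores, labels)
    met <- classification_metrics(scores, labels, cut$cutoff)
    expect_equal(met$sn + met$sp - 1, youden_brute_force(scores, labels)$j,
                 tolerance = 1e-12)
  }
})

test_that("AUC power behaves like the test it approximates", {
  # null effect: power equals the significance level
  expect_equal(power_auc(0.5 + 1e-12, 40, 40)$power, 0.05, tolerance = 1e-3)
  # the study-sized strong effect is adequately powered
  strong <- power_auc(0.97, 71, 19)
  expect_gte(strong$power, 0.995)  # rounds to 1.00
  expect_true(strong$adequate)
  # monotone in the positive-class size
  powers <- sapply(c(5, 10, 20, 40, 80), function(m)
    power_auc(0.7, m, 30)$power)
  expect_true(all(diff(powers) > 0))
  expect_error(power_auc(1, 10, 10), class = "ueff_error_invalid_input")
})

test_that("roc_analysis bundles a coherent diagnostic row", {
  set.seed(46)
  scores <- c(rnorm(60, 1.5), rnorm(30))
  labels <- rep(c(1, 0), c(60, 30))
  r <- roc_analysis(scores, labels)
  expect_s3_class(r, "roc_result")
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_true(all(c(r$sn, r$sp, r$ppv, r$npv, r$ta) >= 0 &
                    c(r$sn, r$sp, r$ppv, r$npv, r$ta) <= 1))
  met <- classification_metrics(scores, labels, r$cutoff)
  expect_equal(r$ta, met$ta)
  expect_equal(r$n_pos, 60)
  expect_equal(r$n_neg, 30)
})
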
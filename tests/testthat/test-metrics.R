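test_that("confusion counts match enumeration and a brute-force scan", {
  cc <- confusion(c(1, 0), c(1, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  cc2 <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(c(cc2$TP, cc2$FN, cc2$FP, cc2$TN), c(1, 1, 1, 1))
  expect_error(confusion(c(1, 0), c(1)), "lengths differ")

  withr::with_seed(42, {
    for (i in 1:5) {
      yt <- rbinom(50, 1, 0.4); yp <- rbinom(50, 1, 0.5)
      cc <- confusion(yt, yp)
      brute <- c(TP = 0, TN = 0, FP = 0, FN = 0)
      for (k in seq_along(yt)) {
        lab <- if (yt[k] == 1 && yp[k] == 1) "TP"
        else if (yt[k] == 0 && yp[k] == 0) "TN"
        else if (yt[k] == 0 && yp[k] == 1) "FP" else "FN"
        brute[lab] <- brute[lab] + 1
      }
      expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), unname(brute))
    }
  })
})

test_that("scalar metrics follow their formulas", {
  cc <- structure(list(TP = 40, TN = 60, FP = 10, FN = 20),
                  class = "confusion_counts")
  expect_equal(accuracy(cc), 100 / 130, tolerance = 1e-12)
  expect_equal(ppv(cc), 0.8)
  expect_equal(recall(cc), 2 / 3)
  expect_equal(f_score(cc), 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))
  expect_equal(mcc(cc), 2200 / sqrt(50 * 60 * 70 * 80), tolerance = 1e-12)

  # F equals the common value when PPV == recall
  cc2 <- structure(list(TP = 30, TN = 50, FP = 10, FN = 10),
                   class = "confusion_counts")
  expect_equal(f_score(cc2), ppv(cc2))

  # degenerate denominators return 0 with a warning
  cc3 <- structure(list(TP = 0, TN = 5, FP = 0, FN = 5),
                   class = "confusion_counts")
  expect_warning(expect_equal(ppv(cc3), 0), "zero denominator")
})

test_that("MCC hits its bounds and is swap-symmetric", {
  perf <- structure(list(TP = 5, TN = 5, FP = 0, FN = 0),
                    class = "confusion_counts")
  inv <- structure(list(TP = 0, TN = 0, FP = 5, FN = 5),
                   class = "confusion_counts")
  expect_equal(mcc(perf), 1)
  expect_equal(mcc(inv), -1)
  withr::with_seed(3, for (i in 1:20) {
    v <- as.list(rpois(4, 8) + 1)
    names(v) <- c("TP", "TN", "FP", "FN")
    a <- structure(v, class = "confusion_counts")
    b <- structure(list(TP = v$TN, TN = v$TP, FP = v$FN, FN = v$FP),
                   class = "confusion_counts")
    expect_equal(mcc(a), mcc(b), tolerance = 1e-12)
    expect_true(mcc(a) >= -1 && mcc(a) <= 1)
  })
})

test_that("MCC normalization is the affine map onto [0,1]", {
  expect_equal(normalize_mcc(0.5), 0.75)
  expect_equal(normalize_mcc(0.511), 0.7555)
  expect_equal(normalize_mcc(-1), 0)
  expect_error(normalize_mcc(1.5), "\\[-1,1\\]")
  m <- seq(-1, 1, by = 0.25)
  expect_true(all(diff(normalize_mcc(m)) > 0))  # monotone
})

test_that("trapezoidal AUC equals the Mann-Whitney probability", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2)), 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "one class")

  mann_whitney <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    g <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(g)
  }
  withr::with_seed(7, for (i in 1:200) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    expect_equal(roc_auc(y, s), mann_whitney(y, s), tolerance = 1e-12)
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, for (i in 1:10) {
    y <- rbinom(60, 1, 0.4); if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- rnorm(60)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(y, s), ref, tolerance = 1e-10)
  })
})

test_that("support-weighted recall equals accuracy", {
  withr::with_seed(5, for (i in 1:20) {
    y <- rbinom(40, 1, 0.3); p <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    prf <- hfselect:::.weighted_prf(y, p)
    expect_equal(prf[["recall"]], accuracy(confusion(y, p)),
                 tolerance = 1e-12)
  })
})

test_that("evaluation profiles validate ranges and normalize MCC", {
  p <- evaluation_profile(0.8, 0.7, 0.75, 0.5, 0.79, 0.8)
  expect_equal(p$mcc_normalized, 0.75)
  expect_error(evaluation_profile(1.2, 0.7, 0.7, 0.5, 0.7, 0.7),
               "out of range")
})

test_that("evaluate_model beats the majority baseline on planted signal", {
  co <- generate_cohort(cohort_spec(n = 600, p = 12, seed = 21))
  split <- split_train_test(co$table, 0.25, seed = 21)
  train <- subset_rows(co$table, split$train_indices)
  test <- subset_rows(co$table, split$test_indices)
  prof <- evaluate_model(train, test, co$truth$informative_indices,
                         model_seed = 1, num_trees = 150)
  baseline <- max(mean(test$outcome), 1 - mean(test$outcome))
  expect_gt(prof$acc, baseline)
  expect_gt(prof$auc, 0.6)

  # subset order must not matter
  prof2 <- evaluate_model(train, test, rev(co$truth$informative_indices),
                          model_seed = 1, num_trees = 150)
  expect_equal(prof, prof2)
})

test_that("label permutation drives the test MCC into a null band", {
  co <- generate_cohort(cohort_spec(n = 300, p = 8, seed = 31))
  split <- split_train_test(co$table, 0.3, seed = 31)
  mccs <- withr::with_seed(99, vapply(1:20, function(i) {
    t2 <- co$table
    t2$outcome <- sample(t2$outcome)
    tr <- subset_rows(t2, split$train_indices)
    te <- subset_rows(t2, split$test_indices)
    evaluate_model(tr, te, 1:4, model_seed = i, num_trees = 40)$mcc
  }, numeric(1)))
  expect_lt(abs(mean(mccs)), 0.1)
})
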
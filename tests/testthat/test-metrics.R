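test_that("confusion counts follow the >= threshold convention", {
  cc <- confusion_at_threshold(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0), 0.5)
  expect_equal(cc, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))

  perfect <- confusion_at_threshold(c(0.9, 0.1), c(1, 0))
  expect_equal(perfect$FP + perfect$FN, 0L)

  all_low <- confusion_at_threshold(rep(0.2, 4), rep(1, 4))
  expect_equal(all_low$TP, 0L)
  expect_equal(all_low$FN, 4L)
  expect_error(confusion_at_threshold(numeric(0), numeric(0)), "empty")
})

test_that("threshold metrics evaluate their formulas with guarded zeros", {
  m <- compute_metrics(list(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$acc, 0.8)
  expect_equal(m$f1, 0.75)
  expect_equal(m$mcc, 14 / 24)

  expect_warning(m0 <- compute_metrics(list(TP = 4, FP = 0, TN = 0, FN = 0)),
                 "MCC undefined")
  expect_equal(m0$precision, 1)
  expect_equal(m0$recall, 1)
  expect_equal(m0$f1, 1)
  expect_equal(m0$mcc, 0)

  # label swap (TP<->TN, FP<->FN) preserves accuracy and MCC
  sw <- suppressWarnings(compute_metrics(list(TP = 5, FP = 1, TN = 3, FN = 1)))
  expect_equal(sw$acc, m$acc)
  expect_equal(sw$mcc, m$mcc)
})

test_that("metrics match an independent formula oracle on exhaustive grids", {
  oracle <- function(tp, fp, tn, fn) {
    safe <- function(num, den) if (den == 0) 0 else num / den
    pr <- safe(tp, tp + fp); rc <- safe(tp, tp + fn)
    list(precision = pr, recall = rc,
         acc = safe(tp + tn, tp + fp + tn + fn),
         f1 = safe(2 * pr * rc, pr + rc),
         mcc = safe(tp * tn - fp * fn,
                    sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)))
  }
  grid <- expand.grid(tp = 0:12, fp = 0:12, tn = 0:12, fn = 0:12)
  grid <- grid[rowSums(grid) <= 12 & rowSums(grid) > 0, ]
  for (r in seq_len(nrow(grid))) {
    got <- suppressWarnings(compute_metrics(
      list(TP = grid$tp[r], FP = grid$fp[r],
           TN = grid$tn[r], FN = grid$fn[r])))
    want <- oracle(grid$tp[r], grid$fp[r], grid$tn[r], grid$fn[r])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("ROC AUC equals the concordant-pair statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)

  set.seed(3)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-9)
  }
  expect_error(roc_auc(c(0.5, 0.6), c(1, 1)), "both classes")
})

test_that("ROC AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    s <- runif(n)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-9)
  }
})

test_that("AUPR uses descending-score step integration", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aupr(c(0.3, 0.5), c(1, 1)), 1)
  expect_equal(aupr(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_error(aupr(c(0.2, 0.3), c(0, 0)), "positive")
})

test_that("pooled t-test reproduces hand-derived cases", {
  same <- equal_variance_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  ht <- equal_variance_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ht$df, 4)
  expect_lt(abs(ht$t - (-3.674)), 1e-3)
  expect_lt(abs(ht$p - 0.0214), 1e-3)

  sw <- equal_variance_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$t, -ht$t)
  expect_equal(sw$p, ht$p)

  # closed-form pooled-variance cross-check
  a <- c(0.2, 0.5, 0.9, 0.4); b <- c(0.8, 0.3, 0.7)
  got <- equal_variance_t_test(a, b)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_manual), length(a) + length(b) - 2),
               tolerance = 1e-12)
  expect_error(equal_variance_t_test(1, c(1, 2)), "at least 2")
})
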
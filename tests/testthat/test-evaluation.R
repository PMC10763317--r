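test_that("negative sampling avoids known positives and is seeded", {
  pos <- cbind(c(1, 2, 3), c(1, 1, 2))
  neg <- sample_negatives(pos, n_lnc = 10, n_dis = 8, seed = 4)
  expect_equal(nrow(neg), nrow(pos))
  pos_keys <- paste(pos[, 1], pos[, 2])
  expect_false(any(paste(neg$lnc, neg$dis) %in% pos_keys))
  expect_true(all(neg$lnc >= 1 & neg$lnc <= 10))
  expect_true(all(neg$dis >= 1 & neg$dis <= 8))

  neg2 <- sample_negatives(pos, 10, 8, seed = 4)
  expect_identical(neg, neg2)
  neg3 <- sample_negatives(pos, 10, 8, seed = 5)
  expect_false(identical(neg, neg3))

  expect_error(sample_negatives(pos, 2, 2, n = 3), "only 1 unknown")
})

test_that("CV plans satisfy the 20%/fivefold partition invariants", {
  labeled <- data.frame(lnc = rep(1:20, 10), dis = rep(1:10, 20),
                        label = rep(c(1, 0), each = 100))
  plan <- make_cv_plan(labeled, seed = 1)
  expect_length(plan$test_idx, 40)
  cv <- unlist(plan$folds)
  expect_length(cv, 160)
  expect_true(all(lengths(plan$folds) == 32))
  expect_equal(length(intersect(plan$test_idx, cv)), 0)
  expect_equal(anyDuplicated(cv), 0)
  expect_setequal(c(plan$test_idx, cv), seq_len(200))
  # stratification: each fold balanced within one pair
  for (f in plan$folds) {
    expect_lte(abs(sum(labeled$label[f] == 1) - sum(labeled$label[f] == 0)), 1)
  }
  expect_lte(abs(sum(labeled$label[plan$test_idx] == 1) -
                 sum(labeled$label[plan$test_idx] == 0)), 1)

  expect_identical(make_cv_plan(labeled, seed = 1), plan)
  expect_false(identical(make_cv_plan(labeled, seed = 2)$test_idx,
                         plan$test_idx))
  expect_error(make_cv_plan(labeled[1:5, ]), "at least 10")
  tiny <- data.frame(lnc = 1:12, dis = 1, label = c(rep(1, 9), 0, 0, 0))
  expect_error(make_cv_plan(tiny), "minority class")
})

test_that("cross-validation reports five folds plus mean and test rows", {
  fx <- tiny_benchmark()
  g <- fx$graph
  labeled <- build_labeled_pairs(g, seed = 6)
  plan <- make_cv_plan(labeled, seed = 6)
  cfg <- fast_config(train = list(epochs = 4L))
  rep1 <- run_cross_validation(g, labeled, cfg, plan)
  expect_s3_class(rep1, "cv_report")
  expect_equal(nrow(rep1$folds), 5)
  expect_named(rep1$mean,
               c("auc", "aupr", "acc", "f1", "mcc", "precision", "recall"))
  expect_equal(nrow(rep1$test), 1)
  expect_true(all(rep1$folds$auc >= 0 & rep1$folds$auc <= 1))

  rep2 <- run_cross_validation(g, labeled, cfg, plan)
  expect_identical(rep1$folds, rep2$folds)  # fixed seeds, identical report
})

test_that("masking keeps every held-out positive out of the training graph", {
  fx <- tiny_benchmark()
  g <- fx$graph
  labeled <- build_labeled_pairs(g, seed = 9)
  plan <- make_cv_plan(labeled, seed = 9)
  test_pos <- labeled[plan$test_idx, ]
  test_pos <- as.matrix(test_pos[test_pos$label == 1, c("lnc", "dis")])
  for (f in seq_along(plan$folds)) {
    val <- labeled[plan$folds[[f]], ]
    val_pos <- as.matrix(val[val$label == 1, c("lnc", "dis")])
    masked <- mask_fold_edges(g, rbind(val_pos, test_pos))
    expect_equal(sum(masked$Z_ld[val_pos]), 0)
    expect_equal(sum(masked$Z_ld[test_pos]), 0)
    # everything else untouched
    expect_equal(sum(g$Z_ld) - sum(masked$Z_ld),
                 nrow(unique(rbind(val_pos, test_pos))))
  }
})

test_that("ablation produces both variant tables with the expected rows", {
  fx <- tiny_benchmark()
  g <- fx$graph
  labeled <- build_labeled_pairs(g, seed = 5)
  plan <- make_cv_plan(labeled, seed = 5)
  cfg <- fast_config(train = list(epochs = 2L))
  ab <- run_ablation(g, labeled, cfg, plan)
  gv <- ab$graph_variants
  expect_equal(nrow(gv), 3)
  expect_named(gv, c("interclass_Z", "intraclass_S", "auc", "aupr"))
  expect_true(any(gv$interclass_Z & gv$intraclass_S))  # full model row
  tv <- ab$transformer_variants
  expect_equal(nrow(tv), 4)
  expect_named(tv, c("add", "norm", "ffn", "auc", "aupr"))
  expect_true(all(tv$auc >= 0 & tv$auc <= 1))
})

test_that("the hyperparameter sweep covers the requested grid", {
  fx <- tiny_benchmark()
  g <- fx$graph
  labeled <- build_labeled_pairs(g, seed = 5)
  plan <- make_cv_plan(labeled, seed = 5)
  cfg <- fast_config(train = list(epochs = 2L))
  grid <- run_sweep(g, labeled, cfg, plan,
                    layers = c(1L, 2L), sizes = c(8L, 16L))
  expect_equal(nrow(grid), 4)
  expect_setequal(grid$layers, c(1L, 2L))
  expect_setequal(grid$embedding, c(8L, 16L))
  expect_true(all(is.finite(grid$auc)))
})
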
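#' Sample negative (unknown) lncRNA-disease pairs
#'
#' Draws pairs uniformly without replacement from the lncRNA x disease
#' universe excluding the known positives. By convention as many negatives
#' as positives are drawn (balanced 1:1 sampling).
#'
#' @param positives two-column matrix/data frame of known positive
#'   (lncRNA index, disease index) pairs.
#' @param n_lnc,n_dis class sizes defining the pair universe.
#' @param n number of negatives (default: one per positive).
#' @param seed integer RNG seed.
#' @return data frame with columns `lnc`, `dis`.
#' @export
sample_negatives <- function(positives, n_lnc, n_dis, n = NULL, seed = 1L) {
  pos <- .as_pair_matrix(positives)
  if (is.null(n)) n <- nrow(pos)
  universe <- n_lnc * n_dis
  pos_lin <- (pos[, 2] - 1L) * n_lnc + pos[, 1]
  available <- universe - length(unique(pos_lin))
  if (n > available) {
    stop(sprintf("requested %d negatives but only %d unknown pairs exist",
                 n, available))
  }
  set.seed(as.integer(seed))
  candidates <- setdiff(seq_len(universe), pos_lin)
  chosen <- sample(candidates, n)
  data.frame(lnc = ((chosen - 1L) %% n_lnc) + 1L,
             dis = ((chosen - 1L) %/% n_lnc) + 1L)
}

#' Build a stratified test/cross-validation split plan
#'
#' Holds out 20% of the labeled pairs as a test set (never used in training
#' or validation), and partitions the remaining 80% into five near-equal
#' folds. Both splits are stratified by label so class balance is preserved.
#'
#' @param labeled_pairs data frame with columns `lnc`, `dis`, `label`.
#' @param seed integer RNG seed.
#' @param n_folds number of CV folds (default 5).
#' @param test_fraction fraction held out as the final test set
#'   (default 0.2).
#' @return object of class `cv_plan`: list with `test_idx` (row indices
#'   into `labeled_pairs`), `folds` (list of index vectors partitioning the
#'   rest), `seed`, `n_folds`, `test_fraction`.
#' @export
make_cv_plan <- function(labeled_pairs, seed = 1L, n_folds = 5L,
                         test_fraction = 0.2) {
  if (nrow(labeled_pairs) < 10) stop("need at least 10 labeled pairs")
  y <- labeled_pairs$label
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  if (min(sum(y == 1), sum(y == 0)) < n_folds) {
    stop(sprintf("too few pairs in the minority class for %d folds", n_folds))
  }
  set.seed(as.integer(seed))
  test_idx <- integer(0)
  fold_of <- integer(nrow(labeled_pairs))
  for (cls in c(1, 0)) {
    idx <- sample(which(y == cls))
    n_test <- round(test_fraction * length(idx))
    test_idx <- c(test_idx, idx[seq_len(n_test)])
    rest <- idx[-seq_len(n_test)]
    # round-robin over a shuffled order keeps fold sizes within 1
    fold_of[rest] <- rep_len(seq_len(n_folds), length(rest))
  }
  folds <- lapply(seq_len(n_folds), function(f) {
    setdiff(which(fold_of == f), test_idx)
  })
  structure(list(test_idx = sort(test_idx), folds = folds,
                 seed = as.integer(seed), n_folds = as.integer(n_folds),
                 test_fraction = test_fraction),
            class = "cv_plan")
}

# Metrics row for one scored set.
.metric_row <- function(scores, labels, threshold) {
  cc <- confusion_at_threshold(scores, labels, threshold)
  m <- suppressWarnings(compute_metrics(cc))
  data.frame(auc = roc_auc(scores, labels), aupr = aupr(scores, labels),
             acc = m$acc, f1 = m$f1, mcc = m$mcc,
             precision = m$precision, recall = m$recall)
}

#' Run the held-out test + fivefold cross-validation protocol
#'
#' For each fold, the positive pairs of that fold and of the test set are
#' masked out of the association block (leak-free transductive evaluation),
#' the model is trained on the remaining four folds and scored on the held
#' fold. After the folds, one final model is trained on the whole CV split
#' (test positives masked) and evaluated on the test set.
#'
#' @param graph a `het_graph` with the full known association block.
#' @param labeled_pairs data frame with columns `lnc`, `dis`, `label`.
#' @param config configuration from [load_config()]; `config$eval$mask`
#'   disables edge masking when `FALSE`.
#' @param plan a `cv_plan` from [make_cv_plan()].
#' @return object of class `cv_report`: list with `folds` (per-fold metric
#'   data frame), `mean` (column means over folds), `test` (test-set metric
#'   row), and `threshold`.
#' @export
run_cross_validation <- function(graph, labeled_pairs, config = load_config(),
                                 plan = make_cv_plan(labeled_pairs)) {
  stopifnot(inherits(plan, "cv_plan"))
  threshold <- config$eval$threshold
  mask_on <- isTRUE(config$eval$mask)
  test_pos <- .positive_pairs(labeled_pairs, plan$test_idx)

  fold_rows <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    val_idx <- plan$folds[[f]]
    train_idx <- setdiff(unlist(plan$folds[-f]), plan$test_idx)
    masked <- if (mask_on) {
      mask_fold_edges(graph, rbind(.positive_pairs(labeled_pairs, val_idx),
                                   test_pos))
    } else graph
    model <- train_model(masked, labeled_pairs[train_idx, ],
                         config, seed = plan$seed + f,
                         eval_exclude = labeled_pairs[c(val_idx, plan$test_idx),
                                                      c("lnc", "dis")])
    scores <- predict(model, masked, labeled_pairs[val_idx, c("lnc", "dis")])
    fold_rows[[f]] <- cbind(fold = f,
                            .metric_row(scores, labeled_pairs$label[val_idx],
                                        threshold))
  }
  folds_df <- do.call(rbind, fold_rows)

  cv_idx <- setdiff(seq_len(nrow(labeled_pairs)), plan$test_idx)
  masked_test <- if (mask_on) mask_fold_edges(graph, test_pos) else graph
  final_model <- train_model(masked_test, labeled_pairs[cv_idx, ],
                             config, seed = plan$seed,
                             eval_exclude = labeled_pairs[plan$test_idx,
                                                          c("lnc", "dis")])
  test_scores <- predict(final_model, masked_test,
                         labeled_pairs[plan$test_idx, c("lnc", "dis")])
  test_row <- .metric_row(test_scores, labeled_pairs$label[plan$test_idx],
                          threshold)

  structure(list(folds = folds_df,
                 mean = colMeans(folds_df[, -1, drop = FALSE]),
                 test = test_row, threshold = threshold),
            class = "cv_report")
}

.positive_pairs <- function(labeled_pairs, idx) {
  sub <- labeled_pairs[idx, , drop = FALSE]
  as.matrix(sub[sub$label == 1, c("lnc", "dis"), drop = FALSE])
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds | mean AUC %.4f, AUPR %.4f | test AUC %.4f, AUPR %.4f\n",
              nrow(x$folds), x$mean[["auc"]], x$mean[["aupr"]],
              x$test$auc, x$test$aupr))
  invisible(x)
}

#' Run the full evaluation protocol on a benchmark dataset
#'
#' Samples balanced negatives, builds one (or several, `repeats`) CV plans
#' and runs [run_cross_validation()] per repeat.
#'
#' @param graph a `het_graph`.
#' @param config configuration; `config$eval$repeats` plans are evaluated.
#' @param seed master seed; repeat r uses `seed + 100 * r` for its
#'   negatives and plan.
#' @param repeats number of independent repetitions (defaults to
#'   `config$eval$repeats`).
#' @return list of `cv_report`s (one per repeat) with attribute
#'   `grand_mean` (mean of per-repeat fold means).
#' @export
evaluate_protocol <- function(graph, config = load_config(), seed = 1L,
                              repeats = config$eval$repeats) {
  reports <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rep_seed <- as.integer(seed) + 100L * r
    labeled <- build_labeled_pairs(graph, seed = rep_seed,
                                   ratio = config$eval$negative_ratio)
    plan <- make_cv_plan(labeled, seed = rep_seed,
                         n_folds = config$eval$folds,
                         test_fraction = config$eval$test_fraction)
    reports[[r]] <- run_cross_validation(graph, labeled, config, plan)
  }
  means <- do.call(rbind, lapply(reports, function(r) r$mean))
  attr(reports, "grand_mean") <- colMeans(means)
  reports
}

#' Labeled pair set from a graph's association block
#'
#' All known positives plus `ratio` times as many sampled negatives.
#'
#' @param graph a `het_graph`.
#' @param seed RNG seed for the negative draw.
#' @param ratio negatives per positive (default 1).
#' @return data frame with columns `lnc`, `dis`, `label`.
#' @export
build_labeled_pairs <- function(graph, seed = 1L, ratio = 1) {
  pos <- which(graph$Z_ld == 1, arr.ind = TRUE)
  colnames(pos) <- c("lnc", "dis")
  if (nrow(pos) == 0) stop("graph has no known associations")
  neg <- sample_negatives(pos, graph$n_l, graph$n_d,
                          n = round(ratio * nrow(pos)), seed = seed)
  rbind(data.frame(lnc = pos[, "lnc"], dis = pos[, "dis"], label = 1),
        cbind(neg, label = 0))
}

#' Graph-component and transformer-module ablation
#'
#' Evaluates (a) graph variants: interclass-only (similarity blocks reduced
#' to the identity), intraclass-only (association blocks zeroed) and the
#' full graph; (b) transformer variants: residual connection, layer
#' normalization or feed-forward sublayer disabled, and the full encoder.
#' Each variant runs the same cross-validation protocol.
#'
#' @param graph a `het_graph`.
#' @param labeled_pairs data frame with columns `lnc`, `dis`, `label`.
#' @param config configuration.
#' @param plan a `cv_plan` shared by all variants.
#' @return list with data frames `graph_variants` (columns `interclass_Z`,
#'   `intraclass_S`, `auc`, `aupr`) and `transformer_variants` (columns
#'   `add`, `norm`, `ffn`, `auc`, `aupr`).
#' @export
run_ablation <- function(graph, labeled_pairs, config = load_config(),
                         plan = make_cv_plan(labeled_pairs)) {
  eval_auc <- function(g, cfg) {
    rep <- run_cross_validation(g, labeled_pairs, cfg, plan)
    c(auc = unname(rep$mean[["auc"]]), aupr = unname(rep$mean[["aupr"]]))
  }
  eye <- function(S) diag(1, nrow(S))
  z_only <- assemble_adjacency(eye(graph$S_ll), eye(graph$S_dd), eye(graph$S_mm),
                               graph$Z_ld, graph$Z_lm, graph$Z_md,
                               graph$lnc_ids, graph$dis_ids, graph$mir_ids)
  s_only <- assemble_adjacency(graph$S_ll, graph$S_dd, graph$S_mm,
                               0 * graph$Z_ld, 0 * graph$Z_lm, 0 * graph$Z_md,
                               graph$lnc_ids, graph$dis_ids, graph$mir_ids)
  gv <- rbind(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  graph_res <- t(mapply(function(gg, cfg) eval_auc(gg, cfg),
                        list(z_only, s_only, graph),
                        list(config, config, config)))
  graph_variants <- data.frame(interclass_Z = gv[, 1], intraclass_S = gv[, 2],
                               auc = graph_res[, "auc"],
                               aupr = graph_res[, "aupr"])

  tv <- rbind(c(FALSE, TRUE, TRUE), c(TRUE, FALSE, TRUE),
              c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))
  t_rows <- lapply(seq_len(nrow(tv)), function(i) {
    cfg <- config
    cfg$transformer$use_add <- tv[i, 1]
    cfg$transformer$use_norm <- tv[i, 2]
    cfg$transformer$use_ffn <- tv[i, 3]
    eval_auc(graph, cfg)
  })
  t_res <- do.call(rbind, t_rows)
  transformer_variants <- data.frame(add = tv[, 1], norm = tv[, 2],
                                     ffn = tv[, 3],
                                     auc = t_res[, "auc"],
                                     aupr = t_res[, "aupr"])
  list(graph_variants = graph_variants,
       transformer_variants = transformer_variants)
}

#' GCN hyperparameter sweep (layers x embedding size)
#'
#' Evaluates the CV protocol over a grid of GCN depths and embedding sizes
#' and reports the mean AUC per cell.
#'
#' @param graph a `het_graph`.
#' @param labeled_pairs data frame with columns `lnc`, `dis`, `label`.
#' @param config base configuration (its GCN settings are overridden per
#'   cell).
#' @param plan a `cv_plan` shared by all cells.
#' @param layers integer vector of GCN layer counts.
#' @param sizes integer vector of embedding sizes.
#' @return data frame with columns `layers`, `embedding`, `auc`, `aupr`.
#' @export
run_sweep <- function(graph, labeled_pairs, config = load_config(),
                      plan = make_cv_plan(labeled_pairs),
                      layers = c(1L, 2L, 3L), sizes = c(64L, 128L, 256L)) {
  grid <- expand.grid(layers = layers, embedding = sizes)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$gcn$layers <- grid$layers[i]
    cfg$gcn$embedding <- grid$embedding[i]
    rep <- run_cross_validation(graph, labeled_pairs, cfg, plan)
    c(auc = unname(rep$mean[["auc"]]), aupr = unname(rep$mean[["aupr"]]))
  })
  cbind(grid, do.call(rbind, res))
}
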
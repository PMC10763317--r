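# Analytic gradients for the full model, mirrored against the forward pass
# in model.R. Verified against central finite differences in the test suite.

# Backward through one encoder layer. d_out_* are gradients w.r.t. the
# layer outputs; returns gradients for the layer parameters and the inputs.
.encoder_layer_backward <- function(cache, lp, meta, d_out_a, d_out_b) {
  emb <- meta$emb; h <- meta$heads; dh <- emb %/% h
  g <- list(Wq = 0 * lp$Wq, Wk = 0 * lp$Wk, Wv = 0 * lp$Wv, W0 = 0 * lp$W0,
            g1 = 0 * lp$g1, b1 = 0 * lp$b1, g2 = 0 * lp$g2, b2 = 0 * lp$b2,
            Wf1 = 0 * lp$Wf1, bf1 = 0 * lp$bf1,
            Wf2 = 0 * lp$Wf2, bf2 = 0 * lp$bf2)

  if (meta$use_ffn) {
    if (meta$use_norm) {
      bk_a <- .layer_norm_backward(d_out_a, cache$ln2a, lp$g2)
      bk_b <- .layer_norm_backward(d_out_b, cache$ln2b, lp$g2)
      g$g2 <- bk_a$dgain + bk_b$dgain
      g$b2 <- bk_a$dbias + bk_b$dbias
      dR2a <- bk_a$dX; dR2b <- bk_b$dX
    } else {
      dR2a <- d_out_a; dR2b <- d_out_b
    }
    dFa <- dR2a; dFb <- dR2b
    dUa <- if (meta$use_add) dR2a else matrix(0, nrow(dR2a), emb)
    dUb <- if (meta$use_add) dR2b else matrix(0, nrow(dR2b), emb)
    # FFN: F = relu(U Wf1 + bf1) Wf2 + bf2
    g$Wf2 <- crossprod(cache$hid_a, dFa) + crossprod(cache$hid_b, dFb)
    g$bf2 <- colSums(dFa) + colSums(dFb)
    dhid_a <- dFa %*% t(lp$Wf2); dhid_b <- dFb %*% t(lp$Wf2)
    dpre_a <- dhid_a * (cache$pre_a > 0); dpre_b <- dhid_b * (cache$pre_b > 0)
    g$Wf1 <- crossprod(cache$Ua, dpre_a) + crossprod(cache$Ub, dpre_b)
    g$bf1 <- colSums(dpre_a) + colSums(dpre_b)
    dUa <- dUa + dpre_a %*% t(lp$Wf1)
    dUb <- dUb + dpre_b %*% t(lp$Wf1)
  } else {
    dUa <- d_out_a; dUb <- d_out_b
  }

  if (meta$use_norm) {
    bk_a <- .layer_norm_backward(dUa, cache$ln1a, lp$g1)
    bk_b <- .layer_norm_backward(dUb, cache$ln1b, lp$g1)
    g$g1 <- bk_a$dgain + bk_b$dgain
    g$b1 <- bk_a$dbias + bk_b$dbias
    dR1a <- bk_a$dX; dR1b <- bk_b$dX
  } else {
    dR1a <- dUa; dR1b <- dUb
  }
  dMa <- dR1a; dMb <- dR1b
  dTa <- if (meta$use_add) dR1a else matrix(0, nrow(dR1a), emb)
  dTb <- if (meta$use_add) dR1b else matrix(0, nrow(dR1b), emb)

  # Output projection of the spliced heads.
  g$W0 <- crossprod(cache$Oa, dMa) + crossprod(cache$Ob, dMb)
  dOa <- dMa %*% t(lp$W0); dOb <- dMb %*% t(lp$W0)

  dQa <- matrix(0, nrow(dOa), emb); dQb <- matrix(0, nrow(dOa), emb)
  dKa <- matrix(0, nrow(dOa), emb); dKb <- matrix(0, nrow(dOa), emb)
  dVa <- matrix(0, nrow(dOa), emb); dVb <- matrix(0, nrow(dOa), emb)
  sc <- 1 / sqrt(dh)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dh + 1):(i * dh)
    qa <- cache$Qa[, cols, drop = FALSE]; qb <- cache$Qb[, cols, drop = FALSE]
    ka <- cache$Ka[, cols, drop = FALSE]; kb <- cache$Kb[, cols, drop = FALSE]
    va <- cache$Va[, cols, drop = FALSE]; vb <- cache$Vb[, cols, drop = FALSE]
    w11 <- cache$a11[, i]; w21 <- cache$a21[, i]
    dOah <- dOa[, cols, drop = FALSE]; dObh <- dOb[, cols, drop = FALSE]
    # O_a = w11 va + (1-w11) vb ; O_b = w21 va + (1-w21) vb
    da11 <- rowSums(dOah * va); da12 <- rowSums(dOah * vb)
    da21 <- rowSums(dObh * va); da22 <- rowSums(dObh * vb)
    dVa[, cols] <- w11 * dOah + w21 * dObh
    dVb[, cols] <- (1 - w11) * dOah + (1 - w21) * dObh
    # w11 = sigmoid(s11 - s12): two-way softmax over the row logits.
    du1 <- (da11 - da12) * w11 * (1 - w11)
    du2 <- (da21 - da22) * w21 * (1 - w21)
    ds11 <- du1; ds12 <- -du1; ds21 <- du2; ds22 <- -du2
    dQa[, cols] <- (ds11 * ka + ds12 * kb) * sc
    dQb[, cols] <- (ds21 * ka + ds22 * kb) * sc
    dKa[, cols] <- (ds11 * qa + ds21 * qb) * sc
    dKb[, cols] <- (ds12 * qa + ds22 * qb) * sc
  }
  g$Wq <- crossprod(cache$Ta, dQa) + crossprod(cache$Tb, dQb)
  g$Wk <- crossprod(cache$Ta, dKa) + crossprod(cache$Tb, dKb)
  g$Wv <- crossprod(cache$Ta, dVa) + crossprod(cache$Tb, dVb)
  dTa <- dTa + dQa %*% t(lp$Wq) + dKa %*% t(lp$Wk) + dVa %*% t(lp$Wv)
  dTb <- dTb + dQb %*% t(lp$Wq) + dKb %*% t(lp$Wk) + dVb %*% t(lp$Wv)
  list(grads = g, dTa = dTa, dTb = dTb)
}

# Loss + full analytic gradient for one batch.
.model_loss_grad <- function(params, norm, li, di, labels) {
  meta <- params$meta
  fw <- .model_forward(params, norm, li, di)
  loss <- bce_loss(fw$p, labels, meta$clamp)
  B <- length(labels)
  # d loss / d logit for mean BCE with sigmoid head; clamped scores have
  # zero gradient through the clamp but (p - y)/B is the exact subgradient
  # used universally (clamp only ever binds at numerical saturation).
  dlogit <- (fw$p - labels) / B

  grads <- list(gcn = list(W = lapply(params$gcn$W, function(w) 0 * w)),
                enc = NULL, head = NULL)
  grads$head <- list(w = crossprod(fw$xcat, dlogit), b = sum(dlogit))
  dxcat <- tcrossprod(dlogit, drop(params$head$w))
  emb <- meta$emb
  dTa <- dxcat[, seq_len(emb), drop = FALSE]
  dTb <- dxcat[, emb + seq_len(emb), drop = FALSE]

  enc_grads <- vector("list", meta$enc_layers)
  for (e in rev(seq_len(meta$enc_layers))) {
    bk <- .encoder_layer_backward(fw$enc_caches[[e]], params$enc[[e]],
                                  meta, dTa, dTb)
    enc_grads[[e]] <- bk$grads
    dTa <- bk$dTa
    dTb <- bk$dTb
  }
  grads$enc <- enc_grads

  # Scatter pair-token gradients back onto node embeddings (duplicate
  # indices accumulate).
  dZ <- matrix(0, meta$n_t, emb)
  agg <- rowsum(rbind(dTa, dTb), group = c(fw$rows_a, fw$rows_b))
  dZ[as.integer(rownames(agg)), ] <- agg

  # GCN backward: H_{l+1} = act(X_tilde H_l W_l); X_tilde is symmetric.
  dH <- dZ
  L <- meta$gcn_layers
  for (l in rev(seq_len(L))) {
    dM <- .activation_backward(dH, fw$gcn$M[[l]], fw$gcn$H[[l + 1]],
                               params$gcn$activations[l])
    grads$gcn$W[[l]] <- crossprod(fw$gcn$P[[l]], dM)
    if (l > 1) dH <- norm$X_tilde %*% tcrossprod(dM, params$gcn$W[[l]])
  }
  list(loss = loss, grads = grads, scores = fw$p)
}

# ---- parameter flattening (shared by Adam and the gradient checker) ------

.params_to_list <- function(params) {
  out <- list()
  for (l in seq_along(params$gcn$W)) out[[paste0("gcn.W", l)]] <- params$gcn$W[[l]]
  for (e in seq_along(params$enc)) {
    for (nm in names(params$enc[[e]])) {
      out[[paste0("enc", e, ".", nm)]] <- params$enc[[e]][[nm]]
    }
  }
  out[["head.w"]] <- params$head$w
  out[["head.b"]] <- params$head$b
  out
}

.grads_to_list <- function(grads) {
  out <- list()
  for (l in seq_along(grads$gcn$W)) out[[paste0("gcn.W", l)]] <- grads$gcn$W[[l]]
  for (e in seq_along(grads$enc)) {
    for (nm in names(grads$enc[[e]])) {
      out[[paste0("enc", e, ".", nm)]] <- grads$enc[[e]][[nm]]
    }
  }
  out[["head.w"]] <- grads$head$w
  out[["head.b"]] <- grads$head$b
  out
}

.list_to_params <- function(flat, params) {
  for (l in seq_along(params$gcn$W)) params$gcn$W[[l]] <- flat[[paste0("gcn.W", l)]]
  for (e in seq_along(params$enc)) {
    for (nm in names(params$enc[[e]])) {
      params$enc[[e]][[nm]] <- flat[[paste0("enc", e, ".", nm)]]
    }
  }
  params$head$w <- flat[["head.w"]]
  params$head$b <- flat[["head.b"]]
  params
}

#' Train the pair classifier on a heterogeneous graph
#'
#' Full-batch Adam optimization of the binary cross-entropy over the given
#' labeled pairs, with all randomness driven by `seed`. Two regularizers
#' align training with the masked-edge evaluation regime and are on by
#' default (see [default_config()]):
#' * supervision-edge dropout (`train$edge_dropout`): each epoch, every
#'   training-positive edge is removed from the propagation graph with this
#'   probability, so the model learns to score a pair from its neighborhood
#'   rather than from its own edge;
#' * negative resampling (`train$resample_negatives`): each epoch the
#'   negative examples are redrawn uniformly from the unknown-pair pool
#'   (never touching `eval_exclude` pairs), preventing memorization of one
#'   fixed negative sample.
#'
#' The caller is responsible for masking held-out positive edges out of the
#' graph first (see [mask_fold_edges()]); [run_cross_validation()] does this
#' automatically.
#'
#' @param graph a `het_graph` whose `Z_ld` holds the training-visible
#'   associations.
#' @param train_pairs data frame with columns `lnc`, `dis` (1-based class
#'   indices) and `label` (0/1).
#' @param config configuration from [load_config()].
#' @param seed integer seed (initialization, dropout, resampling).
#' @param eval_exclude optional two-column matrix/data frame of pairs that
#'   must never be drawn as resampled negatives (e.g. held-out evaluation
#'   pairs).
#' @return object of class `graphlda_model`: list with `params`,
#'   `loss_trace` (one BCE value per epoch, evaluated before each update),
#'   `config` and `seed`.
#' @export
train_model <- function(graph, train_pairs, config = load_config(), seed = 1L,
                        eval_exclude = NULL) {
  stopifnot(inherits(graph, "het_graph"))
  if (!all(c("lnc", "dis", "label") %in% names(train_pairs))) {
    stop("train_pairs must have columns lnc, dis, label")
  }
  li <- as.integer(train_pairs$lnc)
  di <- as.integer(train_pairs$dis)
  y <- as.numeric(train_pairs$label)
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  if (any(li < 1 | li > graph$n_l) || any(di < 1 | di > graph$n_d)) {
    stop("training pair index out of range")
  }

  dropout <- config$train$edge_dropout
  resample <- isTRUE(config$train$resample_negatives)
  # training positives whose edges are visible in the graph (dropout targets)
  pos <- cbind(li, di)[y == 1, , drop = FALSE]
  pos <- pos[graph$Z_ld[pos] == 1, , drop = FALSE]
  neg_pool <- NULL
  if (resample) {
    known <- which(graph$Z_ld == 1)
    excl <- known
    if (!is.null(eval_exclude)) {
      ep <- .as_pair_matrix(eval_exclude)
      excl <- c(excl, (ep[, 2] - 1L) * graph$n_l + ep[, 1])
    }
    excl <- c(excl, (di - 1L) * graph$n_l + li)  # keep fixed pairs out too
    neg_pool <- setdiff(seq_len(graph$n_l * graph$n_d), excl)
    if (length(neg_pool) < sum(y == 0)) {
      resample <- FALSE  # degenerate universe: fall back to the fixed set
    }
  }

  norm_fixed <- normalize_graph(graph)
  params <- init_model(norm_fixed$n_t, config, seed)
  flat <- .params_to_list(params)
  m <- lapply(flat, function(x) 0 * x)
  v <- lapply(flat, function(x) 0 * x)
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  lr <- config$train$lr
  epochs <- config$train$epochs
  trace <- numeric(epochs)
  n_neg <- sum(y == 0)

  set.seed(as.integer(seed) + 1L)
  for (t in seq_len(epochs)) {
    if (resample && n_neg > 0) {
      nl <- sample(neg_pool, n_neg)
      bli <- c(li[y == 1], ((nl - 1L) %% graph$n_l) + 1L)
      bdi <- c(di[y == 1], ((nl - 1L) %/% graph$n_l) + 1L)
      by <- c(rep(1, sum(y == 1)), rep(0, n_neg))
    } else {
      bli <- li; bdi <- di; by <- y
    }
    norm <- if (dropout > 0 && nrow(pos) > 0) {
      keep_drop <- stats::runif(nrow(pos)) < dropout
      normalize_graph(mask_fold_edges(graph, pos[keep_drop, , drop = FALSE]))
    } else {
      norm_fixed
    }
    lg <- .model_loss_grad(params, norm, bli, bdi, by)
    if (!is.finite(lg$loss)) {
      stop(sprintf("training diverged: non-finite loss at epoch %d", t))
    }
    trace[t] <- lg$loss
    gflat <- .grads_to_list(lg$grads)
    for (k in names(flat)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * gflat[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * gflat[[k]]^2
      mh <- m[[k]] / (1 - b1^t)
      vh <- v[[k]] / (1 - b2^t)
      flat[[k]] <- flat[[k]] - lr * mh / (sqrt(vh) + aeps)
    }
    params <- .list_to_params(flat, params)
  }
  structure(list(params = params, loss_trace = trace,
                 config = config, seed = as.integer(seed)),
            class = "graphlda_model")
}

#' @export
print.graphlda_model <- function(x, ...) {
  cat(sprintf(
    "<graphlda_model> %d GCN layer(s), emb %d, %d encoder layer(s), %d head(s); final BCE %.4f after %d epochs\n",
    x$params$meta$gcn_layers, x$params$meta$emb, x$params$meta$enc_layers,
    x$params$meta$heads, x$loss_trace[length(x$loss_trace)],
    length(x$loss_trace)))
  invisible(x)
}

#' Predict association scores with a trained model
#'
#' @param object a `graphlda_model`.
#' @param graph the (masked) `het_graph` or `norm_graph` to score on.
#' @param pairs two-column matrix/data frame of (lncRNA index, disease index).
#' @param ... unused.
#' @return numeric vector of scores in (0, 1).
#' @export
predict.graphlda_model <- function(object, graph, pairs, ...) {
  norm <- if (inherits(graph, "norm_graph")) graph else normalize_graph(graph)
  score_pairs(object$params, norm, pairs)
}
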
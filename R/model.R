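#' @title GCN + transformer pair classifier
#' @description
#' The model encodes every node of the normalized heterogeneous graph with a
#' stack of graph-convolution layers, then classifies a candidate
#' (lncRNA, disease) pair by running the two node embeddings as a length-2
#' token sequence through a transformer encoder (multi-head scaled
#' dot-product attention, residual + layer norm, position-wise feed-forward),
#' concatenating the two output tokens and applying a sigmoid linear head.
#' Training minimizes binary cross-entropy with hand-derived analytic
#' gradients and an Adam optimizer.
#' @name graphlda-model
NULL

.relu <- function(x) pmax(x, 0)

.sigmoid <- function(x) stats::plogis(x)

# Numerically stable row-wise softmax.
.row_softmax <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

.apply_activation <- function(M, act) {
  switch(act,
         relu = .relu(M),
         softmax = .row_softmax(M),
         identity = M,
         stop(sprintf("unknown activation '%s'", act)))
}

# Backward through an activation given pre-activation M and output H.
.activation_backward <- function(dH, M, H, act) {
  switch(act,
         relu = dH * (M > 0),
         softmax = H * (dH - rowSums(dH * H)),
         identity = dH,
         stop(sprintf("unknown activation '%s'", act)))
}

.glorot <- function(fan_in, fan_out, nrow = fan_in, ncol = fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
}

#' Initialize model parameters
#'
#' Glorot-uniform fan-based initialization for all weight matrices, ones for
#' layer-norm gains and zeros for biases, fully determined by `seed`.
#'
#' @param n_t number of graph nodes (input dimension of the first GCN layer).
#' @param config a configuration list from [load_config()].
#' @param seed integer RNG seed.
#' @return a parameter list with components `gcn` (list of layer weight
#'   matrices plus activations), `enc` (list of encoder-layer parameter
#'   lists), `head` (final linear weights) and `meta` (dimensions/toggles).
#' @export
init_model <- function(n_t, config = load_config(), seed = 1L) {
  set.seed(as.integer(seed))
  emb <- config$gcn$embedding
  L <- config$gcn$layers
  heads <- config$transformer$heads
  if (emb %% heads != 0) {
    stop(sprintf("embedding size %d is not divisible by %d attention heads",
                 emb, heads))
  }
  ffn_dim <- config$transformer$ffn_mult * emb

  gcn_W <- vector("list", L)
  dims_in <- c(n_t, rep(emb, L - 1))
  for (l in seq_len(L)) gcn_W[[l]] <- .glorot(dims_in[l], emb)
  acts <- c(rep(config$gcn$hidden_activation, max(0L, L - 1L)),
            config$gcn$final_activation)

  enc <- lapply(seq_len(config$transformer$layers), function(e) {
    list(Wq = .glorot(emb, emb), Wk = .glorot(emb, emb), Wv = .glorot(emb, emb),
         W0 = .glorot(emb, emb),
         g1 = rep(1, emb), b1 = rep(0, emb),
         g2 = rep(1, emb), b2 = rep(0, emb),
         Wf1 = .glorot(emb, ffn_dim), bf1 = rep(0, ffn_dim),
         Wf2 = .glorot(ffn_dim, emb), bf2 = rep(0, emb))
  })
  head <- list(w = .glorot(2 * emb, 1), b = 0)

  list(gcn = list(W = gcn_W, activations = acts),
       enc = enc, head = head,
       meta = list(n_t = n_t, emb = emb, gcn_layers = L, heads = heads,
                   enc_layers = config$transformer$layers, ffn_dim = ffn_dim,
                   eps = config$transformer$ln_eps,
                   use_add = config$transformer$use_add,
                   use_norm = config$transformer$use_norm,
                   use_ffn = config$transformer$use_ffn,
                   clamp = config$train$clamp))
}

#' Single graph-convolution layer
#'
#' Computes `activation(X_tilde %*% H %*% W)`: multiplying by the normalized
#' propagation matrix integrates each node's neighborhood, the weight matrix
#' maps into the embedding space.
#'
#' @param X_tilde symmetric-normalized propagation matrix.
#' @param H input node features (rows are nodes).
#' @param W layer weight matrix.
#' @param activation one of `"relu"`, `"softmax"` (row-wise) or
#'   `"identity"`.
#' @return transformed node feature matrix.
#' @export
gcn_layer <- function(X_tilde, H, W, activation = "relu") {
  if (ncol(X_tilde) != nrow(H) || ncol(H) != nrow(W)) {
    stop(sprintf(
      "non-conformable shapes: X_tilde %dx%d, H %dx%d, W %dx%d",
      nrow(X_tilde), ncol(X_tilde), nrow(H), ncol(H), nrow(W), ncol(W)))
  }
  .apply_activation(X_tilde %*% H %*% W, activation)
}

#' Encode all graph nodes with the GCN stack
#'
#' @param norm a `norm_graph` from [normalize_graph()].
#' @param params model parameters from [init_model()].
#' @return embedding matrix Z with one row per node (order
#'   \[lncRNAs, diseases, miRNAs\]).
#' @export
encode_nodes <- function(norm, params) {
  .gcn_forward(norm, params)$H[[params$meta$gcn_layers + 1]]
}

# GCN forward with the caches the backward pass needs:
# H[[1]] = X_feature, P[[l]] = X_tilde %*% H[[l]], M[[l]] = preactivation.
.gcn_forward <- function(norm, params) {
  L <- params$meta$gcn_layers
  H <- vector("list", L + 1)
  P <- vector("list", L)
  M <- vector("list", L)
  H[[1]] <- norm$X_feature
  for (l in seq_len(L)) {
    P[[l]] <- norm$X_tilde %*% H[[l]]
    M[[l]] <- P[[l]] %*% params$gcn$W[[l]]
    H[[l + 1]] <- .apply_activation(M[[l]], params$gcn$activations[l])
  }
  list(H = H, P = P, M = M)
}

#' Multi-head scaled dot-product attention over a token sequence
#'
#' Each head linearly projects the tokens to queries, keys and values,
#' forms attention weights as the row-wise softmax of `Q K^T / sqrt(d_k)`,
#' and averages the values accordingly; head outputs are concatenated
#' ("spliced") and mapped by the output projection.
#'
#' @param tokens numeric matrix, one row per token.
#' @param params list with square projection matrices `Wq`, `Wk`, `Wv`,
#'   `W0` (model dim x model dim) and `n_heads`.
#' @return matrix of transformed tokens (same shape as `tokens`), with
#'   attribute `"attention"`: a list of per-head attention-weight matrices
#'   whose rows each sum to 1.
#' @export
multihead_attention <- function(tokens, params) {
  d <- ncol(tokens)
  h <- params$n_heads
  if (d %% h != 0) {
    stop(sprintf("token dimension %d is not divisible by %d heads", d, h))
  }
  dh <- d %/% h
  Q <- tokens %*% params$Wq
  K <- tokens %*% params$Wk
  V <- tokens %*% params$Wv
  out <- matrix(0, nrow(tokens), d)
  attn <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dh + 1):(i * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    A <- .row_softmax(S)
    attn[[i]] <- A
    out[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  res <- out %*% params$W0
  attr(res, "attention") <- attn
  res
}

# Row-wise layer norm with cache (xhat, istd) for the backward pass.
.layer_norm_forward <- function(X, gain, bias, eps) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- sweep(sweep(xhat, 2, gain, "*"), 2, bias, "+")
  list(out = out, xhat = xhat, istd = istd)
}

.layer_norm_backward <- function(dout, cache, gain) {
  dxhat <- sweep(dout, 2, gain, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$istd * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX,
       dgain = colSums(dout * cache$xhat),
       dbias = colSums(dout))
}

#' Residual connection followed by layer normalization
#'
#' Computes `LayerNorm(fx + x)` per token: the sublayer output is added to
#' its input and each token vector is standardized over its features before
#' a learned affine rescale.
#'
#' @param x,fx token matrices of identical shape (rows are tokens).
#' @param gain,bias layer-norm affine parameters (length = feature dim).
#' @param eps variance regularizer.
#' @return normalized token matrix.
#' @export
add_and_norm <- function(x, fx, gain = rep(1, ncol(x)),
                         bias = rep(0, ncol(x)), eps = 1e-5) {
  stopifnot(all(dim(x) == dim(fx)))
  .layer_norm_forward(fx + x, gain, bias, eps)$out
}

#' Position-wise feed-forward network
#'
#' `ReLU(x w1 + b1) w2 + b2`, applied independently to each token row.
#'
#' @param x token matrix (rows are tokens).
#' @param w1,b1 first linear map (expansion) and bias.
#' @param w2,b2 second linear map (projection) and bias.
#' @return transformed token matrix.
#' @export
feed_forward <- function(x, w1, b1, w2, b2) {
  sweep(.relu(sweep(x %*% w1, 2, b1, "+")) %*% w2, 2, b2, "+")
}

#' Binary cross-entropy loss
#'
#' Mean over the batch of `-(y log p + (1-y) log(1-p))`, with scores clamped
#' away from 0/1 before the logarithm.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 labels.
#' @param clamp clamping margin for the logarithms.
#' @return non-negative scalar loss.
#' @export
bce_loss <- function(scores, labels, clamp = 1e-7) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  p <- pmin(pmax(scores, clamp), 1 - clamp)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Score candidate (lncRNA, disease) pairs
#'
#' Runs the full forward pass: GCN node encoding, the 2-token transformer
#' encoder on each pair and the sigmoid head.
#'
#' @param params model parameters (from [init_model()] or
#'   [train_model()]`$params`).
#' @param norm a `norm_graph`.
#' @param pairs two-column matrix/data frame of (lncRNA index, disease
#'   index), 1-based within their entity classes.
#' @return numeric vector of association scores strictly inside (0, 1).
#' @export
score_pairs <- function(params, norm, pairs) {
  pairs <- .as_pair_matrix(pairs)
  if (nrow(pairs) == 0) return(numeric(0))
  if (any(pairs[, 1] < 1 | pairs[, 1] > norm$n_l) ||
      any(pairs[, 2] < 1 | pairs[, 2] > norm$n_d)) {
    stop(sprintf("pair index out of range for %d lncRNAs x %d diseases",
                 norm$n_l, norm$n_d))
  }
  .model_forward(params, norm, pairs[, 1], pairs[, 2])$p
}

# Full batched forward pass. li/di are 1-based indices into the lncRNA and
# disease classes; tokens are the pair's two node embeddings. All pair-level
# work is vectorized over the batch (seq length is fixed at 2).
.model_forward <- function(params, norm, li, di) {
  meta <- params$meta
  gcn <- .gcn_forward(norm, params)
  Z <- gcn$H[[meta$gcn_layers + 1]]
  rows_a <- li
  rows_b <- norm$n_l + di
  Ta <- Z[rows_a, , drop = FALSE]
  Tb <- Z[rows_b, , drop = FALSE]
  enc_caches <- vector("list", meta$enc_layers)
  for (e in seq_len(meta$enc_layers)) {
    fc <- .encoder_layer_forward(Ta, Tb, params$enc[[e]], meta)
    enc_caches[[e]] <- fc
    Ta <- fc$out_a
    Tb <- fc$out_b
  }
  xcat <- cbind(Ta, Tb)
  logits <- drop(xcat %*% params$head$w) + params$head$b
  p <- .sigmoid(logits)
  list(p = p, logits = logits, xcat = xcat,
       gcn = gcn, rows_a = rows_a, rows_b = rows_b,
       enc_caches = enc_caches)
}

# One encoder layer, batched over B pairs of 2-token sequences.
# For a 2-token sequence the softmax over each attention row reduces to a
# two-way split computed from the logit difference (exactly normalized).
.encoder_layer_forward <- function(Ta, Tb, lp, meta) {
  emb <- meta$emb; h <- meta$heads; dh <- emb %/% h
  Qa <- Ta %*% lp$Wq; Qb <- Tb %*% lp$Wq
  Ka <- Ta %*% lp$Wk; Kb <- Tb %*% lp$Wk
  Va <- Ta %*% lp$Wv; Vb <- Tb %*% lp$Wv
  B <- nrow(Ta)
  Oa <- matrix(0, B, emb); Ob <- matrix(0, B, emb)
  a11 <- a21 <- matrix(0, B, h)
  sc <- 1 / sqrt(dh)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dh + 1):(i * dh)
    qa <- Qa[, cols, drop = FALSE]; qb <- Qb[, cols, drop = FALSE]
    ka <- Ka[, cols, drop = FALSE]; kb <- Kb[, cols, drop = FALSE]
    va <- Va[, cols, drop = FALSE]; vb <- Vb[, cols, drop = FALSE]
    s11 <- rowSums(qa * ka) * sc; s12 <- rowSums(qa * kb) * sc
    s21 <- rowSums(qb * ka) * sc; s22 <- rowSums(qb * kb) * sc
    w11 <- .sigmoid(s11 - s12)   # softmax over {s11, s12}
    w21 <- .sigmoid(s21 - s22)
    a11[, i] <- w11; a21[, i] <- w21
    Oa[, cols] <- w11 * va + (1 - w11) * vb
    Ob[, cols] <- w21 * va + (1 - w21) * vb
  }
  Ma <- Oa %*% lp$W0; Mb <- Ob %*% lp$W0
  R1a <- if (meta$use_add) Ta + Ma else Ma
  R1b <- if (meta$use_add) Tb + Mb else Mb
  if (meta$use_norm) {
    ln1a <- .layer_norm_forward(R1a, lp$g1, lp$b1, meta$eps)
    ln1b <- .layer_norm_forward(R1b, lp$g1, lp$b1, meta$eps)
    Ua <- ln1a$out; Ub <- ln1b$out
  } else {
    ln1a <- ln1b <- NULL
    Ua <- R1a; Ub <- R1b
  }
  if (meta$use_ffn) {
    pre_a <- sweep(Ua %*% lp$Wf1, 2, lp$bf1, "+")
    pre_b <- sweep(Ub %*% lp$Wf1, 2, lp$bf1, "+")
    hid_a <- .relu(pre_a); hid_b <- .relu(pre_b)
    Fa <- sweep(hid_a %*% lp$Wf2, 2, lp$bf2, "+")
    Fb <- sweep(hid_b %*% lp$Wf2, 2, lp$bf2, "+")
    R2a <- if (meta$use_add) Ua + Fa else Fa
    R2b <- if (meta$use_add) Ub + Fb else Fb
    if (meta$use_norm) {
      ln2a <- .layer_norm_forward(R2a, lp$g2, lp$b2, meta$eps)
      ln2b <- .layer_norm_forward(R2b, lp$g2, lp$b2, meta$eps)
      out_a <- ln2a$out; out_b <- ln2b$out
    } else {
      ln2a <- ln2b <- NULL
      out_a <- R2a; out_b <- R2b
    }
  } else {
    pre_a <- pre_b <- hid_a <- hid_b <- NULL
    ln2a <- ln2b <- NULL
    out_a <- Ua; out_b <- Ub
  }
  list(Ta = Ta, Tb = Tb, Qa = Qa, Qb = Qb, Ka = Ka, Kb = Kb,
       Va = Va, Vb = Vb, a11 = a11, a21 = a21, Oa = Oa, Ob = Ob,
       ln1a = ln1a, ln1b = ln1b, Ua = Ua, Ub = Ub,
       pre_a = pre_a, pre_b = pre_b, hid_a = hid_a, hid_b = hid_b,
       ln2a = ln2a, ln2b = ln2b, out_a = out_a, out_b = out_b)
}
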
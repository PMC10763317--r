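# A 4-node toy setup used by the mechanics and gradient tests:
# 2 lncRNAs, 1 disease, 1 miRNA with a couple of edges.
toy_norm <- function() {
  S1 <- diag(2); S2 <- matrix(1, 1, 1); S3 <- matrix(1, 1, 1)
  Z_ld <- matrix(c(1, 0), 2, 1)
  Z_lm <- matrix(c(0, 1), 2, 1)
  Z_md <- matrix(1, 1, 1)
  normalize_graph(assemble_adjacency(S1, S2, S3, Z_ld, Z_lm, Z_md))
}

toy_config <- function(...) {
  load_config(overrides = utils::modifyList(
    list(gcn = list(embedding = 4L),
         transformer = list(heads = 2L, layers = 1L, ffn_mult = 2L)),
    list(...)))
}

test_that("gcn layer computes activation(X_tilde H W)", {
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_layer(diag(4), H, diag(3), "identity"), H)

  out <- gcn_layer(diag(4), H, diag(3), "softmax")
  expect_equal(rowSums(out), rep(1, 4))

  Xt <- matrix(0.5, 2, 2)
  expect_equal(gcn_layer(Xt, diag(2), diag(2), "identity"),
               matrix(0.5, 2, 2))
  expect_error(gcn_layer(diag(3), H, diag(3), "identity"),
               "non-conformable")
})

test_that("node encoding is deterministic with the expected shape", {
  norm <- toy_norm()
  params <- init_model(norm$n_t, toy_config(), seed = 3)
  Z1 <- encode_nodes(norm, params)
  Z2 <- encode_nodes(norm, params)
  expect_identical(Z1, Z2)
  expect_equal(dim(Z1), c(norm$n_t, 4L))
  expect_true(all(is.finite(Z1)))

  # one layer reduces to a single gcn_layer call
  cfg1 <- toy_config(gcn = list(layers = 1L, embedding = 4L,
                                final_activation = "identity"))
  p1 <- init_model(norm$n_t, cfg1, seed = 3)
  expect_equal(encode_nodes(norm, p1),
               gcn_layer(norm$X_tilde, norm$X_feature, p1$gcn$W[[1]],
                         "identity"))
})

test_that("multi-head attention weights are row-stochastic", {
  set.seed(1)
  d <- 8
  ap <- list(Wq = matrix(rnorm(d * d, sd = 0.3), d),
             Wk = matrix(rnorm(d * d, sd = 0.3), d),
             Wv = matrix(rnorm(d * d, sd = 0.3), d),
             W0 = matrix(rnorm(d * d, sd = 0.3), d),
             n_heads = 2L)
  tokens <- matrix(rnorm(5 * d), 5, d)
  out <- multihead_attention(tokens, ap)
  expect_equal(dim(out), dim(tokens))
  for (A in attr(out, "attention")) {
    expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)
  }

  # identical query rows give uniform weights: output tokens all equal
  same <- matrix(rep(rnorm(d), 4), 4, d, byrow = TRUE)
  out_same <- multihead_attention(same, ap)
  for (A in attr(out_same, "attention")) {
    expect_equal(A, matrix(0.25, 4, 4))
  }

  # sequence length 1: output = value projection of the single token
  one <- matrix(rnorm(d), 1, d)
  out_one <- multihead_attention(one, ap)
  expect_equal(out_one, (one %*% ap$Wv) %*% ap$W0, ignore_attr = TRUE)

  expect_error(multihead_attention(matrix(0, 2, 6),
                                   utils::modifyList(ap, list(n_heads = 4L))),
               "divisible")
})

test_that("batched 2-token attention agrees with the generic operator", {
  norm <- toy_norm()
  cfg <- toy_config()
  params <- init_model(norm$n_t, cfg, seed = 8)
  li <- c(1L, 2L, 1L); di <- c(1L, 1L, 1L)
  fw <- graphlda:::.model_forward(params, norm, li, di)
  Z <- encode_nodes(norm, params)
  lp <- params$enc[[1]]
  for (r in seq_along(li)) {
    tokens <- rbind(Z[li[r], ], Z[norm$n_l + di[r], ])
    generic <- multihead_attention(tokens,
                                   list(Wq = lp$Wq, Wk = lp$Wk, Wv = lp$Wv,
                                        W0 = lp$W0,
                                        n_heads = params$meta$heads))
    cache <- fw$enc_caches[[1]]
    batched <- rbind(cache$Oa[r, ] %*% lp$W0, cache$Ob[r, ] %*% lp$W0)
    expect_equal(unname(batched), unname(generic[1:2, , drop = FALSE]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("add-and-norm standardizes each token before the affine map", {
  set.seed(2)
  x <- matrix(rnorm(6 * 5), 6, 5)
  ln <- add_and_norm(x, 0 * x, eps = 1e-8)
  expect_equal(unname(rowMeans(ln)), rep(0, 6), tolerance = 1e-6)
  expect_equal(apply(ln, 1, function(r) mean(r^2)), rep(1, 6),
               tolerance = 1e-3)

  # a constant token collapses to ~0 under the epsilon-regularized variance
  const <- matrix(3, 1, 5)
  expect_equal(unname(add_and_norm(const, 0 * const)), matrix(0, 1, 5),
               tolerance = 1e-6)
})

test_that("feed-forward applies ReLU between the two affine maps", {
  expect_equal(feed_forward(matrix(c(-1, -2), 1), diag(2), c(0, 0),
                            diag(2), c(0, 0)),
               matrix(0, 1, 2))
  x <- matrix(c(0.5, 2), 1)
  expect_equal(feed_forward(x, diag(2), c(0, 0), diag(2), c(0, 0)), x)
  expect_equal(feed_forward(matrix(c(1, -1), 1), diag(2), c(0, 2),
                            diag(2), c(0, 0)),
               matrix(c(1, 1), 1))
})

test_that("pair scores are valid probabilities and permutation-equivariant", {
  norm <- toy_norm()
  params <- init_model(norm$n_t, toy_config(), seed = 4)
  pairs <- cbind(c(1, 2, 1, 2), c(1, 1, 1, 1))
  s <- score_pairs(params, norm, pairs)
  expect_true(all(s > 0 & s < 1))
  perm <- c(3, 1, 4, 2)
  expect_equal(score_pairs(params, norm, pairs[perm, ]), s[perm])
  expect_error(score_pairs(params, norm, cbind(5, 1)), "out of range")
})

test_that("binary cross-entropy evaluates its closed form", {
  expect_lt(bce_loss(1 - 1e-9, 1), 1e-6)
  expect_equal(bce_loss(0.5, 0), -log(0.5))
  s <- c(0.9, 0.2, 0.6); y <- c(1, 0, 1)
  expect_equal(bce_loss(s, y), bce_loss(1 - s, 1 - y))
  expect_true(is.finite(bce_loss(c(0, 1), c(0, 1))))  # clamp guards the log
  expect_error(bce_loss(0.5, 2), "binary")
})

test_that("attention rows sum to one at every layer of every forward pass", {
  norm <- toy_norm()
  cfg <- toy_config(transformer = list(layers = 2L, heads = 2L,
                                       ffn_mult = 2L))
  params <- init_model(norm$n_t, cfg, seed = 10)
  fw <- graphlda:::.model_forward(params, norm, c(1L, 2L), c(1L, 1L))
  for (cache in fw$enc_caches) {
    expect_true(all(cache$a11 >= 0 & cache$a11 <= 1))
    expect_true(all(cache$a21 >= 0 & cache$a21 <= 1))
    # the complementary weight is 1 - a by construction: rows sum exactly
    expect_equal(cache$a11 + (1 - cache$a11),
                 matrix(1, nrow(cache$a11), ncol(cache$a11)))
  }
})

test_that("analytic gradients match central finite differences", {
  norm <- toy_norm()
  cfg <- toy_config(gcn = list(embedding = 4L,
                               final_activation = "identity"))
  params <- init_model(norm$n_t, cfg, seed = 11)
  # scale parameters up so gradient magnitudes are well above FD noise
  flat <- graphlda:::.params_to_list(params)
  set.seed(99)
  for (k in names(flat)) flat[[k]] <- flat[[k]] * 3
  params <- graphlda:::.list_to_params(flat, params)

  li <- c(1L, 2L, 1L, 2L); di <- c(1L, 1L, 1L, 1L); y <- c(1, 0, 0, 1)
  lg <- graphlda:::.model_loss_grad(params, norm, li, di, y)
  gflat <- graphlda:::.grads_to_list(lg$grads)
  loss_at <- function(fl) {
    graphlda:::.model_loss_grad(graphlda:::.list_to_params(fl, params),
                                norm, li, di, y)$loss
  }
  h <- 1e-5
  worst <- 0
  for (k in names(flat)) {
    idx <- sample(length(flat[[k]]), min(4, length(flat[[k]])))
    for (i in idx) {
      fp <- flat; fp[[k]][i] <- fp[[k]][i] + h
      fm <- flat; fm[[k]][i] <- fm[[k]][i] - h
      num <- (loss_at(fp) - loss_at(fm)) / (2 * h)
      ana <- gflat[[k]][i]
      rel <- abs(num - ana) / max(abs(num) + abs(ana), 1e-4)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})
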
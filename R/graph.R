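#' Assemble the heterogeneous block adjacency matrix
#'
#' Stacks the three intraclass similarity blocks (lncRNA-lncRNA,
#' disease-disease, miRNA-miRNA) and the three binary interclass association
#' blocks into one symmetric adjacency matrix over all nodes, in the fixed
#' row/column order \[lncRNAs, diseases, miRNAs\]:
#' \preformatted{
#'   [ S_ll    Z_ld    Z_lm  ]
#'   [ Z_ld^T  S_dd    Z_md^T]
#'   [ Z_lm^T  Z_md    S_mm  ]
#' }
#'
#' @param S_ll,S_dd,S_mm square similarity matrices (symmetric, unit
#'   diagonal, entries in \[0,1\]).
#' @param Z_ld binary lncRNA x disease association matrix.
#' @param Z_lm binary lncRNA x miRNA association matrix.
#' @param Z_md binary miRNA x disease association matrix.
#' @param lnc_ids,dis_ids,mir_ids optional entity id vectors; default to the
#'   dimnames of the blocks or generated ids.
#' @return an object of class `het_graph`: the blocks, the id vectors, the
#'   counts `n_l`, `n_d`, `n_m`, `n_t`, and the assembled matrix `X`.
#' @export
assemble_adjacency <- function(S_ll, S_dd, S_mm, Z_ld, Z_lm, Z_md,
                               lnc_ids = NULL, dis_ids = NULL, mir_ids = NULL) {
  .check_similarity_matrix(S_ll, "S_ll")
  .check_similarity_matrix(S_dd, "S_dd")
  .check_similarity_matrix(S_mm, "S_mm")
  n_l <- nrow(S_ll); n_d <- nrow(S_dd); n_m <- nrow(S_mm)
  .check_block_dim(Z_ld, n_l, n_d, "Z_ld (lncRNA x disease)")
  .check_block_dim(Z_lm, n_l, n_m, "Z_lm (lncRNA x miRNA)")
  .check_block_dim(Z_md, n_m, n_d, "Z_md (miRNA x disease)")

  lnc_ids <- .resolve_ids(lnc_ids, rownames(S_ll), n_l, "L")
  dis_ids <- .resolve_ids(dis_ids, rownames(S_dd), n_d, "D")
  mir_ids <- .resolve_ids(mir_ids, rownames(S_mm), n_m, "M")

  n_t <- n_l + n_d + n_m
  X <- matrix(0, n_t, n_t)
  il <- seq_len(n_l); id <- n_l + seq_len(n_d); im <- n_l + n_d + seq_len(n_m)
  X[il, il] <- S_ll;     X[il, id] <- Z_ld;     X[il, im] <- Z_lm
  X[id, il] <- t(Z_ld);  X[id, id] <- S_dd;     X[id, im] <- t(Z_md)
  X[im, il] <- t(Z_lm);  X[im, id] <- Z_md;     X[im, im] <- S_mm
  node_ids <- c(lnc_ids, dis_ids, mir_ids)
  dimnames(X) <- list(node_ids, node_ids)

  structure(
    list(lnc_ids = lnc_ids, dis_ids = dis_ids, mir_ids = mir_ids,
         n_l = n_l, n_d = n_d, n_m = n_m, n_t = n_t,
         S_ll = S_ll, S_dd = S_dd, S_mm = S_mm,
         Z_ld = Z_ld, Z_lm = Z_lm, Z_md = Z_md,
         X = X),
    class = "het_graph"
  )
}

.check_block_dim <- function(Z, nr, nc, name) {
  if (!is.matrix(Z) || nrow(Z) != nr || ncol(Z) != nc) {
    stop(sprintf("%s must be %d x %d, got %d x %d", name, nr, nc,
                 if (is.matrix(Z)) nrow(Z) else length(Z),
                 if (is.matrix(Z)) ncol(Z) else 1L))
  }
  if (!all(Z %in% c(0, 1))) {
    stop(sprintf("%s must be binary (0/1 entries only)", name))
  }
  invisible(Z)
}

.resolve_ids <- function(ids, dn, n, prefix) {
  if (!is.null(ids)) {
    if (length(ids) != n) stop(sprintf("expected %d ids, got %d", n, length(ids)))
    return(as.character(ids))
  }
  if (!is.null(dn)) return(dn)
  sprintf("%s%03d", prefix, seq_len(n))
}

#' @export
print.het_graph <- function(x, ...) {
  cat(sprintf("<het_graph> %d lncRNAs + %d diseases + %d miRNAs = %d nodes; %d known LDAs\n",
              x$n_l, x$n_d, x$n_m, x$n_t, sum(x$Z_ld)))
  invisible(x)
}

#' Row-normalized feature matrix
#'
#' Divides every row of the assembled adjacency matrix by its sum so each
#' node's feature vector is its normalized connection profile. All-zero rows
#' (isolated nodes) are left as zeros.
#'
#' @param g a `het_graph` (or a bare square matrix).
#' @return matrix of the same shape whose nonzero rows sum to 1.
#' @export
build_feature_matrix <- function(g) {
  X <- if (inherits(g, "het_graph")) g$X else g
  rs <- rowSums(X)
  pos <- rs > 0
  X[pos, ] <- X[pos, , drop = FALSE] / rs[pos]
  X
}

#' Add self-connections
#'
#' @param X square adjacency matrix.
#' @return `X + I` (a diagonal already equal to 1 becomes 2; the identity is
#'   added unconditionally).
#' @export
add_self_loops <- function(X) {
  if (!is.matrix(X) || nrow(X) != ncol(X)) stop("X must be a square matrix")
  X + diag(nrow(X))
}

#' Symmetric Laplacian normalization
#'
#' Computes the degree of each node of the self-connected adjacency matrix
#' and rescales it as `E^{-1/2} X_hat E^{-1/2}`, the propagation operator of
#' the graph convolutional encoder.
#'
#' @param X_hat non-negative square matrix with strictly positive row sums
#'   (guaranteed after [add_self_loops()]).
#' @return list with `degree` (numeric vector) and `X_tilde` (normalized
#'   matrix, symmetric whenever `X_hat` is).
#' @export
symmetric_normalize <- function(X_hat) {
  if (!is.matrix(X_hat) || nrow(X_hat) != ncol(X_hat)) {
    stop("X_hat must be a square matrix")
  }
  if (any(X_hat < 0)) stop("X_hat must be non-negative")
  degree <- rowSums(X_hat)
  if (any(degree <= 0)) {
    stop("internal error: zero degree row after self-loops")
  }
  inv_sqrt <- 1 / sqrt(degree)
  X_tilde <- X_hat * tcrossprod(inv_sqrt)
  list(degree = degree, X_tilde = X_tilde)
}

#' Normalize a heterogeneous graph for the GCN encoder
#'
#' Bundles the feature matrix (row-normalized adjacency, without
#' self-loops), the self-connected adjacency, its degree vector and the
#' symmetrically normalized propagation matrix.
#'
#' @param g a `het_graph`.
#' @return object of class `norm_graph` with `X_feature`, `X_hat`, `degree`,
#'   `X_tilde`, `n_t` and the entity counts/ids carried over.
#' @export
normalize_graph <- function(g) {
  stopifnot(inherits(g, "het_graph"))
  X_feature <- build_feature_matrix(g)
  X_hat <- add_self_loops(g$X)
  norm <- symmetric_normalize(X_hat)
  structure(
    list(X_feature = X_feature, X_hat = X_hat,
         degree = norm$degree, X_tilde = norm$X_tilde,
         n_l = g$n_l, n_d = g$n_d, n_m = g$n_m, n_t = g$n_t,
         lnc_ids = g$lnc_ids, dis_ids = g$dis_ids, mir_ids = g$mir_ids),
    class = "norm_graph"
  )
}

#' Mask held-out lncRNA-disease edges out of the graph
#'
#' Returns a copy of the graph whose lncRNA-disease association block has
#' the given pairs set to 0 (both symmetric positions of the assembled
#' matrix), so that validation/test positives cannot leak into training.
#' All other blocks are untouched.
#'
#' @param g a `het_graph`.
#' @param held_out_pairs two-column matrix or data frame of 1-based
#'   (lncRNA index, disease index) pairs; may have zero rows.
#' @return a `het_graph` with the masked block.
#' @export
mask_fold_edges <- function(g, held_out_pairs) {
  stopifnot(inherits(g, "het_graph"))
  pairs <- .as_pair_matrix(held_out_pairs)
  if (nrow(pairs) == 0) return(g)
  if (any(pairs[, 1] < 1 | pairs[, 1] > g$n_l) ||
      any(pairs[, 2] < 1 | pairs[, 2] > g$n_d)) {
    stop(sprintf("pair index out of range for %d lncRNAs x %d diseases",
                 g$n_l, g$n_d))
  }
  g$Z_ld[pairs] <- 0
  g$X[cbind(pairs[, 1], g$n_l + pairs[, 2])] <- 0  # (lnc row, dis col)
  g$X[cbind(g$n_l + pairs[, 2], pairs[, 1])] <- 0  # mirrored position
  g
}

# X indices: the lnc rows are 1..n_l and disease columns are n_l + j,
# so the (lnc, dis) positions in X are exactly cbind(i, n_l + j).
.as_pair_matrix <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (is.null(pairs) || length(pairs) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  if (!is.matrix(pairs) || ncol(pairs) < 2) {
    stop("pairs must be a two-column matrix or data frame")
  }
  storage.mode(pairs) <- "integer"
  pairs[, 1:2, drop = FALSE]
}
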
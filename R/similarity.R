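#' Semantic contribution profile of a disease term
#'
#' Every term in the ancestor closure of `target` contributes to the
#' semantics of `target`: the target itself contributes 1, and each ancestor
#' contributes `delta` times the largest contribution among its children
#' that also lie in the closure (contributions decay multiplicatively along
#' the best root-ward path). The semantic value DV is the sum of all
#' contributions.
#'
#' @param ontology a [disease_ontology()].
#' @param target term id whose profile is computed.
#' @param delta semantic decay factor in (0, 1); conventionally 0.5.
#' @return an object of class `semantic_profile`: list with `target`,
#'   `delta`, `contributions` (named numeric over the closure) and `dv`.
#' @export
semantic_contributions <- function(ontology, target, delta = 0.5) {
  stopifnot(inherits(ontology, "disease_ontology"))
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1) {
    stop(sprintf("delta must lie strictly in (0, 1), got %s", format(delta)))
  }
  closure <- ancestor_closure(ontology, target)
  contrib <- stats::setNames(numeric(length(closure)), closure)
  # Reversed topological order puts children before their parents, so each
  # ancestor sees its relevant children already resolved.
  order_rev <- rev(ontology$topo_order)
  order_rev <- order_rev[order_rev %in% closure]
  for (d in order_rev) {
    if (d == target) {
      contrib[[d]] <- 1
    } else {
      kids <- intersect(ontology$children[[d]], closure)
      contrib[[d]] <- delta * max(contrib[kids])
    }
  }
  structure(
    list(target = target, delta = delta, contributions = contrib,
         dv = sum(contrib)),
    class = "semantic_profile"
  )
}

#' Disease semantic similarity between two profiles
#'
#' The similarity of two diseases is the summed contribution, from both
#' sides, of the terms their ancestor closures share, normalized by the sum
#' of the two semantic values:
#' \deqn{DS(d_i, d_j) = \frac{\sum_{t \in Col(d_i) \cap Col(d_j)}
#'   (D_{d_i}(t) + D_{d_j}(t))}{DV(d_i) + DV(d_j)}}
#' It is symmetric, lies in \[0, 1\], and equals 1 for identical diseases.
#'
#' @param p1,p2 objects from [semantic_contributions()] built on the same
#'   ontology with the same `delta`.
#' @return a single similarity score in \[0, 1\].
#' @export
disease_semantic_similarity <- function(p1, p2) {
  stopifnot(inherits(p1, "semantic_profile"), inherits(p2, "semantic_profile"))
  if (!isTRUE(all.equal(p1$delta, p2$delta))) {
    stop(sprintf("profiles use different decay factors (%g vs %g)",
                 p1$delta, p2$delta))
  }
  shared <- intersect(names(p1$contributions), names(p2$contributions))
  if (length(shared) == 0) return(0)
  sum(p1$contributions[shared] + p2$contributions[shared]) / (p1$dv + p2$dv)
}

#' Pairwise disease semantic similarity matrix
#'
#' @param ontology a [disease_ontology()].
#' @param disease_ids ordered character vector of term ids (no duplicates);
#'   every id must be present in the ontology.
#' @param delta semantic decay factor in (0, 1).
#' @return symmetric numeric matrix with unit diagonal, dimnames set to
#'   `disease_ids`.
#' @export
disease_similarity_matrix <- function(ontology, disease_ids, delta = 0.5) {
  if (anyDuplicated(disease_ids)) {
    stop(sprintf("duplicate disease ids: %s",
                 paste(unique(disease_ids[duplicated(disease_ids)]), collapse = ", ")))
  }
  missing <- setdiff(disease_ids, ontology$terms)
  if (length(missing) > 0) {
    stop(sprintf("disease ids absent from ontology: %s",
                 paste(missing, collapse = ", ")))
  }
  profiles <- lapply(disease_ids, semantic_contributions,
                     ontology = ontology, delta = delta)
  n <- length(disease_ids)
  S <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- disease_semantic_similarity(profiles[[i]], profiles[[j]])
        S[i, j] <- s
        S[j, i] <- s
      }
    }
  }
  dimnames(S) <- list(disease_ids, disease_ids)
  S
}

#' Functional similarity between two entities from their disease sets
#'
#' Best-match averaging: each disease of one entity is matched to its most
#' semantically similar disease of the other entity, and the matched scores
#' from both directions are averaged over the total number of diseases
#' (p + q). If either set is empty the similarity is defined as 0.
#'
#' @param diseases1,diseases2 character vectors of disease ids.
#' @param ds square similarity matrix with dimnames covering all ids (e.g.
#'   from [disease_similarity_matrix()]).
#' @return a single similarity score in \[0, 1\].
#' @export
functional_similarity <- function(diseases1, diseases2, ds) {
  diseases1 <- unique(diseases1)
  diseases2 <- unique(diseases2)
  if (length(diseases1) == 0 || length(diseases2) == 0) return(0)
  missing <- setdiff(c(diseases1, diseases2), rownames(ds))
  if (length(missing) > 0) {
    stop(sprintf("disease ids absent from similarity matrix: %s",
                 paste(missing, collapse = ", ")))
  }
  sub <- ds[diseases1, diseases2, drop = FALSE]
  (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) /
    (length(diseases1) + length(diseases2))
}

#' Pairwise functional similarity matrix for a set of entities
#'
#' @param entity_disease_map named list: entity id -> character vector of
#'   associated disease ids (possibly empty).
#' @param ds disease similarity matrix with dimnames.
#' @return symmetric numeric matrix with unit diagonal, one row per entity
#'   in the order of `entity_disease_map`. Entities with empty disease sets
#'   get off-diagonal zeros.
#' @export
functional_similarity_matrix <- function(entity_disease_map, ds) {
  ids <- names(entity_disease_map)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("entity_disease_map must be a uniquely named list")
  }
  n <- length(ids)
  S <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- functional_similarity(entity_disease_map[[i]],
                                   entity_disease_map[[j]], ds)
        S[i, j] <- s
        S[j, i] <- s
      }
    }
  }
  dimnames(S) <- list(ids, ids)
  S
}

# Invariant guard used when similarity blocks enter the graph builder.
.check_similarity_matrix <- function(S, name = "similarity matrix") {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop(sprintf("%s must be square", name))
  }
  if (any(!is.finite(S)) || any(S < -1e-12) || any(S > 1 + 1e-12)) {
    stop(sprintf("%s entries must lie in [0, 1]", name))
  }
  if (max(abs(S - t(S))) > 1e-9) stop(sprintf("%s must be symmetric", name))
  if (max(abs(diag(S) - 1)) > 1e-9) {
    stop(sprintf("%s must have a unit diagonal", name))
  }
  invisible(S)
}
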
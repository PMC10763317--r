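#' Specification for a synthetic benchmark
#'
#' Defines the size and planted structure of a generated dataset: entity
#' counts, ontology shape and a latent block model. Each of the `n_groups`
#' groups couples a branch of the ontology (diseases) with a share of the
#' lncRNAs and miRNAs; associations appear with probability `p_in` inside a
#' matched group and `p_out` otherwise, so the planted structure is
#' learnable whenever `p_in > p_out` and absent when they coincide.
#'
#' @param n_lnc,n_dis,n_mir entity counts.
#' @param n_terms number of ontology terms (must be >= `n_dis` + 1 so every
#'   disease maps to a non-root term).
#' @param max_parents maximum number of parents per non-root term.
#' @param depth maximum ontology depth below the root.
#' @param n_groups number of latent groups.
#' @param p_in,p_out association probabilities within/between groups;
#'   requires `0 <= p_out <= p_in <= 1`.
#' @param seed master RNG seed; every generated artifact derives its own
#'   stream from it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lnc, n_dis, n_mir, n_terms = 2 * n_dis,
                           max_parents = 2L, depth = 4L, n_groups = 4L,
                           p_in = 0.3, p_out = 0.02, seed = 7L) {
  stopifnot(n_lnc > 0, n_dis > 0, n_mir > 0, n_groups >= 1,
            depth >= 1, max_parents >= 1)
  if (!(p_out <= p_in && p_in <= 1 && p_out >= 0)) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  if (n_terms < n_dis + 1) stop("n_terms must be at least n_dis + 1")
  if (n_terms < n_groups + 1) stop("n_terms must exceed n_groups")
  structure(list(n_lnc = as.integer(n_lnc), n_dis = as.integer(n_dis),
                 n_mir = as.integer(n_mir), n_terms = as.integer(n_terms),
                 max_parents = as.integer(max_parents),
                 depth = as.integer(depth), n_groups = as.integer(n_groups),
                 p_in = p_in, p_out = p_out, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Named benchmark presets
#'
#' `"small"` is the default benchmark: 60 lncRNAs, 40 diseases, 50 miRNAs,
#' 4 planted groups, within/between association probabilities 0.3/0.02 —
#' small enough that the full CV protocol runs in minutes on one CPU while
#' keeping the planted structure clearly recoverable. `"tiny"` is a
#' smoke-test size. `"null"` is `"small"` with `p_in = p_out = 0.1`
#' (no structure, chance-level benchmark).
#'
#' @param name preset name.
#' @param seed master seed (default 7).
#' @return a [synthetic_spec()].
#' @export
synthetic_preset <- function(name = c("small", "tiny", "null"), seed = 7L) {
  name <- match.arg(name)
  switch(name,
    small = synthetic_spec(60, 40, 50, n_terms = 80, n_groups = 4,
                           p_in = 0.3, p_out = 0.02, seed = seed),
    tiny = synthetic_spec(12, 10, 8, n_terms = 24, n_groups = 2,
                          p_in = 0.5, p_out = 0.05, seed = seed),
    null = synthetic_spec(60, 40, 50, n_terms = 80, n_groups = 4,
                          p_in = 0.1, p_out = 0.1, seed = seed))
}

# One derived stream per artifact so files stay independent of the order in
# which they are generated.
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Generate a random rooted ontology DAG
#'
#' Builds a rooted DAG with `n_groups` top-level branches. Each non-root
#' term is assigned to a branch and a depth; its first parent is a
#' shallower term of the same branch (the branch root at depth 1), and up
#' to `max_parents - 1` extra same-branch parents may be added. Keeping
#' parents within a branch makes the branches genuine subtrees, so disease
#' groups carry real semantic-similarity signal.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `ontology` (a [disease_ontology()]), `term_branch`
#'   (named integer vector, 0 for the root), and `branch_roots`.
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(.sub_seed(spec$seed, 1L))
  terms <- sprintf("T%03d", seq_len(spec$n_terms))
  root <- terms[1]
  g <- spec$n_groups
  branch_roots <- terms[1 + seq_len(g)]
  term_branch <- stats::setNames(integer(spec$n_terms), terms)
  term_branch[branch_roots] <- seq_len(g)
  term_depth <- stats::setNames(rep(0L, spec$n_terms), terms)
  term_depth[branch_roots] <- 1L

  edges <- data.frame(parent = root, child = branch_roots)
  rest <- terms[-(1:(g + 1))]
  if (length(rest) > 0) {
    term_branch[rest] <- rep_len(seq_len(g), length(rest))
    for (t in rest) {
      b <- term_branch[[t]]
      members <- names(term_branch)[term_branch == b & term_depth > 0]
      members <- members[members != t & term_depth[members] < spec$depth]
      if (length(members) == 0) members <- branch_roots[b]
      # first parent: any already-placed, shallower-than-max member
      p1 <- if (length(members) == 1) members else sample(members, 1)
      term_depth[[t]] <- term_depth[[p1]] + 1L
      parents <- p1
      extra_pool <- members[members != p1 & term_depth[members] < term_depth[[t]]]
      n_extra <- sample(0:(spec$max_parents - 1L), 1)
      if (n_extra > 0 && length(extra_pool) > 0) {
        n_extra <- min(n_extra, length(extra_pool))
        parents <- c(parents, if (length(extra_pool) == 1) extra_pool
                     else sample(extra_pool, n_extra))
      }
      edges <- rbind(edges, data.frame(parent = parents, child = t))
    }
  }
  onto <- disease_ontology(edges, terms = terms)
  list(ontology = onto, term_branch = term_branch,
       branch_roots = branch_roots)
}

#' Generate planted-block heterogeneous associations
#'
#' Diseases are mapped to non-root ontology terms (balanced across
#' branches; the disease's group is its branch), and lncRNAs/miRNAs are
#' assigned uniformly to groups. Every interclass pair is then associated
#' independently with probability `p_in` when the two groups match and
#' `p_out` otherwise.
#'
#' @param spec a [synthetic_spec()].
#' @param onto_info output of [generate_ontology()].
#' @return list with binary matrices `Z_ld`, `Z_lm`, `Z_md` (dimnames set
#'   to entity ids; disease ids are ontology term ids), and `groups` (list
#'   of named integer vectors `lnc`, `dis`, `mir`).
#' @export
generate_heterogeneous_associations <- function(spec, onto_info) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(.sub_seed(spec$seed, 2L))
  tb <- onto_info$term_branch
  non_root <- names(tb)[tb > 0]
  # balanced pick of disease terms across branches
  by_branch <- split(non_root, tb[non_root])
  quota <- rep(spec$n_dis %/% spec$n_groups, spec$n_groups)
  extra <- spec$n_dis - sum(quota)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  dis_ids <- unlist(lapply(seq_len(spec$n_groups), function(b) {
    pool <- by_branch[[as.character(b)]]
    if (length(pool) < quota[b]) {
      stop(sprintf("branch %d has %d terms but needs %d diseases",
                   b, length(pool), quota[b]))
    }
    sort(sample(pool, quota[b]))
  }), use.names = FALSE)

  lnc_ids <- sprintf("L%03d", seq_len(spec$n_lnc))
  mir_ids <- sprintf("M%03d", seq_len(spec$n_mir))
  grp_l <- stats::setNames(sample(rep_len(seq_len(spec$n_groups), spec$n_lnc)),
                           lnc_ids)
  grp_d <- stats::setNames(as.integer(tb[dis_ids]), dis_ids)
  grp_m <- stats::setNames(sample(rep_len(seq_len(spec$n_groups), spec$n_mir)),
                           mir_ids)

  bern_block <- function(ga, gb, ids_a, ids_b) {
    p <- ifelse(outer(ga, gb, "=="), spec$p_in, spec$p_out)
    Z <- matrix(as.numeric(stats::runif(length(p)) < p), nrow(p), ncol(p))
    dimnames(Z) <- list(ids_a, ids_b)
    Z
  }
  Z_ld <- bern_block(grp_l, grp_d, lnc_ids, dis_ids)
  Z_lm <- bern_block(grp_l, grp_m, lnc_ids, mir_ids)
  Z_md <- bern_block(grp_m, grp_d, mir_ids, dis_ids)
  list(Z_ld = Z_ld, Z_lm = Z_lm, Z_md = Z_md,
       groups = list(lnc = grp_l, dis = grp_d, mir = grp_m))
}

#' Generate a complete on-disk benchmark dataset
#'
#' Writes the ontology, the entity id lists, the three association edge
#' lists, the truth group assignments and a JSON manifest (spec + seed)
#' into `dir`, in exactly the formats the package's readers consume.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if absent).
#' @return (invisibly) list with the in-memory objects (`ontology`,
#'   `onto_info`, `assoc`, `index`) and `dir`.
#' @export
generate_benchmark <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create output directory %s", dir))
  onto_info <- generate_ontology(spec)
  assoc <- generate_heterogeneous_associations(spec, onto_info)
  idx <- entity_index(lnc_ids = rownames(assoc$Z_ld),
                      dis_ids = colnames(assoc$Z_ld),
                      mir_ids = rownames(assoc$Z_md))

  write_ontology(onto_info$ontology, file.path(dir, "ontology.tsv"))
  writeLines(idx$lnc_ids, file.path(dir, "lnc_ids.txt"))
  writeLines(idx$dis_ids, file.path(dir, "dis_ids.txt"))
  writeLines(idx$mir_ids, file.path(dir, "mir_ids.txt"))
  write_edge_list(assoc$Z_ld, file.path(dir, "lnc_disease.tsv"))
  write_edge_list(assoc$Z_lm, file.path(dir, "lnc_mirna.tsv"))
  write_edge_list(assoc$Z_md, file.path(dir, "mirna_disease.tsv"))
  groups_df <- data.frame(
    entity = c(names(assoc$groups$lnc), names(assoc$groups$dis),
               names(assoc$groups$mir)),
    class = rep(c("lncRNA", "disease", "miRNA"),
                c(spec$n_lnc, spec$n_dis, spec$n_mir)),
    group = c(assoc$groups$lnc, assoc$groups$dis, assoc$groups$mir))
  utils::write.table(groups_df, file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(generator = "graphlda synthetic benchmark",
                   spec = unclass(spec), seed = spec$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(ontology = onto_info$ontology, onto_info = onto_info,
                 assoc = assoc, index = idx, dir = dir))
}

#' Load a benchmark dataset from disk
#'
#' @param dir a directory written by [generate_benchmark()].
#' @return list with `ontology`, `index`, `Z_ld`, `Z_lm`, `Z_md`, `groups`
#'   (data frame) and `manifest`.
#' @export
load_benchmark <- function(dir) {
  ontology <- read_ontology(file.path(dir, "ontology.tsv"))
  idx <- entity_index(
    lnc_ids = readLines(file.path(dir, "lnc_ids.txt")),
    dis_ids = readLines(file.path(dir, "dis_ids.txt")),
    mir_ids = readLines(file.path(dir, "mir_ids.txt")))
  Z_ld <- read_edge_list(file.path(dir, "lnc_disease.tsv"),
                         idx$lnc_ids, idx$dis_ids)
  Z_lm <- read_edge_list(file.path(dir, "lnc_mirna.tsv"),
                         idx$lnc_ids, idx$mir_ids)
  Z_md <- read_edge_list(file.path(dir, "mirna_disease.tsv"),
                         idx$mir_ids, idx$dis_ids)
  groups <- utils::read.delim(file.path(dir, "groups.tsv"),
                              stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  list(ontology = ontology, index = idx, Z_ld = Z_ld, Z_lm = Z_lm,
       Z_md = Z_md, groups = groups, manifest = manifest)
}

#' Build the heterogeneous graph from a benchmark dataset
#'
#' Computes disease semantic similarity over the ontology, lncRNA and miRNA
#' functional similarity from their associated-disease sets, and assembles
#' the block adjacency matrix.
#'
#' @param data a list as returned by [load_benchmark()] (or the in-memory
#'   equivalent).
#' @param delta semantic decay factor.
#' @return a `het_graph`.
#' @export
build_heterogeneous_graph <- function(data, delta = 0.5) {
  S_dd <- disease_similarity_matrix(data$ontology, data$index$dis_ids, delta)
  dis_sets_of <- function(Z) {
    lapply(stats::setNames(seq_len(nrow(Z)), rownames(Z)), function(i) {
      colnames(Z)[Z[i, ] == 1]
    })
  }
  S_ll <- functional_similarity_matrix(dis_sets_of(data$Z_ld), S_dd)
  S_mm <- functional_similarity_matrix(dis_sets_of(data$Z_md), S_dd)
  assemble_adjacency(S_ll, S_dd, S_mm, data$Z_ld, data$Z_lm, data$Z_md,
                     data$index$lnc_ids, data$index$dis_ids,
                     data$index$mir_ids)
}
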
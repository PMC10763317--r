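# Shared fixtures and independent oracles.

# chain: root -> mid -> W
chain_ontology <- function() {
  disease_ontology(data.frame(parent = c("root", "mid"),
                              child = c("mid", "W")))
}

# diamond: r -> a -> c, r -> b -> c
diamond_ontology <- function() {
  disease_ontology(data.frame(parent = c("r", "r", "a", "b"),
                              child = c("a", "b", "c", "c")))
}

# random DAG: term i (i >= 2) draws 1..3 parents among terms 1..(i-1)
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  edges <- NULL
  terms <- sprintf("t%02d", seq_len(n_terms))
  for (i in seq(2, n_terms)) {
    k <- sample(seq_len(min(3L, i - 1L)), 1)
    parents <- terms[sample(i - 1L, k)]
    edges <- rbind(edges, data.frame(parent = parents, child = terms[i]))
  }
  disease_ontology(edges, terms = terms)
}

# Brute-force semantic-contribution oracle: the contribution of ancestor a
# to target W is the max over all directed paths a -> ... -> W of
# delta^(path length), computed by explicit path enumeration (independent
# of the DP in the package).
oracle_contributions <- function(ontology, target, delta = 0.5) {
  best_path <- function(a) {
    if (a == target) return(0L)  # path length 0
    lens <- integer(0)
    for (c in ontology$children[[a]]) {
      sub <- best_path(c)
      if (!is.na(sub)) lens <- c(lens, sub + 1L)
    }
    if (length(lens) == 0) return(NA_integer_)
    min(lens)  # max over paths of delta^len is attained at the shortest
  }
  closure <- ancestor_closure(ontology, target)
  vapply(stats::setNames(closure, closure),
         function(a) delta^best_path(a), numeric(1))
}

# Mann-Whitney AUC oracle: concordant pair counting with ties worth 1/2.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small deterministic benchmark graph shared across tests (built once).
tiny_graph_env <- new.env()
tiny_benchmark <- function() {
  if (is.null(tiny_graph_env$data)) {
    dir <- file.path(tempdir(), "graphlda-tiny-fixture")
    spec <- synthetic_preset("tiny", seed = 11L)
    generate_benchmark(spec, dir)
    data <- load_benchmark(dir)
    tiny_graph_env$data <- data
    tiny_graph_env$graph <- build_heterogeneous_graph(data)
    tiny_graph_env$dir <- dir
  }
  list(data = tiny_graph_env$data, graph = tiny_graph_env$graph,
       dir = tiny_graph_env$dir)
}

# fast training configuration for smoke tests
fast_config <- function(...) {
  load_config(overrides = utils::modifyList(
    list(gcn = list(embedding = 16L),
         transformer = list(layers = 1L, heads = 2L, ffn_mult = 2L),
         train = list(epochs = 5L)),
    list(...)))
}
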
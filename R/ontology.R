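#' Disease ontology DAG
#'
#' Builds a rooted directed acyclic graph of disease terms from parent->child
#' edges. Each term's ancestor closure (the term plus everything reachable by
#' following child->parent edges) is the support on which semantic
#' contributions are computed.
#'
#' @param parent_edges two-column data frame or matrix of character ids,
#'   first column the parent, second the child. May have zero rows.
#' @param terms optional character vector of term ids; defaults to the ids
#'   appearing in `parent_edges`. Extra ids become isolated terms.
#' @return an object of class `disease_ontology` with elements `terms`,
#'   `parents` (named list), `children` (named list), `edges` (data frame
#'   with columns `parent`, `child`) and `topo_order` (parents before
#'   children).
#' @export
disease_ontology <- function(parent_edges, terms = NULL) {
  if (is.matrix(parent_edges)) {
    parent_edges <- as.data.frame(parent_edges, stringsAsFactors = FALSE)
  }
  if (ncol(parent_edges) < 2 && nrow(parent_edges) > 0) {
    stop("parent_edges must have two columns (parent, child)")
  }
  if (nrow(parent_edges) > 0) {
    edges <- data.frame(parent = as.character(parent_edges[[1]]),
                        child = as.character(parent_edges[[2]]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(parent = character(0), child = character(0))
  }
  if (any(edges$parent == edges$child)) {
    bad <- which(edges$parent == edges$child)[1]
    stop(sprintf("self-edge on term '%s' (edge %d)", edges$parent[bad], bad))
  }
  edges <- unique(edges)
  all_terms <- unique(c(terms, edges$parent, edges$child))
  if (length(all_terms) == 0) stop("ontology has no terms")

  parents <- split(edges$parent, factor(edges$child, levels = all_terms))
  children <- split(edges$child, factor(edges$parent, levels = all_terms))

  topo <- .topological_order(all_terms, parents)
  if (is.null(topo)) {
    cyc <- .find_cycle(all_terms, children)
    stop(sprintf("ontology contains a cycle: %s", paste(cyc, collapse = " -> ")))
  }
  structure(
    list(terms = all_terms, parents = parents, children = children,
         edges = edges, topo_order = topo),
    class = "disease_ontology"
  )
}

#' @export
print.disease_ontology <- function(x, ...) {
  n_root <- sum(vapply(x$terms, function(t) length(x$parents[[t]]) == 0, logical(1)))
  cat(sprintf("<disease_ontology> %d terms, %d parent->child edges, %d root(s)\n",
              length(x$terms), nrow(x$edges), n_root))
  invisible(x)
}

# Kahn's algorithm; returns NULL when a cycle prevents a full ordering.
.topological_order <- function(terms, parents) {
  indeg <- vapply(terms, function(t) length(parents[[t]]), integer(1))
  names(indeg) <- terms
  child_of <- lapply(terms, function(t) character(0))
  names(child_of) <- terms
  for (t in terms) {
    for (p in parents[[t]]) child_of[[p]] <- c(child_of[[p]], t)
  }
  queue <- terms[indeg == 0]
  out <- character(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (c in child_of[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) != length(terms)) NULL else out
}

# Locates one directed cycle by DFS, for the error message only.
.find_cycle <- function(terms, children) {
  state <- stats::setNames(rep(0L, length(terms)), terms)  # 0 new, 1 open, 2 done
  stack <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[[v]] <<- 1L
    stack <<- c(stack, v)
    for (c in children[[v]]) {
      if (!is.null(found)) return()
      if (state[[c]] == 1L) {
        i <- match(c, stack)
        found <<- c(stack[i:length(stack)], c)
        return()
      }
      if (state[[c]] == 0L) visit(c)
    }
    stack <<- stack[-length(stack)]
    state[[v]] <<- 2L
  }
  for (t in terms) if (state[[t]] == 0L) visit(t)
  found
}

#' Ancestor closure of a term
#'
#' Returns the term together with every ancestor reachable by following
#' child->parent edges (the node-set on which the term's semantic profile
#' lives).
#'
#' @param ontology a [disease_ontology()].
#' @param term a term id present in the ontology.
#' @return character vector of term ids (unordered set; always contains
#'   `term`).
#' @export
ancestor_closure <- function(ontology, term) {
  stopifnot(inherits(ontology, "disease_ontology"))
  if (!term %in% ontology$terms) {
    stop(sprintf("unknown term id '%s'", term))
  }
  seen <- term
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Read an ontology from a parent/child TSV
#'
#' Two tab-separated columns `parent_id<TAB>child_id`; lines starting with
#' `#` are comments; a single optional header line `parent<TAB>child` is
#' skipped. Cycles and self-edges are rejected.
#'
#' @param path path to the TSV file.
#' @return a [disease_ontology()].
#' @export
read_ontology <- function(path) {
  rows <- .read_two_column_tsv(path, what = "ontology edge")
  if (nrow(rows) > 0 &&
      tolower(rows[1, 1]) %in% c("parent", "parent_id") &&
      tolower(rows[1, 2]) %in% c("child", "child_id")) {
    rows <- rows[-1, , drop = FALSE]
  }
  disease_ontology(rows)
}

#' Write an ontology to a parent/child TSV
#'
#' @param ontology a [disease_ontology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  stopifnot(inherits(ontology, "disease_ontology"))
  utils::write.table(ontology$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("parent", "child"))
  invisible(path)
}

# Shared low-level reader: two tab-separated columns, '#' comments.
# Returns a character matrix with an attribute of source line numbers.
.read_two_column_tsv <- function(path, what = "edge") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    out <- matrix(character(0), ncol = 2)
    attr(out, "line") <- integer(0)
    return(out)
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    bad <- idx[which(nf != 2)[1]]
    stop(sprintf("%s file %s: expected 2 tab-separated columns at line %d, got %d",
                 what, path, bad, nf[which(nf != 2)[1]]))
  }
  out <- matrix(trimws(unlist(parts)), ncol = 2, byrow = TRUE)
  attr(out, "line") <- idx
  out
}
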
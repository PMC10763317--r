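#' Entity index over the three node classes
#'
#' Records the fixed node ordering \[lncRNAs, diseases, miRNAs\] used by
#' every matrix in the package and provides id <-> index lookup.
#'
#' @param lnc_ids,dis_ids,mir_ids character id vectors, unique within each
#'   class.
#' @return object of class `entity_index`.
#' @export
entity_index <- function(lnc_ids, dis_ids, mir_ids) {
  check <- function(ids, what) {
    ids <- as.character(ids)
    if (length(ids) == 0) stop(sprintf("no %s ids", what))
    if (anyDuplicated(ids)) {
      stop(sprintf("duplicate %s ids: %s", what,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    ids
  }
  structure(list(lnc_ids = check(lnc_ids, "lncRNA"),
                 dis_ids = check(dis_ids, "disease"),
                 mir_ids = check(mir_ids, "miRNA")),
            class = "entity_index")
}

#' @export
print.entity_index <- function(x, ...) {
  cat(sprintf("<entity_index> %d lncRNAs, %d diseases, %d miRNAs\n",
              length(x$lnc_ids), length(x$dis_ids), length(x$mir_ids)))
  invisible(x)
}

#' Read a binary association block from a two-column edge list
#'
#' Each line is `id_a<TAB>id_b`; `#` comments and one optional header line
#' are allowed. Duplicate edges collapse to a single 1 with a warning;
#' unknown ids are reported with their line number.
#'
#' @param path path to the TSV edge list.
#' @param row_ids,col_ids entity id universes defining the matrix shape and
#'   order.
#' @return binary numeric matrix with dimnames `(row_ids, col_ids)`.
#' @export
read_edge_list <- function(path, row_ids, col_ids) {
  rows <- .read_two_column_tsv(path, what = "edge list")
  lines <- attr(rows, "line")
  Z <- matrix(0, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  if (nrow(rows) == 0) return(Z)
  # optional single header line: both fields outside both universes
  if (!(rows[1, 1] %in% row_ids) && !(rows[1, 2] %in% col_ids)) {
    rows <- rows[-1, , drop = FALSE]
    lines <- lines[-1]
    if (nrow(rows) == 0) return(Z)
  }
  ri <- match(rows[, 1], row_ids)
  ci <- match(rows[, 2], col_ids)
  if (anyNA(ri)) {
    bad <- which(is.na(ri))[1]
    stop(sprintf("%s line %d: unknown row id '%s'", path, lines[bad],
                 rows[bad, 1]))
  }
  if (anyNA(ci)) {
    bad <- which(is.na(ci))[1]
    stop(sprintf("%s line %d: unknown column id '%s'", path, lines[bad],
                 rows[bad, 2]))
  }
  if (anyDuplicated(cbind(ri, ci))) {
    warning(sprintf("%s: %d duplicate edge(s) collapsed", path,
                    sum(duplicated(cbind(ri, ci)))), call. = FALSE)
  }
  Z[cbind(ri, ci)] <- 1
  Z
}

#' Write a binary association block as a two-column edge list
#'
#' @param Z binary matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(Z, path) {
  idx <- which(Z == 1, arr.ind = TRUE)
  df <- data.frame(a = rownames(Z)[idx[, 1]], b = colnames(Z)[idx[, 2]])
  df <- df[order(df$a, df$b), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a dense matrix as TSV with id headers
#'
#' First row and first column carry the ids; the body is the dense matrix.
#'
#' @param M matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense matrix written by [write_matrix_tsv()]
#'
#' @param path input path.
#' @return numeric matrix with dimnames restored.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}
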
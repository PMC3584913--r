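#' Similarity sources
#'
#' Every per-source dataset (sequence identities, expression profiles, PPI
#' edges) is reduced to the same interface: a named source exposing a
#' symmetric similarity in \[0, 1\] over an explicit set of covered
#' proteins. Queries outside the coverage are "uncovered", not zero — the
#' integration step substitutes a zero score for them.
#'
#' @name sim_source
NULL

new_sim_source <- function(name, mat) {
  stopifnot(is.matrix(mat), identical(rownames(mat), colnames(mat)))
  structure(list(name = name, proteins = rownames(mat), mat = mat),
            class = "sim_source")
}

#' @export
print.sim_source <- function(x, ...) {
  cat("<sim_source> ", x$name, ": ", length(x$proteins),
      " proteins covered\n", sep = "")
  invisible(x)
}

#' @rdname sim_source
#' @param source A similarity source.
#' @export
source_coverage <- function(source) source$proteins

#' @rdname sim_source
#' @param p,q Protein ids; both must be covered.
#' @export
source_sim <- function(source, p, q) {
  stopifnot(inherits(source, "sim_source"))
  miss <- setdiff(c(p, q), source$proteins)
  if (length(miss) > 0) {
    abort(paste0("protein(s) not covered by source '", source$name, "': ",
                 paste(miss, collapse = ", ")))
  }
  source$mat[p, q]
}

#' Build a similarity source from a percent-identity matrix
#'
#' Sequence similarity is percent identity divided by 100. The input matrix
#' must be square with matching row/column ids, entries in \[0, 100\] and
#' symmetric within `tol`; the diagonal is forced to 1.
#'
#' @param mat A square numeric matrix with protein ids as dimnames, or a
#'   data frame whose first column holds protein ids (the on-disk layout,
#'   see [read_similarity_matrix()]).
#' @param name Source name (default `"sequence"`).
#' @param tol Symmetry tolerance (default `1e-6`).
#' @return A `sim_source`.
#' @export
identity_source <- function(mat, name = "sequence", tol = 1e-6) {
  mat <- as_protein_matrix(mat)
  if (any(mat < 0 | mat > 100)) {
    bad <- which(mat < 0 | mat > 100, arr.ind = TRUE)[1, ]
    abort(paste0("percent identity out of [0, 100] at (",
                 rownames(mat)[bad[1]], ", ", colnames(mat)[bad[2]], "): ",
                 mat[bad[1], bad[2]]))
  }
  if (max(abs(mat - t(mat))) > tol) {
    abort(paste0("identity matrix asymmetric beyond tolerance ", tol))
  }
  sim <- (mat + t(mat)) / 200
  diag(sim) <- 1
  new_sim_source(name, sim)
}

#' Build a similarity source from an expression matrix
#'
#' Protein-protein similarity is the Pearson correlation of expression
#' profiles, clipped below at 0 (sources must be nonnegative so that kNN
#' scores stay in \[0, k\]); the diagonal is 1. Proteins measured by
#' several rows (e.g. multiple probes) are averaged into one profile first;
#' constant rows are dropped from the coverage with a warning.
#'
#' @param expr Numeric matrix (rows = proteins, columns = samples) with
#'   protein ids as rownames, or the data-frame layout of
#'   [read_expression_matrix()].
#' @param name Source name (default `"expression"`).
#' @param keep_negative Keep raw (possibly negative) correlations instead
#'   of clipping at 0 (default `FALSE`).
#' @return A `sim_source`.
#' @export
expression_source <- function(expr, name = "expression",
                              keep_negative = FALSE) {
  expr <- as_protein_matrix(expr, square = FALSE)
  if (ncol(expr) < 3) abort("need at least 3 samples to correlate profiles")
  if (anyDuplicated(rownames(expr)) > 0) {
    expr <- rowsum(expr, rownames(expr)) /
      as.vector(table(rownames(expr))[unique(rownames(expr))])
    expr <- expr[sort(rownames(expr)), , drop = FALSE]
  }
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    dropped <- rownames(expr)[sds == 0]
    warn(paste0("dropping ", length(dropped),
                " constant expression profile(s): ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else ""))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) == 0) abort("no non-constant expression profiles left")
  r <- cor(t(expr))
  if (!keep_negative) r <- pmax(r, 0)
  diag(r) <- 1
  new_sim_source(name, r)
}

#' Build a similarity source from a PPI edge list
#'
#' Interaction is treated as binary similarity: 1 on edges, 0 otherwise.
#' The graph is undirected; self-loops are dropped with a warning; isolated
#' proteins (degree 0) carry no signal and are excluded from the coverage.
#'
#' @param edges A data frame with two columns of protein ids (any names;
#'   the first two columns are used).
#' @param name Source name (default `"ppi"`).
#' @return A `sim_source`.
#' @export
ppi_source <- function(edges, name = "ppi") {
  edges <- as_tibble(edges)
  stopifnot(ncol(edges) >= 2)
  e <- tibble(from = as.character(edges[[1]]), to = as.character(edges[[2]]))
  loops <- e$from == e$to
  if (any(loops)) {
    warn(paste0("dropping ", sum(loops), " self-loop(s)"))
    e <- e[!loops, , drop = FALSE]
  }
  if (nrow(e) == 0) abort("PPI graph has no edges after dropping self-loops")
  nodes <- sort(unique(c(e$from, e$to)))
  mat <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  mat[cbind(e$from, e$to)] <- 1
  mat[cbind(e$to, e$from)] <- 1
  diag(mat) <- 1
  new_sim_source(name, mat)
}

as_protein_matrix <- function(x, square = TRUE) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    x <- m
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (square) {
    if (is.null(colnames(x)) || !identical(rownames(x), colnames(x))) {
      abort("square similarity matrix must have matching row/column ids")
    }
  }
  x
}

#' Readers for the per-source file formats
#'
#' `read_similarity_matrix()` reads a square TSV (header row of protein
#' ids, first column of protein ids); `read_expression_matrix()` reads a
#' proteins x samples TSV (first column `protein_id`); `read_ppi_edges()`
#' reads a 2-column edge-list TSV.
#'
#' @param path File path.
#' @return A numeric matrix (similarity / expression) or a tibble of edges.
#' @export
read_similarity_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()))
  as_protein_matrix(df, square = TRUE)
}

#' @rdname read_similarity_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()))
  as_protein_matrix(df, square = FALSE)
}

#' @rdname read_similarity_matrix
#' @export
read_ppi_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}

#' Writers matching the per-source readers
#'
#' @param mat Numeric matrix with protein rownames (and identical colnames
#'   for the square case).
#' @param path Output file path.
#' @param id_col Header used for the id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "protein_id") {
  df <- as_tibble(mat, rownames = id_col)
  readr::write_tsv(df, path)
  invisible(path)
}
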
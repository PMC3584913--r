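#' Protein-term annotation tables
#'
#' An annotation table is a tidy tibble with one row per (protein, term)
#' assignment and a `propagated` attribute recording whether the table is
#' closed under the true-path rule (every assignment accompanied by all
#' ancestor assignments).
#'
#' @param x A data frame with columns `protein` and `term` (an optional
#'   `evidence` column is carried along).
#' @param propagated Logical; is `x` already an ancestor closure?
#' @return A tibble of class `annotation_tbl`.
#' @export
annotation_table <- function(x, propagated = FALSE) {
  x <- as_tibble(x)
  stopifnot(all(c("protein", "term") %in% names(x)))
  x <- distinct(arrange(x, protein, term))
  structure(x, class = c("annotation_tbl", class(tibble())),
            propagated = isTRUE(propagated))
}

#' @rdname annotation_table
#' @param ann An object to test / query.
#' @export
is_propagated <- function(ann) isTRUE(attr(ann, "propagated"))

#' Read / write annotation TSVs
#'
#' The on-disk format is a UTF-8 TSV with a header line and columns
#' `protein_id`, `term_id` and optionally `evidence_code` (a GAF-like
#' subset).
#'
#' @param path File path.
#' @param propagated Logical flag stored on the returned table.
#' @return [read_annotations()]: an [annotation_table()];
#'   [write_annotations()]: `path`, invisibly.
#' @export
read_annotations <- function(path, propagated = FALSE) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  stopifnot(all(c("protein_id", "term_id") %in% names(df)))
  df <- rename(df, protein = "protein_id", term = "term_id")
  if ("evidence_code" %in% names(df)) df <- rename(df, evidence = "evidence_code")
  annotation_table(df, propagated = propagated)
}

#' @rdname read_annotations
#' @param ann An [annotation_table()].
#' @export
write_annotations <- function(ann, path) {
  out <- rename(as_tibble(ann), protein_id = "protein", term_id = "term")
  if ("evidence" %in% names(out)) out <- rename(out, evidence_code = "evidence")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Propagate annotations up the ontology (true-path closure)
#'
#' Replaces each protein's term set by its ancestor closure: a protein
#' annotated with a term is annotated with every ancestor of that term up
#' to the namespace root. Idempotent; the result carries
#' `propagated = TRUE`.
#'
#' @param ann An [annotation_table()].
#' @param dag An [ontology_dag()] covering every annotated term.
#' @return A propagated [annotation_table()].
#' @export
propagate_annotations <- function(ann, dag) {
  check_dag(dag)
  ann <- annotation_table(ann, propagated = is_propagated(ann))
  miss <- setdiff(unique(ann$term), dag$terms)
  if (length(miss) > 0) {
    abort(paste0("annotation(s) to unknown term(s): ",
                 paste(miss, collapse = ", ")))
  }
  anc <- dag$ancestors[ann$term]
  closed <- tibble(
    protein = rep(ann$protein, lengths(anc)),
    term = unlist(anc, use.names = FALSE)
  )
  annotation_table(distinct(closed), propagated = TRUE)
}

# named list protein -> character vector of terms
annotation_sets <- function(ann) {
  split(ann$term, factor(ann$protein, levels = unique(ann$protein)))
}

#' Estimate per-term annotation probabilities
#'
#' The probability of a term is the fraction of annotated proteins carrying
#' it, estimated from a propagated annotation table. The denominator is
#' per-namespace: the number of proteins with at least one annotation in
#' the term's namespace, so that each namespace root has probability
#' exactly 1 after propagation (a protein annotated only with biological
#' processes says nothing about the prevalence of molecular functions).
#' Under propagation the estimate is monotone non-increasing from parent
#' to child. Terms with zero annotations are floored at `epsilon` so
#' logarithms stay finite.
#'
#' @param ann A propagated [annotation_table()].
#' @param dag An [ontology_dag()].
#' @param epsilon Floor applied to zero-count terms (default `1e-9`).
#' @return A tibble of class `term_probs` with columns `term` and `p`, and
#'   attribute `n_proteins`.
#' @export
term_probabilities <- function(ann, dag, epsilon = 1e-9) {
  check_dag(dag)
  if (nrow(ann) == 0) abort("annotation table is empty")
  if (!is_propagated(ann)) {
    abort("`ann` must be propagated (see propagate_annotations())")
  }
  stopifnot(epsilon > 0)
  miss <- setdiff(unique(ann$term), dag$terms)
  if (length(miss) > 0) {
    abort(paste0("annotation(s) to unknown term(s): ",
                 paste(miss, collapse = ", ")))
  }
  ann_df <- mutate(as_tibble(ann), namespace = dag$namespace[term])
  ns_sizes <- ann_df %>%
    distinct(protein, namespace) %>%
    count(namespace, name = "n_annotated")
  denom <- set_names(ns_sizes$n_annotated, ns_sizes$namespace)
  counts <- count(ann_df, term, name = "n_annotated")
  out <- tibble(term = dag$terms) %>%
    left_join(counts, by = "term") %>%
    mutate(p = pmax(dplyr::coalesce(n_annotated, 0L) /
                      pmax(denom[dag$namespace[term]], 1L), epsilon)) %>%
    mutate(p = unname(p)) %>%
    select(term, p)
  structure(out, class = c("term_probs", class(tibble())),
            n_proteins = dplyr::n_distinct(ann$protein), epsilon = epsilon)
}

prob_lookup <- function(probs) set_names(probs$p, probs$term)

#' Minimum-subsumer probability of a term pair
#'
#' The joint probability of two same-namespace terms is the minimum
#' annotation probability over their common ancestors, with each term's
#' ancestor closure including the term itself. The namespace root is always
#' a common ancestor, so the value is well defined and at most 1.
#'
#' @param dag An [ontology_dag()].
#' @param probs A [term_probabilities()] table.
#' @param f,g Term ids in the same namespace.
#' @return A probability in `(0, 1]`.
#' @export
min_subsumer_probability <- function(dag, probs, f, g) {
  check_dag(dag)
  if (dag$namespace[[f]] != dag$namespace[[g]]) {
    abort(paste0("terms in different namespaces: ", f, " (",
                 dag$namespace[[f]], ") vs ", g, " (", dag$namespace[[g]], ")"))
  }
  common <- intersect(dag$ancestors[[f]], dag$ancestors[[g]])
  pl <- prob_lookup(probs)
  min(pl[common])
}

#' Lin semantic similarity between two ontology terms
#'
#' The information-theoretic similarity of Lin: twice the log-probability of
#' the pair's minimum subsumer over the sum of the terms' own
#' log-probabilities,
#' \deqn{linsim(f, f') = \frac{2 \log p_{ms}(f, f')}{\log p(f) + \log p(f')}.}
#' The measure is symmetric, lies in \[0, 1\], equals 1 when `f == g`
#' (by convention even for probability-1 terms) and equals 0 when the only
#' information the terms share is the namespace root (log 1 = 0 numerator).
#' Log base cancels in the ratio, so natural logs are used.
#'
#' @inheritParams min_subsumer_probability
#' @return A similarity in `[0, 1]`.
#' @export
lin_similarity <- function(dag, probs, f, g) {
  if (f == g) {
    check_dag(dag)
    if (!f %in% dag$terms) abort(paste0("unknown term id: ", f))
    return(1)
  }
  pms <- min_subsumer_probability(dag, probs, f, g)
  pl <- prob_lookup(probs)
  denom <- log(pl[[f]]) + log(pl[[g]])
  if (denom == 0) return(0)          # both terms certain, f != g: no information
  val <- 2 * log(pms) / denom
  min(max(val, 0), 1)
}

# pairwise linsim matrix between two term vectors; cross-namespace pairs -> 0
lin_similarity_matrix <- function(dag, probs, terms_from, terms_to) {
  pl <- prob_lookup(probs)
  logp <- log(pl)
  anc <- dag$ancestors
  ns <- dag$namespace
  out <- matrix(0, length(terms_from), length(terms_to),
                dimnames = list(terms_from, terms_to))
  for (i in seq_along(terms_from)) {
    f <- terms_from[i]
    for (j in seq_along(terms_to)) {
      g <- terms_to[j]
      if (ns[[f]] != ns[[g]]) next
      if (f == g) { out[i, j] <- 1; next }
      denom <- logp[[f]] + logp[[g]]
      if (denom == 0) next
      pms <- min(pl[intersect(anc[[f]], anc[[g]])])
      out[i, j] <- min(max(2 * log(pms) / denom, 0), 1)
    }
  }
  out
}
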
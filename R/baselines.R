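#' CAFA baseline: term priors
#'
#' The Priors baseline scores every query protein identically: a term's
#' score is the fraction of annotated proteins carrying it in the reference
#' annotation corpus. Common terms outrank rare ones for every protein, so
#' the predictor's term-centric AUC is exactly 0.5.
#'
#' @param ann A propagated, non-empty [annotation_table()].
#' @param terms Terms to score (default: all annotated terms).
#' @return A tibble with columns `term` and `score`.
#' @export
prior_scores <- function(ann, terms = NULL) {
  if (nrow(ann) == 0) abort("annotation table is empty")
  n_prot <- dplyr::n_distinct(ann$protein)
  counts <- count(as_tibble(ann), term, name = "n_annotated")
  if (is.null(terms)) terms <- sort(unique(ann$term))
  tibble(term = terms) %>%
    left_join(counts, by = "term") %>%
    mutate(score = dplyr::coalesce(n_annotated, 0L) / n_prot) %>%
    select(term, score)
}

#' @rdname prior_scores
#' @param queries Query protein ids to replicate the prior over.
#' @return [prior_score_table()]: a [score_table()] with identical rows.
#' @export
prior_score_table <- function(ann, queries, terms = NULL) {
  pri <- prior_scores(ann, terms)
  df <- tidyr::expand_grid(protein = queries, term = pri$term) %>%
    left_join(pri, by = "term")
  score_table(df, source = "prior", proteins = queries, terms = pri$term)
}

#' Read tabular alignment hits
#'
#' Reads the 4-column subset of tabular BLAST output used by the BLAST and
#' Gotcha baselines: `query_id`, `subject_id`, `percent_identity`,
#' `e_value`. E-values must be strictly positive (their logarithm is
#' taken); identities must lie in \[0, 100\].
#'
#' @param path File path.
#' @return A tibble with columns `query`, `subject`, `identity`, `evalue`.
#' @export
read_blast_hits <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    query_id = "c", subject_id = "c",
    percent_identity = "d", e_value = "d"))
  hits <- tibble(query = df$query_id, subject = df$subject_id,
                 identity = df$percent_identity, evalue = df$e_value)
  validate_hits(hits)
}

validate_hits <- function(hits) {
  stopifnot(all(c("query", "subject", "identity", "evalue") %in% names(hits)))
  if (any(hits$evalue <= 0)) abort("e-values must be strictly positive")
  if (any(hits$identity < 0 | hits$identity > 100)) {
    abort("percent identities must lie in [0, 100]")
  }
  as_tibble(hits)
}

#' CAFA baseline: BLAST top hit
#'
#' A term's score for a query is the best percent identity (divided by
#' 100) among the query's alignment hits to proteins annotated with the
#' term; 0 when no annotated protein is hit.
#'
#' @param hits Alignment hits for one query (columns `subject`,
#'   `identity`, `evalue`; see [read_blast_hits()]).
#' @param ann An [annotation_table()] over the subject proteins.
#' @param term A term id.
#' @return A score in `[0, 1]`.
#' @export
blast_score <- function(hits, ann, term) {
  hits <- validate_hits(add_query_col(hits))
  carriers <- ann$protein[ann$term == term]
  ident <- hits$identity[hits$subject %in% carriers]
  if (length(ident) == 0) 0 else max(ident) / 100
}

#' CAFA baseline: Gotcha
#'
#' A term's score for a query is the sum, over the query's hits to
#' proteins annotated with the term, of the negative log10 E-values.
#' E-values at or above 1 would contribute negatively and are clamped to
#' 0. In the original method the raw scores are then propagated
#' cumulatively towards the ontology root — each term accumulates the
#' scores of its descendants; [gotcha_score_table()] applies that post-step
#' by default.
#'
#' @inheritParams blast_score
#' @return A nonnegative score.
#' @export
gotcha_score <- function(hits, ann, term) {
  hits <- validate_hits(add_query_col(hits))
  carriers <- ann$protein[ann$term == term]
  ev <- hits$evalue[hits$subject %in% carriers]
  sum(pmax(0, -log10(ev)))
}

add_query_col <- function(hits) {
  if (!"query" %in% names(hits)) hits$query <- "query"
  hits
}

#' Score tables for the alignment-based baselines
#'
#' Drivers applying [blast_score()] / [gotcha_score()] to every query in a
#' multi-query hit table and every target term.
#'
#' @param hits A [read_blast_hits()] tibble (multi-query).
#' @param ann An [annotation_table()] over the subject proteins.
#' @param terms Target term ids.
#' @param queries Query ids (default: those present in `hits`).
#' @return A [score_table()].
#' @export
blast_score_table <- function(hits, ann, terms, queries = NULL) {
  hits <- validate_hits(hits)
  if (is.null(queries)) queries <- sort(unique(hits$query))
  mat <- baseline_matrix(hits, ann, terms, queries,
                         function(ev, ident) max(ident) / 100)
  score_from_wide(mat, source = "blast")
}

#' @rdname blast_score_table
#' @param dag An [ontology_dag()], required when `propagate = TRUE`.
#' @param propagate Cumulatively propagate raw Gotcha scores towards the
#'   root (default `TRUE`).
#' @export
gotcha_score_table <- function(hits, ann, terms, queries = NULL,
                               dag = NULL, propagate = TRUE) {
  hits <- validate_hits(hits)
  if (is.null(queries)) queries <- sort(unique(hits$query))
  mat <- baseline_matrix(hits, ann, terms, queries,
                         function(ev, ident) sum(pmax(0, -log10(ev))))
  if (propagate) {
    if (is.null(dag)) abort("`dag` is required to propagate Gotcha scores")
    out <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
    for (f in colnames(mat)) {
      for (a in intersect(dag$ancestors[[f]], colnames(mat))) {
        out[, a] <- out[, a] + mat[, f]
      }
    }
    mat <- out
  }
  score_from_wide(mat, source = "gotcha")
}

baseline_matrix <- function(hits, ann, terms, queries, fun) {
  ann <- filter(as_tibble(ann), term %in% terms)
  carriers <- split(ann$protein, ann$term)
  by_query <- split(hits, factor(hits$query, levels = queries))
  mat <- matrix(0, length(queries), length(terms),
                dimnames = list(queries, terms))
  for (q in queries) {
    h <- by_query[[q]]
    if (is.null(h) || nrow(h) == 0) next
    for (f in terms) {
      keep <- h$subject %in% carriers[[f]]
      if (any(keep)) mat[q, f] <- fun(h$evalue[keep], h$identity[keep])
    }
  }
  mat
}
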
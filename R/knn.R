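#' Nearest neighbours of a query protein under one similarity source
#'
#' Returns the `k` training proteins most similar to the query. Proteins
#' with zero similarity are never included (so a PPI query with 3
#' interactors gets 3 neighbours, not `k` zero-padded ones); ties at the
#' cut are broken by lexicographic protein id; the query itself is excluded
#' even when it appears in the training set. A query outside the source's
#' coverage yields an empty neighbour list flagged `covered = FALSE`
#' rather than an error, so downstream integration can substitute a zero
#' score.
#'
#' @param source A [sim_source][identity_source()].
#' @param query A protein id.
#' @param training Character vector of training protein ids.
#' @param k Number of neighbours (default 20, the value used throughout).
#' @return A tibble of class `neighbor_list` with columns `neighbor`,
#'   `similarity` (non-increasing) and attributes `query` and `covered`.
#' @export
nearest_neighbors <- function(source, query, training, k = 20) {
  stopifnot(inherits(source, "sim_source"), k >= 1)
  training <- setdiff(intersect(training, source$proteins), query)
  if (!query %in% source$proteins || length(training) == 0) {
    out <- tibble(neighbor = character(0), similarity = double(0))
    return(structure(out, class = c("neighbor_list", class(tibble())),
                     query = query, covered = query %in% source$proteins))
  }
  sims <- source$mat[query, training]
  keep <- sims > 0
  sims <- sims[keep]
  ids <- training[keep]
  ord <- order(-sims, ids)
  take <- head(ord, k)
  out <- tibble(neighbor = ids[take], similarity = unname(sims[take]))
  structure(out, class = c("neighbor_list", class(tibble())),
            query = query, covered = TRUE)
}

#' @rdname nearest_neighbors
#' @param nbrs A `neighbor_list`.
#' @export
neighbors_covered <- function(nbrs) isTRUE(attr(nbrs, "covered"))

#' kNN prediction score for one protein-term pair
#'
#' The similarity-weighted neighbour vote: the sum, over the query's
#' nearest neighbours annotated with the term, of their similarities to
#' the query. With similarities in \[0, 1\] the score lies in \[0, k\].
#'
#' @param nbrs A [nearest_neighbors()] list.
#' @param ann An [annotation_table()] covering the neighbour proteins.
#' @param term A term id.
#' @return A nonnegative score.
#' @export
knn_score <- function(nbrs, ann, term) {
  carriers <- ann$protein[ann$term == term]
  sum(nbrs$similarity[nbrs$neighbor %in% carriers])
}

#' Lin-similarity-augmented kNN score
#'
#' Extends the plain kNN vote so that neighbours annotated with terms
#' *similar* to the target also contribute: each neighbour adds its
#' similarity times the sum of Lin similarities between its annotated
#' terms and the target term,
#' \deqn{score(p, f) = \sum_{p' \in N_k(p)} sim(p, p')
#'   \sum_{f' \in functions(p')} linsim(f', f).}
#' Cross-namespace terms contribute 0. The `tau` threshold keeps only
#' contributions with `linsim >= tau`; at `tau = 1` (when no distinct pair
#' reaches similarity 1) the score reduces exactly to [knn_score()].
#'
#' @inheritParams knn_score
#' @param dag An [ontology_dag()].
#' @param probs A [term_probabilities()] table.
#' @param term Target term id.
#' @param tau Minimum Lin similarity for a contribution (default 0).
#' @return A nonnegative score.
#' @export
linsim_knn_score <- function(nbrs, ann, dag, probs, term, tau = 0) {
  stopifnot(tau >= 0, tau <= 1)
  if (nrow(nbrs) == 0) return(0)
  ann_nbr <- filter(as_tibble(ann), protein %in% nbrs$neighbor)
  if (nrow(ann_nbr) == 0) return(0)
  uterms <- unique(ann_nbr$term)
  L <- lin_similarity_matrix(dag, probs, uterms, term)[, 1, drop = TRUE]
  L <- set_names(L, uterms)
  L[L < tau] <- 0
  contrib <- set_names(nbrs$similarity, nbrs$neighbor)
  sum(contrib[ann_nbr$protein] * L[ann_nbr$term])
}

#' Score every query against every term for one source
#'
#' Vectorised driver over [knn_score()] / [linsim_knn_score()]: computes
#' the full proteins x terms score matrix for one similarity source.
#' Uncovered queries get an all-zero row and a `FALSE` coverage flag.
#'
#' @param source A [sim_source][identity_source()].
#' @param queries Character vector of query protein ids.
#' @param terms Character vector of target term ids (non-empty).
#' @param training Character vector of training protein ids.
#' @param ann An [annotation_table()] of the training proteins.
#' @param k Neighbourhood size (default 20).
#' @param mode `"plain"` (the indicator vote) or `"linsim"` (the Lin
#'   similarity variant; requires `dag` and `probs`).
#' @param dag,probs Ontology and term probabilities, for `mode = "linsim"`.
#' @param tau Lin-similarity threshold, for `mode = "linsim"`.
#' @return A [score_table()] named after the source.
#' @export
score_all <- function(source, queries, terms, training, ann, k = 20,
                      mode = c("plain", "linsim"), dag = NULL, probs = NULL,
                      tau = 0) {
  mode <- arg_match(mode)
  if (length(terms) == 0) abort("empty term list")
  stopifnot(k >= 1)
  ann <- as_tibble(ann)
  if (mode == "linsim" && (is.null(dag) || is.null(probs))) {
    abort("mode = \"linsim\" requires `dag` and `probs`")
  }

  ann_train <- filter(ann, protein %in% training)
  # training x term indicator (plain) or annotated-term membership (linsim)
  if (mode == "plain") {
    ann_use <- filter(ann_train, term %in% terms)
  } else {
    ann_use <- ann_train
    uterms <- unique(ann_use$term)
    L <- lin_similarity_matrix(dag, probs, uterms, terms)
    L[L < tau] <- 0
  }
  carriers <- split(ann_use$protein, ann_use$term)
  by_protein <- split(ann_use$term, ann_use$protein)

  mat <- matrix(0, length(queries), length(terms),
                dimnames = list(queries, terms))
  covered <- set_names(rep(FALSE, length(queries)), queries)
  for (q in queries) {
    nbrs <- nearest_neighbors(source, q, training, k)
    covered[[q]] <- neighbors_covered(nbrs)
    if (nrow(nbrs) == 0) next
    if (mode == "plain") {
      sims <- set_names(nbrs$similarity, nbrs$neighbor)
      for (f in terms) {
        hit <- intersect(carriers[[f]], nbrs$neighbor)
        if (length(hit) > 0) mat[q, f] <- sum(sims[hit])
      }
    } else {
      # accumulate similarity mass per annotated term, then map through L
      mass <- set_names(rep(0, length(uterms)), uterms)
      for (i in seq_len(nrow(nbrs))) {
        fts <- by_protein[[nbrs$neighbor[i]]]
        if (!is.null(fts)) mass[fts] <- mass[fts] + nbrs$similarity[i]
      }
      mat[q, ] <- as.vector(mass %*% L)
    }
  }
  score_from_wide(mat, source = source$name, covered = covered)
}
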
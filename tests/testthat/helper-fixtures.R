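# shared toy fixtures, built in code

# linear chain root -> t1 -> ... -> t{n-1} in one namespace
chain_dag <- function(n = 3, ns = "MF") {
  ids <- c(paste0(ns, ":root"), paste0(ns, ":t", seq_len(n - 1)))
  ontology_dag(tibble::tibble(
    term = ids,
    parent = c(NA, ids[-n]),
    namespace = ns
  ))
}

# MF: root -> {a, b}; c is_a a and b (multi-parent); d is_a a. BP: root -> x.
diamond_dag <- function() {
  ontology_dag(tibble::tibble(
    term = c("MF:root", "MF:a", "MF:b", "MF:c", "MF:c", "MF:d",
             "BP:root", "BP:x"),
    parent = c(NA, "MF:root", "MF:root", "MF:a", "MF:b", "MF:a",
               NA, "BP:root"),
    namespace = c(rep("MF", 6), rep("BP", 2))
  ))
}

# probability table with stated values (already parent-monotone)
probs_for <- function(dag, p) {
  stopifnot(setequal(names(p), dag$terms))
  structure(tibble::tibble(term = names(p), p = unname(p)),
            class = c("term_probs", class(tibble::tibble())),
            n_proteins = NA_integer_, epsilon = 1e-9)
}

# similarity source straight from a named similarity matrix in [0, 1]
sim_source_from <- function(mat, name = "toy") {
  identity_source(mat * 100, name = name)
}

# neighbour list literal
nbrs_of <- function(query, ids, sims) {
  structure(tibble::tibble(neighbor = ids, similarity = sims),
            class = c("neighbor_list", class(tibble::tibble())),
            query = query, covered = TRUE)
}

# score table with a single (protein, term) cell per source value
one_cell_scores <- function(value, protein = "P1", term = "MF:t1",
                            source = "toy") {
  score_table(tibble::tibble(protein = protein, term = term, score = value),
              source = source)
}

# independent ancestor-closure oracle: iterate parent expansion to fixpoint
oracle_ancestors <- function(dag, term) {
  out <- term
  repeat {
    nxt <- unique(c(out, unlist(dag$parents[out], use.names = FALSE)))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}

# brute-force pair-counting AUC oracle
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# grid search over the weight simplex at fixed resolution (hinge objective)
oracle_grid_min <- function(D, res = 1e-3) {
  m <- ncol(D)
  best <- Inf
  if (m == 2) {
    for (x in seq(0, 1, by = res)) {
      v <- sum(pmax(0, -as.vector(D %*% c(x, 1 - x))))
      if (v < best) best <- v
    }
  } else if (m == 3) {
    xs <- seq(0, 1, by = res)
    for (x in xs) {
      ys <- seq(0, 1 - x, by = res)
      W <- cbind(x, ys, 1 - x - ys)
      mn <- min(rowSums(pmax(-(W %*% t(D)), 0)))
      if (mn < best) best <- mn
    }
  } else {
    stop("oracle supports m <= 3")
  }
  best
}

# planted rank-loss problem: source 1 ranks correctly (with one tied pair so
# the zero-loss set is exactly the first vertex), source 2 reverses every pair
planted_problem <- function(m = 2, n_pairs = 30) {
  stopifnot(m >= 2)
  d1 <- c(0, runif(n_pairs - 1, 0.2, 1))   # one tie, rest positive
  D <- cbind(d1, -matrix(runif(n_pairs * (m - 1), 0.2, 1), n_pairs))
  colnames(D) <- paste0("s", seq_len(m))
  structure(list(pairs = tibble::tibble(protein = "p", pos = "y", neg = "n"),
                 D = D, source_names = colnames(D)),
            class = "rank_loss_problem")
}

# small fully-wired synthetic scene shared by integration-style tests;
# coverage raised so even tiny PPI graphs have edges
tiny_scene <- function(seed = 11, n_proteins = 60, n_terms = 30,
                       n_test = 20,
                       coverage = c(seq = 1, expr = 0.9, ppi = 0.6), ...) {
  cfg <- synthetic_config(n_proteins = n_proteins, n_terms = n_terms,
                          seed = seed, coverage = coverage, ...)
  ds <- simulate_dataset(cfg)
  proteins <- sort(unique(ds$ann$protein))
  test <- proteins[seq_len(n_test)]
  list(
    cfg = cfg, dag = ds$dag, ann = ds$ann, sources = ds$sources,
    seq = identity_source(ds$sources$identity),
    expr = suppressWarnings(expression_source(ds$sources$expression)),
    ppi = ppi_source(ds$sources$ppi),
    test = test,
    train = setdiff(proteins, test),
    terms = sort(unique(ds$ann$term))
  )
}
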
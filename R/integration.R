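#' Per-source weight vectors
#'
#' Nonnegative weights over the similarity sources summing to 1 (a point of
#' the probability simplex), either global or specific to one ontology
#' cluster.
#'
#' @param w Numeric vector of nonnegative weights summing to 1 (within
#'   `1e-9`).
#' @param source_names Character vector naming the sources, same length as
#'   `w`.
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(w, source_names = names(w)) {
  if (is.null(source_names)) {
    source_names <- paste0("source", seq_along(w))
  }
  stopifnot(length(w) == length(source_names))
  if (any(w < -1e-12)) abort("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) abort("weights must sum to 1")
  structure(list(w = set_names(pmax(as.numeric(w), 0), source_names),
                 source_names = source_names),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector>\n")
  print(round(x$w, 4))
  invisible(x)
}

#' Integrate per-source scores by fixed three-group averaging (MS-kNN)
#'
#' The CAFA predictor: the final score of a (protein, term) cell is one
#' third of the sequence score, plus one third of the PPI score, plus
#' `1/(3J)` times the sum over the `J` expression datasets' scores,
#' \deqn{score(p,f) = \tfrac13 score^{SEQ} + \tfrac13 score^{PPI}
#'   + \tfrac1{3J} \sum_{j=1}^{J} score_j^{EXP}.}
#' A source missing for a run, or a protein outside a source's coverage,
#' contributes 0 while the `1/3` coefficients stay fixed — proteins seen by
#' several sources are deliberately scored higher (increased confidence).
#' Setting `renormalize = TRUE` instead reweights to `1/(number of groups
#' provided)`, for runs where a whole pipeline is absent.
#'
#' @param seq,ppi [score_table()]s for the sequence and PPI sources, or
#'   `NULL` when absent.
#' @param expr A [score_table()], a list of `J` of them (one per expression
#'   dataset, pre-averaged here with the `1/(3J)` coefficient), or `NULL`.
#' @param renormalize Reweight over provided groups instead of the fixed
#'   thirds (default `FALSE`, the CAFA-faithful rule).
#' @return A [score_table()] named `"ms-knn"`.
#' @export
average_scores <- function(seq = NULL, ppi = NULL, expr = NULL,
                           renormalize = FALSE) {
  if (inherits(expr, "score_tbl")) expr <- list(expr)
  groups <- list(seq = seq, ppi = ppi, expr = expr)
  provided <- !vapply(groups, is.null, logical(1))
  if (!any(provided)) abort("no score tables provided")
  all_sts <- c(groups[c("seq", "ppi")][provided[c("seq", "ppi")]],
               if (provided[["expr"]]) expr)
  do.call(check_same_grid, unname(all_sts))
  ref <- all_sts[[1]]

  denom <- if (renormalize) sum(provided) else 3
  acc <- matrix(0, length(score_proteins(ref)), length(score_terms(ref)),
                dimnames = list(score_proteins(ref), score_terms(ref)))
  if (provided[["seq"]]) acc <- acc + score_wide(seq) / denom
  if (provided[["ppi"]]) acc <- acc + score_wide(ppi) / denom
  if (provided[["expr"]]) {
    j <- length(expr)
    for (st in expr) acc <- acc + score_wide(st) / (denom * j)
  }
  covered <- Reduce(`|`, lapply(all_sts, score_covered))
  score_from_wide(acc, source = "ms-knn", covered = covered)
}

#' Weighted average of per-source scores
#'
#' Entry-wise \eqn{\sum_j w_j \, score_j(p, f)} over aligned score tables;
#' with uniform weights over (sequence, PPI, dataset-averaged expression)
#' this reproduces [average_scores()].
#'
#' @param scores List of `m` [score_table()]s sharing the same grid.
#' @param w A [weight_vector()] of length `m`.
#' @return A [score_table()] named `"ms-w-knn"`.
#' @export
weighted_average <- function(scores, w) {
  stopifnot(inherits(w, "weight_vector"))
  if (length(scores) != length(w$w)) {
    abort("length(scores) must equal the number of weights")
  }
  do.call(check_same_grid, unname(scores))
  ref <- scores[[1]]
  acc <- matrix(0, length(score_proteins(ref)), length(score_terms(ref)),
                dimnames = list(score_proteins(ref), score_terms(ref)))
  for (j in seq_along(scores)) acc <- acc + w$w[[j]] * score_wide(scores[[j]])
  covered <- Reduce(`|`, lapply(scores, score_covered))
  score_from_wide(acc, source = "ms-w-knn", covered = covered)
}

#' Assemble the rank-loss weight-learning problem
#'
#' For every training protein, every pair of an annotated (positive) term
#' `y` and an unannotated (negative) term `y-bar` contributes one
#' rank constraint: the integrated score of `y` should not fall below the
#' integrated score of `y-bar`. Negatives are drawn from terms annotated in
#' at least one training protein (absence of annotation elsewhere is
#' treated as negative evidence — a known weakness of the formulation, see
#' the methods vignette). The full pair set is quadratic, so it is
#' subsampled to at most `max_pairs` pairs with a fixed seed.
#'
#' @param scores Named list of `m` [score_table()]s over the training
#'   proteins (one per source).
#' @param ann An [annotation_table()] of the training proteins.
#' @param max_pairs Cap on the number of (protein, positive, negative)
#'   pairs (default 10000).
#' @param seed Seed for the subsample (default 1).
#' @return An object of class `rank_loss_problem`: the pair table, the
#'   `P x m` matrix `D` of per-source score differences
#'   `f(x, y) - f(x, y-bar)`, and the source names.
#' @export
rank_loss_problem <- function(scores, ann, max_pairs = 10000, seed = 1) {
  stopifnot(length(scores) >= 1, max_pairs >= 1)
  do.call(check_same_grid, unname(scores))
  ref <- scores[[1]]
  source_names <- vapply(seq_along(scores), function(j) {
    nm <- names(scores)[j]
    if (!is.null(nm) && nzchar(nm)) nm else attr(scores[[j]], "source_name")
  }, character(1))
  proteins <- score_proteins(ref)
  terms <- score_terms(ref)
  ann <- filter(as_tibble(ann), protein %in% proteins, term %in% terms)
  annotated_terms <- sort(unique(ann$term))
  pos_sets <- split(ann$term, factor(ann$protein, levels = proteins))

  pairs <- purrr::map_dfr(proteins, function(pr) {
    y <- pos_sets[[pr]]
    if (length(y) == 0) return(tibble())
    ybar <- setdiff(annotated_terms, y)
    if (length(ybar) == 0) return(tibble())
    tidyr::expand_grid(protein = pr, pos = y, neg = ybar)
  })
  if (nrow(pairs) == 0) abort("no (positive, negative) term pairs available")
  if (nrow(pairs) > max_pairs) {
    idx <- withr::with_seed(seed, sample.int(nrow(pairs), max_pairs))
    pairs <- pairs[sort(idx), , drop = FALSE]
  }

  D <- matrix(0, nrow(pairs), length(scores),
              dimnames = list(NULL, source_names))
  for (j in seq_along(scores)) {
    m <- score_wide(scores[[j]])
    D[, j] <- m[cbind(pairs$protein, pairs$pos)] -
      m[cbind(pairs$protein, pairs$neg)]
  }
  structure(list(pairs = pairs, D = D, source_names = source_names),
            class = "rank_loss_problem")
}

#' @export
print.rank_loss_problem <- function(x, ...) {
  cat("<rank_loss_problem> ", nrow(x$D), " rank pairs, ",
      ncol(x$D), " sources (", paste(x$source_names, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# hinge rank loss and a subgradient at w; canonical pull towards uniform
rank_loss_objective <- function(D, w, canonical = 0) {
  viol <- pmax(0, -as.vector(D %*% w))
  obj <- sum(viol)
  if (canonical > 0) obj <- obj + canonical * sum(abs(w - 1 / length(w)))
  obj
}

rank_loss_subgradient <- function(D, w, canonical = 0) {
  active <- as.vector(D %*% w) < 0
  g <- if (any(active)) -colSums(D[active, , drop = FALSE]) else rep(0, ncol(D))
  if (canonical > 0) g <- g + canonical * sign(w - 1 / length(w))
  g
}

#' Learn global source weights by rank-loss minimisation (MS-W-kNN)
#'
#' Solves the large-margin weight-learning program
#' \deqn{\min_{w, \xi} \sum_i \sum_{y \in Y_i, \bar y \in \bar Y_i}
#'   \xi_i(y, \bar y) \quad \mathrm{s.t.}\;
#'   w^\top(f(x_i, y) - f(x_i, \bar y)) \ge -\xi_i(y, \bar y),\;
#'   \xi \ge 0,\; w^\top e = 1,\; w \ge 0,}
#' i.e. it places the weight vector on the simplex so that, summed over all
#' rank pairs, true terms outscore false terms with minimal total hinge
#' violation. The slack variables are eliminated analytically
#' (\eqn{\xi = \max(0, -w^\top d)}), leaving a convex piecewise-linear
#' objective over the simplex that is minimised exactly by a cutting-plane
#' loop whose small master linear programs are solved with
#' [pracma::linprog()]. Flat (degenerate) optima are canonicalised by a
#' `1e-9` secondary pull towards the uniform vector, making the returned
#' vertex reproducible.
#'
#' @param problem A [rank_loss_problem()].
#' @param max_iter Cutting-plane iteration cap (default 300).
#' @param tol Upper/lower bound gap at which to stop (default 1e-10).
#' @return An object of class `msknn_weights`: fields `w` (named weights),
#'   `objective` (the hinge objective at `w`), `n_pairs`, `iterations`,
#'   `converged`. Has [tidy()] and [glance()] methods.
#' @export
learn_weights <- function(problem, max_iter = 300, tol = 1e-10) {
  stopifnot(inherits(problem, "rank_loss_problem"))
  D <- problem$D
  m <- ncol(D)
  if (m == 1) {
    return(new_msknn_weights(set_names(1, problem$source_names),
                             rank_loss_objective(D, 1), nrow(D), 0L, TRUE))
  }
  scale <- max(abs(D))
  if (scale == 0) {
    # every pair has identical per-source scores: objective is flat,
    # the canonical solution is the uniform vector
    return(new_msknn_weights(set_names(rep(1 / m, m), problem$source_names),
                             0, nrow(D), 0L, TRUE))
  }
  canonical <- 1e-9 * scale
  add_cut <- function(w) {
    obj <- rank_loss_objective(D, w, canonical)
    g <- rank_loss_subgradient(D, w, canonical)
    cut <- c(g, obj - sum(g * w))
    dup <- FALSE
    if (!is.null(cuts[["g"]])) {
      d <- abs(cuts$g - matrix(cut[seq_len(m)], nrow(cuts$g), m, byrow = TRUE))
      dup <- any(rowSums(d) + abs(cuts$b - cut[m + 1]) < 1e-12 * max(1, scale))
    }
    if (!dup) {
      cuts$g <<- rbind(cuts$g, cut[seq_len(m)])
      cuts$b <<- c(cuts$b, cut[m + 1])
    }
    if (obj < best$obj) best <<- list(obj = obj, w = w)
    dup
  }
  cuts <- list(g = NULL, b = NULL)
  best <- list(obj = Inf, w = NULL)
  # initial bundle: simplex vertices + uniform
  pts <- rbind(diag(m), rep(1 / m, m))
  for (i in seq_len(nrow(pts))) add_cut(pts[i, ])

  solve_master <- function() {
    # min t  s.t.  t >= g_i.w + b_i, sum w = 1, w >= 0, t >= 0
    cc <- c(rep(0, m), 1)
    A <- cbind(cuts$g, -1)
    b <- -cuts$b
    tryCatch(
      pracma::linprog(cc, A = A, b = b,
                      Aeq = matrix(c(rep(1, m), 0), 1), beq = 1,
                      maxiter = 2000L + 20L * nrow(A)),
      error = function(e) NULL
    )
  }
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    sol <- solve_master()
    if (is.null(sol) || is.null(sol$x) || !isTRUE(sol$errno == 1)) {
      # numerically degenerate bundle: keep the strongest recent cuts and retry
      keep <- unique(c(seq_len(min(m + 1, length(cuts$b))),
                       utils::tail(seq_along(cuts$b), 20)))
      cuts$g <- cuts$g[keep, , drop = FALSE]
      cuts$b <- cuts$b[keep]
      sol <- solve_master()
      if (is.null(sol) || is.null(sol$x) || !isTRUE(sol$errno == 1)) break
    }
    w <- pmax(sol$x[seq_len(m)], 0)
    w <- w / sum(w)
    lower <- sol$fval
    dup <- add_cut(w)
    if (best$obj - lower <= tol * max(1, abs(best$obj)) || dup) {
      # a repeated support point means the model is already exact at w
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("cutting-plane loop stopped before certifying optimality; returning best iterate")
  }
  new_msknn_weights(set_names(best$w, problem$source_names),
                    rank_loss_objective(D, best$w), nrow(D),
                    iterations, converged)
}

new_msknn_weights <- function(w, objective, n_pairs, iterations, converged) {
  structure(list(w = w, objective = objective, n_pairs = n_pairs,
                 iterations = iterations, converged = converged),
            class = "msknn_weights")
}

#' @export
print.msknn_weights <- function(x, ...) {
  cat("<msknn_weights> rank-loss objective ", format(x$objective),
      " over ", x$n_pairs, " pairs\n", sep = "")
  print(round(x$w, 4))
  invisible(x)
}

#' @rdname learn_weights
#' @param x An `msknn_weights` object.
#' @param ... Unused.
#' @method tidy msknn_weights
#' @export
tidy.msknn_weights <- function(x, ...) {
  tibble(source = names(x$w), weight = unname(x$w))
}

#' @rdname learn_weights
#' @method glance msknn_weights
#' @export
glance.msknn_weights <- function(x, ...) {
  tibble(objective = x$objective, n_pairs = x$n_pairs,
         n_sources = length(x$w), iterations = x$iterations,
         converged = x$converged)
}

#' @rdname learn_weights
#' @export
as_weight_vector <- function(x) {
  stopifnot(inherits(x, "msknn_weights"))
  weight_vector(x$w / sum(x$w), names(x$w))
}

#' Learn cluster-specific source weights (MS-CW-kNN)
#'
#' Solves the rank-loss program independently on each ontology cluster,
#' restricted to the rank pairs whose positive and negative terms both fall
#' in that cluster. A cluster with no training pairs falls back to uniform
#' weights (with a message). A cluster's weights apply to all its terms.
#'
#' @param problem A [rank_loss_problem()].
#' @param clusters A tibble with columns `term` and `cluster` (see
#'   [cluster_terms()]) covering every term in the problem.
#' @inheritParams learn_weights
#' @return A named list of `msknn_weights`, one per cluster.
#' @export
learn_cluster_weights <- function(problem, clusters, max_iter = 300,
                                  tol = 1e-10) {
  stopifnot(inherits(problem, "rank_loss_problem"))
  cl <- set_names(clusters$cluster, clusters$term)
  used <- unique(c(problem$pairs$pos, problem$pairs$neg))
  miss <- setdiff(used, names(cl))
  if (length(miss) > 0) {
    abort(paste0("terms without a cluster id: ", paste(miss, collapse = ", ")))
  }
  m <- ncol(problem$D)
  out <- list()
  for (cid in sort(unique(unname(cl)))) {
    keep <- cl[problem$pairs$pos] == cid & cl[problem$pairs$neg] == cid
    if (!any(keep)) {
      inform(paste0("cluster '", cid,
                    "' has no rank pairs; falling back to uniform weights"))
      out[[cid]] <- new_msknn_weights(
        set_names(rep(1 / m, m), problem$source_names), NA_real_, 0L, 0L, TRUE)
      next
    }
    sub <- structure(list(pairs = problem$pairs[keep, , drop = FALSE],
                          D = problem$D[keep, , drop = FALSE],
                          source_names = problem$source_names),
                     class = "rank_loss_problem")
    out[[cid]] <- learn_weights(sub, max_iter = max_iter, tol = tol)
  }
  out
}

#' Apply cluster-specific weights to per-source scores
#'
#' @param scores List of `m` aligned [score_table()]s.
#' @param cluster_weights Named list of `msknn_weights` from
#'   [learn_cluster_weights()].
#' @param clusters Tibble with columns `term`, `cluster` covering the score
#'   tables' terms; terms whose cluster has no learned weights get uniform
#'   weights.
#' @return A [score_table()] named `"ms-cw-knn"`.
#' @export
weighted_average_by_cluster <- function(scores, cluster_weights, clusters) {
  do.call(check_same_grid, unname(scores))
  ref <- scores[[1]]
  m <- length(scores)
  cl <- set_names(clusters$cluster, clusters$term)
  terms <- score_terms(ref)
  acc <- matrix(0, length(score_proteins(ref)), length(terms),
                dimnames = list(score_proteins(ref), terms))
  wides <- lapply(scores, score_wide)
  for (f in terms) {
    cid <- cl[[f]]
    w <- if (!is.null(cid) && cid %in% names(cluster_weights)) {
      cluster_weights[[cid]]$w
    } else {
      rep(1 / m, m)
    }
    for (j in seq_len(m)) acc[, f] <- acc[, f] + w[[j]] * wides[[j]][, f]
  }
  covered <- Reduce(`|`, lapply(scores, score_covered))
  score_from_wide(acc, source = "ms-cw-knn", covered = covered)
}

#' Read / write weight vectors as JSON
#'
#' Serialised as a flat `{source_name: weight}` object.
#'
#' @param w A [weight_vector()] or `msknn_weights`.
#' @param path File path.
#' @return [write_weights()]: `path`, invisibly; [read_weights()]: a
#'   [weight_vector()].
#' @export
write_weights <- function(w, path) {
  if (inherits(w, "msknn_weights")) w <- as_weight_vector(w)
  stopifnot(inherits(w, "weight_vector"))
  jsonlite::write_json(as.list(w$w), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  weight_vector(unlist(x), names(x))
}
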
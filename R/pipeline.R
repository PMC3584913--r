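#' Run the full multi-source prediction pipeline
#'
#' Scores every query against every term on each provided similarity
#' source with [score_all()], then integrates the per-source score tables
#' with the chosen scheme: plain three-group averaging (`"average"`, the
#' CAFA predictor), globally learned weights (`"weighted"`) or
#' ontology-cluster-specific weights (`"cluster"`). Weight learning uses
#' the training proteins' own per-source scores as features. Sources
#' missing a query contribute a zero score (the CAFA missing-source rule).
#'
#' @param sources Named list of [sim_source][identity_source()]s; names
#'   among `seq`, `ppi`, `expr` (an `expr` entry may itself be a list of
#'   sources, one per expression dataset).
#' @param queries,training Character vectors of protein ids.
#' @param ann Training [annotation_table()] (raw or propagated; the inner
#'   vote uses it as given).
#' @param terms Term ids to score.
#' @param dag An [ontology_dag()] (needed for `mode = "linsim"` and
#'   `integration = "cluster"`).
#' @param k Neighbourhood size (default 20).
#' @param mode `"plain"` or `"linsim"` per-source scoring.
#' @param integration `"average"`, `"weighted"` or `"cluster"`.
#' @param cluster_level `"root"` or `"first"` (for `"cluster"`).
#' @param tau Lin-similarity threshold (for `mode = "linsim"`).
#' @param probs Optional [term_probabilities()] (computed from the
#'   propagated training annotations when needed and absent).
#' @param max_pairs,weight_seed Rank-pair cap and subsample seed for
#'   weight learning.
#' @param renormalize Passed to [average_scores()].
#' @return A list: `integrated` (a [score_table()]), `per_source` (named
#'   list of score tables) and, for learned schemes, `weights`.
#' @export
predict_functions <- function(sources, queries, training, ann, terms,
                              dag = NULL, k = 20,
                              mode = c("plain", "linsim"),
                              integration = c("average", "weighted",
                                              "cluster"),
                              cluster_level = c("root", "first"),
                              tau = 0, probs = NULL,
                              max_pairs = 10000, weight_seed = 1,
                              renormalize = FALSE) {
  mode <- arg_match(mode)
  integration <- arg_match(integration)
  cluster_level <- arg_match(cluster_level)
  known <- c("seq", "ppi", "expr")
  if (is.null(names(sources)) || !all(names(sources) %in% known)) {
    abort("`sources` must be a named list with names among seq, ppi, expr")
  }
  if (mode == "linsim" && is.null(probs)) {
    if (is.null(dag)) abort("mode = \"linsim\" requires `dag`")
    probs <- term_probabilities(propagate_annotations(ann, dag), dag)
  }
  expr_sources <- sources$expr
  if (inherits(expr_sources, "sim_source")) expr_sources <- list(expr_sources)

  run1 <- function(src) {
    score_all(src, queries, terms, training, ann, k = k, mode = mode,
              dag = dag, probs = probs, tau = tau)
  }
  per_source <- list()
  if (!is.null(sources$seq)) per_source$seq <- run1(sources$seq)
  if (!is.null(sources$ppi)) per_source$ppi <- run1(sources$ppi)
  if (!is.null(expr_sources)) {
    per_source$expr <- lapply(expr_sources, run1)
    if (length(per_source$expr) == 1) per_source$expr <- per_source$expr[[1]]
  }

  if (integration == "average") {
    integrated <- average_scores(seq = per_source$seq, ppi = per_source$ppi,
                                 expr = per_source$expr,
                                 renormalize = renormalize)
    return(list(integrated = integrated, per_source = per_source))
  }

  # learned schemes: features are the training proteins' own source scores
  group_scores <- function(who) {
    train_tabs <- list()
    if (!is.null(sources$seq)) {
      train_tabs$seq <- score_all(sources$seq, who, terms, training, ann,
                                  k = k, mode = mode, dag = dag,
                                  probs = probs, tau = tau)
    }
    if (!is.null(sources$ppi)) {
      train_tabs$ppi <- score_all(sources$ppi, who, terms, training, ann,
                                  k = k, mode = mode, dag = dag,
                                  probs = probs, tau = tau)
    }
    if (!is.null(expr_sources)) {
      exprs <- lapply(expr_sources, function(s) {
        score_all(s, who, terms, training, ann, k = k, mode = mode,
                  dag = dag, probs = probs, tau = tau)
      })
      train_tabs$expr <- if (length(exprs) == 1) exprs[[1]] else {
        avg <- Reduce(`+`, lapply(exprs, score_wide)) / length(exprs)
        score_from_wide(avg, source = "expression",
                        covered = Reduce(`|`, lapply(exprs, score_covered)))
      }
    }
    train_tabs
  }
  train_feats <- group_scores(training)
  problem <- rank_loss_problem(train_feats, ann, max_pairs = max_pairs,
                               seed = weight_seed)

  query_tabs <- per_source
  if (!is.null(query_tabs$expr) && is.list(query_tabs$expr) &&
      !inherits(query_tabs$expr, "score_tbl")) {
    avg <- Reduce(`+`, lapply(query_tabs$expr, score_wide)) /
      length(query_tabs$expr)
    query_tabs$expr <- score_from_wide(
      avg, source = "expression",
      covered = Reduce(`|`, lapply(query_tabs$expr, score_covered)))
  }
  query_tabs <- query_tabs[names(train_feats)]

  if (integration == "weighted") {
    fit <- learn_weights(problem)
    integrated <- weighted_average(query_tabs, as_weight_vector(fit))
    return(list(integrated = integrated, per_source = per_source,
                weights = fit))
  }
  if (is.null(dag)) abort("integration = \"cluster\" requires `dag`")
  clusters <- cluster_terms(dag, level = cluster_level)
  fits <- learn_cluster_weights(problem, clusters)
  integrated <- weighted_average_by_cluster(query_tabs, fits, clusters)
  list(integrated = integrated, per_source = per_source, weights = fits)
}

#' Truncate predictions to a CAFA submission
#'
#' CAFA caps a submission at 1000 terms per protein: scores are sorted per
#' protein and only the top `top` terms kept, with ties at the cutoff rank
#' broken by term id; zero-score rows are dropped first.
#'
#' @param pred A [score_table()] (or tibble with `protein`, `term`,
#'   `score`).
#' @param top Maximum terms per protein (default 1000).
#' @return A tibble with at most `top` rows per protein, ordered by
#'   protein, descending score, term id.
#' @export
cafa_submission <- function(pred, top = 1000) {
  as_tibble(pred) %>%
    filter(score > 0) %>%
    arrange(protein, dplyr::desc(score), term) %>%
    group_by(protein) %>%
    slice(seq_len(min(top, n()))) %>%
    ungroup()
}

#' Evaluate predictions with the four CAFA measures
#'
#' Computes the term-centric AUC and the three protein-centric sweeps
#' (threshold, top-N, information-content-weighted threshold) against a
#' gold annotation table.
#'
#' @param pred A [score_table()] over the test proteins.
#' @param gold An [annotation_table()] of the test proteins' true
#'   annotations (propagated here if raw).
#' @param dag An [ontology_dag()].
#' @param min_count Term eligibility threshold for [term_auc()] (default
#'   15).
#' @param n_top Top-N size (default 20).
#' @param ic Optional information-content table; computed from `gold`
#'   when absent.
#' @param thresholds Optional threshold grid for the sweeps.
#' @return An object of class `msknn_eval` with fields `term_auc`,
#'   `threshold`, `topn`, `weighted`; [glance()] collapses it to one row.
#' @export
evaluate_predictions <- function(pred, gold, dag, min_count = 15,
                                 n_top = 20, ic = NULL, thresholds = NULL) {
  if (nrow(gold) == 0) abort("gold annotation table is empty")
  if (!is_propagated(gold)) gold <- propagate_annotations(gold, dag)
  if (is.null(ic)) {
    ic <- information_content(gold, terms = union(score_terms(pred),
                                                  unique(gold$term)))
  }
  res <- list(
    term_auc = term_auc(pred, gold, min_count = min_count),
    threshold = protein_threshold_curve(pred, gold, dag,
                                        thresholds = thresholds),
    topn = topn_metric(pred, gold, n = n_top),
    weighted = weighted_threshold_curve(pred, gold, dag, ic,
                                        thresholds = thresholds)
  )
  structure(res, class = "msknn_eval")
}

#' @export
print.msknn_eval <- function(x, ...) {
  cat("<msknn_eval>\n")
  print(glance(x))
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x An `msknn_eval` object.
#' @param ... Unused.
#' @method glance msknn_eval
#' @export
glance.msknn_eval <- function(x, ...) {
  tibble(
    term_auc = x$term_auc$macro,
    threshold_area = curve_area(x$threshold),
    topn_area = attr(x$topn, "area"),
    weighted_area = curve_area(x$weighted),
    n_terms = nrow(x$term_auc$per_term)
  )
}

#' Write an evaluation report to JSON (+ per-term TSV)
#'
#' @param eval An [evaluate_predictions()] result.
#' @param path Output JSON path; a sibling `<path>.terms.tsv` gets the
#'   per-term AUC table.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  stopifnot(inherits(eval, "msknn_eval"))
  report <- list(
    summary = as.list(glance(eval)),
    term_auc = list(macro = eval$term_auc$macro,
                    per_term = eval$term_auc$per_term),
    threshold = list(area = curve_area(eval$threshold),
                     curve = as_tibble(eval$threshold)),
    topn = list(area = attr(eval$topn, "area"),
                precision = attr(eval$topn, "precision"),
                recall = attr(eval$topn, "recall")),
    weighted = list(area = curve_area(eval$weighted),
                    curve = as_tibble(eval$weighted))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  readr::write_tsv(eval$term_auc$per_term,
                   paste0(path, ".terms.tsv"))
  invisible(path)
}

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored;
#' numeric-looking values are converted. Used by the command-line
#' wrapper.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort(paste0("malformed config line: ", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
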
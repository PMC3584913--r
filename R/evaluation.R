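#' Rank-based ROC AUC
#'
#' The Mann-Whitney statistic: the probability that a random positive
#' outscores a random negative, with ties counted one half. Equivalent to
#' trapezoidal integration of the ROC curve. A single-class input has no
#' ROC curve; the result is "undefined" (`NA`), and such terms are
#' excluded from macro averages.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), same length.
#' @return The AUC in `[0, 1]`, or `NA_real_` for single-class input.
#' @export
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Term-centric AUC (the function-centric CAFA measure)
#'
#' For each eligible term, all test proteins are ranked by their predicted
#' score for that term and the rank AUC is computed against the term's
#' gold labels; the macro average is taken over eligible terms with a
#' defined AUC. A term is eligible when at least `min_count` test proteins
#' are annotated with it (the pre-CAFA analysis used more than 15, the
#' CAFA assessment more than 25).
#'
#' @param pred A [score_table()] covering the test proteins.
#' @param gold A propagated [annotation_table()] of the test proteins'
#'   true annotations.
#' @param min_count Minimum number of annotated test proteins for a term
#'   to be evaluated (default 15).
#' @return An object of class `term_auc`: per-term tibble (`term`,
#'   `n_pos`, `auc`) plus the macro average; has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
term_auc <- function(pred, gold, min_count = 15) {
  if (!is_propagated(gold)) abort("`gold` must be a propagated annotation table")
  proteins <- score_proteins(pred)
  gold <- filter(as_tibble(gold), protein %in% proteins)
  counts <- count(gold, term, name = "n_pos")
  eligible <- filter(counts, n_pos >= min_count)$term
  eligible <- intersect(eligible, score_terms(pred))
  if (length(eligible) == 0) {
    abort(paste0("no eligible terms: none annotate at least ", min_count,
                 " test proteins"))
  }
  wide <- score_wide(pred)
  gold_sets <- split(gold$protein, gold$term)
  per_term <- purrr::map_dfr(eligible, function(f) {
    labels <- proteins %in% gold_sets[[f]]
    tibble(term = f, n_pos = sum(labels),
           auc = rank_auc(wide[, f], labels))
  })
  macro <- mean(per_term$auc, na.rm = TRUE)
  structure(list(per_term = per_term, macro = macro,
                 min_count = min_count, n_proteins = length(proteins)),
            class = "term_auc")
}

#' @export
print.term_auc <- function(x, ...) {
  cat("<term_auc> macro AUC ", round(x$macro, 4), " over ",
      nrow(x$per_term), " eligible terms (min_count = ", x$min_count,
      ", ", x$n_proteins, " test proteins)\n", sep = "")
  invisible(x)
}

#' @rdname term_auc
#' @param x A `term_auc` object.
#' @param ... Unused.
#' @method tidy term_auc
#' @export
tidy.term_auc <- function(x, ...) x$per_term

#' @rdname term_auc
#' @method glance term_auc
#' @export
glance.term_auc <- function(x, ...) {
  tibble(macro_auc = x$macro, n_terms = nrow(x$per_term),
         n_undefined = sum(is.na(x$per_term$auc)),
         min_count = x$min_count, n_proteins = x$n_proteins)
}

#' @rdname term_auc
#' @param object A `term_auc` object.
#' @method autoplot term_auc
#' @export
autoplot.term_auc <- function(object, ...) {
  ggplot2::ggplot(object$per_term, ggplot2::aes(x = auc)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$macro, linetype = 2) +
    ggplot2::labs(x = "per-term AUC", y = "terms",
                  title = paste0("Term-centric AUC (macro = ",
                                 round(object$macro, 3), ")")) +
    ggplot2::theme_minimal()
}

#' Information content of annotated terms
#'
#' The negative log frequency of a term among the annotated proteins of a
#' reference corpus, used to weight precision/recall so that rare,
#' specific terms count more. After propagation the root has frequency 1
#' and IC 0. Natural logs are used (scale only). Terms absent from the
#' corpus get the `epsilon`-floored IC `-log(epsilon)`.
#'
#' @param ann A propagated, non-empty [annotation_table()] (the reference
#'   corpus).
#' @param terms Optional terms to report (default: annotated terms).
#' @param epsilon Frequency floor for unannotated terms (default `1e-9`).
#' @return A tibble with columns `term` and `ic`.
#' @export
information_content <- function(ann, terms = NULL, epsilon = 1e-9) {
  if (nrow(ann) == 0) abort("annotation table is empty")
  if (!is_propagated(ann)) abort("`ann` must be propagated")
  n_prot <- dplyr::n_distinct(ann$protein)
  counts <- count(as_tibble(ann), term, name = "n_annotated")
  if (is.null(terms)) terms <- sort(unique(ann$term))
  tibble(term = terms) %>%
    left_join(counts, by = "term") %>%
    mutate(freq = pmax(dplyr::coalesce(n_annotated, 0L) / n_prot, epsilon),
           ic = -log(freq)) %>%
    select(term, ic)
}

#' Default threshold grid for precision-recall sweeps
#'
#' kNN scores are unnormalised sums, so a fixed 0-1 grid would collapse;
#' instead 101 evenly spaced quantiles of the score distribution are used
#' (plus a threshold above the maximum so the empty-prediction end of the
#' curve exists).
#'
#' @param pred A [score_table()].
#' @param n Number of quantiles (default 101).
#' @return A sorted numeric vector of thresholds.
#' @export
default_thresholds <- function(pred, n = 101) {
  s <- pred$score
  qs <- unname(quantile(s, probs = seq(0, 1, length.out = n), names = FALSE))
  sort(unique(c(qs, max(s) + 1e-9)))
}

#' Protein-centric precision-recall sweep (the Threshold measure)
#'
#' At each threshold, the terms scored strictly above it are propagated
#' towards the root, and per-protein precision and recall of that closed
#' set against the propagated gold annotation are computed. Precision is
#' averaged over proteins with at least one prediction at that threshold
#' (a convention the assessment leaves open); recall over all evaluated
#' proteins. The summary area is the trapezoid under the recall-ordered
#' precision curve; the raw curve is returned so alternative integration
#' conventions can be applied.
#'
#' @param pred A [score_table()].
#' @param gold A propagated [annotation_table()] of the same test
#'   proteins.
#' @param dag An [ontology_dag()].
#' @param thresholds Ascending thresholds (default:
#'   [default_thresholds()]).
#' @return An object of class `pr_curve`: tibble (`threshold`,
#'   `precision`, `recall`, `n_predicted`) with an `area` attribute; has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
protein_threshold_curve <- function(pred, gold, dag, thresholds = NULL) {
  pr_sweep(pred, gold, dag, thresholds, weights = NULL, propagate = TRUE,
           measure = "threshold")
}

#' Information-content weighted precision-recall sweep
#'
#' Identical mechanics to [protein_threshold_curve()], but each term
#' counts with its information-content weight instead of 1 in the
#' true-positive, predicted and gold masses. With unit IC it reproduces
#' the unweighted sweep exactly.
#'
#' @inheritParams protein_threshold_curve
#' @param ic A tibble with columns `term`, `ic` (see
#'   [information_content()]) covering every evaluated term.
#' @return A `pr_curve` object.
#' @export
weighted_threshold_curve <- function(pred, gold, dag, ic, thresholds = NULL) {
  w <- set_names(ic$ic, ic$term)
  pr_sweep(pred, gold, dag, thresholds, weights = w, propagate = TRUE,
           measure = "weighted threshold")
}

pr_sweep <- function(pred, gold, dag, thresholds, weights, propagate,
                     measure) {
  if (!is_propagated(gold)) abort("`gold` must be a propagated annotation table")
  if (!is.null(thresholds) && length(thresholds) == 0) {
    abort("empty threshold list")
  }
  if (is.null(thresholds)) thresholds <- default_thresholds(pred)
  thresholds <- sort(thresholds)
  proteins <- intersect(score_proteins(pred), unique(gold$protein))
  if (length(proteins) == 0) abort("no test protein has gold annotations")
  terms <- score_terms(pred)
  if (!is.null(weights)) {
    need <- unique(c(terms, gold$term))
    miss <- setdiff(need, names(weights))
    if (length(miss) > 0) {
      abort(paste0("terms without an information-content weight: ",
                   paste(head(miss, 5), collapse = ", ")))
    }
  }
  wt <- function(f) if (is.null(weights)) length(f) else sum(weights[f])
  wide <- score_wide(pred)
  gold_sets <- split(filter(as_tibble(gold), protein %in% proteins)$term,
                     filter(as_tibble(gold), protein %in% proteins)$protein)
  curve <- purrr::map_dfr(thresholds, function(t) {
    precs <- c(); recs <- c(); n_pred <- 0L
    for (pr in proteins) {
      above <- terms[wide[pr, ] > t]
      predset <- if (propagate && length(above) > 0) {
        unique(unlist(dag$ancestors[above], use.names = FALSE))
      } else above
      gd <- gold_sets[[pr]]
      if (length(predset) > 0) {
        n_pred <- n_pred + 1L
        tp <- wt(intersect(predset, gd))
        precs <- c(precs, tp / wt(predset))
        recs <- c(recs, tp / wt(gd))
      } else {
        recs <- c(recs, 0)
      }
    }
    tibble(threshold = t,
           precision = if (n_pred > 0) mean(precs) else NA_real_,
           recall = mean(recs),
           n_predicted = n_pred)
  })
  area <- pr_area(curve$recall, curve$precision)
  structure(curve, class = c("pr_curve", class(tibble())),
            area = area, measure = measure)
}

# trapezoid over the recall-ordered curve, NA precisions dropped
pr_area <- function(recall, precision) {
  keep <- !is.na(precision)
  r <- recall[keep]; p <- precision[keep]
  if (length(r) < 2) return(NA_real_)
  ord <- order(r)
  r <- r[ord]; p <- p[ord]
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

#' @rdname protein_threshold_curve
#' @param curve A `pr_curve` object.
#' @export
curve_area <- function(curve) attr(curve, "area")

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve> ", attr(x, "measure"), " sweep, ", nrow(x),
      " thresholds, area ", round(attr(x, "area"), 4), "\n", sep = "")
  NextMethod()
}

#' @rdname protein_threshold_curve
#' @param x,object A `pr_curve` object.
#' @param ... Unused.
#' @method glance pr_curve
#' @export
glance.pr_curve <- function(x, ...) {
  tibble(measure = attr(x, "measure"), area = attr(x, "area"),
         n_thresholds = nrow(x))
}

#' @rdname protein_threshold_curve
#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(precision))
  ggplot2::ggplot(df, ggplot2::aes(x = recall, y = precision)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = paste0(attr(object, "measure"), " sweep (area = ",
                                 round(attr(object, "area"), 3), ")")) +
    ggplot2::theme_minimal()
}

#' Top-N precision and recall
#'
#' For each protein the `n` highest-scoring terms are retained, expanding
#' to include every term tied with the n-th score; zero-score terms are
#' never retained, and a protein with no nonzero score is skipped (with a
#' message). Precision and recall of the retained set are computed against
#' the propagated gold annotation. The summary area runs the threshold
#' sweep on the top-n-restricted score table.
#'
#' @param pred A [score_table()].
#' @param gold A propagated [annotation_table()].
#' @param n Number of top scores to keep (default 20).
#' @return An object of class `topn_metric`: per-protein tibble
#'   (`protein`, `n_retained`, `precision`, `recall`) with macro averages
#'   and the restricted-sweep area as attributes; has [tidy()] and
#'   [glance()] methods.
#' @export
topn_metric <- function(pred, gold, n = 20) {
  stopifnot(n >= 1)
  if (!is_propagated(gold)) abort("`gold` must be a propagated annotation table")
  proteins <- intersect(score_proteins(pred), unique(gold$protein))
  terms <- score_terms(pred)
  wide <- score_wide(pred)
  gold_sets <- split(filter(as_tibble(gold), protein %in% proteins)$term,
                     filter(as_tibble(gold), protein %in% proteins)$protein)
  skipped <- character(0)
  rows <- list()
  restricted <- wide * 0
  for (pr in proteins) {
    s <- wide[pr, ]
    nz <- s[s > 0]
    if (length(nz) == 0) { skipped <- c(skipped, pr); next }
    cutoff <- if (length(nz) >= n) sort(nz, decreasing = TRUE)[n] else min(nz)
    retained <- names(s)[s >= cutoff & s > 0]
    restricted[pr, retained] <- s[retained]
    gd <- gold_sets[[pr]]
    tp <- length(intersect(retained, gd))
    rows[[pr]] <- tibble(protein = pr, n_retained = length(retained),
                         precision = tp / length(retained),
                         recall = tp / length(gd))
  }
  if (length(skipped) > 0) {
    inform(paste0("skipping ", length(skipped),
                  " protein(s) with no nonzero scores"))
  }
  if (length(rows) == 0) abort("every protein had only zero scores")
  per_protein <- bind_rows(rows)
  sub <- score_from_wide(restricted, source = attr(pred, "source_name"))
  sweep <- pr_sweep(sub, gold, dag = NULL, thresholds = NULL, weights = NULL,
                    propagate = FALSE, measure = "top-n")
  structure(per_protein,
            class = c("topn_metric", class(tibble())),
            n = n, skipped = skipped,
            precision = mean(per_protein$precision),
            recall = mean(per_protein$recall),
            area = attr(sweep, "area"), curve = sweep)
}

#' @export
print.topn_metric <- function(x, ...) {
  cat("<topn_metric> n = ", attr(x, "n"), ": macro precision ",
      round(attr(x, "precision"), 4), ", macro recall ",
      round(attr(x, "recall"), 4), ", area ",
      round(attr(x, "area"), 4), "\n", sep = "")
  NextMethod()
}

#' @rdname topn_metric
#' @param x A `topn_metric` object.
#' @param ... Unused.
#' @method glance topn_metric
#' @export
glance.topn_metric <- function(x, ...) {
  tibble(n = attr(x, "n"), precision = attr(x, "precision"),
         recall = attr(x, "recall"), area = attr(x, "area"),
         n_proteins = nrow(x), n_skipped = length(attr(x, "skipped")))
}
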
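#' Prediction score tables
#'
#' Prediction scores for one predictor are kept tidy: one row per
#' (protein, term) cell over a complete protein x term grid, with the
#' source name and a per-protein coverage flag as attributes. A protein not
#' covered by the underlying similarity source keeps an all-zero row and
#' `covered = FALSE`, so integration can distinguish "no signal" from
#' "source absent".
#'
#' @param x A data frame with columns `protein`, `term`, `score`; missing
#'   cells of the grid are filled with 0.
#' @param source Name of the producing source/predictor.
#' @param proteins,terms Optional orderings of the grid axes (defaults:
#'   sorted ids present in `x`).
#' @param covered Optional named logical vector over proteins (default: all
#'   `TRUE`).
#' @return A tibble of class `score_tbl`.
#' @export
score_table <- function(x, source = "scores", proteins = NULL, terms = NULL,
                        covered = NULL) {
  x <- as_tibble(x)
  stopifnot(all(c("protein", "term", "score") %in% names(x)))
  if (is.null(proteins)) proteins <- sort(unique(x$protein))
  if (is.null(terms)) terms <- sort(unique(x$term))
  if (length(terms) == 0) abort("empty term list")
  grid <- tidyr::expand_grid(protein = proteins, term = terms)
  out <- left_join(grid, select(x, protein, term, score),
                   by = c("protein", "term")) %>%
    mutate(score = dplyr::coalesce(score, 0))
  if (is.null(covered)) covered <- set_names(rep(TRUE, length(proteins)), proteins)
  stopifnot(setequal(names(covered), proteins))
  structure(out, class = c("score_tbl", class(tibble())),
            source_name = source, proteins = proteins, terms = terms,
            covered = covered[proteins])
}

score_proteins <- function(st) attr(st, "proteins")
score_terms <- function(st) attr(st, "terms")

#' @rdname score_table
#' @param st A `score_tbl`.
#' @export
score_covered <- function(st) attr(st, "covered")

# proteins x terms dense matrix view
score_wide <- function(st) {
  m <- matrix(st$score, nrow = length(score_proteins(st)),
              ncol = length(score_terms(st)), byrow = TRUE,
              dimnames = list(score_proteins(st), score_terms(st)))
  m
}

score_from_wide <- function(mat, source = "scores", covered = NULL) {
  df <- tibble(
    protein = rep(rownames(mat), each = ncol(mat)),
    term = rep(colnames(mat), times = nrow(mat)),
    score = as.vector(t(mat))
  )
  score_table(df, source = source, proteins = rownames(mat),
              terms = colnames(mat), covered = covered)
}

check_same_grid <- function(...) {
  sts <- list(...)
  ref <- sts[[1]]
  for (st in sts[-1]) {
    if (!identical(score_proteins(st), score_proteins(ref)) ||
        !identical(score_terms(st), score_terms(ref))) {
      abort("score tables must share identical protein and term orderings")
    }
  }
  invisible(ref)
}

#' Read / write prediction score TSVs
#'
#' The serialized triple format `protein_id`, `term_id`, `score` — the same
#' layout used for CAFA submissions before top-1000 truncation.
#'
#' @param path File path.
#' @param source Source name stored on the table.
#' @return [read_scores()]: a [score_table()]; [write_scores()]: `path`,
#'   invisibly.
#' @export
read_scores <- function(path, source = "scores") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = "c", term_id = "c", score = "d"))
  score_table(rename(df, protein = "protein_id", term = "term_id"),
              source = source)
}

#' @rdname read_scores
#' @param st A [score_table()] (or any tibble with `protein`, `term`,
#'   `score`).
#' @param digits If non-`NULL`, scores are rounded to this many decimals
#'   before writing (CAFA submissions print 2).
#' @param drop_zero Drop zero-score rows (default `FALSE`).
#' @export
write_scores <- function(st, path, digits = NULL, drop_zero = FALSE) {
  out <- as_tibble(st)[, c("protein", "term", "score")]
  if (drop_zero) out <- filter(out, score != 0)
  if (!is.null(digits)) out$score <- round(out$score, digits)
  readr::write_tsv(rename(out, protein_id = "protein", term_id = "term"), path)
  invisible(path)
}
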
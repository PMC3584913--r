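test_that("three-group averaging reproduces the published worked example", {
  # per-source scores (expression pre-averaged) -> integrated average
  cells <- list(
    SYK  = c(0.14, 0, 2.17, 0.77),
    NOS3 = c(0.23, 0, 1.95, 0.73),
    NOS1 = c(0.29, 0, 1.92, 0.74),
    OAZ2 = c(0.17, 0, 1.80, 0.66),
    OAZ1 = c(0.18, 0, 1.63, 0.60),
    PEPD = c(0.22, 0, 0, 0.07),
    PON1 = c(0.26, 1, 0, 0.42)
  )
  for (p in names(cells)) {
    v <- cells[[p]]
    out <- average_scores(seq = one_cell_scores(v[3]),
                          ppi = one_cell_scores(v[2]),
                          expr = one_cell_scores(v[1]))
    expect_equal(round(out$score, 2), v[4], info = p)
  }
  # all-zero sources stay zero
  z <- average_scores(seq = one_cell_scores(0), ppi = one_cell_scores(0),
                      expr = one_cell_scores(0))
  expect_equal(z$score, 0)
})

test_that("multiple expression datasets enter with the 1/(3J) coefficient", {
  out <- average_scores(seq = one_cell_scores(3), ppi = one_cell_scores(0),
                        expr = list(one_cell_scores(1), one_cell_scores(2),
                                    one_cell_scores(6)))
  expect_equal(out$score, 3 / 3 + (1 + 2 + 6) / 9)
})

test_that("missing whole sources contribute zero unless renormalized", {
  out <- average_scores(seq = one_cell_scores(3))
  expect_equal(out$score, 1)             # CAFA-faithful: 3 * 1/3
  out2 <- average_scores(seq = one_cell_scores(3), renormalize = TRUE)
  expect_equal(out2$score, 3)
})

test_that("integrated scores never decrease when a zeroed source is restored", {
  scene <- tiny_scene(seed = 23, n_proteins = 40, n_terms = 20, n_test = 10)
  st_seq <- score_all(scene$seq, scene$test, scene$terms, scene$train,
                      scene$ann, k = 5)
  st_ppi <- score_all(scene$ppi, scene$test, scene$terms, scene$train,
                      scene$ann, k = 5)
  st_exp <- score_all(scene$expr, scene$test, scene$terms, scene$train,
                      scene$ann, k = 5)
  zero_ppi <- score_table(
    dplyr::mutate(tibble::as_tibble(st_ppi), score = 0))
  full <- average_scores(seq = st_seq, ppi = st_ppi, expr = st_exp)
  holed <- average_scores(seq = st_seq, ppi = zero_ppi, expr = st_exp)
  expect_true(all(full$score >= holed$score - 1e-12))
})

test_that("weighted averaging matches hand arithmetic and the uniform identity", {
  a <- one_cell_scores(2); b <- one_cell_scores(4)
  out <- weighted_average(list(a, b), weight_vector(c(0.5, 0.5), c("a", "b")))
  expect_equal(out$score, 3)

  first <- weighted_average(list(a, b), weight_vector(c(1, 0), c("a", "b")))
  expect_equal(first$score, a$score)

  scene <- tiny_scene(seed = 29, n_proteins = 40, n_terms = 20, n_test = 8)
  st <- list(
    seq = score_all(scene$seq, scene$test, scene$terms, scene$train,
                    scene$ann, k = 5),
    ppi = score_all(scene$ppi, scene$test, scene$terms, scene$train,
                    scene$ann, k = 5),
    expr = score_all(scene$expr, scene$test, scene$terms, scene$train,
                     scene$ann, k = 5))
  uniform <- weighted_average(st, weight_vector(rep(1 / 3, 3), names(st)))
  avg <- average_scores(seq = st$seq, ppi = st$ppi, expr = st$expr)
  expect_equal(uniform$score, avg$score, tolerance = 1e-12)
  # bounded by the largest per-source score
  expect_true(all(avg$score <= pmax(st$seq$score, st$ppi$score,
                                    st$expr$score) + 1e-12))
})

test_that("weight vectors live on the simplex", {
  expect_error(weight_vector(c(0.5, 0.6)), "sum to 1")
  expect_error(weight_vector(c(1.2, -0.2)), "nonnegative")
  w <- weight_vector(c(0.25, 0.75), c("a", "b"))
  expect_equal(sum(w$w), 1)
})

test_that("rank-loss problems pair positives with annotated negatives, capped", {
  st1 <- score_table(tibble::tibble(
    protein = rep(c("p1", "p2"), each = 3),
    term = rep(c("f1", "f2", "f3"), 2),
    score = c(3, 1, 0, 0, 2, 1)), source = "s1")
  ann <- annotation_table(tibble::tibble(
    protein = c("p1", "p2"), term = c("f1", "f2")))
  prob <- rank_loss_problem(list(s1 = st1), ann)
  # p1: pos f1, neg f2 (annotated elsewhere); p2: pos f2, neg f1. f3 never
  # annotated -> never a negative.
  expect_equal(nrow(prob$D), 2)
  expect_false("f3" %in% prob$pairs$neg)
  expect_equal(sort(prob$pairs$pos), c("f1", "f2"))
  expect_equal(unname(prob$D[prob$pairs$protein == "p1", 1]), 3 - 1)

  capped <- rank_loss_problem(list(s1 = st1), ann, max_pairs = 1, seed = 4)
  expect_equal(nrow(capped$D), 1)
  capped2 <- rank_loss_problem(list(s1 = st1), ann, max_pairs = 1, seed = 4)
  expect_identical(capped$pairs, capped2$pairs)   # seeded, reproducible
})

test_that("weight learning solves the rank-loss program exactly", {
  # m = 1: the simplex is a point
  p1 <- structure(list(pairs = tibble::tibble(),
                       D = matrix(c(1, -2), 2, 1,
                                  dimnames = list(NULL, "only")),
                       source_names = "only"),
                  class = "rank_loss_problem")
  f1 <- learn_weights(p1)
  expect_equal(unname(f1$w), 1)

  # perfectly informative source vs reversing source: unique optimum (1, 0)
  set.seed(31)
  prob <- planted_problem(m = 2)
  fit <- learn_weights(prob)
  expect_equal(fit$objective, 0, tolerance = 1e-9)
  expect_equal(unname(fit$w), c(1, 0), tolerance = 1e-9)

  prob3 <- planted_problem(m = 3)
  fit3 <- learn_weights(prob3)
  expect_equal(fit3$objective, 0, tolerance = 1e-9)
  expect_equal(unname(fit3$w), c(1, 0, 0), tolerance = 1e-9)

  # duplicated identical sources: flat objective, canonical uniform returned
  set.seed(33)
  d <- rnorm(15)
  dup <- structure(list(pairs = tibble::tibble(),
                        D = cbind(s1 = d, s2 = d),
                        source_names = c("s1", "s2")),
                   class = "rank_loss_problem")
  fdup <- learn_weights(dup)
  base <- sum(pmax(0, -d))
  for (x in seq(0, 1, by = 0.25)) {
    expect_equal(sum(pmax(0, -(dup$D %*% c(x, 1 - x)))), base)
  }
  expect_equal(unname(fdup$w), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("learned objective is never worse than a fine simplex grid search", {
  set.seed(37)
  for (m in c(2, 3)) {
    for (rep in 1:3) {
      D <- matrix(rnorm(20 * m), 20, m,
                  dimnames = list(NULL, paste0("s", 1:m)))
      prob <- structure(list(pairs = tibble::tibble(), D = D,
                             source_names = colnames(D)),
                        class = "rank_loss_problem")
      fit <- learn_weights(prob)
      grid <- oracle_grid_min(D, res = if (m == 2) 1e-3 else 1e-2)
      expect_lte(fit$objective, grid + 1e-6)
    }
  }
})

test_that("weight learning recovers the single informative source", {
  # the sequence channel carries planted signal; the competitor is a
  # random similarity matrix of comparable magnitude (the hinge objective
  # is not scale-invariant, so "noise" must compete at the same scale)
  hits <- 0
  for (seed in 1:5) {
    scene <- tiny_scene(seed = 40 + seed, n_proteins = 50, n_terms = 24,
                        n_test = 0,
                        signal = c(seq = 0.9, expr = 0, ppi = 0))
    set.seed(1000 + seed)
    n <- length(scene$train)
    noise <- matrix(runif(n * n, 0, 100), n, n)
    noise <- (noise + t(noise)) / 2
    dimnames(noise) <- list(scene$train, scene$train)
    src_noise <- identity_source(noise, name = "noise")
    st <- list(
      seq = score_all(scene$seq, scene$train, scene$terms, scene$train,
                      scene$ann, k = 10),
      noise = score_all(src_noise, scene$train, scene$terms, scene$train,
                        scene$ann, k = 10))
    prob <- rank_loss_problem(st, scene$ann, max_pairs = 3000, seed = 1)
    fit <- learn_weights(prob)
    if (fit$w[["seq"]] >= 0.8) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("cluster-specific weights reduce to the global fit and fall back", {
  set.seed(51)
  prob <- planted_problem(m = 2, n_pairs = 40)
  one_cluster <- tibble::tibble(term = c("y", "n"), cluster = "all")
  # pair table of the planted problem uses terms y/n for every pair
  prob$pairs <- tibble::tibble(protein = "p",
                               pos = rep("y", nrow(prob$D)),
                               neg = rep("n", nrow(prob$D)))
  cw <- learn_cluster_weights(prob, one_cluster)
  expect_equal(names(cw), "all")
  expect_equal(cw$all$w, learn_weights(prob)$w)

  # two clusters with opposite informative sources
  D <- rbind(cbind(c(0, runif(19, 0.2, 1)), -runif(20, 0.2, 1)),
             cbind(-runif(20, 0.2, 1), c(0, runif(19, 0.2, 1))))
  colnames(D) <- c("s1", "s2")
  prob2 <- structure(list(
    pairs = tibble::tibble(protein = "p",
                           pos = rep(c("a1", "b1"), each = 20),
                           neg = rep(c("a2", "b2"), each = 20)),
    D = D, source_names = colnames(D)), class = "rank_loss_problem")
  clusters <- tibble::tibble(term = c("a1", "a2", "b1", "b2", "z1"),
                             cluster = c("A", "A", "B", "B", "Z"))
  expect_message(cw2 <- learn_cluster_weights(prob2, clusters), "uniform")
  expect_equal(unname(cw2$A$w), c(1, 0), tolerance = 1e-9)
  expect_equal(unname(cw2$B$w), c(0, 1), tolerance = 1e-9)
  expect_equal(unname(cw2$Z$w), c(0.5, 0.5))   # empty cluster -> uniform

  # applying the per-cluster weights picks each cluster's informative source
  st1 <- score_table(tibble::tibble(
    protein = "p", term = c("a1", "b1"), score = c(5, 1)), source = "s1")
  st2 <- score_table(tibble::tibble(
    protein = "p", term = c("a1", "b1"), score = c(1, 5)), source = "s2")
  mixed <- weighted_average_by_cluster(list(st1, st2), cw2,
                                       clusters[clusters$term %in%
                                                  c("a1", "b1"), ])
  expect_equal(mixed$score[mixed$term == "a1"], 5)
  expect_equal(mixed$score[mixed$term == "b1"], 5)
})

test_that("weights serialize to JSON and back", {
  w <- weight_vector(c(seq = 0.6, ppi = 0.3, expr = 0.1))
  path <- tempfile(fileext = ".json")
  write_weights(w, path)
  back <- read_weights(path)
  expect_equal(back$w, w$w)
})
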
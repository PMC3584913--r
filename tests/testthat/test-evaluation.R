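test_that("rank AUC matches pair counting, handles ties and single classes", {
  expect_equal(rank_auc(c(1, 1, 1, 1), c(1, 0, 1, 0)), 0.5)
  expect_equal(rank_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rank_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_true(is.na(rank_auc(c(1, 2, 3), c(1, 1, 1))))

  set.seed(61)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(rank_auc(scores, labels), oracle_auc(scores, labels))
    # complement identity
    expect_equal(rank_auc(scores, labels) + rank_auc(scores, 1 - labels), 1)
  }
})

test_that("term-centric AUC averages eligible terms against gold labels", {
  proteins <- paste0("p", 1:10)
  gold <- annotation_table(tibble::tibble(
    protein = c(proteins[1:6], proteins[3:8]),
    term = c(rep("f1", 6), rep("f2", 6))), propagated = TRUE)
  # predictor equal to the gold labels
  pred <- score_table(tibble::tibble(
    protein = rep(proteins, 2),
    term = rep(c("f1", "f2"), each = 10),
    score = c(as.numeric(proteins %in% proteins[1:6]),
              as.numeric(proteins %in% proteins[3:8]))))
  res <- term_auc(pred, gold, min_count = 5)
  expect_equal(res$per_term$auc, c(1, 1))
  expect_equal(res$macro, 1)

  # constant predictor: exactly 0.5 on every eligible term
  const <- score_table(tibble::tibble(
    protein = rep(proteins, 2), term = rep(c("f1", "f2"), each = 10),
    score = 0.7))
  res2 <- term_auc(const, gold, min_count = 5)
  expect_true(all(res2$per_term$auc == 0.5))

  # macro equals the mean of brute-force per-term AUCs
  set.seed(71)
  noisy <- score_table(tibble::tibble(
    protein = rep(proteins, 2), term = rep(c("f1", "f2"), each = 10),
    score = runif(20)))
  res3 <- term_auc(noisy, gold, min_count = 5)
  grid_proteins <- unique(noisy$protein)   # the table's own protein order
  expected <- mean(c(
    oracle_auc(noisy$score[noisy$term == "f1"],
               grid_proteins %in% proteins[1:6]),
    oracle_auc(noisy$score[noisy$term == "f2"],
               grid_proteins %in% proteins[3:8])))
  expect_equal(res3$macro, expected)

  expect_error(term_auc(pred, gold, min_count = 7), "eligible")
  expect_s3_class(glance(res), "tbl_df")
  expect_equal(nrow(tidy(res)), 2)
})

test_that("threshold sweep propagates predictions and sweeps precision/recall", {
  dag <- chain_dag(3)   # MF:root -> MF:t1 -> MF:t2
  gold <- propagate_annotations(annotation_table(tibble::tibble(
    protein = c("p1", "p2"), term = c("MF:t2", "MF:t1"))), dag)
  pred <- score_table(tibble::tibble(
    protein = rep(c("p1", "p2"), each = 3),
    term = rep(dag$terms, 2),
    score = c(0.9, 0.8, 0.7,    # p1: root, t1, t2
              0.9, 0.6, 0.2)))  # p2
  curve <- protein_threshold_curve(pred, gold, dag,
                                   thresholds = c(0, 0.65, 1))
  # t = 0: every term predicted for both proteins
  # p1 gold {root,t1,t2}: prec 1, rec 1; p2 gold {root,t1}: prec 2/3, rec 1
  expect_equal(curve$precision[1], mean(c(1, 2 / 3)))
  expect_equal(curve$recall[1], 1)
  # t = 0.65: p1 predicts {root,t1,t2} (all above), p2 predicts {root} only
  expect_equal(curve$precision[2], mean(c(1, 1)))
  expect_equal(curve$recall[2], mean(c(1, 1 / 2)))
  # t = 1: nothing predicted; precision undefined, recall 0
  expect_true(is.na(curve$precision[3]))
  expect_equal(curve$recall[3], 0)
  expect_equal(curve$n_predicted[3], 0)

  # closure: a sub-threshold ancestor is pulled in by an above-threshold child
  pred2 <- score_table(tibble::tibble(
    protein = "p1", term = dag$terms, score = c(0, 0, 0.9)))
  curve2 <- protein_threshold_curve(pred2, gold, dag, thresholds = 0.5)
  expect_equal(curve2$precision[1], 1)   # closure {t2,t1,root} = gold
  expect_equal(curve2$recall[1], 1)
})

test_that("top-n keeps the n best scores expanding ties, skipping zero rows", {
  terms <- paste0("f", 1:6)
  gold <- annotation_table(tibble::tibble(
    protein = "p1", term = terms[1:4]), propagated = TRUE)
  pred <- score_table(tibble::tibble(
    protein = "p1", term = terms, score = c(5, 4, 3, 3, 2, 1)))
  res <- topn_metric(pred, gold, n = 3)
  expect_equal(res$n_retained, 4)        # both tied 3s retained
  # retained = {f1,f2,f3,f4}; gold = {f1..f4} -> all 4 correct
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)

  # exactly n scored terms, all correct: recall = n / |gold|
  pred2 <- score_table(tibble::tibble(
    protein = "p1", term = terms, score = c(2, 1.5, 1, 0, 0, 0)))
  res2 <- topn_metric(pred2, gold, n = 3)
  expect_equal(res2$precision, 1)
  expect_equal(res2$recall, 3 / 4)

  # all terms sharing one score: everything retained
  pred3 <- score_table(tibble::tibble(
    protein = "p1", term = terms, score = 1))
  res3 <- topn_metric(pred3, gold, n = 3)
  expect_equal(res3$n_retained, 6)

  # zero-score protein skipped with a message
  pred4 <- score_table(tibble::tibble(
    protein = c("p1", "p2"), term = "f1", score = c(1, 0)))
  gold4 <- annotation_table(tibble::tibble(
    protein = c("p1", "p2"), term = "f1"), propagated = TRUE)
  expect_message(res4 <- topn_metric(pred4, gold4, n = 2), "skipping")
  expect_equal(nrow(res4), 1)
})

test_that("information content is negative log frequency with floor", {
  ann <- annotation_table(tibble::tibble(
    protein = c(paste0("p", 1:10), "p1"),
    term = c(rep("root", 10), "rare")), propagated = TRUE)
  ic <- information_content(ann, terms = c("root", "rare", "absent"),
                            epsilon = 1e-6)
  v <- setNames(ic$ic, ic$term)
  expect_equal(unname(v["root"]), 0)
  expect_equal(unname(v["rare"]), -log(0.1))   # freq 0.1 -> about 2.3026
  expect_equal(unname(v["rare"]), 2.302585, tolerance = 1e-6)
  expect_equal(unname(v["absent"]), -log(1e-6))
})

test_that("weighted sweep downweights cheap terms and reduces at unit IC", {
  dag <- ontology_dag(tibble::tibble(
    term = c("MF:root", "MF:t1", "MF:t2", "MF:t3"),
    parent = c(NA, "MF:root", "MF:root", "MF:root"),
    namespace = "MF"))
  gold <- propagate_annotations(annotation_table(tibble::tibble(
    protein = "p1", term = c("MF:t2", "MF:t3"))), dag)
  pred <- score_table(tibble::tibble(
    protein = "p1", term = c("MF:t1", "MF:t2", "MF:t3"),
    score = c(0.9, 0.8, 0.7)))   # t1 is wrong, t2/t3 right
  ic <- tibble::tibble(term = c("MF:root", "MF:t1", "MF:t2", "MF:t3"),
                       ic = c(0, 2, 1, 1))
  wc <- weighted_threshold_curve(pred, gold, dag, ic, thresholds = 0.5)
  # predicted closure {t1,t2,t3,root}: correct mass 1+1+0, total 2+1+1+0
  expect_equal(wc$precision[1], 0.5)
  expect_equal(wc$recall[1], 1)
  uc <- protein_threshold_curve(pred, gold, dag, thresholds = 0.5)
  expect_equal(uc$precision[1], 3 / 4)   # root counts as a correct unit

  # unit IC reproduces the unweighted sweep exactly
  scene <- tiny_scene(seed = 77, n_proteins = 30, n_terms = 20, n_test = 10)
  st <- score_all(scene$seq, scene$test, scene$terms, scene$train,
                  scene$ann, k = 5)
  gold2 <- propagate_annotations(annotation_table(
    dplyr::filter(tibble::as_tibble(scene$ann),
                  protein %in% scene$test)), scene$dag)
  ones <- tibble::tibble(term = scene$dag$terms, ic = 1)
  w1 <- weighted_threshold_curve(st, gold2, scene$dag, ones)
  u1 <- protein_threshold_curve(st, gold2, scene$dag)
  expect_equal(w1$precision, u1$precision)
  expect_equal(w1$recall, u1$recall)
  expect_equal(curve_area(w1), curve_area(u1))

  # perfect predictions give weighted precision 1 wherever defined
  perfect <- score_table(tibble::tibble(
    protein = "p1", term = c("MF:t2", "MF:t3"), score = 1))
  pc <- weighted_threshold_curve(perfect, gold, dag, ic, thresholds = 0.5)
  expect_equal(pc$precision[1], 1)
})

test_that("the prior baseline has term AUC exactly one half", {
  scene <- tiny_scene(seed = 83, n_proteins = 40, n_terms = 20, n_test = 15)
  gold <- propagate_annotations(annotation_table(
    dplyr::filter(tibble::as_tibble(scene$ann),
                  protein %in% scene$test)), scene$dag)
  train_ann <- propagate_annotations(annotation_table(
    dplyr::filter(tibble::as_tibble(scene$ann),
                  protein %in% scene$train)), scene$dag)
  pri <- prior_score_table(train_ann, queries = scene$test,
                           terms = scene$dag$terms)
  res <- term_auc(pri, gold, min_count = 3)
  # universally-annotated terms (e.g. roots) have no negatives: undefined,
  # excluded from the macro average
  defined <- res$per_term$auc[!is.na(res$per_term$auc)]
  expect_gt(length(defined), 0)
  expect_true(all(defined == 0.5))
  expect_equal(res$macro, 0.5)
})

test_that("autoplot methods return ggplot objects", {
  scene <- tiny_scene(seed = 89, n_proteins = 30, n_terms = 20, n_test = 10)
  st <- score_all(scene$seq, scene$test, scene$terms, scene$train,
                  scene$ann, k = 5)
  gold <- propagate_annotations(annotation_table(
    dplyr::filter(tibble::as_tibble(scene$ann),
                  protein %in% scene$test)), scene$dag)
  ta <- term_auc(st, gold, min_count = 2)
  expect_s3_class(autoplot(ta), "ggplot")
  curve <- protein_threshold_curve(st, gold, scene$dag)
  expect_s3_class(autoplot(curve), "ggplot")
})
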
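test_that("patient CV splits are balanced, disjoint and reproducible", {
  cohort <- tiny_cohort(n_patients = 10)
  sp <- patient_cv_split(cohort, folds = 5, seed = 3)
  expect_equal(as.numeric(table(sp$fold)), rep(2, 5))  # 10 patients, 5 folds
  sf <- attr(sp, "slice_fold")
  for (f in 1:5) {
    train_pat <- cohort_patients(cohort)[sf != f]
    test_pat <- cohort_patients(cohort)[sf == f]
    expect_length(intersect(train_pat, test_pat), 0)
  }
  sp2 <- patient_cv_split(cohort, folds = 5, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, patient_cv_split(cohort, folds = 5, seed = 4)))
  expect_error(patient_cv_split(cohort, folds = 11, seed = 1), "fewer patients")
})

test_that("ranking orders by ascending distance with index tie-breaks", {
  rk <- rank_database(0, matrix(c(1, 3, 2), ncol = 1))
  expect_equal(rk$order, c(1, 3, 2))

  db <- matrix(c(0, 1, 1, 5), ncol = 1)  # exact tie between rows 2 and 3
  expect_equal(rank_database(0, db)$order, c(1, 2, 3, 4))

  # a database copy of the query ranks first at distance zero
  q <- c(0.3, -0.2)
  db2 <- rbind(c(1, 1), q, c(2, 0))
  rk2 <- rank_database(q, db2)
  expect_equal(rk2$order[1], 2)
  expect_equal(rk2$distances[2], 0)

  # permuting database rows permutes the ranking consistently
  set.seed(6)
  db3 <- matrix(rnorm(14), 7, 2)
  perm <- sample(7)
  a <- rank_database(q, db3)$order
  b <- rank_database(q, db3[perm, ])$order
  expect_equal(perm[b], a)
  expect_error(rank_database(q, db3[0, , drop = FALSE]), "empty")
})

test_that("average precision and precision at n follow their definitions", {
  expect_equal(average_precision(c(TRUE, TRUE, TRUE)), 1)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE)), 5 / 6)
  expect_equal(average_precision(c(FALSE, TRUE)), 0.5)
  expect_error(average_precision(c(FALSE, FALSE)), "undefined")

  expect_equal(prec_at_n(c(TRUE, FALSE), 2), 0.5)
  expect_equal(prec_at_n(c(TRUE, TRUE, FALSE, TRUE), 4), 0.75)  # n = database size
  expect_equal(prec_at_n(rep(TRUE, 5), 3), 1)
  expect_error(prec_at_n(c(TRUE, FALSE), 3), "database size")
})

test_that("AP and prec@n match brute force on random relevance patterns", {
  set.seed(47)
  for (i in 1:200) {
    m <- sample(3:30, 1)
    rel <- sample(c(TRUE, FALSE), m, replace = TRUE)
    if (!any(rel)) rel[sample(m, 1)] <- TRUE
    expect_equal(average_precision(rel), brute_ap(rel))
    n <- sample(m, 1)
    expect_equal(prec_at_n(rel, n), sum(rel[1:n]) / n)
  }
})

test_that("per-class mean APs, weighted by query counts, give the pooled mAP", {
  cohort <- tiny_cohort(n_patients = 9)
  res <- evaluate_pipeline(cohort, tiny_config(), folds = 3, metrics = "cfml")
  s <- res$scores$cfml
  weighted <- sum(s$per_class$map * s$per_class$n_queries) / sum(s$per_class$n_queries)
  expect_equal(weighted, s$map_pooled, tolerance = 1e-12)
  expect_true(all(s$per_query$ap >= 0 & s$per_query$ap <= 1))
})

test_that("fold models never see query-fold data (leakage canary)", {
  cohort <- tiny_cohort(n_patients = 6)
  cfg <- tiny_config()
  enc <- encode_cohort_cv(cohort, cfg, folds = 3)
  # poison one slice that fold 1 holds out; fold-1 models must not move
  idx <- enc$folds[[1]]$test_idx[1]
  poisoned <- cohort
  poisoned$cases[[idx]]$image <- poisoned$cases[[idx]]$image + 1000
  enc2 <- encode_cohort_cv(poisoned, cfg, folds = 3)
  expect_identical(enc$folds[[1]]$models$pca, enc2$folds[[1]]$models$pca)
  expect_identical(enc$folds[[1]]$models$model, enc2$folds[[1]]$models$model)
  expect_identical(enc$folds[[1]]$X_train, enc2$folds[[1]]$X_train)
  expect_false(identical(enc$folds[[1]]$X_test, enc2$folds[[1]]$X_test))
})

test_that("a cohort with no class signal retrieves at chance", {
  cohort <- generate_cohort(phantom_params(
    n_patients = 15, slices_per_patient = c(2, 2), image_size = 64,
    tumor_radius_range = c(6, 10), separability = 0, seed = 19
  ))
  enc <- encode_cohort_cv(cohort, tiny_config(), folds = 3)
  s <- score_retrieval(enc, "cfml")
  labels <- cohort_labels(cohort)
  sf <- attr(enc$split, "slice_fold")
  chance <- mean(vapply(1:3, function(f) {
    chance_map(labels[sf == f], labels[sf != f], seed = f)
  }, numeric(1)))
  expect_lt(abs(s$map_mean - chance), 0.1)
})

test_that("Fisher vectors beat bag of words at matched signature length", {
  cohort <- tiny_cohort(n_patients = 9)
  fv_cfg <- tiny_config(pca_variance = 1.0)  # d = W^2 = 9, so matched K is fixed
  fv <- evaluate_pipeline(cohort, fv_cfg, folds = 3, metrics = "cfml")
  d <- nrow(fv$encodings$folds[[1]]$models$pca$components)
  bow_cfg <- tiny_config(pca_variance = 1.0, encoder = "bow", K = 2L * d * fv_cfg$K)
  expect_equal(signature_length(d, fv_cfg$K, fv_cfg$N, "fv"),
               signature_length(d, bow_cfg$K, bow_cfg$N, "bow"))
  bow <- evaluate_pipeline(cohort, bow_cfg, folds = 3, metrics = "cfml")
  expect_gte(fv$scores$cfml$map_mean, bow$scores$cfml$map_mean)
})
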
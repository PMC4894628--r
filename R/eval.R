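#' Patient-stratified cross-validation split
#'
#' Assigns whole patients to folds so that slices from one patient never
#' appear in both the training database and the query set; without this
#' guard, retrieval scores are inflated by near-duplicate slices of the same
#' patient. Patients are shuffled with the seed and dealt round-robin, so
#' fold sizes differ by at most one patient.
#'
#' @param cohort a [cbir_cohort()].
#' @param folds number of folds (default 5).
#' @param seed shuffle seed.
#' @return An object of class `fold_split`: data frame mapping `patient_id`
#'   to `fold` (1-based), plus the per-slice fold vector as attribute
#'   `slice_fold`.
#' @export
patient_cv_split <- function(cohort, folds = 5L, seed = 1L) {
  stopifnot(inherits(cohort, "cbir_cohort"))
  folds <- as.integer(folds)
  patients <- unique(cohort_patients(cohort))
  if (length(patients) < folds) {
    stop("fewer patients (", length(patients), ") than folds (", folds, ")")
  }
  shuffled <- with_seed(seed, sample(patients))
  assign <- data.frame(
    patient_id = shuffled,
    fold = ((seq_along(shuffled) - 1L) %% folds) + 1L,
    stringsAsFactors = FALSE
  )
  slice_fold <- assign$fold[match(cohort_patients(cohort), assign$patient_id)]
  structure(assign, class = c("fold_split", "data.frame"),
            slice_fold = slice_fold, folds = folds, seed = as.integer(seed))
}

#' Rank a database of signatures against a query
#'
#' Orders database rows by ascending distance to the query: the learned
#' metric (squared distance in the projected space) when a
#' [fit_cfml()] model is given, plain squared Euclidean distance otherwise.
#' Exact distance ties are broken by database index, so the ranking is a
#' stable permutation.
#'
#' @param query signature vector (or, with a metric, either a raw signature
#'   of dimension `F` or an already-projected vector of dimension `D`).
#' @param database matrix of signatures or projections, one per row.
#' @param metric a `metric_model`, or `NULL` for Euclidean.
#' @return List with `order` (permutation of row indices, best first) and
#'   `distances` (in database order).
#' @export
rank_database <- function(query, database, metric = NULL) {
  if (is.null(dim(database))) database <- matrix(database, nrow = 1)
  if (nrow(database) == 0L) stop("empty database")
  if (!is.null(metric)) {
    stopifnot(inherits(metric, "metric_model"))
    if (length(query) == ncol(metric$L)) query <- as.numeric(project_signatures(metric, query))
    if (ncol(database) == ncol(metric$L)) database <- project_signatures(metric, database)
  }
  if (length(query) != ncol(database)) {
    stop("query dimension does not match database")
  }
  diff <- sweep(database, 2, query)
  d <- unname(rowSums(diff^2))
  list(order = order(d, seq_along(d)), distances = d)
}

#' Average precision of a ranked relevance pattern
#'
#' The mean of the precisions at the ranks where a relevant item sits,
#' computed over the full ranking (no truncation).
#'
#' @param relevant logical (or 0/1) vector in rank order, best first; must
#'   contain at least one relevant item.
#' @return Scalar in (0, 1].
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE))  # (1/1 + 2/3) / 2 = 5/6
#' @export
average_precision <- function(relevant) {
  rel <- as.logical(relevant)
  if (!any(rel)) stop("average precision undefined: no relevant item")
  prec <- cumsum(rel) / seq_along(rel)
  mean(prec[rel])
}

#' Precision at n
#'
#' Fraction of the first `n` ranked items that are relevant.
#'
#' @param relevant logical (or 0/1) vector in rank order.
#' @param n cutoff, at most `length(relevant)`.
#' @return Scalar in \[0, 1\].
#' @export
prec_at_n <- function(relevant, n) {
  rel <- as.logical(relevant)
  n <- as.integer(n)
  if (n < 1L || n > length(rel)) {
    stop("`n` must be between 1 and the database size (", length(rel), ")")
  }
  sum(rel[seq_len(n)]) / n
}

# Stride-subsampled ROI pixel set of one case (shared by model fitting and
# signature building so train and test features see the same sampling).
case_pixel_set <- function(case, config) {
  roi <- augment_tumor_region(case$tumor_mask, config$R)
  px <- roi_pixels(roi)
  if (config$stride > 1L) {
    nr <- nrow(case$image)
    keep <- px_row(px, nr) %% config$stride == 0L &
      px_col(px, nr) %% config$stride == 0L
    if (sum(keep) >= config$N) px <- px[keep]
  }
  px
}

#' Fit the feature-extraction models on a training set
#'
#' Draws a uniform seeded sample of up to `config$pca_sample_size` raw
#' patches from the ROI pixels of the training cases, fits the PCA reduction
#' on it, projects the same sample, and fits the vocabulary (GMM for the
#' Fisher vector, k-means centroids for BoW) on the projected sample. Only
#' the supplied cases contribute, so fitting on a training fold can never
#' leak query-fold information.
#'
#' @param cases list of [tumor_case()] objects (training set).
#' @param config a [pipeline_config()].
#' @param fold fold index used in the seed fan-out (0 outside CV).
#' @return An object of class `cbir_models`: `pca`, `model`, `config`.
#' @export
fit_pipeline_models <- function(cases, config, fold = 0L) {
  stopifnot(inherits(config, "pipeline_config"))
  px_sets <- lapply(cases, case_pixel_set, config = config)
  counts <- lengths(px_sets)
  total <- sum(counts)
  if (total < config$W^2) stop("training set yields too few patches")
  n_sample <- min(config$pca_sample_size, total)
  picked <- with_seed(stage_seed(config$seed, "pca_sample", fold),
                      sort(sample.int(total, n_sample)))
  bounds <- cumsum(counts)
  case_of <- findInterval(picked - 1L, c(0L, bounds), rightmost.closed = FALSE)
  sample_desc <- matrix(0, n_sample, config$W^2)
  row0 <- 0L
  for (ci in unique(case_of)) {
    local_idx <- picked[case_of == ci] - c(0L, bounds)[ci]
    px <- px_sets[[ci]][local_idx]
    m <- extract_patches(cases[[ci]]$image, px, config$W)
    sample_desc[row0 + seq_len(nrow(m)), ] <- m
    row0 <- row0 + nrow(m)
  }
  pca <- fit_pca(sample_desc, config$pca_variance)
  feats <- apply_pca(pca, sample_desc)
  model <- if (config$encoder == "fv") {
    fit_gmm(feats, config$K, seed = stage_seed(config$seed, "gmm", fold))
  } else {
    fit_bow_vocabulary(feats, config$K, seed = stage_seed(config$seed, "vocab", fold))
  }
  structure(list(pca = pca, model = model, config = config),
            class = "cbir_models")
}

#' Encode a list of cases into a signature matrix
#'
#' @param cases list of [tumor_case()] objects.
#' @param models a [fit_pipeline_models()] result.
#' @return Matrix with one signature per row.
#' @export
encode_cases <- function(cases, models) {
  stopifnot(inherits(models, "cbir_models"))
  sigs <- lapply(cases, build_signature, config = models$config,
                 pca = models$pca, model = models$model)
  do.call(rbind, sigs)
}

#' Encode a cohort under patient-stratified cross-validation
#'
#' For each fold, fits PCA and the vocabulary on the training folds only and
#' encodes both the training (database) and held-out (query) slices. The
#' result carries everything label-dependent scoring needs, so the same
#' encodings can be scored with different metrics or permuted labels without
#' re-extracting features.
#'
#' @param cohort a [cbir_cohort()].
#' @param config a [pipeline_config()].
#' @param folds number of CV folds.
#' @return An object of class `cbir_cv_encodings`.
#' @export
encode_cohort_cv <- function(cohort, config, folds = 5L) {
  stopifnot(inherits(cohort, "cbir_cohort"))
  split <- patient_cv_split(cohort, folds, seed = stage_seed(config$seed, "split"))
  slice_fold <- attr(split, "slice_fold")
  fold_data <- lapply(seq_len(folds), function(f) {
    train_idx <- which(slice_fold != f)
    test_idx <- which(slice_fold == f)
    models <- fit_pipeline_models(cohort$cases[train_idx], config, fold = f)
    list(
      train_idx = train_idx,
      test_idx = test_idx,
      models = models,
      X_train = encode_cases(cohort$cases[train_idx], models),
      X_test = encode_cases(cohort$cases[test_idx], models)
    )
  })
  structure(
    list(folds = fold_data, split = split, labels = cohort_labels(cohort),
         patients = cohort_patients(cohort), config = config),
    class = "cbir_cv_encodings"
  )
}

#' Score retrieval on cross-validated encodings
#'
#' Every held-out slice queries the training database of its fold; rankings
#' are scored with average precision and precision at `n`, where a database
#' slice is relevant iff it shares the query's class. With
#' `metric = "cfml"`, the metric is learned per fold on the training
#' signatures and labels only.
#'
#' @param encodings an [encode_cohort_cv()] result.
#' @param metric `"cfml"` (learned metric) or `"euclidean"`.
#' @param labels optional label vector overriding the cohort labels (used
#'   for permutation nulls); one label per slice.
#' @param prec_n cutoffs for precision at n (ignored where the database is
#'   smaller than the cutoff).
#' @return An object of class `cbir_scores`: `per_fold` data frame (fold,
#'   `map`, `prec*`, `n_queries`), `per_class` data frame (pooled over
#'   folds), `per_query` data frame, `map_mean`, `map_sd`, `map_pooled`.
#' @export
score_retrieval <- function(encodings, metric = c("cfml", "euclidean"),
                            labels = NULL, prec_n = c(10L, 20L)) {
  stopifnot(inherits(encodings, "cbir_cv_encodings"))
  metric <- match.arg(metric)
  labels <- labels %||% encodings$labels
  if (length(labels) != length(encodings$labels)) {
    stop("`labels` must have one entry per slice")
  }
  config <- encodings$config
  prec_cols <- paste0("prec", prec_n)
  per_query <- list()
  per_fold <- list()
  for (f in seq_along(encodings$folds)) {
    fd <- encodings$folds[[f]]
    ytr <- labels[fd$train_idx]
    yte <- labels[fd$test_idx]
    if (metric == "cfml") {
      mm <- fit_cfml(build_pair_scatter(fd$X_train, ytr),
                     D = config$D, lambda_reg = config$lambda_reg)
      db <- project_signatures(mm, fd$X_train)
      qs <- project_signatures(mm, fd$X_test)
    } else {
      db <- fd$X_train
      qs <- fd$X_test
    }
    nq <- nrow(qs)
    ap <- numeric(nq)
    pn <- matrix(NA_real_, nq, length(prec_n), dimnames = list(NULL, prec_cols))
    for (i in seq_len(nq)) {
      rk <- rank_database(qs[i, ], db)
      rel <- ytr[rk$order] == yte[i]
      if (!any(rel)) {
        # the query's class is absent from this fold's database: AP undefined
        ap[i] <- NA_real_
        next
      }
      ap[i] <- average_precision(rel)
      for (j in seq_along(prec_n)) {
        if (prec_n[j] <= length(rel)) pn[i, j] <- prec_at_n(rel, prec_n[j])
      }
    }
    if (anyNA(ap)) {
      warning(sum(is.na(ap)), " query slice(s) in fold ", f,
              " had no same-class database slice; excluded from AP averages")
    }
    per_query[[f]] <- data.frame(fold = f, label = yte, ap = ap, pn)
    per_fold[[f]] <- data.frame(
      fold = f, map = mean(ap, na.rm = TRUE),
      as.list(colMeans(pn, na.rm = TRUE)),
      n_queries = nq
    )
  }
  per_query <- do.call(rbind, per_query)
  per_fold <- do.call(rbind, per_fold)
  per_class <- do.call(rbind, lapply(sort(unique(per_query$label)), function(cl) {
    sub <- per_query[per_query$label == cl, , drop = FALSE]
    data.frame(class = cl, map = mean(sub$ap, na.rm = TRUE),
               as.list(colMeans(sub[prec_cols], na.rm = TRUE)),
               n_queries = sum(!is.na(sub$ap)))
  }))
  structure(
    list(metric = metric, per_fold = per_fold, per_class = per_class,
         per_query = per_query,
         map_mean = mean(per_fold$map), map_sd = stats::sd(per_fold$map),
         map_pooled = mean(per_query$ap, na.rm = TRUE)),
    class = "cbir_scores"
  )
}

#' @export
print.cbir_scores <- function(x, ...) {
  cat(sprintf("<cbir_scores> metric=%s: mAP %.4f +/- %.4f over %d folds\n",
              x$metric, x$map_mean, x$map_sd, nrow(x$per_fold)))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Run the full retrieval evaluation on a cohort
#'
#' Encodes the cohort once under patient-stratified cross-validation, then
#' scores each requested metric on the shared encodings. Headline numbers
#' are the mean and standard deviation of the per-fold mAP (one run per
#' held-out fold), with per-class breakdowns pooled over folds.
#'
#' @param cohort a [cbir_cohort()].
#' @param config a [pipeline_config()].
#' @param folds number of CV folds.
#' @param metrics metrics to score on the shared encodings.
#' @return An object of class `cbir_eval`: `scores` (named list of
#'   [score_retrieval()] results), `encodings`, `config`.
#' @export
evaluate_pipeline <- function(cohort, config = pipeline_config(),
                              folds = 5L, metrics = c("cfml", "euclidean")) {
  encodings <- encode_cohort_cv(cohort, config, folds)
  scores <- lapply(metrics, function(m) score_retrieval(encodings, m))
  names(scores) <- metrics
  structure(list(scores = scores, encodings = encodings, config = config),
            class = "cbir_eval")
}

#' @export
print.cbir_eval <- function(x, ...) {
  cat("<cbir_eval>\n")
  for (m in names(x$scores)) {
    s <- x$scores[[m]]
    cat(sprintf("  %-10s mAP %.4f +/- %.4f\n", m, s$map_mean, s$map_sd))
  }
  invisible(x)
}

#' Permute cohort labels at the patient level
#'
#' Shuffles which class each patient carries while keeping all slices of a
#' patient on one label (the exchangeable unit of the study design is the
#' patient, not the slice).
#'
#' @param cohort a [cbir_cohort()].
#' @param seed permutation seed.
#' @return Integer vector of permuted labels, one per slice.
#' @export
permute_patient_labels <- function(cohort, seed = 1L) {
  patients <- cohort_patients(cohort)
  labels <- cohort_labels(cohort)
  ids <- unique(patients)
  by_patient <- labels[match(ids, patients)]
  permuted <- with_seed(seed, sample(by_patient))
  names(permuted) <- ids
  as.integer(permuted[patients])
}

#' Permutation-null mean average precision of cross-validated encodings
#'
#' Estimates the mAP expected when class labels carry no information about
#' the signatures: patient-level labels are randomly permuted `n_perm` times
#' and each permutation is scored on the fixed encodings with the
#' label-free (Euclidean) ranking, relevance judged by the permuted labels.
#' Under label exchangeability this expectation equals the class-prior
#' chance level (see [chance_map()]); a pipeline that leaked labels into the
#' features would exceed it. A supervised metric retrained on the permuted
#' labels is deliberately not used here: at small patient counts it
#' genuinely exploits the realized overlap between permuted and true labels,
#' inflating the null above the class prior without any leakage.
#'
#' @param encodings an [encode_cohort_cv()] result.
#' @param cohort the cohort the encodings came from.
#' @param n_perm number of permutations averaged.
#' @param seed base seed; permutation `i` uses `seed + i`.
#' @param metric metric scored under permuted labels.
#' @return List with `map` (mean over permutations), `per_perm` (vector) and
#'   `chance` (the random-ranking class-prior baseline on the same folds).
#' @export
permutation_null_map <- function(encodings, cohort, n_perm = 10L, seed = 1L,
                                 metric = "euclidean") {
  per_perm <- vapply(seq_len(n_perm), function(i) {
    perm <- permute_patient_labels(cohort, seed = seed + i)
    score_retrieval(encodings, metric, labels = perm)$map_mean
  }, numeric(1))
  labels <- cohort_labels(cohort)
  sf <- attr(encodings$split, "slice_fold")
  chance <- mean(vapply(seq_along(encodings$folds), function(f) {
    chance_map(labels[sf == f], labels[sf != f],
               seed = stage_seed(seed, "baseline", f))
  }, numeric(1)))
  list(map = mean(per_perm), per_perm = per_perm, chance = chance)
}

#' Chance-level mean average precision
#'
#' Empirical expectation of the mAP under uniformly random rankings, given
#' the query and database label compositions; the baseline that an
#' uninformative retrieval system attains (close to the class-prior
#' fraction of relevant items).
#'
#' @param query_labels labels of the query slices.
#' @param db_labels labels of the database slices.
#' @param n_rankings random rankings simulated per query composition.
#' @param seed RNG seed.
#' @return Scalar expected mAP.
#' @export
chance_map <- function(query_labels, db_labels, n_rankings = 200L, seed = 1L) {
  m <- length(db_labels)
  with_seed(seed, {
    per_class <- vapply(unique(query_labels), function(cl) {
      r <- sum(db_labels == cl)
      if (r == 0) return(NA_real_)
      mean(vapply(seq_len(n_rankings), function(i) {
        rel <- logical(m)
        rel[sample.int(m, r)] <- TRUE
        average_precision(rel)
      }, numeric(1)))
    }, numeric(1))
    names(per_class) <- unique(query_labels)
    mean(per_class[as.character(query_labels)], na.rm = TRUE)
  })
}
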
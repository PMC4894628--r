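#' Sweep one pipeline parameter and tabulate retrieval performance
#'
#' Re-runs the cross-validated evaluation once per value of a single
#' parameter while all other parameters stay at `base_config`, mirroring the
#' one-at-a-time parameter studies of the method (dilation radius, pooling
#' regions, patch size, vocabulary size, metric rank).
#'
#' @param cohort a [cbir_cohort()].
#' @param base_config a [pipeline_config()].
#' @param parameter one of `"R"`, `"N"`, `"W"`, `"K"`, `"D"`.
#' @param values values to evaluate.
#' @param folds CV folds.
#' @param metric metric to report.
#' @return Data frame with one row per value: `parameter`, `value`,
#'   `map_mean`, `map_sd`, `prec10`, `prec20`.
#' @export
run_sweep <- function(cohort, base_config, parameter, values,
                      folds = 5L, metric = "cfml") {
  if (!parameter %in% c("R", "N", "W", "K", "D")) {
    stop("`parameter` must be one of R, N, W, K, D")
  }
  rows <- lapply(values, function(v) {
    cfg <- base_config
    cfg[[parameter]] <- as.integer(v)
    cfg <- do.call(pipeline_config, c(unclass(cfg), list(preset = "paper")))
    ev <- evaluate_pipeline(cohort, cfg, folds = folds, metrics = metric)
    s <- ev$scores[[metric]]
    data.frame(parameter = parameter, value = v,
               map_mean = s$map_mean, map_sd = s$map_sd,
               prec10 = mean(s$per_fold$prec10, na.rm = TRUE),
               prec20 = mean(s$per_fold$prec20, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Build a retrieval database from a cohort
#'
#' Encodes every slice with fitted models and keeps the metadata needed to
#' answer queries.
#'
#' @param cohort a [cbir_cohort()].
#' @param models a [fit_pipeline_models()] result.
#' @return An object of class `cbir_database`.
#' @export
build_database <- function(cohort, models) {
  structure(
    list(signatures = encode_cases(cohort$cases, models),
         labels = cohort_labels(cohort),
         patients = cohort_patients(cohort)),
    class = "cbir_database"
  )
}

#' Retrieve the most similar database slices for a query case
#'
#' Encodes the query with the same fitted models as the database and ranks
#' database slices by the learned metric (or Euclidean distance).
#'
#' @param case a [tumor_case()] query.
#' @param database a [build_database()] result.
#' @param models the [fit_pipeline_models()] used to build the database.
#' @param metric a [fit_cfml()] model, or `NULL` for Euclidean distance.
#' @param top_n number of hits to return.
#' @return Data frame with `rank`, `index`, `label`, `patient_id`,
#'   `distance`, ascending in distance.
#' @export
retrieve_similar <- function(case, database, models, metric = NULL,
                             top_n = 10L) {
  stopifnot(inherits(database, "cbir_database"))
  top_n <- min(as.integer(top_n), nrow(database$signatures))
  sig <- build_signature(case, models$config, models$pca, models$model)
  rk <- rank_database(sig, database$signatures, metric)
  idx <- rk$order[seq_len(top_n)]
  data.frame(
    rank = seq_len(top_n),
    index = idx,
    label = database$labels[idx],
    patient_id = database$patients[idx],
    distance = rk$distances[idx]
  )
}
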
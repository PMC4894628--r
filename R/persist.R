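#' Save fitted pipeline models to an HDF5 file
#'
#' Serializes the PCA reduction, the vocabulary (GMM or k-means centroids),
#' the configuration and, optionally, a learned metric into one HDF5
#' container with a versioned schema, so a trained pipeline can be reused
#' for querying without refitting.
#'
#' @param models a [fit_pipeline_models()] result.
#' @param path destination file; overwritten if present.
#' @param metric optional [fit_cfml()] model stored alongside.
#' @return `path`, invisibly.
#' @export
save_models <- function(models, path, metric = NULL) {
  stopifnot(inherits(models, "cbir_models"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write("1", path, "schema_version")

  rhdf5::h5createGroup(path, "pca")
  rhdf5::h5write(models$pca$mean, path, "pca/mean")
  rhdf5::h5write(models$pca$components, path, "pca/components")
  rhdf5::h5write(models$pca$eigenvalues, path, "pca/eigenvalues")
  rhdf5::h5write(models$pca$explained_fraction, path, "pca/explained_fraction")

  rhdf5::h5createGroup(path, "vocabulary")
  if (models$config$encoder == "fv") {
    rhdf5::h5write(models$model$weights, path, "vocabulary/weights")
    rhdf5::h5write(models$model$means, path, "vocabulary/means")
    rhdf5::h5write(models$model$variances, path, "vocabulary/variances")
  } else {
    rhdf5::h5write(models$model, path, "vocabulary/centroids")
  }

  rhdf5::h5createGroup(path, "config")
  for (nm in names(unclass(models$config))) {
    rhdf5::h5write(models$config[[nm]], path, paste0("config/", nm))
  }

  if (!is.null(metric)) {
    stopifnot(inherits(metric, "metric_model"))
    rhdf5::h5createGroup(path, "metric")
    rhdf5::h5write(metric$L, path, "metric/L")
    rhdf5::h5write(metric$eigenvalues, path, "metric/eigenvalues")
    rhdf5::h5write(metric$lambda_reg, path, "metric/lambda_reg")
  }
  invisible(path)
}

#' Load pipeline models saved by [save_models()]
#'
#' @param path HDF5 model file.
#' @return List with `models` (a `cbir_models`) and `metric` (a
#'   `metric_model` or `NULL`).
#' @export
load_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)
  if (!any(contents$name == "schema_version")) {
    stop("format error: not a model file (missing schema_version)")
  }
  rd <- function(f) rhdf5::h5read(path, f)
  version <- as.character(rd("schema_version"))
  if (version != "1") stop("unsupported model schema version: ", version)

  cfg_names <- contents$name[contents$group == "/config"]
  cfg <- lapply(cfg_names, function(nm) {
    v <- rd(paste0("config/", nm))
    if (is.array(v)) v <- as.vector(v)
    v
  })
  names(cfg) <- cfg_names
  cfg$normalize_per_subregion <- as.logical(cfg$normalize_per_subregion)
  config <- do.call(pipeline_config, cfg)

  pca <- structure(
    list(mean = as.numeric(rd("pca/mean")),
         components = as.matrix(rd("pca/components")),
         eigenvalues = as.numeric(rd("pca/eigenvalues")),
         explained_fraction = as.numeric(rd("pca/explained_fraction"))),
    class = "pca_model"
  )
  model <- if (config$encoder == "fv") {
    structure(
      list(weights = as.numeric(rd("vocabulary/weights")),
           means = as.matrix(rd("vocabulary/means")),
           variances = as.matrix(rd("vocabulary/variances"))),
      class = "gmm_model"
    )
  } else {
    as.matrix(rd("vocabulary/centroids"))
  }
  metric <- NULL
  if (any(contents$group == "/metric")) {
    metric <- structure(
      list(L = as.matrix(rd("metric/L")),
           eigenvalues = as.numeric(rd("metric/eigenvalues")),
           lambda_reg = as.numeric(rd("metric/lambda_reg"))),
      class = "metric_model"
    )
  }
  list(
    models = structure(list(pca = pca, model = model, config = config),
                       class = "cbir_models"),
    metric = metric
  )
}
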
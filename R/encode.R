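#' Fisher vector of a patch set
#'
#' Encodes a set of `T` descriptors by the normalized gradient of their
#' average log-likelihood under the GMM vocabulary, using the diagonal
#' closed-form approximation of the Fisher information matrix. Only the
#' gradients with respect to the component means and variances are used, so
#' the encoding has length `2 * d * K`. Per component `k` the two
#' `d`-dimensional blocks are
#'
#' \deqn{g_{\mu k} = \frac{1}{T\sqrt{w_k}} \sum_t \gamma_t(k)
#'       \frac{x_t-\mu_k}{\sigma_k}, \qquad
#'       g_{\sigma k} = \frac{1}{T\sqrt{2 w_k}} \sum_t \gamma_t(k)
#'       \left(\frac{(x_t-\mu_k)^2}{\sigma_k^2}-1\right)}
#'
#' with all operations element-wise per dimension; blocks are concatenated
#' as \eqn{(g_{\mu 1}, g_{\sigma 1}, \ldots, g_{\mu K}, g_{\sigma K})}.
#' Being an average over descriptors, the encoding is invariant to
#' duplicating the patch set.
#'
#' @param model a [fit_gmm()] vocabulary.
#' @param patches descriptor matrix (rows are descriptors); its column count
#'   must match the model dimension.
#' @return Numeric vector of length `2 * d * K`. An empty patch set yields a
#'   zero vector with a warning.
#' @export
encode_fv <- function(model, patches) {
  stopifnot(inherits(model, "gmm_model"))
  K <- length(model$weights)
  d <- ncol(model$means)
  if (is.null(dim(patches))) patches <- matrix(patches, nrow = 1)
  if (nrow(patches) == 0L) {
    warning("empty patch set; returning zero Fisher vector")
    return(numeric(2 * d * K))
  }
  T_ <- nrow(patches)
  gamma <- gmm_posterior(model, patches)
  sigma <- sqrt(model$variances)
  out <- numeric(2 * d * K)
  for (k in seq_len(K)) {
    u <- sweep(patches, 2, model$means[k, ])
    u <- sweep(u, 2, sigma[k, ], "/")
    g_mu <- colSums(gamma[, k] * u) / (T_ * sqrt(model$weights[k]))
    g_sig <- colSums(gamma[, k] * (u^2 - 1)) / (T_ * sqrt(2 * model$weights[k]))
    out[((k - 1) * 2 * d + 1):((k - 1) * 2 * d + d)] <- g_mu
    out[((k - 1) * 2 * d + d + 1):(k * 2 * d)] <- g_sig
  }
  out
}

#' Fit a k-means visual vocabulary for the bag-of-words baseline
#'
#' @param features descriptor matrix (training sample).
#' @param K vocabulary size.
#' @param seed RNG seed for k-means.
#' @return A `K x d` centroid matrix.
#' @export
fit_bow_vocabulary <- function(features, K, seed = 1L) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  if (K > nrow(features)) {
    stop("K = ", K, " exceeds the number of descriptors (", nrow(features), ")")
  }
  # fixed iteration budget: vocabulary quality plateaus well before exact
  # convergence, and the budget keeps fitting deterministic in cost
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(features, centers = as.integer(K),
                  iter.max = 100L, nstart = 3L, algorithm = "Lloyd")
  ))
  unname(km$centers)
}

#' Bag-of-words histogram of a patch set
#'
#' Hard-assigns each descriptor to its nearest centroid (Euclidean distance,
#' ties to the lowest centroid index) and counts occurrences.
#'
#' @param vocabulary `K x d` centroid matrix from [fit_bow_vocabulary()].
#' @param patches descriptor matrix.
#' @return Numeric count vector of length `K` summing to `nrow(patches)`.
#' @export
encode_bow <- function(vocabulary, patches) {
  if (is.null(dim(patches))) patches <- matrix(patches, nrow = 1)
  K <- nrow(vocabulary)
  if (nrow(patches) == 0L) return(numeric(K))
  if (ncol(patches) != ncol(vocabulary)) {
    stop("descriptor dimension does not match vocabulary dimension")
  }
  dmat <- pairwise_sqdist(patches, vocabulary)
  assign <- max.col(-dmat, ties.method = "first")
  as.numeric(tabulate(assign, nbins = K))
}

#' Power- and L2-normalize a signature
#'
#' Applies the signed power transform `f(z) = sign(z) |z|^alpha` to each
#' component (alpha typically 0.5, which de-sparsifies the Fisher vector),
#' then L2-normalizes the whole vector. The all-zero vector maps to itself.
#'
#' @param v numeric vector.
#' @param alpha power exponent in (0, 1].
#' @return Numeric vector of unit L2 norm (or zeros).
#' @export
normalize_signature <- function(v, alpha = 0.5) {
  stopifnot(is.numeric(v), alpha > 0, alpha <= 1)
  p <- sign(v) * abs(v)^alpha
  nrm <- sqrt(sum(p^2))
  if (nrm > 0) p / nrm else p
}

#' Build the image-level signature of one case
#'
#' Runs the full per-image feature pipeline: augment the tumor region by
#' dilation, split the ROI into `N` intensity-order subregions, extract raw
#' `W x W` patches at each (stride-subsampled) subregion pixel, project them
#' through the fitted PCA, encode each subregion with the Fisher vector (or
#' BoW) vocabulary, concatenate the `N` encodings in bin order, and
#' normalize (signed power + L2 for FV; L2 for BoW).
#'
#' With `config$stride > 1`, ROI pixels are subsampled on a stride grid
#' before pooling (falling back to all pixels if fewer than `N` survive), so
#' subregion sizes stay balanced on the retained set.
#'
#' @param case a [tumor_case()].
#' @param config a [pipeline_config()].
#' @param pca a [fit_pca()] model.
#' @param model a [fit_gmm()] vocabulary (`encoder = "fv"`) or centroid
#'   matrix (`encoder = "bow"`).
#' @return Numeric signature vector: length `2 * d * K * N` for FV, `K * N`
#'   for BoW; unit L2 norm unless degenerate.
#' @export
build_signature <- function(case, config, pca, model) {
  stopifnot(inherits(case, "tumor_case"), inherits(config, "pipeline_config"))
  roi <- augment_tumor_region(case$tumor_mask, config$R)
  px <- roi_pixels(roi)
  if (config$stride > 1L) {
    nr <- nrow(case$image)
    keep <- px_row(px, nr) %% config$stride == 0L &
      px_col(px, nr) %% config$stride == 0L
    if (sum(keep) >= config$N) px <- px[keep]
  }
  part <- partition_pixels(case$image, px, config$N)
  enc <- lapply(part$subregions, function(sub) {
    z <- apply_pca(pca, extract_patches(case$image, sub, config$W))
    if (config$encoder == "fv") {
      v <- encode_fv(model, z)
      if (config$normalize_per_subregion) v <- normalize_signature(v, config$alpha)
      v
    } else {
      v <- encode_bow(model, z)
      if (config$normalize_per_subregion) {
        nrm <- sqrt(sum(v^2))
        if (nrm > 0) v <- v / nrm
      }
      v
    }
  })
  sig <- unlist(enc, use.names = FALSE)
  if (config$normalize_per_subregion) {
    nrm <- sqrt(sum(sig^2))
    if (nrm > 0) sig <- sig / nrm
    sig
  } else if (config$encoder == "fv") {
    normalize_signature(sig, config$alpha)
  } else {
    nrm <- sqrt(sum(sig^2))
    if (nrm > 0) sig / nrm else sig
  }
}

#' Expected signature length for a configuration
#'
#' `2 * d * K * N` for the Fisher vector and `K * N` for bag of words, where
#' `d` is the PCA-reduced descriptor dimension: for a matched-length
#' comparison, BoW needs a vocabulary `2d` times larger than FV.
#'
#' @param d reduced descriptor dimension.
#' @param K vocabulary size.
#' @param N number of pooling subregions.
#' @param encoder `"fv"` or `"bow"`.
#' @return Integer length.
#' @export
signature_length <- function(d, K, N, encoder = c("fv", "bow")) {
  encoder <- match.arg(encoder)
  if (encoder == "fv") 2L * as.integer(d) * as.integer(K) * as.integer(N)
  else as.integer(K) * as.integer(N)
}
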
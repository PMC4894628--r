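#' Extract vectorized raw patches around a set of pixels
#'
#' The local features of the pipeline are raw `W x W` intensity windows
#' centered at each pixel of a pooling subregion (gradient-based descriptors
#' such as SIFT carry less information than raw intensities in this imaging
#' context). Windows are vectorized in row-major order; windows extending
#' past the image border are completed by edge replication, so the number of
#' descriptors always equals the number of pixels.
#'
#' @param image numeric intensity matrix.
#' @param pixels integer vector of 1-based column-major pixel indices.
#' @param W patch side (odd integer >= 3).
#' @return A numeric matrix with `length(pixels)` rows and `W^2` columns.
#' @export
extract_patches <- function(image, pixels, W) {
  if (!is.numeric(W) || length(W) != 1L || W < 3 || W %% 2 != 1) {
    stop("`W` must be an odd integer >= 3")
  }
  W <- as.integer(W)
  h <- (W - 1L) %/% 2L
  nr <- nrow(image)
  nc <- ncol(image)
  rows <- px_row(pixels, nr)
  cols <- px_col(pixels, nr)
  out <- matrix(0, length(pixels), W * W)
  for (q in seq_len(W * W)) {
    di <- (q - 1L) %/% W - h
    dj <- (q - 1L) %% W - h
    rr <- clamp(rows + di, 1L, nr)
    cc <- clamp(cols + dj, 1L, nc)
    out[, q] <- image[cbind(rr, cc)]
  }
  out
}

#' Fit a PCA reduction for patch descriptors
#'
#' Eigen-decomposes the sample covariance of a training sample of patch
#' descriptors and keeps the smallest number of leading components whose
#' cumulative explained variance reaches `variance_target`. PCA both
#' decorrelates the descriptors (matching the diagonal-covariance GMM
#' assumption) and suppresses the noisy low-energy directions. No whitening
#' is applied; the mixture's diagonal variances absorb scale.
#'
#' Component signs follow a fixed convention (largest-magnitude loading of
#' each component positive) so fitted models are reproducible.
#'
#' @param sample numeric matrix, one descriptor per row; needs at least as
#'   many rows as columns.
#' @param variance_target fraction of variance to retain, in (0, 1].
#' @return An object of class `pca_model`: `mean`, `components` (d x p with
#'   orthonormal rows), `eigenvalues`, `explained_fraction`.
#' @export
fit_pca <- function(sample, variance_target = 0.99) {
  if (!is.matrix(sample) || !is.numeric(sample)) {
    stop("`sample` must be a numeric matrix")
  }
  if (nrow(sample) < ncol(sample)) {
    stop("need at least as many sample rows (", nrow(sample),
         ") as descriptor dimensions (", ncol(sample), ")")
  }
  stopifnot(variance_target > 0, variance_target <= 1)
  mu <- colMeans(sample)
  eg <- eigen(stats::cov(sample), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total <- sum(ev)
  if (total <= 0) {
    warning("degenerate sample with zero variance; keeping one component")
    d <- 1L
    explained <- 1
  } else {
    cum <- cumsum(ev) / total
    d <- which(cum >= variance_target - 1e-12)[1]
    explained <- cum[d]
  }
  comps <- t(eg$vectors[, seq_len(d), drop = FALSE])
  for (i in seq_len(d)) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  structure(
    list(mean = mu, components = comps, eigenvalues = ev,
         explained_fraction = explained),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d -> %d dims, explained fraction %.4f\n",
              ncol(x$components), nrow(x$components), x$explained_fraction))
  invisible(x)
}

#' Project patch descriptors through a fitted PCA model
#'
#' @param model a [fit_pca()] result.
#' @param patches numeric matrix whose column count matches the model.
#' @return Matrix with the same rows and `nrow(model$components)` columns.
#' @export
apply_pca <- function(model, patches) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(patches))) patches <- matrix(patches, nrow = 1)
  if (ncol(patches) != length(model$mean)) {
    stop("descriptor dimension ", ncol(patches),
         " does not match PCA model dimension ", length(model$mean))
  }
  sweep(patches, 2, model$mean) %*% t(model$components)
}
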
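#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' The GMM is the "probabilistic visual vocabulary" under which Fisher
#' vectors are computed: `K` components with free weights, means and
#' diagonal covariances, fitted by maximum likelihood on a training sample
#' of (PCA-reduced) patch descriptors. Initialization is k-means from the
#' given seed; per-dimension variances are floored at `1e-6` times the data
#' variance in that dimension; EM stops when the mean log-likelihood gain
#' per observation drops below `tol` or after `max_iter` iterations.
#'
#' @param features numeric matrix, one descriptor per row (rows must exceed
#'   `K`).
#' @param K number of mixture components.
#' @param seed RNG seed for the k-means initialization.
#' @param max_iter EM iteration cap.
#' @param tol mean log-likelihood convergence tolerance.
#' @return An object of class `gmm_model`: `weights` (K, summing to one),
#'   `means` (K x d), `variances` (K x d), `loglik`, `iterations`,
#'   `converged`.
#' @export
fit_gmm <- function(features, K, seed = 1L, max_iter = 200L, tol = 1e-6) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  n <- nrow(features)
  d <- ncol(features)
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be >= 1")
  if (K > n) stop("K = ", K, " exceeds the number of descriptors (", n, ")")

  data_var <- apply(features, 2, stats::var)
  floor_var <- pmax(1e-6 * data_var, 1e-12)

  init <- with_seed(seed, gmm_init(features, K))
  w <- init$weights
  mu <- init$means
  sigma2 <- pmax(init$variances, rep(floor_var, each = K))

  x2 <- features^2
  loglik_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lp <- gmm_log_components(features, x2, w, mu, sigma2)
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    loglik <- mean(lse)
    gamma <- exp(lp - lse)

    nk <- colSums(gamma)
    nk <- pmax(nk, 1e-300)
    w <- nk / n
    mu <- (t(gamma) %*% features) / nk
    ex2 <- (t(gamma) %*% x2) / nk
    sigma2 <- pmax(ex2 - mu^2, rep(floor_var, each = K))

    if (iter >= max_iter) break
    if (is.finite(loglik_old) && loglik - loglik_old < tol) {
      converged <- TRUE
      break
    }
    loglik_old <- loglik
  }

  structure(
    list(weights = as.numeric(w / sum(w)), means = mu, variances = sigma2,
         loglik = loglik, iterations = iter, converged = converged),
    class = "gmm_model"
  )
}

# k-means initialization; falls back to distinct random rows if kmeans fails
# (e.g. heavily duplicated descriptors).
gmm_init <- function(features, K) {
  n <- nrow(features)
  km <- tryCatch(
    stats::kmeans(features, centers = K, iter.max = 30L, nstart = 1L,
                  algorithm = "Lloyd"),
    error = function(e) NULL,
    warning = function(w) suppressWarnings(
      stats::kmeans(features, centers = K, iter.max = 30L, nstart = 1L,
                    algorithm = "Lloyd")
    )
  )
  if (!is.null(km) && length(unique(km$cluster)) == K) {
    assign <- km$cluster
    centers <- km$centers
  } else {
    centers <- features[sample.int(n, K), , drop = FALSE]
    dmat <- pairwise_sqdist(features, centers)
    assign <- max.col(-dmat, ties.method = "first")
  }
  d <- ncol(features)
  means <- matrix(0, K, d)
  vars <- matrix(0, K, d)
  wts <- numeric(K)
  gvar <- apply(features, 2, stats::var)
  for (k in seq_len(K)) {
    idx <- which(assign == k)
    wts[k] <- max(length(idx), 1) / n
    if (length(idx) == 0L) {
      means[k, ] <- centers[k, ]
      vars[k, ] <- gvar
    } else {
      xk <- features[idx, , drop = FALSE]
      means[k, ] <- colMeans(xk)
      vars[k, ] <- if (length(idx) > 1L) apply(xk, 2, stats::var) else gvar
    }
  }
  list(weights = wts / sum(wts), means = means, variances = pmax(vars, 1e-12))
}

# n x K matrix of log(w_k) + log N(x_i; mu_k, diag(sigma2_k)).
gmm_log_components <- function(x, x2, w, mu, sigma2) {
  K <- length(w)
  n <- nrow(x)
  lp <- matrix(0, n, K)
  for (k in seq_len(K)) {
    inv <- 1 / sigma2[k, ]
    cst <- log(w[k]) - 0.5 * sum(log(2 * pi * sigma2[k, ]))
    quad <- x2 %*% inv - 2 * (x %*% (mu[k, ] * inv)) + sum(mu[k, ]^2 * inv)
    lp[, k] <- cst - 0.5 * quad
  }
  lp
}

pairwise_sqdist <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * x %*% t(centers)
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> K=%d, d=%d, loglik=%.4f (%s after %d iterations)\n",
              length(x$weights), ncol(x$means), x$loglik,
              if (x$converged) "converged" else "stopped", x$iterations))
  invisible(x)
}

#' Posterior component responsibilities under a GMM
#'
#' Soft assignment of each descriptor to each mixture component, computed in
#' the log domain (log-sum-exp) so small densities do not underflow.
#' Responsibilities below `1e-12` are truncated to zero and rows are
#' renormalized, so each row sums to exactly one.
#'
#' @param model a [fit_gmm()] result.
#' @param x descriptor matrix (or single descriptor vector).
#' @return Matrix of `nrow(x)` rows and `K` columns of responsibilities.
#' @export
gmm_posterior <- function(model, x) {
  stopifnot(inherits(model, "gmm_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$means)) {
    stop("descriptor dimension ", ncol(x), " does not match model dimension ",
         ncol(model$means))
  }
  lp <- gmm_log_components(x, x^2, model$weights, model$means, model$variances)
  m <- apply(lp, 1, max)
  g <- exp(lp - (m + log(rowSums(exp(lp - m)))))
  g[g < 1e-12] <- 0
  g / rowSums(g)
}
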
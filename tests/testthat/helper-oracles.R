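# Independent oracles used across tests. These deliberately use the most
# direct (brute-force) formulation of each quantity, not the package's
# optimized code paths.

# Minimum Euclidean distance from every pixel to the mask foreground,
# by explicit scan over foreground pixels.
brute_distance_to_fg <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  fg <- which(mask == 1)
  dmin <- matrix(Inf, nr, nc)
  for (i in fg) {
    r <- ((i - 1) %% nr) + 1
    c <- ((i - 1) %/% nr) + 1
    dmin <- pmin(dmin, sqrt((rows - r)^2 + (cols - c)^2))
  }
  dmin
}

brute_dilate <- function(mask, R) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[brute_distance_to_fg(mask) <= R] <- 1L
  out
}

# Total log-likelihood of descriptor rows X under a diagonal GMM.
gmm_loglik_direct <- function(X, w, mu, sigma2) {
  n <- nrow(X)
  K <- length(w)
  total <- 0
  for (t in seq_len(n)) {
    dens <- vapply(seq_len(K), function(k) {
      w[k] * prod(stats::dnorm(X[t, ], mu[k, ], sqrt(sigma2[k, ])))
    }, numeric(1))
    total <- total + log(sum(dens))
  }
  total
}

# Fisher vector by numerical differentiation of the log-likelihood with
# respect to component means and standard deviations, normalized by 1/T and
# the diagonal closed-form Fisher information (F_mu = w/sigma^2,
# F_sigma = 2w/sigma^2).
fv_numeric_oracle <- function(model, X, h = 1e-5) {
  w <- model$weights
  mu <- model$means
  sigma2 <- model$variances
  sigma <- sqrt(sigma2)
  K <- length(w)
  d <- ncol(mu)
  T_ <- nrow(X)
  out <- numeric(2 * d * K)
  for (k in seq_len(K)) {
    for (j in seq_len(d)) {
      mp <- mu; mp[k, j] <- mp[k, j] + h
      mm <- mu; mm[k, j] <- mm[k, j] - h
      dmu <- (gmm_loglik_direct(X, w, mp, sigma2) -
                gmm_loglik_direct(X, w, mm, sigma2)) / (2 * h)
      sp <- sigma; sp[k, j] <- sp[k, j] + h
      sm <- sigma; sm[k, j] <- sm[k, j] - h
      dsig <- (gmm_loglik_direct(X, w, mu, sp^2) -
                 gmm_loglik_direct(X, w, mu, sm^2)) / (2 * h)
      out[(k - 1) * 2 * d + j] <- dmu * sigma[k, j] / (T_ * sqrt(w[k]))
      out[(k - 1) * 2 * d + d + j] <- dsig * sigma[k, j] / (T_ * sqrt(2 * w[k]))
    }
  }
  out
}

# Random diagonal GMM + data for oracle tests.
random_gmm_instance <- function(K, d, T_) {
  w <- runif(K, 0.5, 2); w <- w / sum(w)
  mu <- matrix(rnorm(K * d, 0, 2), K, d)
  sigma2 <- matrix(runif(K * d, 0.3, 1.5), K, d)
  model <- structure(
    list(weights = w, means = mu, variances = sigma2),
    class = "gmm_model"
  )
  X <- matrix(rnorm(T_ * d, 0, 2), T_, d)
  list(model = model, X = X)
}

# Average precision straight from its definition.
brute_ap <- function(rel) {
  pos <- which(as.logical(rel))
  mean(vapply(pos, function(p) sum(rel[1:p]) / p, numeric(1)))
}

# Pair scatter matrices by explicit double loop over unordered pairs.
brute_pair_scatter <- function(X, labels) {
  n <- nrow(X)
  p <- ncol(X)
  MS <- matrix(0, p, p); MD <- matrix(0, p, p)
  nS <- 0; nD <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- X[i, ] - X[j, ]
      op <- tcrossprod(dd)
      if (labels[i] == labels[j]) {
        MS <- MS + op; nS <- nS + 1
      } else {
        MD <- MD + op; nD <- nD + 1
      }
    }
  }
  list(M_S = MS / nS, M_D = MD / nD)
}

# Small phantom cohort + reduced configuration used by pipeline-level tests.
tiny_cohort <- function(n_patients = 9, seed = 7, separability = 1.2) {
  generate_cohort(phantom_params(
    n_patients = n_patients, slices_per_patient = c(2, 2),
    image_size = 64, tumor_radius_range = c(6, 10),
    separability = separability, seed = seed
  ))
}

tiny_config <- function(...) {
  args <- list(R = 4, N = 2, W = 3, K = 4,
               pca_sample_size = 4000, stride = 2, seed = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pipeline_config, c(args, list(preset = "fast")))
}
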
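#' Same-class and different-class pair scatter matrices
#'
#' For signatures `x_1..x_n` with labels, builds the mean outer product of
#' pair differences over all unordered same-label pairs (`M_S`) and all
#' unordered different-label pairs (`M_D`):
#' \deqn{M_S = \frac{1}{|S|}\sum_{(i,j)\in S}(x_i-x_j)(x_i-x_j)^\top}
#' and likewise for `M_D`. All pairs enter; no sampling. The sums are
#' computed through within-class/total scatter identities (cost `O(n F^2)`
#' rather than `O(n^2 F^2)`), which give exactly the same matrices as the
#' explicit double loop.
#'
#' @param signatures numeric matrix, one signature per row.
#' @param labels vector of class labels, one per row; at least two classes,
#'   and at least one same-class pair overall.
#' @return An object of class `pair_scatter`: `M_S`, `M_D` (symmetric
#'   positive semi-definite), `n_same`, `n_diff`.
#' @export
build_pair_scatter <- function(signatures, labels) {
  x <- as.matrix(signatures)
  n <- nrow(x)
  if (length(labels) != n) stop("`labels` length must match signature rows")
  labels <- as.vector(labels)
  classes <- unique(labels)
  if (length(classes) < 2L) {
    stop("at least two classes are required (different-class pairs undefined)")
  }
  p <- ncol(x)
  sum_same <- matrix(0, p, p)
  n_same <- 0
  within <- matrix(0, p, p)  # sum over classes of n_c * centered scatter
  for (cl in classes) {
    xc <- x[labels == cl, , drop = FALSE]
    nc_ <- nrow(xc)
    if (nc_ < 2L) next
    sc <- crossprod(sweep(xc, 2, colMeans(xc)))
    sum_same <- sum_same + nc_ * sc
    within <- within + nc_ * sc
    n_same <- n_same + nc_ * (nc_ - 1) / 2
  }
  if (n_same == 0) stop("no same-class pairs: every class has a single member")
  # Sum over all unordered pairs of (x_i - x_j)(x_i - x_j)^T = n * total scatter.
  total <- n * crossprod(sweep(x, 2, colMeans(x)))
  n_all <- n * (n - 1) / 2
  M_S <- sum_same / n_same
  M_D <- (total - sum_same) / (n_all - n_same)
  M_S <- (M_S + t(M_S)) / 2
  M_D <- (M_D + t(M_D)) / 2
  structure(list(M_S = M_S, M_D = M_D, n_same = n_same,
                 n_diff = n_all - n_same),
            class = "pair_scatter")
}

#' Closed-form metric learning
#'
#' Learns a rank-`D` projection `L` minimizing
#' `Tr(L (M_S - M_D) L')` subject to `L (M_S + lambda I) L' = I`, i.e.
#' shrinking same-class squared distances while stretching different-class
#' ones. The solution is closed form: the rows of `L` are the eigenvectors
#' of the generalized symmetric eigenproblem
#' `M_D v = eta (M_S + lambda I) v` with the `D` largest eigenvalues, scaled
#' so the constraint holds exactly. The learned squared Mahalanobis distance
#' is then the squared Euclidean distance between `L`-projected signatures.
#'
#' @param scatter a [build_pair_scatter()] result.
#' @param D projection rank (<= signature dimension).
#' @param lambda_reg regularizer added to `M_S` (an absolute constant, not
#'   scaled by the trace); keeps the constraint matrix invertible for
#'   high-dimensional signatures.
#' @return An object of class `metric_model`: `L` (D x F), `eigenvalues`
#'   (descending), `lambda_reg`.
#' @export
fit_cfml <- function(scatter, D = 2L, lambda_reg = 1.5e-4) {
  stopifnot(inherits(scatter, "pair_scatter"))
  F_ <- nrow(scatter$M_S)
  D <- as.integer(D)
  if (D < 1L || D > F_) stop("`D` must be between 1 and ", F_)
  if (lambda_reg < 0) stop("`lambda_reg` must be >= 0")
  A <- scatter$M_S + diag(lambda_reg, F_)
  U <- tryCatch(chol(A), error = function(e) {
    stop("M_S + lambda*I is not positive definite; use lambda_reg > 0",
         call. = FALSE)
  })
  # B = U^{-T} M_D U^{-1}: same eigenvalues as the generalized problem.
  C <- backsolve(U, scatter$M_D, transpose = TRUE)
  B <- backsolve(U, t(C), transpose = TRUE)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  V <- eg$vectors[, seq_len(D), drop = FALSE]
  L <- t(backsolve(U, V))
  for (i in seq_len(D)) {
    j <- which.max(abs(L[i, ]))
    if (L[i, j] < 0) L[i, ] <- -L[i, ]
  }
  structure(
    list(L = L, eigenvalues = eg$values[seq_len(D)], lambda_reg = lambda_reg),
    class = "metric_model"
  )
}

#' @export
print.metric_model <- function(x, ...) {
  cat(sprintf("<metric_model> rank %d over %d dims, eigenvalues: %s\n",
              nrow(x$L), ncol(x$L),
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  invisible(x)
}

#' Learned squared Mahalanobis distance between two signatures
#'
#' `d(x, y) = ||Lx - Ly||^2`, the squared Mahalanobis distance with
#' `M = L'L`. For ranking a whole database, project once with
#' [project_signatures()] and compare squared Euclidean distances in the
#' `D`-dimensional space; the two routes agree to machine precision.
#'
#' @param model a [fit_cfml()] model.
#' @param x,y signature vectors of matching dimension.
#' @return Non-negative scalar.
#' @export
learned_distance <- function(model, x, y) {
  stopifnot(inherits(model, "metric_model"))
  if (length(x) != ncol(model$L) || length(y) != ncol(model$L)) {
    stop("signature dimension does not match the metric model")
  }
  v <- model$L %*% (x - y)
  sum(v^2)
}

#' Project signatures into the learned low-rank space
#'
#' @param model a [fit_cfml()] model.
#' @param signatures matrix of signatures (rows) or a single vector.
#' @return Matrix with `D` columns.
#' @export
project_signatures <- function(model, signatures) {
  stopifnot(inherits(model, "metric_model"))
  if (is.null(dim(signatures))) signatures <- matrix(signatures, nrow = 1)
  signatures %*% t(model$L)
}
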
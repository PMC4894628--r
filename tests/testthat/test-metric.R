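test_that("pair scatter matches hand enumeration on tiny inputs", {
  # two identical points per class: no within-class spread
  X <- matrix(c(0, 0, 2, 2), ncol = 1)
  sc <- build_pair_scatter(X, c(1, 1, 2, 2))
  expect_equal(as.numeric(sc$M_S), 0)
  # the 4 cross pairs all differ by 2 -> mean outer product 4
  expect_equal(as.numeric(sc$M_D), 4)
  expect_equal(sc$n_same, 2)
  expect_equal(sc$n_diff, 4)
})

test_that("pair scatter equals the brute-force double loop", {
  set.seed(19)
  for (i in 1:5) {
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2 || !any(duplicated(labels))) next
    got <- build_pair_scatter(X, labels)
    want <- brute_pair_scatter(X, labels)
    expect_equal(got$M_S, want$M_S, tolerance = 1e-10)
    expect_equal(got$M_D, want$M_D, tolerance = 1e-10)
  }
})

test_that("a single class is rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(build_pair_scatter(X, rep(1, 5)), "two classes")
})

test_that("the learned projection satisfies its constraint exactly", {
  set.seed(23)
  X <- matrix(rnorm(60 * 5), 60, 5)
  labels <- rep(1:3, each = 20)
  sc <- build_pair_scatter(X, labels)
  mm <- fit_cfml(sc, D = 2, lambda_reg = 1.5e-4)
  A <- sc$M_S + diag(mm$lambda_reg, 5)
  expect_lt(max(abs(mm$L %*% A %*% t(mm$L) - diag(2))), 1e-8)
  expect_true(all(diff(mm$eigenvalues) <= 1e-10))  # descending
})

test_that("no random feasible projection beats the closed-form objective", {
  set.seed(29)
  X <- rbind(matrix(rnorm(80, 0), 40, 2), matrix(rnorm(80, 2), 40, 2))
  labels <- rep(1:2, each = 40)
  sc <- build_pair_scatter(X, labels)
  lam <- 1.5e-4
  mm <- fit_cfml(sc, D = 1, lambda_reg = lam)
  objective <- function(L) sum(diag(L %*% (sc$M_S - sc$M_D) %*% t(L)))
  best <- objective(mm$L)
  U <- chol(sc$M_S + diag(lam, 2))
  for (i in 1:100) {
    V <- qr.Q(qr(matrix(rnorm(2), 2, 1)))
    Lr <- t(backsolve(U, V))  # random rotation in the whitened space: feasible
    expect_lte(best, objective(Lr) + 1e-10)
  }
})

test_that("the projection recovers the separating axis of a 2-D two-class problem", {
  set.seed(37)
  n <- 500
  X <- rbind(cbind(rnorm(n / 2, -2), rnorm(n / 2)),
             cbind(rnorm(n / 2, 2), rnorm(n / 2)))
  labels <- rep(1:2, each = n / 2)
  mm <- fit_cfml(build_pair_scatter(X, labels), D = 1, lambda_reg = 1.5e-4)
  dir <- mm$L[1, ] / sqrt(sum(mm$L[1, ]^2))
  expect_gt(abs(dir[1]), 0.99)  # |cosine| with axis 1
})

test_that("the learned distance is a pseudo-metric computable via stored projections", {
  set.seed(41)
  X <- matrix(rnorm(30 * 4), 30, 4)
  labels <- rep(1:3, each = 10)
  mm <- fit_cfml(build_pair_scatter(X, labels), D = 2)
  x <- X[1, ]; y <- X[2, ]
  expect_equal(learned_distance(mm, x, x), 0)
  expect_equal(learned_distance(mm, x, y), learned_distance(mm, y, x))

  ident <- structure(list(L = diag(4), eigenvalues = rep(1, 4),
                          lambda_reg = 0), class = "metric_model")
  expect_equal(learned_distance(ident, x, y), sum((x - y)^2))

  P <- project_signatures(mm, X)
  for (i in 1:10) {
    a <- sample(30, 1); b <- sample(30, 1); c <- sample(30, 1)
    expect_equal(learned_distance(mm, X[a, ], X[b, ]),
                 sum((P[a, ] - P[b, ])^2), tolerance = 1e-10)
    # triangle inequality on the (non-squared) distances
    dab <- sqrt(learned_distance(mm, X[a, ], X[b, ]))
    dbc <- sqrt(learned_distance(mm, X[b, ], X[c, ]))
    dac <- sqrt(learned_distance(mm, X[a, ], X[c, ]))
    expect_lte(dac, dab + dbc + 1e-10)
  }
  expect_error(learned_distance(mm, x, y[1:3]), "dimension")
})

test_that("degenerate scatter without regularization advises lambda > 0", {
  X <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), 4, 2)  # identical points per class
  sc <- build_pair_scatter(X, c(1, 1, 2, 2))
  expect_error(fit_cfml(sc, D = 1, lambda_reg = 0), "lambda")
  expect_s3_class(fit_cfml(sc, D = 1, lambda_reg = 1e-4), "metric_model")
})
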
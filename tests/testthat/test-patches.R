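test_that("a 3x3 patch reads off the window in row-major order", {
  img <- matrix(0:8, 3, 3, byrow = TRUE)  # raster values 0..8
  center <- which(row(img) == 2 & col(img) == 2)
  expect_equal(as.numeric(extract_patches(img, center, 3)), 0:8)
})

test_that("border windows are completed by edge replication", {
  img <- matrix(7, 12, 12)
  corner <- 1L  # pixel (1, 1)
  p <- extract_patches(img, corner, 9)
  expect_equal(dim(p), c(1L, 81L))
  expect_true(all(p == 7))

  # replication repeats the nearest edge value, not zeros
  img2 <- matrix(seq_len(16), 4, 4)
  p2 <- extract_patches(img2, 1L, 3)
  expect_equal(as.numeric(p2),
               c(img2[1, 1], img2[1, 1], img2[1, 2],
                 img2[1, 1], img2[1, 1], img2[1, 2],
                 img2[2, 1], img2[2, 1], img2[2, 2]))
})

test_that("interior patches equal brute-force window copies", {
  set.seed(5)
  img <- matrix(rnorm(400), 20, 20)
  px <- which(row(img) %in% 3:18 & col(img) %in% 3:18)
  px <- sample(px, 25)
  got <- extract_patches(img, px, 5)
  for (i in seq_along(px)) {
    r <- row(img)[px[i]]; c <- col(img)[px[i]]
    want <- as.numeric(t(img[(r - 2):(r + 2), (c - 2):(c + 2)]))  # row-major
    expect_equal(got[i, ], want)
  }
  expect_equal(nrow(got), length(px))  # T conservation
})

test_that("even patch sizes are rejected", {
  expect_error(extract_patches(matrix(1, 5, 5), 13L, 4), "odd")
})

test_that("PCA recovers exact low-rank structure and full rank at target 1", {
  set.seed(8)
  basis <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  x <- matrix(rnorm(400), 200, 2) %*% t(basis)  # exactly rank 2 in 10-D
  fit <- fit_pca(x, 0.99)
  expect_equal(nrow(fit$components), 2)
  expect_gte(fit$explained_fraction, 0.99)

  full <- matrix(rnorm(300 * 9), 300, 9)
  expect_equal(nrow(fit_pca(full, 1.0)$components), 9)
})

test_that("PCA rows are orthonormal and reconstruction error matches dropped eigenvalue mass", {
  set.seed(13)
  x <- matrix(rnorm(500 * 10), 500, 10) %*% diag(sqrt(seq(0.1, 3, length.out = 10)))
  fit <- fit_pca(x, 0.7)
  G <- fit$components %*% t(fit$components)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)

  d <- nrow(fit$components)
  z <- apply_pca(fit, x)
  recon <- z %*% fit$components
  centered <- sweep(x, 2, fit$mean)
  mse <- mean(rowSums((centered - recon)^2))
  n <- nrow(x)
  expected <- (n - 1) / n * sum(fit$eigenvalues[(d + 1):length(fit$eigenvalues)])
  expect_equal(mse, expected, tolerance = 1e-10)
})

test_that("projection maps the mean to zero, is identity-safe and contractive", {
  set.seed(2)
  x <- matrix(rnorm(200 * 6), 200, 6)
  fit <- fit_pca(x, 0.9)
  expect_equal(as.numeric(apply_pca(fit, fit$mean)), numeric(nrow(fit$components)),
               tolerance = 1e-12)

  ident <- structure(list(mean = rep(0, 6), components = diag(6),
                          eigenvalues = rep(1, 6), explained_fraction = 1),
                     class = "pca_model")
  expect_equal(apply_pca(ident, x), x)

  z <- apply_pca(fit, x)
  centered <- sweep(x, 2, fit$mean)
  expect_true(all(rowSums(z^2) <= rowSums(centered^2) + 1e-10))

  expect_error(apply_pca(fit, x[, 1:4]), "dimension")
})

test_that("a zero-variance sample degrades to one component with a warning", {
  x <- matrix(3, 50, 4)
  expect_warning(fit <- fit_pca(x, 0.99), "degenerate")
  expect_equal(nrow(fit$components), 1)
})
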
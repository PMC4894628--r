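test_that("N = 1 yields a single subregion equal to the ROI pixel set", {
  img <- matrix(runif(36), 6, 6)
  m <- matrix(0, 6, 6); m[2:4, 3:5] <- 1
  part <- divide_by_intensity_order(img, m, 1)
  expect_length(part$subregions, 1)
  expect_setequal(part$subregions[[1]], which(m == 1))
})

test_that("pixels split into low/high intensity bins by value then raster order", {
  # intensities 3,1,4,1,5,9,2,6 in raster (row-major) order on a 2x4 image
  img <- matrix(c(3, 1, 4, 1, 5, 9, 2, 6), 2, 4, byrow = TRUE)
  part <- divide_by_intensity_order(img, matrix(1, 2, 4), 2)
  expect_setequal(sort(img[part$subregions[[1]]]), c(1, 1, 2, 3))
  expect_setequal(sort(img[part$subregions[[2]]]), c(4, 5, 6, 9))
})

test_that("constant images are split by raster order (tie-break rule)", {
  img <- matrix(5, 4, 4)
  part <- divide_by_intensity_order(img, matrix(1, 4, 4), 2)
  # raster order = row-major: rows 1-2 form the first half, rows 3-4 the second
  expect_true(all(row(img)[part$subregions[[1]]] <= 2))
  expect_true(all(row(img)[part$subregions[[2]]] >= 3))
})

test_that("remainder pixels land in the lowest-intensity bins first", {
  img <- matrix(seq_len(12), 3, 4)
  m <- matrix(0, 3, 4); m[which(img <= 10)] <- 1
  part <- divide_by_intensity_order(img, m, 4)
  expect_equal(lengths(part$subregions), c(3, 3, 2, 2))
})

test_that("partitions are disjoint, exhaustive, balanced and intensity-ordered", {
  set.seed(11)
  for (i in 1:100) {
    nr <- sample(5:14, 1); nc <- sample(5:14, 1)
    img <- matrix(sample(0:6, nr * nc, replace = TRUE), nr, nc)  # many ties
    m <- matrix(0, nr, nc)
    m[sample(nr * nc, sample(4:(nr * nc), 1))] <- 1
    N <- sample(1:min(4, sum(m)), 1)
    part <- divide_by_intensity_order(img, m, N)
    px <- unlist(part$subregions)
    expect_equal(sort(px), sort(which(m == 1)))        # coverage
    expect_equal(anyDuplicated(px), 0)                 # disjoint
    sizes <- lengths(part$subregions)
    expect_lte(max(sizes) - min(sizes), 1)             # balance
    if (N > 1) {
      for (b in seq_len(N - 1)) {
        expect_lte(max(img[part$subregions[[b]]]),
                   min(img[part$subregions[[b + 1]]]))  # ordering
      }
    }
  }
})

test_that("translation of image and mask translates the partition", {
  set.seed(3)
  img <- matrix(runif(64), 8, 8)
  m <- matrix(0, 8, 8); m[2:4, 2:5] <- 1
  part <- divide_by_intensity_order(img, m, 3)
  shift <- function(x, dr, dc) {
    out <- matrix(0, nrow(x), ncol(x))
    out[(1 + dr):nrow(x), (1 + dc):ncol(x)] <-
      x[1:(nrow(x) - dr), 1:(ncol(x) - dc)]
    out
  }
  img2 <- shift(img, 2, 1); img2[img2 == 0] <- 99
  part2 <- divide_by_intensity_order(img2, shift(m, 2, 1), 3)
  for (b in 1:3) {
    r1 <- row(img)[part$subregions[[b]]]; c1 <- col(img)[part$subregions[[b]]]
    r2 <- row(img)[part2$subregions[[b]]]; c2 <- col(img)[part2$subregions[[b]]]
    expect_setequal(paste(r1 + 2, c1 + 1), paste(r2, c2))
  }
})

test_that("degenerate inputs raise the documented errors", {
  img <- matrix(runif(16), 4, 4)
  m <- matrix(0, 4, 4); m[1, 1:2] <- 1
  expect_error(divide_by_intensity_order(img, m, 3), "too few pixels")
  expect_error(divide_by_intensity_order(img, m, 0), "N")
  expect_error(divide_by_intensity_order(img, matrix(0, 4, 4), 1), "empty")
})
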
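#' Split an ROI into subregions by intensity order
#'
#' The shape-adaptive spatial pooling used in place of a fixed spatial-grid
#' pyramid: ROI pixels are sorted by intensity in ascending order and cut
#' into `N` consecutive, equal-sized bins; pixels of one bin form one pooling
#' subregion. Because the split follows intensity ranks rather than a grid,
#' it applies to ROIs of any shape.
#'
#' Ties in intensity are broken by raster (row-major) pixel index, and when
#' `|ROI| = qN + r` the first `r` (lowest-intensity) bins receive `q + 1`
#' pixels; both rules are fixed so partitions are reproducible.
#'
#' @param image numeric intensity matrix.
#' @param roi an [augment_tumor_region()] result or a binary mask matrix of
#'   the same shape.
#' @param N number of subregions (>= 1, at most the ROI pixel count).
#' @return An object of class `roi_partition`: list with `subregions` (list
#'   of `N` integer vectors of 1-based column-major pixel indices, ordered
#'   from lowest to highest intensity bin) and `source_shape`.
#' @export
divide_by_intensity_order <- function(image, roi, N) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix")
  }
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!identical(dim(mask), dim(image))) {
    stop("ROI shape does not match image shape")
  }
  partition_pixels(image, roi_pixels(roi), N)
}

# Core partition on an explicit pixel set (used directly by the pipeline when
# stride subsampling reduces the pixel set before pooling).
partition_pixels <- function(image, pixels, N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("`N` must be a single integer >= 1")
  }
  N <- as.integer(N)
  M <- length(pixels)
  if (M == 0L) stop("ROI is empty")
  if (M < N) stop("too few pixels: ROI has ", M, " pixels but N = ", N)
  ord <- order(image[pixels], px_raster_rank(pixels, dim(image)))
  sorted <- pixels[ord]
  q <- M %/% N
  r <- M %% N
  sizes <- q + as.integer(seq_len(N) <= r)
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-N] + 1L)
  subregions <- lapply(seq_len(N), function(i) sorted[starts[i]:ends[i]])
  structure(list(subregions = subregions, source_shape = dim(image)),
            class = "roi_partition")
}

#' @export
print.roi_partition <- function(x, ...) {
  cat(sprintf("<roi_partition> %d subregions over %dx%d, sizes: %s\n",
              length(x$subregions), x$source_shape[1], x$source_shape[2],
              paste(lengths(x$subregions), collapse = ", ")))
  invisible(x)
}
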
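#' Augment the tumor region by disk dilation
#'
#' Builds the region of interest used for feature extraction: the tumor mask
#' dilated with a disk-shaped structuring element of radius `R` pixels, so
#' that peri-tumoral tissue (which carries diagnostic context, e.g.
#' meningiomas abutting the skull) enters the ROI. A pixel is foreground in
#' the result iff its Euclidean distance to some tumor-mask foreground pixel
#' is at most `R`; the result is clipped to the image bounds. `R = 0` returns
#' the tumor mask itself.
#'
#' The dilation is computed by thresholding the exact Euclidean distance
#' transform of the mask complement (`EBImage::distmap`).
#'
#' @param tumor_mask binary matrix with at least one foreground pixel.
#' @param R dilation radius in pixels (integer >= 0).
#' @return An object of class `roi_mask`: list with `mask` (binary integer
#'   matrix, a superset of `tumor_mask`) and `radius_used`.
#' @examples
#' m <- matrix(0, 7, 7); m[4, 4] <- 1
#' sum(augment_tumor_region(m, 1)$mask)  # 5: center plus 4-neighbors
#' @export
augment_tumor_region <- function(tumor_mask, R) {
  if (!is_binary_matrix(tumor_mask)) {
    stop("`tumor_mask` must be a binary (0/1) numeric matrix")
  }
  if (sum(tumor_mask) < 1) {
    stop("`tumor_mask` must contain at least one foreground pixel")
  }
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R < 0) {
    stop("`R` must be a single non-negative number")
  }
  mask <- matrix(as.integer(tumor_mask), nrow(tumor_mask), ncol(tumor_mask))
  if (R == 0) {
    out <- mask
  } else {
    dist_to_tumor <- EBImage::distmap(1L - mask)
    out <- matrix(0L, nrow(mask), ncol(mask))
    out[mask == 1L | dist_to_tumor <= R] <- 1L
  }
  structure(list(mask = out, radius_used = as.numeric(R)), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %dx%d, R=%g, foreground px=%d\n",
              nrow(x$mask), ncol(x$mask), x$radius_used, sum(x$mask)))
  invisible(x)
}

# Foreground pixels of an ROI (or raw binary mask) as 1-based column-major
# linear indices.
roi_pixels <- function(roi) {
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  which(mask == 1L)
}
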
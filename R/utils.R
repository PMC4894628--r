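# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never clobber user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of the single config seed into per-stage, per-fold
# seeds. Stage ids are fixed so every stage is independently reproducible.
stage_seed <- function(seed, stage, fold = 0L) {
  stages <- c(
    split = 1L, pca_sample = 2L, gmm = 3L, vocab = 4L,
    phantom = 5L, permute = 6L, baseline = 7L
  )
  id <- stages[[stage]]
  (as.integer(seed) %% 100003L) * 20011L + id * 1009L + as.integer(fold) * 7919L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pixel sets are 1-based column-major linear indices into the image matrix.
px_row <- function(px, nrow) ((px - 1L) %% nrow) + 1L
px_col <- function(px, nrow) ((px - 1L) %/% nrow) + 1L

# Raster (row-major) rank of a pixel, used as the deterministic tie-break key
# when sorting by intensity.
px_raster_rank <- function(px, dim) {
  (px_row(px, dim[1L]) - 1L) * dim[2L] + px_col(px, dim[1L])
}

is_binary_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
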
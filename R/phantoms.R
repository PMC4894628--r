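#' Parameters of the synthetic phantom cohort generator
#'
#' The generator emulates the structure of a multi-patient brain-tumor slice
#' archive: several pathological classes, an irregular simply-connected tumor
#' per slice, class-specific tumor *texture* (a smoothed noise field whose
#' mean, spread and correlation length depend on the class) and
#' class-specific *peri-tumoral context* (an annulus just outside the mask
#' whose mean intensity and width depend on the class). A per-patient
#' intensity offset shared by all of a patient's slices makes
#' patient-stratified cross-validation genuinely harder than slice-random
#' splitting.
#'
#' `separability` linearly scales every between-class parameter difference:
#' at 0 all classes are drawn from one distribution (labels are exchangeable),
#' at 1 the classes are clearly distinct at the default noise levels.
#'
#' @param n_patients number of patients.
#' @param slices_per_patient integer range `c(min, max)`; each patient
#'   contributes a uniform draw from this range.
#' @param n_classes number of tumor classes (>= 2); patients are assigned to
#'   classes round-robin.
#' @param image_size side of the square slice in pixels.
#' @param tumor_radius_range `c(min, max)` base tumor radius in pixels.
#' @param background_noise_sd standard deviation of the background noise.
#' @param patient_offset_sd standard deviation of the per-patient intensity
#'   offset.
#' @param separability scalar >= 0 scaling between-class differences.
#' @param seed generator seed; identical seeds give bitwise-identical cohorts.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(n_patients = 45L,
                           slices_per_patient = c(2L, 4L),
                           n_classes = 3L,
                           image_size = 96L,
                           tumor_radius_range = c(10, 18),
                           background_noise_sd = 0.04,
                           patient_offset_sd = 0.04,
                           separability = 1,
                           seed = 1L) {
  if (length(slices_per_patient) == 1L) {
    slices_per_patient <- rep(slices_per_patient, 2L)
  }
  p <- list(
    n_patients = as.integer(n_patients),
    slices_per_patient = as.integer(slices_per_patient),
    n_classes = as.integer(n_classes),
    image_size = as.integer(image_size),
    tumor_radius_range = as.numeric(tumor_radius_range),
    background_noise_sd = as.numeric(background_noise_sd),
    patient_offset_sd = as.numeric(patient_offset_sd),
    separability = as.numeric(separability),
    seed = as.integer(seed)
  )
  stopifnot(
    p$n_patients >= 1L, p$n_classes >= 2L,
    all(p$slices_per_patient >= 1L),
    p$slices_per_patient[1] <= p$slices_per_patient[2],
    p$image_size >= 16L,
    length(p$tumor_radius_range) == 2L,
    all(p$tumor_radius_range > 0),
    p$tumor_radius_range[1] <= p$tumor_radius_range[2],
    p$background_noise_sd >= 0, p$patient_offset_sd >= 0,
    p$separability >= 0
  )
  structure(p, class = "phantom_params")
}

# Per-class appearance parameters. All between-class differences scale with
# `separability`; at 0 every class collapses onto the base values.
phantom_class_table <- function(params) {
  n <- params$n_classes
  sep <- params$separability
  z <- if (n == 1L) 0 else (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
  data.frame(
    class = seq_len(n),
    texture_mean = 0.55 + 0.12 * sep * z,
    texture_sd = pmax(0.02, 0.10 * (1 + 0.25 * sep * z)),
    texture_corr = pmax(0.4, 1.6 + 0.6 * sep * z),
    context_mean = 0.40 + 0.15 * sep * z,
    context_width = pmax(1, 5 + 2 * sep * z)
  )
}

# Gaussian white noise smoothed to correlation length `sigma`, standardized.
smoothed_noise_field <- function(nr, nc, sigma) {
  field <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma > 0) field <- EBImage::gblur(field, sigma = sigma)
  (field - mean(field)) / stats::sd(field)
}

# Irregular star-shaped (hence simply connected) tumor mask: a disk whose
# radius is modulated over angle by a low-order harmonic series with relative
# amplitude capped at 0.3.
random_tumor_mask <- function(size, center, r0) {
  amps <- stats::runif(3, 0, 1)
  phases <- stats::runif(3, 0, 2 * pi)
  total <- sum(amps)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dy <- rows - center[1]
  dx <- cols - center[2]
  rr <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  dev <- 0
  if (total > 0) {
    for (k in 1:3) {
      dev <- dev + amps[k] * cos((k + 1) * theta + phases[k])
    }
    dev <- 0.3 * dev / total
  }
  mask <- matrix(0L, size, size)
  mask[rr <= r0 * (1 + dev)] <- 1L
  mask
}

#' Generate a labeled synthetic phantom cohort
#'
#' See [phantom_params()] for what the phantoms emulate. Each slice is built
#' as: background noise everywhere, class-specific smoothed-noise texture
#' inside the tumor mask, class-specific context intensity in an annulus of
#' class-specific width just outside the mask, plus the patient's shared
#' intensity offset.
#'
#' @param params a [phantom_params()].
#' @return A [cbir_cohort()] whose patients each carry one class.
#' @examples
#' cohort <- generate_cohort(phantom_params(n_patients = 6, seed = 2))
#' cohort
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  size <- params$image_size
  classes <- phantom_class_table(params)
  rmax <- params$tumor_radius_range[2] * 1.3
  margin <- ceiling(rmax + max(classes$context_width) + 2)
  if (2 * margin + 2 > size) {
    stop("tumor cannot fit: image_size ", size,
         " too small for tumor_radius_range plus context (need > ",
         2 * margin + 2, ")")
  }
  with_seed(params$seed, {
    cases <- list()
    for (p in seq_len(params$n_patients)) {
      cls <- ((p - 1L) %% params$n_classes) + 1L
      cp <- classes[cls, ]
      pid <- sprintf("P%03d", p)
      offset <- stats::rnorm(1, 0, params$patient_offset_sd)
      n_slices <- if (params$slices_per_patient[1] == params$slices_per_patient[2]) {
        params$slices_per_patient[1]
      } else {
        sample(params$slices_per_patient[1]:params$slices_per_patient[2], 1)
      }
      for (s in seq_len(n_slices)) {
        center <- stats::runif(2, margin + 1, size - margin)
        r0 <- stats::runif(1, params$tumor_radius_range[1],
                           params$tumor_radius_range[2])
        mask <- random_tumor_mask(size, center, r0)
        img <- 0.15 + matrix(stats::rnorm(size^2, 0, params$background_noise_sd),
                             size, size)
        dm <- EBImage::distmap(1 - mask)
        annulus <- mask == 0L & dm <= cp$context_width
        img[annulus] <- cp$context_mean + stats::rnorm(sum(annulus), 0, 0.03)
        field <- smoothed_noise_field(size, size, cp$texture_corr)
        inside <- mask == 1L
        img[inside] <- cp$texture_mean + cp$texture_sd * field[inside]
        img <- img + offset
        cases[[length(cases) + 1L]] <- tumor_case(img, mask, cls, pid)
      }
    }
    cbir_cohort(cases)
  })
}

#' Morphologically jitter a tumor mask
#'
#' Adds a smooth random field, scaled to `magnitude` pixels, to the signed
#' Euclidean distance function of the mask and re-thresholds at zero. This
#' shifts the boundary by roughly `magnitude` pixels while keeping the region
#' coherent, emulating the rough outlines a user would draw; overlap with the
#' original mask is guaranteed.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @param magnitude boundary displacement scale in pixels (>= 0; 0 returns
#'   the mask unchanged).
#' @param seed RNG seed for the displacement field.
#' @return A binary integer matrix of the same shape.
#' @export
perturb_mask <- function(mask, magnitude, seed = 1L) {
  if (!is_binary_matrix(mask)) stop("`mask` must be a binary matrix")
  if (sum(mask) < 1) stop("`mask` must contain at least one foreground pixel")
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0) {
    stop("`magnitude` must be a single non-negative number")
  }
  storage.mode(mask) <- "integer"
  if (magnitude == 0) return(mask)
  sdf <- EBImage::distmap(mask) - EBImage::distmap(1L - mask)
  out <- with_seed(seed, {
    field <- smoothed_noise_field(nrow(mask), ncol(mask), sigma = 3)
    m <- matrix(0L, nrow(mask), ncol(mask))
    m[sdf + magnitude * field > 0] <- 1L
    m
  })
  if (!any(out == 1L & mask == 1L)) {
    out[which.max(sdf)] <- 1L  # keep the deepest interior pixel
  }
  out
}
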
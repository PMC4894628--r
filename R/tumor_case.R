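#' A single tumor slice
#'
#' Bundles one 2D grayscale slice with its binary tumor mask, pathological
#' class label and patient identifier. Intensities are kept on whatever scale
#' they were acquired or generated on; the pipeline never rescales them.
#'
#' @param image numeric matrix of pixel intensities.
#' @param tumor_mask binary (0/1) matrix of the same shape with at least one
#'   foreground pixel.
#' @param label class label (small integer; 1 = meningioma, 2 = glioma,
#'   3 = pituitary tumor for the public CE-MRI dataset).
#' @param patient_id scalar character identifying the patient the slice
#'   belongs to.
#' @return An object of class `tumor_case`.
#' @export
tumor_case <- function(image, tumor_mask, label, patient_id) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix")
  }
  if (!is_binary_matrix(tumor_mask)) {
    stop("`tumor_mask` must be a binary (0/1) numeric matrix")
  }
  if (!identical(dim(image), dim(tumor_mask))) {
    stop("`tumor_mask` shape ", paste(dim(tumor_mask), collapse = "x"),
         " does not match `image` shape ", paste(dim(image), collapse = "x"))
  }
  if (sum(tumor_mask) < 1) {
    stop("`tumor_mask` must contain at least one foreground pixel")
  }
  if (length(label) != 1L || !is.numeric(label) || is.na(label)) {
    stop("`label` must be a single numeric class identifier")
  }
  if (length(patient_id) != 1L || !is.character(patient_id) || is.na(patient_id)) {
    stop("`patient_id` must be a single character string")
  }
  storage.mode(image) <- "double"
  mask <- matrix(as.integer(tumor_mask), nrow(tumor_mask), ncol(tumor_mask))
  structure(
    list(image = image, tumor_mask = mask,
         label = as.integer(label), patient_id = patient_id),
    class = "tumor_case"
  )
}

#' @export
print.tumor_case <- function(x, ...) {
  cat(sprintf("<tumor_case> %dx%d, label=%d, patient=%s, tumor px=%d\n",
              nrow(x$image), ncol(x$image), x$label, x$patient_id,
              sum(x$tumor_mask)))
  invisible(x)
}

#' A cohort of tumor slices
#'
#' An ordered collection of [tumor_case()] objects. Every patient must carry
#' a single class label across all of their slices (slices of one patient are
#' never split across classes, matching the clinical setting).
#'
#' @param cases list of `tumor_case` objects.
#' @return An object of class `cbir_cohort`.
#' @export
cbir_cohort <- function(cases) {
  if (!length(cases) || !all(vapply(cases, inherits, logical(1), "tumor_case"))) {
    stop("`cases` must be a non-empty list of tumor_case objects")
  }
  labels <- vapply(cases, `[[`, integer(1), "label")
  patients <- vapply(cases, `[[`, character(1), "patient_id")
  for (p in unique(patients)) {
    if (length(unique(labels[patients == p])) != 1L) {
      stop("patient ", p, " carries more than one class label")
    }
  }
  structure(
    list(cases = cases, class_set = sort(unique(labels))),
    class = "cbir_cohort"
  )
}

#' @export
length.cbir_cohort <- function(x) length(x$cases)

#' @export
print.cbir_cohort <- function(x, ...) {
  labels <- cohort_labels(x)
  cat(sprintf("<cbir_cohort> %d slices, %d patients, classes: %s\n",
              length(x$cases), length(unique(cohort_patients(x))),
              paste(sprintf("%d (n=%d)", x$class_set,
                            tabulate(factor(labels, x$class_set))),
                    collapse = ", ")))
  invisible(x)
}

#' Per-slice labels of a cohort
#' @param cohort a `cbir_cohort`.
#' @return Integer vector, one label per slice.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$cases, `[[`, integer(1), "label")
}

#' Per-slice patient identifiers of a cohort
#' @param cohort a `cbir_cohort`.
#' @return Character vector, one patient id per slice.
#' @export
cohort_patients <- function(cohort) {
  vapply(cohort$cases, `[[`, character(1), "patient_id")
}
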
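#' Read one tumor slice from an HDF5 container
#'
#' Expects the per-slice layout used throughout this package: datasets
#' `image`, `tumorMask`, `label` and `PID` at the file root. Files of the
#' public brain-tumor CE-MRI archive, which keep the same four fields inside
#' a `cjdata/` group (MATLAB v7.3 containers are HDF5 files), are read
#' transparently. Intensities are returned exactly as stored; no rescaling
#' or type promotion beyond double precision is applied.
#'
#' @param path path to an HDF5 file holding one slice.
#' @return A validated [tumor_case()].
#' @export
read_case <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)
  at_root <- function(f) any(contents$group == "/" & contents$name == f)
  in_cjdata <- function(f) any(contents$group == "/cjdata" & contents$name == f)
  prefix <- if (at_root("image")) {
    ""
  } else if (in_cjdata("image")) {
    "cjdata/"
  } else {
    stop("format error: dataset `image` not found in ", path)
  }
  fields <- c("image", "tumorMask", "label", "PID")
  for (f in fields) {
    ok <- if (prefix == "") at_root(f) else in_cjdata(f)
    if (!ok) stop("format error: dataset `", f, "` not found in ", path)
  }
  rd <- function(f) rhdf5::h5read(path, paste0(prefix, f))
  image <- as_numeric_matrix(rd("image"))
  mask <- as_numeric_matrix(rd("tumorMask"))
  mask[mask != 0] <- 1
  label <- as.numeric(rd("label"))[1]
  pid <- rd("PID")
  if (is.numeric(pid)) pid <- intToUtf8(as.integer(pid))  # MATLAB char codes
  pid <- as.character(pid)[1]
  tumor_case(image, mask, label, pid)
}

as_numeric_matrix <- function(x) {
  x <- drop(x)
  if (!is.matrix(x)) stop("format error: expected a 2D dataset")
  storage.mode(x) <- "double"
  x
}

#' Write one tumor slice to an HDF5 container
#'
#' Writes the four datasets `image` (float64), `tumorMask` (integer 0/1),
#' `label` and `PID` at the file root, the layout [read_case()] reads back
#' losslessly.
#'
#' @param case a [tumor_case()].
#' @param path destination file; overwritten if present.
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path) {
  if (!inherits(case, "tumor_case")) {
    case <- tumor_case(case$image, case$tumor_mask, case$label, case$patient_id)
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(case$image, path, "image")
  rhdf5::h5write(case$tumor_mask, path, "tumorMask")
  rhdf5::h5write(case$label, path, "label")
  rhdf5::h5write(case$patient_id, path, "PID")
  invisible(path)
}

#' Write a cohort as one HDF5 file per slice
#'
#' @param cohort a [cbir_cohort()].
#' @param dir destination directory (created if needed). Files are named
#'   `case_0001.h5`, `case_0002.h5`, ... in cohort order so the on-disk
#'   ordering is stable.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$cases)) {
    write_case(cohort$cases[[i]], file.path(dir, sprintf("case_%04d.h5", i)))
  }
  invisible(dir)
}

#' Read a cohort from a directory of per-slice HDF5 files
#'
#' Files are read in lexicographic order, so a cohort written with
#' [write_cohort()] round-trips with its ordering intact.
#'
#' @param dir directory containing `.h5`/`.mat` slice files.
#' @return A [cbir_cohort()].
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(h5|mat)$", full.names = TRUE))
  if (!length(files)) stop("no .h5/.mat slice files found in ", dir)
  cbir_cohort(lapply(files, read_case))
}
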
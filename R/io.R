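#' Write a DWI dataset as NIfTI + FSL-style sidecars
#'
#' Writes `<prefix>.nii.gz`, `<prefix>.bval` (one row of b-values) and
#' `<prefix>.bvec` (three rows: x, y, z components per volume).
#'
#' @param dwi A `dwi_dataset`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(dwi$data,
                         pixdim = rep(dwi$voxel_size, 3))
  RNifti::writeNifti(img, nii)
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(dwi$scheme$bvals, collapse = " "), bval)
  writeLines(apply(t(dwi$scheme$bvecs), 1, paste, collapse = " "), bvec)
  invisible(c(nii = nii, bval = bval, bvec = bvec))
}

#' Read a DWI dataset from NIfTI + bval/bvec
#'
#' @param prefix Path prefix as used by [write_dwi()], or explicit paths.
#' @param nii,bval,bvec Optional explicit paths overriding the prefix.
#' @param origin Grid origin (mm); defaults to a grid centered on 0, the
#'   package's template-space convention.
#' @return A `dwi_dataset`.
#' @export
read_dwi <- function(prefix = NULL, nii = NULL, bval = NULL, bvec = NULL,
                     origin = NULL) {
  if (!is.null(prefix)) {
    nii <- nii %||% paste0(prefix, ".nii.gz")
    bval <- bval %||% paste0(prefix, ".bval")
    bvec <- bvec %||% paste0(prefix, ".bvec")
  }
  img <- RNifti::readNifti(nii)
  data <- array(as.numeric(img), dim(img))
  bvals <- scan(bval, quiet = TRUE)
  bvecs <- t(matrix(scan(bvec, quiet = TRUE), nrow = 3, byrow = TRUE))
  vox <- RNifti::pixdim(img)[1]
  shape <- dim(data)[1:3]
  if (is.null(origin)) origin <- -(shape - 1) / 2 * vox
  dw <- bvals > 0
  scheme <- new_acq_scheme(bvals, bvecs, sum(!dw))
  new_dwi_dataset(data, scheme, vox, origin)
}

#' Write tensor-derived maps as NIfTI volumes
#'
#' Writes `dxx.nii.gz`, `dyy.nii.gz`, `dzz.nii.gz`, `fa.nii.gz` and
#' `md.nii.gz` into `dir`, plus the full 6-component tensor as
#' `tensor.nii.gz` (component order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#'
#' @param tensors A `tensor_field`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_tensor_maps <- function(tensors, dir) {
  stopifnot(inherits(tensors, "tensor_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- rep(tensors$voxel_size, 3)
  paths <- character()
  for (nm in c("dxx", "dyy", "dzz", "fa", "md")) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(tensors[[nm]], pixdim = px), p)
    paths[nm] <- p
  }
  p <- file.path(dir, "tensor.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(tensors$D, pixdim = px), p)
  paths["tensor"] <- p
  invisible(paths)
}

#' Write a cohort CSV with its data dictionary
#'
#' @param cohort A participant tibble from [make_cohort()].
#' @param path CSV output path; the dictionary is written next to it as
#'   `<path basename>_dictionary.json`.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  dict <- attr(cohort, "dictionary") %||% cohort_dictionary()
  dict_path <- sub("\\.csv$", "_dictionary.json", path)
  jsonlite::write_json(dict, dict_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = path, dictionary = dict_path))
}

#' Read a cohort CSV
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a motion-QC report as JSON
#'
#' @param qc A `motion_qc` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_json <- function(qc, path) {
  stopifnot(inherits(qc, "motion_qc"))
  out <- list(fd_series = qc$fd_series,
              rotation_series = qc$rotation_series,
              flagged_volumes = qc$flagged_volumes,
              replaced_volumes = qc$replaced_volumes,
              mean_fd = qc$mean_fd, excluded = qc$excluded,
              reason = qc$reason, thresholds = qc$thresholds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
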
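#' Write / read a DWI series as NIfTI plus b-value sidecar
#'
#' The 4D magnitude data go to a NIfTI file with the voxel size recorded in
#' the header; the per-acquisition b-values go to an FSL-style text sidecar
#' (one space-separated line, one value per volume).
#'
#' @param dwi a [dwi_series()].
#' @param nii_path output NIfTI path (`.nii` or `.nii.gz`).
#' @param bval_path output b-value sidecar path.
#' @return Invisibly, the two paths.
#' @export
write_dwi_nifti <- function(dwi, nii_path, bval_path = NULL) {
  stopifnot(inherits(dwi, "dwi_series"))
  if (is.null(bval_path)) bval_path <- sub("\\.nii(\\.gz)?$", ".bval", nii_path)
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(dwi$voxel_size_mm, 1)
  RNifti::writeNifti(img, nii_path)
  writeLines(paste(format(dwi$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  invisible(c(nii_path, bval_path))
}

#' @rdname write_dwi_nifti
#' @param nii_path,bval_path input paths.
#' @export
read_dwi_nifti <- function(nii_path, bval_path) {
  img <- RNifti::readNifti(nii_path)
  b <- scan(bval_path, quiet = TRUE)
  vox <- RNifti::pixdim(img)[1:3]
  dwi_series(array(as.numeric(img), dim(img)), b, vox)
}

#' Write / read a tissue mask as uint8 NIfTI
#'
#' @param mask a [tissue_mask()] or logical array.
#' @param path output path.
#' @param voxel_size_mm voxel size for the header.
#' @return Invisibly, the path.
#' @export
write_mask_nifti <- function(mask, path, voxel_size_mm = c(2.5, 2.5, 5.0)) {
  m <- as_mask_array(mask)
  img <- RNifti::asNifti(array(as.integer(m), dim(m)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask_nifti
#' @param label,provenance metadata for the reconstructed [tissue_mask()].
#' @export
read_mask_nifti <- function(path, label = "healthy", provenance = "resampled") {
  img <- RNifti::readNifti(path)
  tissue_mask(array(as.numeric(img) > 0, dim(img)), label, provenance)
}

#' Write a parametric map (or map stack) as NIfTI
#'
#' @param map 3D array, or 4D array for multi-volume output.
#' @param path output path.
#' @param voxel_size_mm voxel size for the header.
#' @return Invisibly, the path.
#' @export
write_map_nifti <- function(map, path, voxel_size_mm = c(2.5, 2.5, 5.0)) {
  img <- RNifti::asNifti(map)
  nd <- length(dim(map))
  RNifti::pixdim(img) <- if (nd == 4) c(voxel_size_mm, 1) else voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read the cohort table as CSV
#'
#' Column order is fixed and documented: patient_id, tissue, metric, median,
#' n_voxels, roi_volume_cm3.
#'
#' @param table a [build_cohort_table()] data.frame.
#' @param path CSV path.
#' @return Invisibly the path; `read_cohort_csv` returns the `cohort_table`.
#' @export
write_cohort_csv <- function(table, path) {
  cols <- c("patient_id", "tissue", "metric", "median", "n_voxels",
            "roi_volume_cm3")
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Validate a DWI dataset on disk
#'
#' Checks that the 4D volume count matches the number of b-value labels, that
#' mask grids agree with the DWI grid, and that signals are non-negative and
#' finite. All violations are collected rather than stopping at the first.
#'
#' @param dwi_path NIfTI path of the 4D series.
#' @param bvals_path b-value sidecar path.
#' @param mask_paths character vector of mask NIfTI paths.
#' @return Data.frame of class `validation_report` with columns `check`,
#'   `ok`, `detail`; attribute `valid` is TRUE when all checks pass.
#' @export
validate_inputs <- function(dwi_path, bvals_path, mask_paths = character(0)) {
  for (p in c(dwi_path, bvals_path, mask_paths))
    if (!file.exists(p)) stop(sprintf("cannot read '%s'", p))
  img <- RNifti::readNifti(dwi_path)
  b <- scan(bvals_path, quiet = TRUE)
  d <- dim(img)
  nvol <- if (length(d) == 4) d[4] else 1L
  rows <- list()
  add <- function(check, ok, detail)
    rows[[length(rows) + 1]] <<- data.frame(check = check, ok = ok,
                                            detail = detail)
  add("volume_label_count", nvol == length(b),
      sprintf("%d volumes, %d b-value labels", nvol, length(b)))
  add("b0_present", any(b == 0),
      if (any(b == 0)) "b = 0 shell present" else "no b = 0 volume")
  vals <- as.numeric(img)
  add("signal_finite", all(is.finite(vals)),
      sprintf("%d non-finite voxels", sum(!is.finite(vals))))
  add("signal_nonnegative", all(vals >= 0, na.rm = TRUE),
      sprintf("%d negative voxels", sum(vals < 0, na.rm = TRUE)))
  for (mp in mask_paths) {
    md <- dim(RNifti::readNifti(mp))[1:3]
    okm <- identical(as.integer(md), as.integer(d[1:3]))
    add(paste0("mask_grid:", basename(mp)), okm,
        sprintf("mask %s vs DWI %s", paste(md, collapse = "x"),
                paste(d[1:3], collapse = "x")))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", "data.frame")
  attr(out, "valid") <- all(out$ok)
  out
}
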
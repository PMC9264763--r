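#' Tissue region-of-interest mask
#'
#' @param mask logical 3D array on the DWI grid.
#' @param label tissue label: "malignant", "benign" or "healthy".
#' @param provenance free-text origin note ("drawn", "generated", "resampled").
#' @return An object of class `tissue_mask`.
#' @export
tissue_mask <- function(mask, label = c("malignant", "benign", "healthy"),
                        provenance = "drawn") {
  label <- match.arg(label)
  mask <- array(as.logical(mask), dim(mask))
  if (length(dim(mask)) != 3) stop("mask must be a 3D logical array")
  structure(list(mask = mask, label = label, provenance = provenance),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("Tissue mask '%s' (%s): %d voxels on a %s grid\n", x$label,
              x$provenance, sum(x$mask), paste(dim(x$mask), collapse = " x ")))
  invisible(x)
}

as_mask_array <- function(m) if (inherits(m, "tissue_mask")) m$mask else m

#' Healthy control ROI in the contralateral breast
#'
#' Constructs a box-shaped control region of exactly `n_target` voxels in the
#' half of the grid contralateral to the malignant lesion (the x-half not
#' containing the malignant mask centroid). Voxels belonging to any lesion
#' mask or exclusion mask (benign lesions, axilla, cysts, artifacts,
#' non-tissue background) are ineligible; the box is grown symmetrically from
#' the centroid of the eligible region until it holds enough eligible voxels,
#' then trimmed to exactly `n_target` voxels (those nearest the box centre,
#' deterministic index tie-break).
#'
#' @param grid_dim length-3 grid size.
#' @param lesion_masks list of [tissue_mask()]s; the one labelled "malignant"
#'   defines laterality, all of them are excluded from the ROI.
#' @param exclusion_masks list of additional logical arrays or `tissue_mask`s
#'   to exclude.
#' @param n_target required ROI size in voxels (default 500).
#' @param seed unused (the construction is deterministic); kept so cohort
#'   drivers can thread a seed scheme through uniformly.
#' @return A [tissue_mask()] labelled "healthy" with exactly `n_target`
#'   voxels.
#' @export
define_healthy_control_roi <- function(grid_dim, lesion_masks,
                                       exclusion_masks = list(),
                                       n_target = 500, seed = NULL) {
  grid_dim <- as.integer(grid_dim)
  labels <- vapply(lesion_masks, function(m)
    if (inherits(m, "tissue_mask")) m$label else "", "")
  imal <- match("malignant", labels)
  if (is.na(imal)) stop("a malignant lesion mask is required to define laterality")
  malm <- as_mask_array(lesion_masks[[imal]])
  cx <- mean(arrayInd(which(malm), grid_dim)[, 1])
  contra_x <- if (cx > grid_dim[1] / 2) seq_len(floor(grid_dim[1] / 2))
              else seq(floor(grid_dim[1] / 2) + 1, grid_dim[1])

  eligible <- array(TRUE, grid_dim)
  for (m in lesion_masks) eligible <- eligible & !as_mask_array(m)
  for (m in exclusion_masks) eligible <- eligible & !as_mask_array(m)
  contra <- array(FALSE, grid_dim)
  contra[contra_x, , ] <- TRUE
  eligible <- eligible & contra
  n_avail <- sum(eligible)
  if (n_avail < n_target)
    stop(sprintf("only %d eligible contralateral voxels available, %d required",
                 n_avail, n_target))

  idx <- arrayInd(which(eligible), grid_dim)
  ctr <- round(colMeans(idx))
  # grow a box around the eligible-region centroid until it holds n_target
  half <- c(1, 1, 0)
  in_box <- function(half) {
    lo <- pmax(ctr - half, 1); hi <- pmin(ctr + half, grid_dim)
    box <- array(FALSE, grid_dim)
    box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    box & eligible
  }
  grow_axis <- 1L
  repeat {
    sel <- in_box(half)
    if (sum(sel) >= n_target) break
    if (all(ctr - half <= 1) && all(ctr + half >= grid_dim))
      stop("box growth exhausted the grid before reaching n_target")  # unreachable given n_avail check
    half[grow_axis] <- half[grow_axis] + 1
    grow_axis <- grow_axis %% 3L + 1L
  }
  # trim to exactly n_target: keep voxels nearest the box centre
  sel_idx <- which(sel)
  coords <- arrayInd(sel_idx, grid_dim)
  d2 <- colSums((t(coords) - ctr)^2)
  keep <- sel_idx[order(d2, sel_idx)][seq_len(n_target)]
  out <- array(FALSE, grid_dim)
  out[keep] <- TRUE
  tissue_mask(out, "healthy", "generated")
}

#' Median of a map over an ROI
#'
#' Median over the in-mask voxels of a parametric map, optionally intersected
#' with a validity mask first (used for ADC, whose negative/undefined voxels
#' are excluded). Even voxel counts use the midpoint of the two central order
#' statistics.
#'
#' @param map numeric 3D array.
#' @param mask a [tissue_mask()] or logical array.
#' @param validity optional logical array.
#' @return List with `median` and `n_voxels`.
#' @export
roi_median <- function(map, mask, validity = NULL) {
  m <- as_mask_array(mask)
  if (!identical(dim(m), dim(map))) stop("mask grid does not match the map")
  if (!is.null(validity)) m <- m & validity
  vals <- map[m]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop("ROI is empty after validity filtering")
  list(median = stats::median(vals), n_voxels = length(vals))
}

rsi_metrics <- c("C1", "C2", "C3", "C1C2", "sqrtC1C2", "ADC")

# metric maps + validity for one analyzed patient
patient_metric_maps <- function(fit, derived, adc) {
  list(maps = list(C1 = array(fit$C[, , , 1], dim(fit$residual)),
                   C2 = array(fit$C[, , , 2], dim(fit$residual)),
                   C3 = array(fit$C[, , , 3], dim(fit$residual)),
                   C1C2 = derived$product,
                   sqrtC1C2 = derived$root_product,
                   ADC = adc$adc),
       validity = list(ADC = adc$valid))
}

#' Cohort table of ROI medians
#'
#' Builds the long-format analysis table: one record per patient x tissue type
#' x metric, each holding the ROI median, the voxel count and the ROI volume.
#' Patients with several benign lesions contribute a single pooled benign
#' record per metric (all benign voxels pooled before the median; set
#' `benign_pooling = "median_of_medians"` for the per-lesion alternative).
#'
#' @param patients list; each element needs `maps` (named list of metric
#'   arrays over `r toString(rsi_metrics)`), `validity` (named list, e.g.
#'   ADC), and `masks` (list with `malignant`, `benign` (list), `healthy`).
#' @param voxel_size_mm voxel size used for ROI volume in cm^3.
#' @param benign_pooling `"pool_voxels"` (default) or `"median_of_medians"`.
#' @return A data.frame of class `cohort_table` with columns `patient_id`,
#'   `tissue`, `metric`, `median`, `n_voxels`, `roi_volume_cm3`.
#' @export
build_cohort_table <- function(patients, voxel_size_mm = c(2.5, 2.5, 5.0),
                               benign_pooling = c("pool_voxels",
                                                  "median_of_medians")) {
  benign_pooling <- match.arg(benign_pooling)
  vox_cm3 <- prod(voxel_size_mm) / 1000
  rows <- list()
  ids <- names(patients)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_along(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    for (tt in c("malignant", "benign", "healthy")) {
      mk <- p$masks[[tt]]
      if (is.null(mk) || (tt != "benign" && sum(as_mask_array(mk)) == 0))
        stop(sprintf("patient %s is missing a %s mask", ids[i], tt))
      for (met in rsi_metrics) {
        map <- p$maps[[met]]
        val <- p$validity[[met]]
        if (tt == "benign") {
          bl <- if (inherits(mk, "tissue_mask")) list(mk) else mk
          if (length(bl) == 0)
            stop(sprintf("patient %s is missing a benign mask", ids[i]))
          if (benign_pooling == "pool_voxels") {
            pooled <- Reduce(`|`, lapply(bl, as_mask_array))
            r <- roi_median(map, pooled, val)
          } else {
            meds <- vapply(bl, function(m) roi_median(map, m, val)$median, 0)
            r <- list(median = stats::median(meds),
                      n_voxels = sum(vapply(bl, function(m)
                        roi_median(map, m, val)$n_voxels, 0L)))
          }
        } else {
          r <- roi_median(map, mk, val)
        }
        rows[[length(rows) + 1]] <-
          data.frame(patient_id = ids[i], tissue = tt, metric = met,
                     median = r$median, n_voxels = r$n_voxels,
                     roi_volume_cm3 = r$n_voxels * vox_cm3)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d patients x %d tissues x %d metrics = %d records\n",
              length(unique(x$patient_id)), length(unique(x$tissue)),
              length(unique(x$metric)), nrow(x)))
  NextMethod()
}
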
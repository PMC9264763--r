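#' Estimate the magnitude-MRI noise floor
#'
#' The noise floor is the mean background signal of the magnitude data. With a
#' supplied background mask it is simply the mean over those voxels. By
#' default, background voxels are found from a histogram (256 equal-width bins)
#' of the mean b = 0 volume: the background forms the lowest-intensity mode,
#' and voxels below the first local minimum after that mode are taken as
#' background.
#'
#' @param dwi a [dwi_series()].
#' @param background_mask optional logical array on the DWI grid.
#' @param bins number of histogram bins for automatic detection.
#' @return Scalar noise-floor estimate in signal units.
#' @export
estimate_noise_floor <- function(dwi, background_mask = NULL, bins = 256) {
  stopifnot(inherits(dwi, "dwi_series"))
  sel <- which(dwi$bvalues == 0)
  if (length(sel) == 0) stop("no b = 0 volume present")
  gd <- dim(dwi$data)[1:3]
  vol <- array(rowMeans(matrix(dwi$data, prod(gd))[, sel, drop = FALSE]), gd)
  if (!is.null(background_mask)) {
    if (!identical(dim(background_mask), dim(vol)))
      stop("background mask grid does not match the DWI grid")
    if (sum(background_mask) == 0)
      stop("background mask covers zero voxels")
    return(mean(vol[background_mask]))
  }
  v <- as.numeric(vol)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])  # flat volume: everything is background
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), bins)
  # lowest-intensity mode: first bin that is a local maximum
  mode_i <- NA_integer_
  for (i in seq_len(bins)) {
    left <- if (i == 1) -Inf else counts[i - 1]
    right <- if (i == bins) -Inf else counts[i + 1]
    if (counts[i] >= left && counts[i] >= right && counts[i] > 0) {
      mode_i <- i; break
    }
  }
  if (is.na(mode_i)) stop("no background mode found in the signal histogram")
  # first local minimum after the mode
  min_i <- NA_integer_
  for (i in seq(mode_i + 1, bins - 1)) {
    if (counts[i] <= counts[i - 1] && counts[i] <= counts[i + 1]) {
      min_i <- i; break
    }
  }
  if (is.na(min_i)) stop("no background/tissue separation found in the histogram")
  thr <- (breaks[min_i] + breaks[min_i + 1]) / 2
  bg <- v[v < thr]
  if (length(bg) == 0) stop("no background voxels below the histogram minimum")
  mean(bg)
}

#' Subtract the noise floor from a DWI series
#'
#' Subtracts a scalar floor from every voxel of every acquisition, clipping at
#' zero (magnitude data and the downstream non-negative fit assume
#' non-negative signal).
#'
#' @param dwi a [dwi_series()].
#' @param floor non-negative scalar.
#' @return A [dwi_series()] of the same shape and labels.
#' @export
subtract_noise_floor <- function(dwi, floor) {
  stopifnot(inherits(dwi, "dwi_series"))
  if (floor < 0) stop("noise floor must be >= 0")
  dwi$data <- pmax(dwi$data - floor, 0)
  dwi
}

#' Average acquisitions within each b-value shell
#'
#' Voxel-wise arithmetic mean of all acquisitions sharing a b-value (diffusion
#' directions and repeated b = 0 volumes alike); output shells are sorted by
#' ascending b.
#'
#' @param dwi a [dwi_series()].
#' @return A `shell_avg_dwi` with one volume per distinct b-value.
#' @export
average_shells <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_series"))
  b <- sort(unique(dwi$bvalues))
  gd <- dim(dwi$data)[1:3]
  m <- matrix(dwi$data, prod(gd))
  vols <- array(0, c(gd, length(b)))
  for (i in seq_along(b)) {
    sel <- which(dwi$bvalues == b[i])
    vols[, , , i] <- rowMeans(m[, sel, drop = FALSE])
  }
  new_shell_avg(vols, b, dwi$voxel_size_mm)
}

#' Normalize shell-averaged data by a b = 0 percentile
#'
#' Divides every shell volume by the q-th percentile (linear interpolation
#' between order statistics, R quantile type 7) of the full b = 0 volume. After
#' normalization the q-th percentile of the b = 0 volume equals 1; ratios
#' between shells at every voxel are unchanged.
#'
#' @param avg a `shell_avg_dwi` from [average_shells()].
#' @param q percentile in (0, 100]; default 98.
#' @return A normalized `shell_avg_dwi`; the applied factor is recorded in
#'   `$norm_factor`.
#' @export
normalize_to_b0_percentile <- function(avg, q = 98) {
  stopifnot(inherits(avg, "shell_avg_dwi"))
  i0 <- which(avg$b == 0)
  if (length(i0) != 1) stop("shell-averaged data must contain one b = 0 volume")
  f <- as.numeric(stats::quantile(avg$volumes[, , , i0], q / 100, type = 7))
  if (!is.finite(f) || f <= 0)
    stop(sprintf("the %gth percentile of the b = 0 volume is not positive", q))
  avg$volumes <- avg$volumes / f
  avg$norm_factor <- if (is.na(avg$norm_factor)) f else avg$norm_factor * f
  avg
}

#' Identity pass-through correction hooks
#'
#' Geometric distortion (reverse-polarity-gradient) and eddy-current correction
#' are performed by external tools on real data; these hooks keep the pipeline
#' stage order explicit and let users substitute a real implementation.
#'
#' @param dwi a [dwi_series()].
#' @return The input, unchanged.
#' @export
rpg_correct <- function(dwi) dwi

#' @rdname rpg_correct
#' @export
eddy_correct <- function(dwi) dwi

#' Preprocessing chain for multi-shell DWI
#'
#' Runs the full preprocessing in fixed order: distortion/eddy hooks,
#' noise-floor estimation and subtraction, shell averaging, then normalization
#' by the 98th percentile of the b = 0 volume. Also retains the shell-averaged
#' data *without* noise correction, which is the input for ADC mapping.
#'
#' @param dwi a [dwi_series()].
#' @param background_mask optional logical array for floor estimation.
#' @param q normalization percentile.
#' @param bins histogram bins for floor estimation.
#' @return List with `avg` (noise-corrected, averaged, normalized
#'   `shell_avg_dwi`), `avg_raw` (averaged only, for ADC), `noise_floor`,
#'   `norm_factor` and a `report` list.
#' @export
preprocess_dwi <- function(dwi, background_mask = NULL, q = 98, bins = 256) {
  dwi <- eddy_correct(rpg_correct(dwi))
  floor <- estimate_noise_floor(dwi, background_mask, bins)
  avg_raw <- average_shells(dwi)
  corrected <- subtract_noise_floor(dwi, floor)
  avg <- normalize_to_b0_percentile(average_shells(corrected), q)
  list(avg = avg, avg_raw = avg_raw, noise_floor = floor,
       norm_factor = avg$norm_factor,
       report = list(noise_floor = floor, norm_factor = avg$norm_factor,
                     percentile = q, histogram_bins = bins,
                     n_acquisitions = dim(dwi$data)[4],
                     shells = avg$b))
}
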
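#' 4D diffusion-weighted series
#'
#' Container for a stack of 3D magnitude volumes, one per acquisition, each
#' labelled with its b-value.
#'
#' @param data 4D numeric array (x, y, z, acquisition), non-negative finite
#'   magnitudes.
#' @param bvalues numeric vector, one b-value per acquisition volume.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(data, bvalues, voxel_size_mm = c(2.5, 2.5, 5.0)) {
  data <- as.array(data)
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4)
    stop("data must be a 4D array (x, y, z, acquisition)")
  if (dim(data)[4] != length(bvalues))
    stop(sprintf("acquisition count (%d) does not match number of b-value labels (%d)",
                 dim(data)[4], length(bvalues)))
  if (any(!is.finite(data)))
    stop("signal values must be finite")
  if (any(bvalues < 0))
    stop("b-values must be >= 0")
  structure(list(data = data, bvalues = as.numeric(bvalues),
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI series: %d x %d x %d grid, %d acquisitions\n",
              d[1], d[2], d[3], d[4]))
  tb <- table(x$bvalues)
  cat("  b-values:", paste(sprintf("%s (x%d)", names(tb), as.integer(tb)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.dwi_series <- function(x) dim(x$data)

# shell-averaged series: one volume per distinct b-value
new_shell_avg <- function(volumes, b, voxel_size_mm, norm_factor = NA_real_) {
  structure(list(volumes = volumes, b = b, voxel_size_mm = voxel_size_mm,
                 norm_factor = norm_factor),
            class = "shell_avg_dwi")
}

#' @export
print.shell_avg_dwi <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("Shell-averaged DWI: %d x %d x %d grid, shells b = %s s/mm^2\n",
              d[1], d[2], d[3], paste(x$b, collapse = ", ")))
  if (!is.na(x$norm_factor))
    cat(sprintf("  normalized (factor %g)\n", x$norm_factor))
  invisible(x)
}

#' @export
dim.shell_avg_dwi <- function(x) dim(x$volumes)

# run fn with a private RNG stream seeded by `seed` (NULL = use current RNG)
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
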
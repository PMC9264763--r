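#' Multi-shell DWI acquisition protocol
#'
#' Describes a diffusion-weighted acquisition as a set of b-value shells with
#' per-shell acquisition counts plus the timing and geometry metadata needed to
#' reproduce the sequence. The default reproduces the breast protocol used
#' throughout this package: b = 0 (2 acquisitions, both phase-encode
#' polarities), 500 (6 directions), 1500 (6) and 4000 (15) s/mm^2, TE 82 ms,
#' TR 9000 ms, gradient pulse duration 29.34 ms, gradient interval 37.67 ms,
#' 2.5 x 2.5 x 5.0 mm^3 voxels.
#'
#' @param shells two-column matrix or data.frame with columns `b` (s/mm^2) and
#'   `n` (number of acquisitions per shell).
#' @param te_ms echo time in ms.
#' @param tr_ms repetition time in ms.
#' @param delta_ms diffusion gradient pulse duration (small delta) in ms.
#' @param Delta_ms diffusion gradient interval (big Delta) in ms.
#' @param voxel_size_mm length-3 numeric, voxel size in mm.
#' @return An object of class `rsi_protocol`.
#' @examples
#' p <- acquisition_protocol()
#' sum(p$shells$n)   # 29 acquisition volumes
#' @export
acquisition_protocol <- function(shells = data.frame(b = c(0, 500, 1500, 4000),
                                                     n = c(2, 6, 6, 15)),
                                 te_ms = 82, tr_ms = 9000,
                                 delta_ms = 29.34, Delta_ms = 37.67,
                                 voxel_size_mm = c(2.5, 2.5, 5.0)) {
  shells <- as.data.frame(shells)
  names(shells)[1:2] <- c("b", "n")
  if (any(!is.finite(shells$b)) || any(shells$b < 0))
    stop("all b-values must be finite and >= 0")
  if (anyDuplicated(shells$b))
    stop("duplicate b-value shells")
  if (!any(shells$b == 0))
    stop("protocol must contain a b = 0 shell")
  if (any(shells$n < 1) || any(shells$n != round(shells$n)))
    stop("every shell needs an integer acquisition count >= 1")
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive lengths")
  shells <- shells[order(shells$b), , drop = FALSE]
  rownames(shells) <- NULL
  structure(list(shells = shells, te_ms = te_ms, tr_ms = tr_ms,
                 delta_ms = delta_ms, Delta_ms = Delta_ms,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "rsi_protocol")
}

#' @export
print.rsi_protocol <- function(x, ...) {
  cat("DWI acquisition protocol\n")
  cat(sprintf("  shells (b s/mm^2 : n): %s  (%d volumes)\n",
              paste(sprintf("%g:%d", x$shells$b, x$shells$n), collapse = ", "),
              sum(x$shells$n)))
  cat(sprintf("  TE %g ms, TR %g ms, delta %g ms, Delta %g ms\n",
              x$te_ms, x$tr_ms, x$delta_ms, x$Delta_ms))
  cat(sprintf("  voxel %g x %g x %g mm\n", x$voxel_size_mm[1],
              x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Per-acquisition b-value labels of a protocol
#'
#' @param protocol an [acquisition_protocol()] object.
#' @return Numeric vector with one b-value per acquisition volume, in shell
#'   order.
#' @export
protocol_bvalues <- function(protocol) {
  stopifnot(inherits(protocol, "rsi_protocol"))
  rep(protocol$shells$b, protocol$shells$n)
}

#' Fixed diffusion spectrum of the compartment model
#'
#' The compartmental diffusivities are fixed constants of the model, not fitted
#' quantities; only the signal contributions C_i are estimated per voxel. The
#' default is the three-compartment breast spectrum: D1 = 0 mm^2/s (restricted),
#' D2 = 1.5e-3 mm^2/s (hindered), D3 = 10.8e-3 mm^2/s (pseudo-diffusion/flow).
#'
#' @param diffusivities strictly increasing non-negative diffusivities, mm^2/s.
#' @return An object of class `rsi_spectrum`.
#' @export
diffusion_spectrum <- function(diffusivities = c(0, 1.5e-3, 10.8e-3)) {
  d <- as.numeric(diffusivities)
  if (length(d) < 1 || any(!is.finite(d)) || any(d < 0))
    stop("diffusivities must be finite and >= 0")
  if (is.unsorted(d, strictly = TRUE))
    stop("diffusivities must be strictly increasing")
  structure(list(diffusivities = d), class = "rsi_spectrum")
}

#' @export
print.rsi_spectrum <- function(x, ...) {
  cat("Fixed diffusion spectrum (mm^2/s):",
      paste(format(x$diffusivities), collapse = ", "), "\n")
  invisible(x)
}
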
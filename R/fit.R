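#' Design matrix of the fixed-spectrum decay model
#'
#' Entry (j, i) is `exp(-b_j * D_i)`; the column of a zero diffusivity
#' (restricted compartment) is all ones. With at least as many distinct
#' b-values as components and distinct diffusivities the matrix has full
#' column rank, so the noiseless model is identifiable.
#'
#' @param b_values distinct non-negative b-values (s/mm^2).
#' @param spectrum a [diffusion_spectrum()].
#' @return Numeric matrix, shells x components.
#' @export
build_design_matrix <- function(b_values, spectrum = diffusion_spectrum()) {
  b <- as.numeric(b_values)
  if (any(b < 0)) stop("b-values must be >= 0")
  if (anyDuplicated(b)) stop("duplicate b-values in design")
  exp(-outer(b, spectrum$diffusivities))
}

#' Fit one voxel's signal-versus-b curve by NNLS
#'
#' @param signal per-shell signal vector (length = rows of `design`).
#' @param design matrix from [build_design_matrix()].
#' @return List with `coef` (non-negative compartment contributions) and
#'   `residual` (attained residual 2-norm).
#' @export
fit_nnls_voxel <- function(signal, design) {
  signal <- as.numeric(signal)
  if (length(signal) != nrow(design))
    stop("signal length must equal the number of design rows")
  if (any(!is.finite(signal))) stop("non-finite signal")
  fit <- nnls_fit(design, signal)
  list(coef = fit$coef, residual = fit$residual)
}

#' Voxel-wise fixed-spectrum compartment fit
#'
#' The central model fit: decomposes the shell-averaged diffusion signal of
#' every voxel into non-negative contributions of fixed-diffusivity
#' compartments, `S(b) = sum_i C_i exp(-b D_i)`, by exact non-negative least
#' squares. For the default breast spectrum the result is the C1 (restricted),
#' C2 (hindered) and C3 (pseudo-diffusion) maps plus a residual-norm map.
#'
#' @param object a `shell_avg_dwi` (from [average_shells()] /
#'   [preprocess_dwi()]), or a numeric matrix of signals (voxels x shells).
#' @param spectrum a [diffusion_spectrum()].
#' @param mask optional logical array (or, for matrix input, logical vector)
#'   restricting the fit; voxels outside the mask are NA in all output maps.
#' @param b_values required when `object` is a matrix: the per-column
#'   b-values.
#' @param ... unused.
#' @return An object of class `rsi_fit` with components `C` (4D array,
#'   last dimension indexing the compartments), `residual` (3D array),
#'   `b_values`, `design`, `spectrum`, `mask`, `data` (the input volumes) and
#'   `voxel_size_mm`. Supports `coef()`, `fitted()`, `residuals()`,
#'   `predict()`, `summary()`, `plot()` and `simulate()`.
#' @examples
#' b <- c(0, 500, 1500, 4000)
#' sig <- matrix(build_design_matrix(b) %*% c(0.32, 2.6, 0.13), 1)
#' fit <- rsi_fit(sig, b_values = b)
#' coef(fit)   # recovers c(0.32, 2.6, 0.13)
#' @export
rsi_fit <- function(object, spectrum = diffusion_spectrum(), mask = NULL,
                    b_values = NULL, ...) {
  if (inherits(object, "shell_avg_dwi")) {
    b <- object$b
    gd <- dim(object$volumes)[1:3]
    Y <- matrix(object$volumes, prod(gd))
    voxel_size <- object$voxel_size_mm
  } else {
    Y <- as.matrix(object)
    if (is.null(b_values))
      stop("b_values must be given for matrix input")
    b <- as.numeric(b_values)
    gd <- c(nrow(Y), 1L, 1L)
    voxel_size <- c(NA_real_, NA_real_, NA_real_)
  }
  p <- length(spectrum$diffusivities)
  if (length(b) < max(3, p))
    stop(sprintf("at least %d distinct b-value shells are required to fit %d components",
                 max(3, p), p))
  design <- build_design_matrix(b, spectrum)
  keep <- if (is.null(mask)) rep(TRUE, nrow(Y)) else as.logical(mask)
  if (length(keep) != nrow(Y)) stop("mask does not match the data grid")
  Cm <- matrix(NA_real_, nrow(Y), p)
  res <- rep(NA_real_, nrow(Y))
  if (any(keep)) {
    sol <- nnls_batch(design, Y[keep, , drop = FALSE])
    Cm[keep, ] <- sol$coef
    res[keep] <- sol$residual
  }
  structure(list(C = array(Cm, c(gd, p)),
                 residual = array(res, gd),
                 b_values = b, design = design, spectrum = spectrum,
                 mask = if (is.null(mask)) NULL else array(keep, gd),
                 data = array(Y, c(gd, length(b))),
                 voxel_size_mm = voxel_size,
                 call = match.call()),
            class = "rsi_fit")
}

#' @export
coef.rsi_fit <- function(object, ...) {
  p <- dim(object$C)[4]
  gd <- dim(object$C)[1:3]
  if (prod(gd) == 1) {
    co <- as.numeric(object$C)
    names(co) <- paste0("C", seq_len(p))
    return(co)
  }
  maps <- lapply(seq_len(p), function(i) array(object$C[, , , i], gd))
  names(maps) <- paste0("C", seq_len(p))
  maps
}

#' @export
fitted.rsi_fit <- function(object, ...) {
  gd <- dim(object$C)[1:3]
  p <- dim(object$C)[4]
  Cm <- matrix(object$C, prod(gd), p)
  array(Cm %*% t(object$design), c(gd, length(object$b_values)))
}

#' @export
residuals.rsi_fit <- function(object, ...) object$data - fitted(object)

#' Predict model signal at new b-values
#'
#' @param object an `rsi_fit`.
#' @param newdata numeric vector of b-values (defaults to the fitted shells).
#' @param ... unused.
#' @return Array (grid x length(newdata)) of model signals.
#' @export
predict.rsi_fit <- function(object, newdata = NULL, ...) {
  b <- if (is.null(newdata)) object$b_values else as.numeric(newdata)
  gd <- dim(object$C)[1:3]
  p <- dim(object$C)[4]
  D <- exp(-outer(b, object$spectrum$diffusivities))
  out <- array(matrix(object$C, prod(gd), p) %*% t(D), c(gd, length(b)))
  if (prod(gd) == 1) as.numeric(out) else out
}

#' Simulate noisy replicates from a fitted compartment model
#'
#' Draws Rician-noise replicates of the fitted signal, one complete set of
#' shell volumes per simulation.
#'
#' @param object an `rsi_fit`.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param sigma Rician channel sd in signal units.
#' @param ... unused.
#' @return List of `nsim` arrays shaped like the fitted data.
#' @export
simulate.rsi_fit <- function(object, nsim = 1, seed = NULL, sigma = 0.025, ...) {
  mu <- fitted(object)
  with_seed(seed, function()
    lapply(seq_len(nsim), function(i) add_rician_noise(mu, sigma)))
}

#' @export
print.rsi_fit <- function(x, ...) {
  gd <- dim(x$C)[1:3]
  cat(sprintf("Fixed-spectrum compartment fit: %d voxels, %d shells (b = %s), %d components\n",
              prod(gd), length(x$b_values),
              paste(x$b_values, collapse = ", "), dim(x$C)[4]))
  if (prod(gd) == 1) {
    print(coef(x))
  }
  invisible(x)
}

#' @export
summary.rsi_fit <- function(object, ...) {
  p <- dim(object$C)[4]
  gd <- dim(object$C)[1:3]
  Cm <- matrix(object$C, prod(gd), p)
  qs <- t(apply(Cm, 2, stats::quantile,
                probs = c(0.05, 0.25, 0.5, 0.75, 0.95), na.rm = TRUE))
  rownames(qs) <- paste0("C", seq_len(p))
  out <- list(quantiles = qs,
              residual = stats::quantile(object$residual,
                                         c(0.5, 0.95), na.rm = TRUE),
              n_voxels = sum(!is.na(object$residual)),
              b_values = object$b_values)
  class(out) <- "summary.rsi_fit"
  out
}

#' @export
print.summary.rsi_fit <- function(x, ...) {
  cat(sprintf("Compartment fit over %d voxels, shells b = %s s/mm^2\n",
              x$n_voxels, paste(x$b_values, collapse = ", ")))
  cat("Compartment quantiles:\n")
  print(round(x$quantiles, 4))
  cat(sprintf("Residual norm: median %.4g, 95%% %.4g\n",
              x$residual[1], x$residual[2]))
  invisible(x)
}

#' @export
plot.rsi_fit <- function(x, slice = NULL, ...) {
  gd <- dim(x$C)[1:3]
  p <- dim(x$C)[4]
  if (prod(gd) == 1) {
    b <- seq(0, max(x$b_values), length.out = 200)
    plot(x$b_values, as.numeric(x$data), xlab = "b (s/mm^2)",
         ylab = "signal", main = "Signal vs b", ...)
    graphics::lines(b, predict(x, b))
    return(invisible(x))
  }
  if (is.null(slice)) slice <- ceiling(gd[3] / 2)
  op <- graphics::par(mfrow = c(1, p), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(p)) {
    m <- x$C[, , slice, i]
    m[is.na(m)] <- 0
    graphics::image(m, axes = FALSE, main = paste0("C", i),
                    col = grDevices::gray.colors(128, 0, 1))
  }
  invisible(x)
}

#' Combination maps from a compartment fit
#'
#' Computes the voxel-wise product C1*C2 of the restricted and hindered
#' contributions and its square root (the latter puts the combination on the
#' same scale as the individual compartment maps).
#'
#' @param fit an `rsi_fit` with >= 2 components.
#' @return List of class `derived_maps` with `product` and `root_product`
#'   arrays.
#' @export
derive_product_maps <- function(fit) {
  stopifnot(inherits(fit, "rsi_fit"))
  gd <- dim(fit$C)[1:3]
  prod_map <- array(fit$C[, , , 1] * fit$C[, , , 2], gd)
  structure(list(product = prod_map, root_product = sqrt(prod_map)),
            class = "derived_maps")
}

#' Mono-exponential ADC map
#'
#' Fits `S(b) = S0 exp(-b * ADC)` per voxel by ordinary least squares of
#' `log S` on b over the shells with b <= `b_max` (default 1500 s/mm^2; higher
#' shells never enter). Input is shell-averaged data *without* noise
#' correction. Voxels with a non-positive signal on any used shell, or with a
#' negative fitted ADC, are marked invalid and excluded downstream.
#'
#' @param avg_raw a `shell_avg_dwi` (not noise-corrected).
#' @param b_max largest b-value used.
#' @param mode `"ols"` (log-linear regression over all used shells) or
#'   `"two_point"` (log-ratio of b = 0 and the largest used shell).
#' @return List of class `adc_map` with `adc` (mm^2/s, NA where invalid) and
#'   logical `valid` arrays.
#' @export
compute_adc_map <- function(avg_raw, b_max = 1500, mode = c("ols", "two_point")) {
  stopifnot(inherits(avg_raw, "shell_avg_dwi"))
  mode <- match.arg(mode)
  use <- which(avg_raw$b <= b_max)
  if (length(use) < 2 || !any(avg_raw$b[use] == 0))
    stop("ADC needs at least two shells with b <= b_max, including b = 0")
  b <- avg_raw$b[use]
  gd <- dim(avg_raw$volumes)[1:3]
  S <- matrix(avg_raw$volumes[, , , use], prod(gd), length(use))
  pos <- rowSums(S <= 0) == 0
  logS <- log(pmax(S, .Machine$double.xmin))
  if (mode == "ols") {
    bc <- b - mean(b)
    slope <- as.numeric(logS %*% bc) / sum(bc^2)
  } else {
    i0 <- which(b == 0)[1]
    imax <- which.max(b)
    slope <- (logS[, imax] - logS[, i0]) / (b[imax] - b[i0])
  }
  adc <- -slope
  valid <- pos & adc >= 0
  adc[!valid] <- NA_real_
  structure(list(adc = array(adc, gd), valid = array(valid, gd),
                 b_used = b, mode = mode),
            class = "adc_map")
}
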
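#' Tissue-level compartment-fraction targets
#'
#' Target median and dispersion (IQR) of the three compartment signal
#' contributions (C1, C2, C3) for one tissue class, used by the phantom
#' generator. Defaults reproduce the breast tissue contrast this package
#' emulates: malignant lesions high in restricted diffusion C1, benign lesions
#' and healthy fibroglandular tissue low in C1; `adipose` is the low-signal,
#' fat-suppressed background filling the rest of the breast.
#'
#' Components are drawn from independent log-normal distributions parameterized
#' by target median and IQR (this guarantees non-negativity, and median/IQR is
#' exactly the information available for each tissue). `patient_share` is the
#' fraction of the squared log-scale dispersion placed at the patient level in
#' hierarchical cohort sampling: patient-level tissue medians scatter with
#' log-sd `sqrt(patient_share) * sigma` and voxels scatter around their
#' patient's median with the remaining `sqrt(1 - patient_share) * sigma`, so
#' the marginal voxel distribution still meets the median/IQR target.
#'
#' @param tissue one of "malignant", "benign", "healthy", "adipose".
#' @param medians,iqrs length-3 non-negative numerics overriding the defaults
#'   (C1, C2, C3 order).
#' @param patient_share fraction in [0, 1] of squared log-dispersion assigned
#'   to between-patient variation.
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params("malignant")$medians   # c(0.32, 2.6, 0.13)
#' @export
tissue_params <- function(tissue = c("malignant", "benign", "healthy", "adipose"),
                          medians = NULL, iqrs = NULL, patient_share = 0.5) {
  tissue <- match.arg(tissue)
  defaults <- list(
    malignant = list(m = c(0.32, 2.60, 0.13), q = c(0.18, 1.70, 0.40)),
    benign    = list(m = c(0.05, 1.60, 0.34), q = c(0.12, 1.50, 0.70)),
    healthy   = list(m = c(0.08, 0.90, 0.34), q = c(0.13, 0.73, 0.43)),
    adipose   = list(m = c(0.05, 0.12, 0.03), q = c(0.03, 0.08, 0.02)))
  if (is.null(medians)) medians <- defaults[[tissue]]$m
  if (is.null(iqrs))    iqrs    <- defaults[[tissue]]$q
  medians <- as.numeric(medians); iqrs <- as.numeric(iqrs)
  if (length(medians) != 3 || length(iqrs) != 3)
    stop("medians and iqrs must have length 3 (C1, C2, C3)")
  if (any(medians < 0)) stop("target medians must be >= 0")
  if (any(iqrs < 0)) stop("target dispersions (IQR) must be >= 0")
  if (patient_share < 0 || patient_share > 1)
    stop("patient_share must lie in [0, 1]")
  structure(list(tissue = tissue, medians = medians, iqrs = iqrs,
                 patient_share = patient_share),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("Tissue '%s': medians (C1,C2,C3) = %s, IQRs = %s, patient share %.2f\n",
              x$tissue, paste(format(x$medians), collapse = ", "),
              paste(format(x$iqrs), collapse = ", "), x$patient_share))
  invisible(x)
}

# log-normal sdlog matching a target median m and IQR q:
# IQR = 2 m sinh(qnorm(.75) sdlog)  =>  sdlog = asinh(q / (2 m)) / qnorm(.75)
lnorm_sdlog <- function(m, q) {
  s <- numeric(length(m))
  pos <- m > 0 & q > 0
  s[pos] <- asinh(q[pos] / (2 * m[pos])) / stats::qnorm(0.75)
  s
}

# draw an n x 3 matrix of component values, lognormal per column
draw_fractions <- function(medians, sdlogs, n) {
  out <- matrix(0, n, 3, dimnames = list(NULL, c("C1", "C2", "C3")))
  for (j in 1:3) {
    if (medians[j] == 0) next
    out[, j] <- if (sdlogs[j] == 0) rep(medians[j], n)
                else stats::rlnorm(n, meanlog = log(medians[j]), sdlog = sdlogs[j])
  }
  out
}

#' Sample compartment-fraction triples for a tissue
#'
#' Draws voxel-level (C1, C2, C3) triples from the marginal log-normal
#' distribution of a tissue (target median and IQR per component). With zero
#' dispersion the draws degenerate to the target medians.
#'
#' @param params a [tissue_params()] object.
#' @param n number of triples.
#' @param seed optional integer seed for a private RNG stream.
#' @return `n` x 3 matrix with columns C1, C2, C3; all entries >= 0.
#' @export
sample_compartment_fractions <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "tissue_params"))
  if (n < 1) stop("n must be >= 1")
  sdl <- lnorm_sdlog(params$medians, params$iqrs)
  with_seed(seed, function() draw_fractions(params$medians, sdl, n))
}

#' Forward tri-exponential signal of one voxel
#'
#' Evaluates the fixed-spectrum multi-exponential decay
#' `S(b) = sum_i C_i exp(-b D_i)` on every acquisition of a protocol; the value
#' is identical across the acquisitions of one shell.
#'
#' @param C non-negative length-3 compartment contributions.
#' @param protocol an [acquisition_protocol()].
#' @param spectrum a [diffusion_spectrum()].
#' @return Numeric vector with one signal value per acquisition volume.
#' @export
synthesize_voxel_signal <- function(C, protocol = acquisition_protocol(),
                                    spectrum = diffusion_spectrum()) {
  C <- as.numeric(C)
  if (length(C) != length(spectrum$diffusivities))
    stop("length of C must match the number of spectrum components")
  if (any(C < 0)) stop("compartment contributions must be >= 0")
  shell_sig <- as.numeric(exp(-outer(protocol$shells$b, spectrum$diffusivities)) %*% C)
  rep(shell_sig, protocol$shells$n)
}

#' Add Rician noise to magnitude signals
#'
#' Replaces every value s by `sqrt((s + g1)^2 + g2^2)` with g1, g2 independent
#' zero-mean Gaussians of sd `sigma` -- the magnitude-MRI noise model. Zero
#' input signal yields Rayleigh-distributed output with mean
#' `sigma * sqrt(pi/2)`, which is the nonzero background noise floor.
#'
#' @param signal numeric vector or array of noise-free magnitudes.
#' @param sigma Gaussian noise sd per channel, in signal units.
#' @param seed optional integer seed for a private RNG stream.
#' @return Object of the same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signal)
  with_seed(seed, function() {
    n <- length(signal)
    noisy <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
    if (!is.null(dim(signal))) dim(noisy) <- dim(signal)
    noisy
  })
}

#' Phantom configuration
#'
#' Bundles the grid, protocol, spectrum, tissue targets, lesion geometry ranges
#' and noise level of a synthetic breast phantom. Defaults define the study
#' conditions of the package's simulations: a 64 x 64 x 12 grid of
#' 2.5 x 2.5 x 5 mm voxels holding two ellipsoidal breasts, each with a
#' fibroglandular core carrying the healthy-tissue contrast inside a
#' fat-suppressed adipose shell; one malignant and >= 1 benign ellipsoidal
#' lesion with diameters drawn from the reported radiology size ranges
#' (malignant 2.1-6.2 cm in-plane, benign 0.5-3.5 cm); Rician noise with
#' sigma = 0.025 in normalized-signal units (b = 0 fibroglandular SNR ~ 50).
#'
#' @param grid_dim length-3 integer grid size.
#' @param protocol an [acquisition_protocol()].
#' @param spectrum a [diffusion_spectrum()].
#' @param tissues named list of [tissue_params()] for malignant, benign,
#'   healthy and adipose.
#' @param noise_sigma Rician channel sd in signal units.
#' @param n_benign number of benign lesions for this patient.
#' @param malignant_diam_cm,benign_diam_cm in-plane lesion diameter ranges, cm.
#' @param malignant_thick_cm,benign_thick_cm through-plane diameter ranges, cm.
#' @param healthy_n_target healthy control ROI size in voxels.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_dim = c(64, 64, 12),
                           protocol = acquisition_protocol(),
                           spectrum = diffusion_spectrum(),
                           tissues = list(malignant = tissue_params("malignant"),
                                          benign = tissue_params("benign"),
                                          healthy = tissue_params("healthy"),
                                          adipose = tissue_params("adipose")),
                           noise_sigma = 0.025,
                           n_benign = 1,
                           malignant_diam_cm = c(2.1, 6.2),
                           malignant_thick_cm = c(1.0, 2.5),
                           benign_diam_cm = c(0.5, 3.5),
                           benign_thick_cm = c(0.5, 1.5),
                           healthy_n_target = 500) {
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 3 || any(grid_dim < 8))
    stop("grid_dim must be three integers >= 8")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_benign < 1) stop("each patient carries at least one benign lesion")
  structure(list(grid_dim = grid_dim, protocol = protocol, spectrum = spectrum,
                 tissues = tissues, noise_sigma = noise_sigma,
                 n_benign = n_benign,
                 malignant_diam_cm = malignant_diam_cm,
                 malignant_thick_cm = malignant_thick_cm,
                 benign_diam_cm = benign_diam_cm,
                 benign_thick_cm = benign_thick_cm,
                 healthy_n_target = healthy_n_target),
            class = "phantom_config")
}

# logical ellipsoid mask on the voxel grid
ellipsoid_mask <- function(grid_dim, center, semi_axes) {
  x <- (seq_len(grid_dim[1]) - center[1]) / semi_axes[1]
  y <- (seq_len(grid_dim[2]) - center[2]) / semi_axes[2]
  z <- (seq_len(grid_dim[3]) - center[3]) / semi_axes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

# cm diameter -> semi-axis in voxels along one grid axis
cm_to_semivox <- function(diam_cm, voxel_mm) pmax(1, diam_cm * 10 / 2 / voxel_mm)

# hierarchical voxel draw for one tissue region: patient-level median
# then within-lesion voxel scatter (see tissue_params docs)
draw_region <- function(params, n) {
  sdl <- lnorm_sdlog(params$medians, params$iqrs)
  s_pat <- sqrt(params$patient_share) * sdl
  s_vox <- sqrt(1 - params$patient_share) * sdl
  centre <- params$medians * exp(stats::rnorm(3, 0, s_pat))
  draw_fractions(centre, s_vox, n)
}

#' Generate one patient phantom
#'
#' Builds ground-truth compartment maps for one synthetic patient (two-breast
#' geometry, one malignant lesion, `n_benign` benign lesions, a 500-voxel
#' healthy control ROI in the contralateral fibroglandular tissue), runs the
#' forward tri-exponential model on every voxel of every acquisition and adds
#' Rician noise. With `noise_sigma = 0` the series equals the forward model of
#' the stored truth exactly.
#'
#' @param config a [phantom_config()].
#' @param seed optional integer seed; the phantom is fully reproducible given
#'   the seed.
#' @return An object of class `patient_phantom`: list with `dwi`
#'   ([dwi_series()]), `masks` (named list of [tissue_mask()]: `malignant`,
#'   `benign` (list), `healthy`, plus the `fibroglandular` and `breast` region
#'   masks), `truth` (list of C1, C2, C3 arrays), `noise_sigma`, `seed`.
#' @export
generate_patient_phantom <- function(config = phantom_config(), seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, function() build_phantom(config, seed))
}

build_phantom <- function(config, seed) {
  gd <- config$grid_dim
  vox <- config$protocol$voxel_size_mm
  # lesion diameters must fit on the grid
  if (max(config$malignant_diam_cm, config$benign_diam_cm) * 10 >
      min(gd[1:2] * vox[1:2]))
    stop("configured lesion diameters exceed the grid extent")

  # two breasts: ellipsoids centred in each x-half
  centres <- list(left  = c(0.27 * gd[1], 0.50 * gd[2], 0.50 * gd[3]),
                  right = c(0.73 * gd[1], 0.50 * gd[2], 0.50 * gd[3]))
  semi <- c(0.20 * gd[1], 0.40 * gd[2], 0.45 * gd[3])
  breast_l <- ellipsoid_mask(gd, centres$left, semi)
  breast_r <- ellipsoid_mask(gd, centres$right, semi)
  fibro_l <- ellipsoid_mask(gd, centres$left, 0.65 * semi)
  fibro_r <- ellipsoid_mask(gd, centres$right, 0.65 * semi)
  breast <- breast_l | breast_r
  fibro <- fibro_l | fibro_r

  place_lesion <- function(diam_cm, thick_cm, host, avoid) {
    ax <- c(cm_to_semivox(stats::runif(1, diam_cm[1], diam_cm[2]), vox[1]),
            cm_to_semivox(stats::runif(1, diam_cm[1], diam_cm[2]), vox[2]),
            cm_to_semivox(stats::runif(1, thick_cm[1], thick_cm[2]), vox[3]))
    host_idx <- which(host)
    for (try in 1:40) {
      ctr_idx <- host_idx[sample.int(length(host_idx), 1)]
      ctr <- arrayInd(ctr_idx, gd)
      m <- ellipsoid_mask(gd, as.numeric(ctr), ax) & breast
      m <- m & !avoid
      if (sum(m) >= 2) return(m)
    }
    stop("could not place a lesion disjoint from existing lesions")
  }

  # malignant lesion in a random breast, centred in fibroglandular tissue
  mal_side <- sample(c("left", "right"), 1)
  mal_host <- if (mal_side == "left") fibro_l else fibro_r
  malignant <- place_lesion(config$malignant_diam_cm, config$malignant_thick_cm,
                            mal_host, array(FALSE, gd))
  # benign lesions in either breast (ipsi- or contralateral), disjoint
  occupied <- malignant
  benign <- vector("list", config$n_benign)
  for (k in seq_len(config$n_benign)) {
    benign[[k]] <- place_lesion(config$benign_diam_cm, config$benign_thick_cm,
                                fibro, occupied)
    occupied <- occupied | benign[[k]]
  }

  # ground-truth compartment maps
  C <- array(0, c(gd, 3))
  assign_region <- function(C, mask, params) {
    idx <- which(mask)
    vals <- draw_region(params, length(idx))
    for (j in 1:3) {
      slab <- C[, , , j]
      slab[idx] <- vals[, j]
      C[, , , j] <- slab
    }
    C
  }
  C <- assign_region(C, breast & !fibro, config$tissues$adipose)
  C <- assign_region(C, fibro & !occupied, config$tissues$healthy)
  for (k in seq_len(config$n_benign))
    C <- assign_region(C, benign[[k]], config$tissues$benign)
  C <- assign_region(C, malignant, config$tissues$malignant)

  # healthy control ROI: box in the contralateral fibroglandular tissue
  lesions <- c(list(tissue_mask(malignant, "malignant", "generated")),
               lapply(benign, tissue_mask, label = "benign",
                      provenance = "generated"))
  healthy <- define_healthy_control_roi(gd, lesions,
                                        exclusion_masks = list(!fibro),
                                        n_target = config$healthy_n_target)

  # forward model + Rician noise
  bshell <- config$protocol$shells$b
  decay <- exp(-outer(bshell, config$spectrum$diffusivities))
  nv <- prod(gd)
  Cm <- matrix(C, nv, 3)
  shell_sig <- Cm %*% t(decay)                       # voxels x shells
  sig <- shell_sig[, rep(seq_along(bshell), config$protocol$shells$n)]
  sig <- add_rician_noise(sig, config$noise_sigma)
  dwi <- dwi_series(array(sig, c(gd, ncol(sig))),
                    protocol_bvalues(config$protocol), vox)

  masks <- list(malignant = lesions[[1]], benign = lesions[-1],
                healthy = healthy,
                fibroglandular = tissue_mask(fibro, "healthy", "generated"),
                breast = tissue_mask(breast, "healthy", "generated"))
  truth <- list(C1 = array(C[, , , 1], gd), C2 = array(C[, , , 2], gd),
                C3 = array(C[, , , 3], gd))
  structure(list(dwi = dwi, masks = masks, truth = truth,
                 noise_sigma = config$noise_sigma,
                 protocol = config$protocol, spectrum = config$spectrum,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "patient_phantom")
}

#' @export
print.patient_phantom <- function(x, ...) {
  d <- dim(x$dwi$data)
  cat(sprintf("Patient phantom: %d x %d x %d grid, %d acquisitions, sigma = %g\n",
              d[1], d[2], d[3], d[4], x$noise_sigma))
  cat(sprintf("  malignant %d voxels; benign %s voxels; healthy ROI %d voxels\n",
              sum(x$masks$malignant$mask),
              paste(vapply(x$masks$benign, function(m) sum(m$mask), 0L),
                    collapse = "+"),
              sum(x$masks$healthy$mask)))
  invisible(x)
}

#' Generate a paired synthetic cohort
#'
#' Generates `n_patients` phantoms, each with one malignant lesion and at least
#' one benign lesion; by default two patients carry a second benign lesion, so
#' the default 12-patient cohort holds 12 malignant and 14 benign lesions. All
#' randomness flows from the master seed: per-patient sub-seeds are drawn once
#' from the master stream, so cohorts are reproducible and individual patients
#' can be regenerated from their recorded sub-seed.
#'
#' @param n_patients number of patients (>= 1).
#' @param config a [phantom_config()]; its `n_benign` is overridden per patient
#'   by the extra-benign assignment.
#' @param seed optional master seed.
#' @param n_extra_benign how many patients carry a second benign lesion.
#' @return An object of class `rsi_cohort`: list of `patient_phantom`s.
#' @export
generate_cohort <- function(n_patients = 12, config = phantom_config(),
                            seed = NULL, n_extra_benign = 2) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  n_extra_benign <- min(n_extra_benign, n_patients)
  with_seed(seed, function() {
    sub_seeds <- sample.int(.Machine$integer.max, n_patients)
    extra <- if (n_extra_benign > 0) sample.int(n_patients, n_extra_benign)
             else integer(0)
    patients <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      cfg <- config
      cfg$n_benign <- 1L + (i %in% extra)
      patients[[i]] <- generate_patient_phantom(cfg, sub_seeds[i])
    }
    names(patients) <- sprintf("P%02d", seq_len(n_patients))
    structure(patients, class = "rsi_cohort")
  })
}

#' @export
print.rsi_cohort <- function(x, ...) {
  nb <- sum(vapply(x, function(p) length(p$masks$benign), 0L))
  cat(sprintf("Synthetic cohort: %d patients, %d malignant and %d benign lesions\n",
              length(x), length(x), nb))
  invisible(x)
}
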
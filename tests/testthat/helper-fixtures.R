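# shared fixtures: everything is generated in code at test time

# reduced phantom for unit tests: small grid, small lesions, small control ROI
small_config <- function(noise_sigma = 0.025, n_benign = 1) {
  phantom_config(grid_dim = c(32, 32, 8),
                 noise_sigma = noise_sigma,
                 n_benign = n_benign,
                 malignant_diam_cm = c(1.5, 2.5),
                 malignant_thick_cm = c(1.0, 1.5),
                 benign_diam_cm = c(0.6, 1.2),
                 benign_thick_cm = c(0.5, 1.0),
                 healthy_n_target = 60)
}

small_pipeline_config <- function(seed = 1, n_patients = 2) {
  pipeline_config(grid_dim = c(32, 32, 8), n_patients = n_patients,
                  n_target = 60, seed = seed)
}

# a dwi_series with known per-shell constant values on a tiny grid
constant_dwi <- function(values_by_acq, grid = c(4, 4, 2),
                         bvalues = rep(0, length(values_by_acq))) {
  arr <- array(rep(values_by_acq, each = prod(grid)),
               c(grid, length(values_by_acq)))
  dwi_series(arr, bvalues, c(2.5, 2.5, 5.0))
}

# brute-force two-sided signed-rank p over all 2^n sign assignments
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(W <= V), mean(W >= V)))
}
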
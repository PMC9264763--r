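test_that("compartment-fraction sampling hits targets and is reproducible", {
  # degenerate dispersion: all draws equal the target medians
  pz <- tissue_params("malignant", iqrs = c(0, 0, 0))
  x <- sample_compartment_fractions(pz, 5, seed = 1)
  expect_equal(x, matrix(rep(c(0.32, 2.6, 0.13), each = 5), 5, 3,
                         dimnames = list(NULL, c("C1", "C2", "C3"))))

  # Monte-Carlo medians converge to the configured targets
  pm <- tissue_params("malignant")
  big <- sample_compartment_fractions(pm, 1e5, seed = 1)
  expect_true(all(big >= 0))
  med <- apply(big, 2, median)
  expect_equal(unname(med), pm$medians, tolerance = 0.02)
  # and the IQRs match the configured dispersions
  iqr <- apply(big, 2, IQR)
  expect_equal(unname(iqr), pm$iqrs, tolerance = 0.05)

  # seed reproducibility
  expect_identical(sample_compartment_fractions(pm, 100, seed = 7),
                   sample_compartment_fractions(pm, 100, seed = 7))
  expect_error(tissue_params("benign", iqrs = c(-1, 1, 1)), ">= 0")
  expect_error(tissue_params("benign", medians = c(-0.1, 1, 1)), ">= 0")
  expect_error(sample_compartment_fractions(pm, 0), ">= 1")
})

test_that("forward voxel signal follows the tri-exponential decay", {
  prot <- acquisition_protocol()
  C <- c(0.32, 2.6, 0.13)
  s <- synthesize_voxel_signal(C, prot)
  expect_length(s, 29)
  b <- protocol_bvalues(prot)
  # b = 0 value is the sum of contributions
  expect_equal(unique(s[b == 0]), sum(C))
  # direct evaluation at b = 1500
  expect_equal(unique(s[b == 1500]),
               0.32 + 2.6 * exp(-2.25) + 0.13 * exp(-16.2),
               tolerance = 1e-12)
  # identical value across a shell's acquisitions
  for (bb in unique(b)) expect_length(unique(s[b == bb]), 1)
  # non-increasing in b
  shell_vals <- vapply(sort(unique(b)), function(bb) s[b == bb][1], 0)
  expect_true(all(diff(shell_vals) <= 0))
  # pure restricted component is b-invariant
  expect_equal(synthesize_voxel_signal(c(1, 0, 0), prot), rep(1, 29))
  expect_error(synthesize_voxel_signal(c(-0.1, 1, 0), prot), ">= 0")
})

test_that("Rician noise model has the right moments and determinism", {
  s <- seq(0, 2, length.out = 10)
  expect_identical(add_rician_noise(s, 0), s)
  expect_identical(add_rician_noise(s, 0.1, seed = 3),
                   add_rician_noise(s, 0.1, seed = 3))
  expect_error(add_rician_noise(s, -1), ">= 0")

  # zero signal: Rayleigh with mean sigma * sqrt(pi/2)
  z <- add_rician_noise(rep(0, 1e6), 1, seed = 11)
  expect_equal(mean(z), sqrt(pi / 2), tolerance = 0.005)

  # high-SNR regime: variance within 5% of sigma^2
  h <- add_rician_noise(rep(10, 2e5), 1, seed = 12)
  expect_equal(var(h), 1, tolerance = 0.05)
})

test_that("noiseless phantom equals the forward model of its truth", {
  cfg <- small_config(noise_sigma = 0)
  ph <- generate_patient_phantom(cfg, seed = 5)
  b <- cfg$protocol$shells$b
  decay <- exp(-outer(b, cfg$spectrum$diffusivities))
  Cm <- cbind(as.numeric(ph$truth$C1), as.numeric(ph$truth$C2),
              as.numeric(ph$truth$C3))
  expected <- (Cm %*% t(decay))[, rep(seq_along(b), cfg$protocol$shells$n)]
  got <- matrix(ph$dwi$data, nrow(Cm))
  expect_equal(max(abs(got - expected)), 0)
  expect_equal(dim(ph$dwi$data)[4], 29)
})

test_that("phantom masks satisfy the geometric invariants", {
  ph <- generate_patient_phantom(small_config(n_benign = 2), seed = 9)
  mal <- ph$masks$malignant$mask
  ben <- Reduce(`|`, lapply(ph$masks$benign, function(m) m$mask))
  expect_gt(sum(mal), 0)
  expect_false(any(mal & ben))                 # disjoint lesions
  expect_true(all(ph$truth$C1 >= 0) && all(ph$truth$C2 >= 0) &&
                all(ph$truth$C3 >= 0))
  expect_equal(sum(ph$masks$healthy$mask), 60) # configured control ROI size
  # same grid everywhere
  expect_identical(dim(mal), dim(ph$truth$C1))
  expect_identical(dim(mal), dim(ph$dwi$data)[1:3])
  # reproducibility
  ph2 <- generate_patient_phantom(small_config(n_benign = 2), seed = 9)
  expect_identical(ph$dwi$data, ph2$dwi$data)
  expect_identical(ph$masks$malignant$mask, ph2$masks$malignant$mask)
})

test_that("cohort structure: paired lesions and extra benigns", {
  cfg <- small_config()
  coh <- generate_cohort(6, cfg, seed = 21, n_extra_benign = 2)
  expect_length(coh, 6)
  n_ben <- vapply(coh, function(p) length(p$masks$benign), 0L)
  expect_true(all(n_ben >= 1))
  expect_equal(sum(n_ben), 8)  # 6 patients + 2 extra benign lesions
  # every patient has a malignant and a healthy mask
  for (p in coh) {
    expect_equal(p$masks$malignant$label, "malignant")
    expect_equal(sum(p$masks$healthy$mask), 60)
  }
  # minimal cohort and errors
  one <- generate_cohort(1, cfg, seed = 3)
  expect_length(one, 1)
  expect_gte(length(one[[1]]$masks$benign), 1)
  expect_error(generate_cohort(0, cfg), ">= 1")
  # master-seed reproducibility
  coh2 <- generate_cohort(6, cfg, seed = 21, n_extra_benign = 2)
  expect_identical(coh[[3]]$dwi$data, coh2[[3]]$dwi$data)
})

test_that("ground-truth tissue medians converge to the configured targets", {
  # pool truth voxels over several patients per tissue; tolerance reflects
  # the between-patient level of the hierarchical draws
  cfg <- small_config()
  coh <- generate_cohort(8, cfg, seed = 33)
  pool <- function(which_mask, map) {
    unlist(lapply(coh, function(p) {
      m <- if (which_mask == "benign")
        Reduce(`|`, lapply(p$masks$benign, function(x) x$mask))
      else p$masks[[which_mask]]$mask
      p$truth[[map]][m]
    }))
  }
  expect_equal(median(pool("malignant", "C1")), 0.32, tolerance = 0.25)
  expect_equal(median(pool("malignant", "C2")), 2.60, tolerance = 0.25)
  expect_lt(median(pool("healthy", "C1")), median(pool("malignant", "C1")))
  expect_lt(median(pool("benign", "C1")), median(pool("malignant", "C1")))
})
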
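test_that("design matrix rows are the exact exponential decays", {
  A <- build_design_matrix(c(0, 500, 4000))
  expect_equal(A[1, ], c(1, 1, 1))
  expect_equal(A[2, ], c(1, exp(-0.75), exp(-5.4)), tolerance = 1e-14)
  expect_equal(A[3, ], c(1, exp(-6), exp(-43.2)), tolerance = 1e-14)
  expect_equal(qr(A)$rank, 3)  # identifiable with three distinct shells
  expect_error(build_design_matrix(c(0, 500, 500)), "duplicate")
  expect_error(build_design_matrix(c(0, -500)), ">= 0")
})

test_that("noiseless signals are recovered to numerical precision", {
  b <- c(0, 500, 1500, 4000)
  A <- build_design_matrix(b)
  C <- c(0.32, 2.6, 0.13)
  fit <- fit_nnls_voxel(as.numeric(A %*% C), A)
  expect_lt(max(abs(fit$coef - C)), 1e-8)
  expect_lt(fit$residual, 1e-10)
})

test_that("volume fit reproduces ground truth on a noiseless phantom", {
  cfg <- small_config(noise_sigma = 0)
  ph <- generate_patient_phantom(cfg, seed = 17)
  avg <- average_shells(ph$dwi)
  fit <- rsi_fit(avg)
  expect_lt(max(abs(fit$C[, , , 1] - ph$truth$C1)), 1e-8)
  expect_lt(max(abs(fit$C[, , , 2] - ph$truth$C2)), 1e-8)
  expect_lt(max(abs(fit$C[, , , 3] - ph$truth$C3)), 1e-8)
  expect_true(all(fit$C >= 0))
  expect_true(all(fit$residual < 1e-8))
})

test_that("fit respects the mask and the minimum-shell precondition", {
  ph <- generate_patient_phantom(small_config(), seed = 23)
  avg <- average_shells(ph$dwi)
  mask <- array(FALSE, dim(avg)[1:3]); mask[16, 16, 4] <- TRUE
  fit <- rsi_fit(avg, mask = mask)
  expect_equal(sum(!is.na(fit$residual)), 1)
  expect_false(is.na(fit$C[16, 16, 4, 1]))
  # fewer than three shells is under-determined for three components
  two <- average_shells(constant_dwi(c(3, 1), bvalues = c(0, 1500)))
  expect_error(rsi_fit(two), "at least 3")
})

test_that("rsi_fit methods are mutually consistent", {
  b <- c(0, 500, 1500, 4000)
  A <- build_design_matrix(b)
  set.seed(31)
  Y <- matrix(runif(9, 0, 2), 3) %*% t(A) + matrix(rnorm(12, 0, 0.05), 3)
  Y <- pmax(Y, 0)
  fit <- rsi_fit(Y, b_values = b)
  expect_s3_class(fit, "rsi_fit")
  expect_equal(fit$data - fitted(fit), residuals(fit))
  expect_equal(as.numeric(fitted(fit)), as.numeric(predict(fit)))
  # residual norm field matches the residual array
  rn <- sqrt(apply(residuals(fit)^2, 1:3, sum))
  expect_equal(as.numeric(rn), as.numeric(fit$residual), tolerance = 1e-10)
  # fitted decay is non-increasing in b (non-negative coefs, decaying columns)
  fv <- matrix(fitted(fit), 3)
  expect_true(all(apply(fv, 1, function(x) all(diff(x) <= 1e-12))))
  # simulate is reproducible given a seed
  expect_identical(simulate(fit, 2, seed = 5), simulate(fit, 2, seed = 5))
  # single-voxel interface returns a named coefficient vector
  one <- rsi_fit(Y[1, , drop = FALSE], b_values = b)
  expect_named(coef(one), c("C1", "C2", "C3"))
})

test_that("combination maps are the product and its square root", {
  b <- c(0, 500, 1500, 4000)
  A <- build_design_matrix(b)
  C <- rbind(c(0.25, 4, 0), c(0, 2, 1), c(0.32, 2.6, 0.13))
  fit <- rsi_fit(C %*% t(A), b_values = b)
  dm <- derive_product_maps(fit)
  expect_equal(as.numeric(dm$product), c(1, 0, 0.832), tolerance = 1e-8)
  expect_equal(as.numeric(dm$root_product), c(1, 0, sqrt(0.832)),
               tolerance = 1e-8)
  expect_equal(dm$root_product^2, dm$product, tolerance = 1e-10)
})

test_that("ADC map matches the mono-exponential closed form", {
  grid <- c(2, 2, 1)
  b <- c(0, 500, 1500)
  vols <- array(rep(exp(-b * 1e-3), each = prod(grid)), c(grid, 3))
  avg <- rsibreast:::new_shell_avg(vols, b, c(2.5, 2.5, 5))
  for (mode in c("ols", "two_point")) {
    adc <- compute_adc_map(avg, mode = mode)
    expect_true(all(adc$valid))
    expect_equal(as.numeric(adc$adc), rep(1e-3, prod(grid)), tolerance = 1e-12)
  }
  # constant signal: ADC = 0, still valid
  flat <- rsibreast:::new_shell_avg(array(1, c(grid, 3)), b, c(2.5, 2.5, 5))
  a0 <- compute_adc_map(flat)
  expect_true(all(a0$valid))
  expect_equal(as.numeric(a0$adc), rep(0, prod(grid)))
  # increasing signal: negative slope, excluded
  up <- rsibreast:::new_shell_avg(
    array(rep(c(1, 2, 3), each = prod(grid)), c(grid, 3)), b, c(2.5, 2.5, 5))
  au <- compute_adc_map(up)
  expect_false(any(au$valid))
  expect_true(all(is.na(au$adc)))
  expect_error(compute_adc_map(flat, b_max = 100), "at least two shells")
})

test_that("shells above b_max never influence the ADC", {
  set.seed(41)
  grid <- c(6, 6, 2)
  b4 <- c(0, 500, 1500, 4000)
  vols <- array(runif(prod(grid) * 4, 0.05, 2), c(grid, 4))
  with4 <- rsibreast:::new_shell_avg(vols, b4, c(2.5, 2.5, 5))
  without4 <- rsibreast:::new_shell_avg(vols[, , , 1:3, drop = FALSE],
                                        b4[1:3], c(2.5, 2.5, 5))
  a1 <- compute_adc_map(with4)
  a2 <- compute_adc_map(without4)
  expect_identical(a1$adc, a2$adc)
  expect_identical(a1$valid, a2$valid)
  expect_equal(a1$b_used, c(0, 500, 1500))
})
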
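make_raster <- function(power, background = 1, pitch = 0.1) {
  structure(
    list(power = power, background_power = background, frequency_ghz = 108,
         pitch_mm = pitch, replicate_index = 1L),
    class = "power_raster")
}

test_that("Beer-Lambert inversion recovers closed-form alphas", {
  r <- make_raster(matrix(1, 3, 3))
  am <- compute_absorbance(r, thickness_mm = 0.5)
  expect_true(all(am$alpha == 0))  # I_s = I_b: no attenuation

  r2 <- make_raster(matrix(exp(-0.75), 3, 3))
  am2 <- compute_absorbance(r2, thickness_mm = 0.5)
  expect_equal(unique(as.vector(am2$alpha)), 1.5)

  # doubling d halves alpha for fixed powers
  am3 <- compute_absorbance(r2, thickness_mm = 1.0)
  expect_equal(am3$alpha, am2$alpha / 2)

  expect_false(am2$skin_corrected)
  expect_equal(am2$n_replicates_averaged, 1L)
})

test_that("bad powers and thickness are rejected with location info", {
  p <- matrix(1, 3, 3); p[2, 3] <- 0
  expect_error(compute_absorbance(make_raster(p), 0.5), "row 2, col 3")
  expect_error(compute_absorbance(make_raster(matrix(1, 2, 2)), 0),
               "thickness")
  expect_error(compute_absorbance(make_raster(matrix(1, 2, 2)), -1),
               "thickness")
})

test_that("replicate averaging is the pixelwise arithmetic mean", {
  a <- compute_absorbance(make_raster(matrix(exp(-0.70), 2, 2)), 0.5)
  b <- compute_absorbance(make_raster(matrix(exp(-0.80), 2, 2)), 0.5)
  avg <- average_replicates(list(a, b))
  expect_equal(unique(as.vector(avg$alpha)), 1.5)
  expect_equal(avg$n_replicates_averaged, 2L)

  # mean of one is the identity
  expect_equal(average_replicates(list(a))$alpha, a$alpha)

  mismatched <- compute_absorbance(make_raster(matrix(1, 3, 3)), 0.5)
  expect_error(average_replicates(list(a, mismatched)), "shape")
  thick <- compute_absorbance(make_raster(matrix(1, 2, 2)), 0.6)
  expect_error(average_replicates(list(a, thick)), "thickness")
})

test_that("averaging three replicates shrinks noise SD by about sqrt(3)", {
  tm <- build_phantom(phantom_spec(tumor_regions = tumor_disc()))
  truth <- tm$alpha[1, 1]
  acq <- acquisition_config(snr = 1e3, n_replicates = 3, rng_seed = 11L)
  amaps <- lapply(simulate_scan(tm, acq), compute_absorbance,
                  thickness_mm = tm$thickness_mm)
  single_err <- amaps[[1]]$alpha - truth
  mean_err <- average_replicates(amaps)$alpha - truth
  ratio <- sd(mean_err) / sd(single_err)
  expect_lt(abs(ratio - 1 / sqrt(3)), 0.10 / sqrt(3))
})

test_that("skin calibration subtracts depth/d exactly once", {
  am <- compute_absorbance(make_raster(matrix(exp(-0.85), 4, 4)), 0.5)
  expect_equal(unique(as.vector(am$alpha)), 1.7)
  cal <- calibrate_skin_background(am, 0.1)
  expect_equal(unique(as.vector(cal$alpha)), 1.5)
  expect_true(cal$skin_corrected)
  expect_error(calibrate_skin_background(cal, 0.1), "twice")

  # zero depth leaves values unchanged but still marks the map corrected
  z <- calibrate_skin_background(am, 0)
  expect_equal(z$alpha, am$alpha)
  expect_true(z$skin_corrected)
  expect_error(calibrate_skin_background(am, -0.1), "skin_optical_depth")
})

test_that("skin depth is recoverable from a reference region", {
  am <- compute_absorbance(make_raster(matrix(exp(-0.81), 4, 4)), 0.5)
  mask <- matrix(FALSE, 4, 4); mask[1:2, ] <- TRUE
  # masked mean 1.62, expected 1.42, d = 0.5 -> 0.1
  expect_equal(estimate_skin_background(am, mask, 1.42), 0.1)
  expect_equal(estimate_skin_background(am, mask, 1.62), 0)
  expect_equal(estimate_skin_background(am, mask, 1.70), 0)  # floored
  expect_error(estimate_skin_background(am, matrix(FALSE, 4, 4), 1.42),
               "no pixels")

  # on a noise-free phantom the generating depth comes back exactly
  spec <- default_spec()
  tm <- build_phantom(spec)
  sc <- simulate_scan(tm, acquisition_config(snr = Inf, n_replicates = 1))
  amap <- compute_absorbance(sc[[1]], spec$sandwich_thickness_mm)
  skin_mask <- tm$alpha == spec$fat_alpha
  expect_equal(estimate_skin_background(amap, skin_mask, spec$fat_alpha),
               spec$skin_optical_depth)
})

test_that("noiseless simulate -> absorbance -> skin-correct round trip is exact", {
  spec <- default_spec()
  tm <- build_phantom(spec)
  sc <- simulate_scan(tm, acquisition_config(snr = Inf))
  amaps <- lapply(sc, compute_absorbance, thickness_mm = tm$thickness_mm)
  rec <- calibrate_skin_background(average_replicates(amaps),
                                   tm$skin_optical_depth)
  expect_lt(max(abs(rec$alpha / tm$alpha - 1)), 1e-12)
})

test_that("alpha of a geometric-mean raster is the mean of the alpha maps", {
  set.seed(5)
  p1 <- matrix(runif(16, 0.2, 0.9), 4, 4)
  p2 <- matrix(runif(16, 0.2, 0.9), 4, 4)
  a1 <- compute_absorbance(make_raster(p1), 0.5)
  a2 <- compute_absorbance(make_raster(p2), 0.5)
  geo <- compute_absorbance(make_raster(sqrt(p1 * p2)), 0.5)
  expect_equal(geo$alpha, (a1$alpha + a2$alpha) / 2)
})

test_that("averaging and skin correction commute", {
  tm <- build_phantom(default_spec())
  acq <- acquisition_config(snr = 1e3, rng_seed = 2L)
  amaps <- lapply(simulate_scan(tm, acq), compute_absorbance,
                  thickness_mm = tm$thickness_mm)
  avg_then_cal <- calibrate_skin_background(average_replicates(amaps), 0.05)
  cal_then_avg <- average_replicates(
    lapply(amaps, calibrate_skin_background, skin_optical_depth = 0.05))
  expect_equal(avg_then_cal$alpha, cal_then_avg$alpha)
})
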
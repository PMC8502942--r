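test_that("phantom rasterisation matches geometry ground truth", {
  # uniform background: no tumor
  tm <- build_phantom(phantom_spec(fat_alpha = 1.42,
                                   tumor_regions = tumor_disc()))
  expect_true(all(tm$alpha == 1.42))
  expect_equal(dim(tm$alpha), c(100L, 100L))

  # grid dimensions forced by ceiling(field / pitch)
  tm2 <- build_phantom(phantom_spec(field_width_mm = 7.05,
                                    field_height_mm = 3,
                                    pixel_pitch_mm = 0.5,
                                    tumor_regions = tumor_disc()))
  expect_equal(dim(tm2$alpha), c(6L, 15L))

  # disc pixel count vs independent brute-force enumeration, several radii
  for (r in c(0.5, 1.0, 1.5, 2.3)) {
    tm3 <- build_phantom(default_spec(radius = r))
    got <- sum(tm3$alpha > 1.42)
    oracle <- brute_force_disc_count(10, 10, 0.1, 5, 5, r)
    expect_identical(got, oracle)
    expect_lt(abs(got - pi * (r / 0.1)^2), 4 + 0.05 * pi * (r / 0.1)^2)
  }
})

test_that("overlapping tumor discs take the maximum excess, not the sum", {
  spec <- phantom_spec(tumor_regions = tumor_disc(
    center_x_mm = c(5, 5), center_y_mm = c(5, 5),
    radius_mm = c(1.5, 1.0), alpha_excess = c(0.1, 0.16)))
  tm <- build_phantom(spec)
  expect_equal(max(tm$alpha), 1.42 + 0.16)
  # pixel at the shared center sees the max of the two, never 1.42+0.26
  expect_equal(tm$alpha[50, 50], 1.58)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(pixel_pitch_mm = 0), "pitch")
  expect_error(phantom_spec(pixel_pitch_mm = -0.1), "pitch")
  expect_error(phantom_spec(fat_alpha = 0), "fat_alpha")
  expect_error(phantom_spec(tumor_regions = tumor_disc(9.5, 5, 1, 0.1)),
               "outside")
  expect_error(phantom_spec(tumor_regions = tumor_disc(5, 5, 0, 0.1)),
               "radius")
  expect_error(phantom_spec(tumor_regions = tumor_disc(5, 5, 1, -0.1)),
               "alpha_excess")
  expect_error(acquisition_config(snr = 0), "snr")
  expect_error(acquisition_config(snr = -2), "snr")
})

test_that("noiseless forward model is the exact Beer-Lambert exponential", {
  tm <- build_phantom(phantom_spec(fat_alpha = 1.5, skin_optical_depth = 0,
                                   sandwich_thickness_mm = 0.5,
                                   tumor_regions = tumor_disc()))
  sc <- simulate_scan(tm, acquisition_config(snr = Inf, n_replicates = 1,
                                             background_power = 1))
  expect_equal(unique(as.vector(sc[[1]]$power)), exp(-0.75))

  # skin depth folds in additively in the exponent
  tm$skin_optical_depth <- 0.1
  sc2 <- simulate_scan(tm, acquisition_config(snr = Inf, n_replicates = 1))
  expect_equal(unique(as.vector(sc2[[1]]$power)), exp(-0.85))
})

test_that("zero attenuation transmits the full background power", {
  tm <- build_phantom(phantom_spec(fat_alpha = 1e-300,
                                   skin_optical_depth = 0,
                                   tumor_regions = tumor_disc()))
  sc <- simulate_scan(tm, acquisition_config(snr = Inf, n_replicates = 1,
                                             background_power = 3.7))
  expect_equal(unique(as.vector(sc[[1]]$power)), 3.7)
})

test_that("noiseless transmitted power decreases strictly with alpha", {
  spec <- default_spec(excess = 0.16)
  tm <- build_phantom(spec)
  sc <- simulate_scan(tm, acquisition_config(snr = Inf, n_replicates = 1))
  tumor <- tm$alpha > spec$fat_alpha
  expect_true(max(sc[[1]]$power[tumor]) < min(sc[[1]]$power[!tumor]))
})

test_that("multiplicative noise has the configured relative SD", {
  tm <- build_phantom(phantom_spec(tumor_regions = tumor_disc()))
  noiseless <- simulate_scan(
    tm, acquisition_config(snr = Inf, n_replicates = 1))[[1]]$power
  noisy <- simulate_scan(
    tm, acquisition_config(snr = 1e4, n_replicates = 1,
                           rng_seed = 42L))[[1]]$power
  rel <- noisy / noiseless - 1
  expect_lt(abs(sd(rel) / 1e-4 - 1), 0.10)  # 1e4 pixels
  expect_true(all(noisy > 0))
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  tm <- build_phantom(default_spec())
  a <- simulate_scan(tm, acquisition_config(rng_seed = 7L))
  b <- simulate_scan(tm, acquisition_config(rng_seed = 7L))
  c <- simulate_scan(tm, acquisition_config(rng_seed = 8L))
  expect_identical(a, b)
  expect_false(identical(a[[1]]$power, c[[1]]$power))
  # replicates within one call carry independent noise
  expect_false(identical(a[[1]]$power, a[[2]]$power))
  expect_equal(length(a), 3L)
})

test_that("spectral panel draws match the requested cohort structure", {
  ta <- tidyr::crossing(
    tibble::tibble(tissue = c("fat", "cancer"),
                   alpha_mean = c(1.42, 1.55), alpha_sd = c(0.05, 0.05)),
    frequency_ghz = default_frequencies())
  panel <- simulate_spectral_panel(ta, n_animals = 20, d = 0.5, rng_seed = 3L)
  expect_equal(nrow(panel), 20 * 2 * 8)
  expect_equal(dplyr::n_distinct(panel$animal), 20L)
  expect_true(all(panel$true_alpha > 0))
  expect_equal(panel$power_ratio, exp(-panel$true_alpha * 0.5))

  # SD = 0 degenerates to identical animals
  ta0 <- dplyr::mutate(ta, alpha_sd = 0)
  p0 <- simulate_spectral_panel(ta0, n_animals = 5, d = 0.5, rng_seed = 1L)
  spread <- dplyr::summarise(
    dplyr::group_by(p0, tissue, frequency_ghz),
    s = dplyr::n_distinct(true_alpha), .groups = "drop")
  expect_true(all(spread$s == 1))

  # sample mean close to the generating mean: within 3 standard errors
  fat <- dplyr::filter(panel, tissue == "fat", frequency_ghz == 108)
  expect_lt(abs(mean(fat$true_alpha) - 1.42), 3 * 0.05 / sqrt(20))

  expect_error(simulate_spectral_panel(ta[0, ], 5, 0.5), "at least one")
  expect_error(
    simulate_spectral_panel(dplyr::mutate(ta, alpha_mean = -1), 5, 0.5),
    "alpha_mean")
})
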
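#' Specify a tissue phantom
#'
#' A phantom is a simulated tissue stack — a uniform skin layer over fatty
#' tissue with zero or more embedded tumor discs — sandwiched between two
#' cover glasses of separation `sandwich_thickness_mm`. It provides ground
#' truth against which every downstream stage (absorbance inversion, skin
#' calibration, segmentation, volumetry) can be validated.
#'
#' Skin is carried as a dimensionless optical depth (ln-units of attenuation),
#' not a thickness/coefficient pair: the analysis only ever removes it as a
#' uniform, position-independent background, so its decomposition is
#' irrelevant.
#'
#' @param field_width_mm,field_height_mm Scan field size in mm. Default
#'   10 x 10 mm, the standard raster extent for these scans.
#' @param pixel_pitch_mm Scan step between pixel centers (mm). Must be > 0.
#' @param sandwich_thickness_mm Thickness `d` of the glass-sandwiched tissue
#'   slab (mm). Required by the Beer-Lambert inversion.
#' @param skin_optical_depth Uniform ln-attenuation contributed by skin
#'   (dimensionless, >= 0).
#' @param fat_alpha Absorption coefficient of the fatty background (mm^-1).
#'   Default 1.42, inside the fatty band 1.400-1.450 mm^-1.
#' @param tumor_regions Data frame (or tibble) with one row per tumor disc and
#'   columns `center_x_mm`, `center_y_mm`, `radius_mm`, `alpha_excess`
#'   (absorption excess over fat, mm^-1). May have zero rows.
#' @param rng_seed Integer seed recorded with the spec (used by consumers that
#'   need a default randomness source).
#'
#' @return A `phantom_spec` object (a validated list).
#' @examples
#' spec <- phantom_spec(tumor_regions = tumor_disc(5, 5, 1.5, 0.16))
#' phantom <- build_phantom(spec)
#' dim(phantom$alpha)
#' @export
phantom_spec <- function(field_width_mm = 10,
                         field_height_mm = 10,
                         pixel_pitch_mm = 0.1,
                         sandwich_thickness_mm = 0.5,
                         skin_optical_depth = 0.05,
                         fat_alpha = 1.42,
                         tumor_regions = tumor_disc(),
                         rng_seed = 1L) {
  tumor_regions <- tibble::as_tibble(tumor_regions)
  spec <- structure(
    list(
      field_width_mm = field_width_mm,
      field_height_mm = field_height_mm,
      pixel_pitch_mm = pixel_pitch_mm,
      sandwich_thickness_mm = sandwich_thickness_mm,
      skin_optical_depth = skin_optical_depth,
      fat_alpha = fat_alpha,
      tumor_regions = tumor_regions,
      rng_seed = as.integer(rng_seed)
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

#' Describe tumor discs for a phantom
#'
#' @param center_x_mm,center_y_mm Disc center coordinates (mm), origin at the
#'   top-left corner of the field, x rightward, y downward.
#' @param radius_mm Disc radius (mm), > 0.
#' @param alpha_excess Absorption excess over the fatty background (mm^-1),
#'   >= 0.
#' @return A tibble with one row per disc, suitable for
#'   [phantom_spec()]'s `tumor_regions`.
#' @examples
#' tumor_disc(5, 5, 1.5, 0.16)
#' tumor_disc()  # no tumor
#' @export
tumor_disc <- function(center_x_mm = double(), center_y_mm = double(),
                       radius_mm = double(), alpha_excess = double()) {
  tibble::tibble(
    center_x_mm = as.double(center_x_mm),
    center_y_mm = as.double(center_y_mm),
    radius_mm = as.double(radius_mm),
    alpha_excess = as.double(alpha_excess)
  )
}

validate_phantom_spec <- function(spec) {
  stopifnot(
    spec$field_width_mm > 0, spec$field_height_mm > 0,
    spec$sandwich_thickness_mm > 0,
    spec$skin_optical_depth >= 0
  )
  if (!is.numeric(spec$pixel_pitch_mm) || spec$pixel_pitch_mm <= 0) {
    stop("`pixel_pitch_mm` must be a positive length in mm", call. = FALSE)
  }
  if (spec$fat_alpha <= 0) {
    stop("`fat_alpha` must be > 0 (mm^-1)", call. = FALSE)
  }
  tr <- spec$tumor_regions
  needed <- c("center_x_mm", "center_y_mm", "radius_mm", "alpha_excess")
  if (!all(needed %in% names(tr))) {
    stop("`tumor_regions` needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tr) > 0) {
    if (any(tr$radius_mm <= 0)) {
      stop("every tumor `radius_mm` must be > 0", call. = FALSE)
    }
    if (any(tr$alpha_excess < 0)) {
      stop("every tumor `alpha_excess` must be >= 0", call. = FALSE)
    }
    inside <- tr$center_x_mm - tr$radius_mm >= 0 &
      tr$center_x_mm + tr$radius_mm <= spec$field_width_mm &
      tr$center_y_mm - tr$radius_mm >= 0 &
      tr$center_y_mm + tr$radius_mm <= spec$field_height_mm
    if (!all(inside)) {
      stop("tumor region ", which(!inside)[1],
           " extends outside the scan field", call. = FALSE)
    }
  }
  invisible(spec)
}

#' Build the ground-truth tissue map of a phantom
#'
#' Rasterises a [phantom_spec()] onto a pixel grid. The grid has
#' `ceiling(field / pitch)` pixels per axis; pixel (i, j) (1-based, row-major,
#' origin top-left) has its center at ((j - 0.5) * pitch, (i - 0.5) * pitch).
#' A pixel belongs to a tumor disc when its center lies inside the disc
#' (distance <= radius); overlapping discs contribute the maximum excess, not
#' the sum.
#'
#' @param spec A [phantom_spec()].
#' @return A `tissue_map`: list with `alpha` (matrix of true tissue absorption
#'   coefficients, mm^-1, skin excluded), `skin_optical_depth`,
#'   `thickness_mm`, `pitch_mm`.
#' @examples
#' tm <- build_phantom(phantom_spec(tumor_regions = tumor_disc()))
#' unique(as.vector(tm$alpha))  # uniform fat
#' @export
build_phantom <- function(spec) {
  validate_phantom_spec(spec)
  nx <- as.integer(ceiling(spec$field_width_mm / spec$pixel_pitch_mm))
  ny <- as.integer(ceiling(spec$field_height_mm / spec$pixel_pitch_mm))
  stopifnot(nx >= 1, ny >= 1)
  pitch <- spec$pixel_pitch_mm
  cx <- (seq_len(nx) - 0.5) * pitch
  cy <- (seq_len(ny) - 0.5) * pitch
  alpha <- matrix(spec$fat_alpha, nrow = ny, ncol = nx)
  excess <- matrix(0, nrow = ny, ncol = nx)
  tr <- spec$tumor_regions
  for (k in seq_len(nrow(tr))) {
    dx2 <- outer(rep(1, ny), (cx - tr$center_x_mm[k])^2)
    dy2 <- outer((cy - tr$center_y_mm[k])^2, rep(1, nx))
    inside <- dx2 + dy2 <= tr$radius_mm[k]^2
    excess[inside] <- pmax(excess[inside], tr$alpha_excess[k])
  }
  structure(
    list(
      alpha = alpha + excess,
      skin_optical_depth = spec$skin_optical_depth,
      thickness_mm = spec$sandwich_thickness_mm,
      pitch_mm = pitch
    ),
    class = "tissue_map"
  )
}

#' Configure a simulated acquisition
#'
#' @param frequency_ghz Imaging frequency (GHz). Default 108, where tissue
#'   absorption is low enough for transmission imaging.
#' @param background_power Background power `I_b` (transmission through the
#'   bare cover glass), arbitrary units, > 0.
#' @param snr Signal-to-noise ratio of the detection chain (> 0). The noise
#'   model is i.i.d. multiplicative Gaussian on power with relative standard
#'   deviation `1/snr`. Use `Inf` to disable noise. Default 1e4 keeps noise
#'   visible at test scale.
#' @param n_replicates Number of repeat scans per subject (default 3, the
#'   standard protocol here).
#' @param rng_seed Integer seed making the simulation reproducible.
#' @return An `acquisition_config` object.
#' @export
acquisition_config <- function(frequency_ghz = 108,
                               background_power = 1,
                               snr = 1e4,
                               n_replicates = 3L,
                               rng_seed = 1L) {
  if (!is.numeric(snr) || length(snr) != 1 || is.na(snr) || snr <= 0) {
    stop("`snr` must be a single positive number (Inf disables noise)",
         call. = FALSE)
  }
  stopifnot(background_power > 0, n_replicates >= 1, frequency_ghz > 0)
  structure(
    list(
      frequency_ghz = frequency_ghz,
      background_power = background_power,
      snr = snr,
      n_replicates = as.integer(n_replicates),
      rng_seed = as.integer(rng_seed)
    ),
    class = "acquisition_config"
  )
}

#' Simulate replicate transmitted-power scans of a phantom
#'
#' Forward model: noiseless power per pixel is
#' `I_b * exp(-skin_optical_depth - alpha * d)`. Each replicate then receives
#' independent multiplicative Gaussian noise with relative standard deviation
#' `1/snr`; the noise factor is clipped below at a tiny positive value so
#' power can never reach zero (at any realistic snr the clip is inactive).
#'
#' @param map A `tissue_map` from [build_phantom()].
#' @param acq An [acquisition_config()].
#' @return A list of `n_replicates` `power_raster` objects, each a list with
#'   `power` (matrix of transmitted power `I_s`), `background_power`,
#'   `frequency_ghz`, `pitch_mm`, `replicate_index`.
#' @examples
#' tm <- build_phantom(phantom_spec())
#' scans <- simulate_scan(tm, acquisition_config(snr = Inf, n_replicates = 1))
#' range(scans[[1]]$power)
#' @export
simulate_scan <- function(map, acq) {
  stopifnot(inherits(map, "tissue_map"), inherits(acq, "acquisition_config"))
  noiseless <- acq$background_power *
    exp(-map$skin_optical_depth - map$alpha * map$thickness_mm)
  make_raster <- function(power, r) {
    stopifnot(all(power > 0))
    structure(
      list(
        power = power,
        background_power = acq$background_power,
        frequency_ghz = acq$frequency_ghz,
        pitch_mm = map$pitch_mm,
        replicate_index = as.integer(r)
      ),
      class = "power_raster"
    )
  }
  withr::with_seed(acq$rng_seed, {
    lapply(seq_len(acq$n_replicates), function(r) {
      if (is.infinite(acq$snr)) {
        factor <- 1
      } else {
        factor <- pmax(1 + stats::rnorm(length(noiseless)) / acq$snr, 1e-12)
        factor <- matrix(factor, nrow = nrow(noiseless))
      }
      make_raster(noiseless * factor, r)
    })
  })
}

#' Simulate a per-animal tissue spectroscopy panel
#'
#' Emulates in-vivo absorption spectroscopy of several tissue types across a
#' cohort: each animal's true absorption coefficient for each tissue at each
#' frequency is drawn from a normal distribution truncated at 0 (mean and SD
#' given per tissue/frequency), then converted to a transmitted-power ratio
#' `I_s / I_b = exp(-alpha * d)` by the Beer-Lambert forward model.
#'
#' @param tissue_alphas Data frame with columns `tissue`, `frequency_ghz`,
#'   `alpha_mean` (mm^-1, > 0) and `alpha_sd` (mm^-1, >= 0).
#' @param n_animals Cohort size (>= 1).
#' @param d Tissue thickness (mm, > 0).
#' @param rng_seed Integer seed.
#' @return A tibble with columns `animal`, `tissue`, `frequency_ghz`,
#'   `true_alpha`, `power_ratio` — `n_animals` records per tissue/frequency.
#' @examples
#' panel <- simulate_spectral_panel(
#'   tibble::tibble(tissue = "fat", frequency_ghz = 108,
#'                  alpha_mean = 1.42, alpha_sd = 0.05),
#'   n_animals = 20, d = 0.5, rng_seed = 7)
#' nrow(panel)
#' @export
simulate_spectral_panel <- function(tissue_alphas, n_animals, d, rng_seed = 1L) {
  tissue_alphas <- tibble::as_tibble(tissue_alphas)
  stopifnot(
    all(c("tissue", "frequency_ghz", "alpha_mean", "alpha_sd") %in%
          names(tissue_alphas)),
    n_animals >= 1, d > 0
  )
  if (nrow(tissue_alphas) == 0) {
    stop("`tissue_alphas` must list at least one tissue/frequency",
         call. = FALSE)
  }
  if (any(tissue_alphas$alpha_mean <= 0)) {
    stop("all `alpha_mean` must be > 0", call. = FALSE)
  }
  if (any(tissue_alphas$alpha_sd < 0)) {
    stop("all `alpha_sd` must be >= 0", call. = FALSE)
  }
  withr::with_seed(as.integer(rng_seed), {
    out <- tidyr::crossing(animal = seq_len(n_animals), tissue_alphas)
    out$true_alpha <- rtruncnorm_pos(nrow(out), out$alpha_mean, out$alpha_sd)
    out$power_ratio <- exp(-out$true_alpha * d)
    dplyr::select(out, "animal", "tissue", "frequency_ghz",
                  "true_alpha", "power_ratio")
  })
}

# Normal draw truncated at 0 by rejection; vectorised over mean/sd.
rtruncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf(
    "<tissue_map> %d x %d px @ %.3g mm, d = %.3g mm, skin depth = %.3g\n",
    nrow(x$alpha), ncol(x$alpha), x$pitch_mm, x$thickness_mm,
    x$skin_optical_depth))
  cat(sprintf("  alpha range: %.4g .. %.4g mm^-1\n",
              min(x$alpha), max(x$alpha)))
  invisible(x)
}

#' @export
print.power_raster <- function(x, ...) {
  cat(sprintf(
    "<power_raster> %d x %d px @ %.3g mm, %g GHz, replicate %d\n",
    nrow(x$power), ncol(x$power), x$pitch_mm, x$frequency_ghz,
    x$replicate_index))
  invisible(x)
}
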
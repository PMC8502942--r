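#' Convert a transmitted-power raster to an absorption-coefficient map
#'
#' Inverts the Beer-Lambert law per pixel: `alpha = ln(I_b / I_s) / d`, so an
#' attenuating sample (`I_s < I_b`) yields a positive absorption coefficient.
#'
#' @param raster A `power_raster` (see [simulate_scan()] or [read_raster()]).
#' @param thickness_mm Tissue slab thickness `d` (mm, > 0). There is no
#'   default: the in-vivo sandwich thickness is acquisition metadata the
#'   caller must supply.
#' @return An `absorbance_map`: list with `alpha` (matrix, mm^-1),
#'   `thickness_mm`, `pitch_mm`, `frequency_ghz`, `skin_corrected` (flag),
#'   `n_replicates_averaged`.
#' @examples
#' tm <- build_phantom(phantom_spec())
#' sc <- simulate_scan(tm, acquisition_config(snr = Inf, n_replicates = 1))
#' am <- compute_absorbance(sc[[1]], thickness_mm = 0.5)
#' @export
compute_absorbance <- function(raster, thickness_mm) {
  stopifnot(inherits(raster, "power_raster"))
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1 ||
      thickness_mm <= 0) {
    stop("`thickness_mm` must be a single positive length (mm)",
         call. = FALSE)
  }
  bad <- which(!(raster$power > 0))
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(raster$power))
    stop(sprintf("non-positive transmitted power at pixel (row %d, col %d)",
                 ij[1], ij[2]), call. = FALSE)
  }
  if (raster$background_power <= 0) {
    stop("`background_power` must be > 0", call. = FALSE)
  }
  new_absorbance_map(
    alpha = log(raster$background_power / raster$power) / thickness_mm,
    thickness_mm = thickness_mm,
    pitch_mm = raster$pitch_mm,
    frequency_ghz = raster$frequency_ghz,
    skin_corrected = FALSE,
    n_replicates_averaged = 1L
  )
}

new_absorbance_map <- function(alpha, thickness_mm, pitch_mm, frequency_ghz,
                               skin_corrected, n_replicates_averaged) {
  stopifnot(all(is.finite(alpha)), thickness_mm > 0)
  structure(
    list(
      alpha = alpha,
      thickness_mm = thickness_mm,
      pitch_mm = pitch_mm,
      frequency_ghz = frequency_ghz,
      skin_corrected = skin_corrected,
      n_replicates_averaged = as.integer(n_replicates_averaged)
    ),
    class = "absorbance_map"
  )
}

#' Average replicate absorbance maps
#'
#' Replicate scans are averaged in alpha-space (the pixelwise arithmetic mean
#' of absorption coefficients), mirroring how repeat scans of the same subject
#' are presented as a mean absorption-coefficient image.
#'
#' @param maps List of `absorbance_map`s with identical shape, thickness,
#'   frequency and skin-correction state.
#' @return One `absorbance_map` with `n_replicates_averaged` equal to the sum
#'   over inputs.
#' @export
average_replicates <- function(maps) {
  if (inherits(maps, "absorbance_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, logical(1), "absorbance_map")))
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(dim(m$alpha), dim(ref$alpha))) {
      stop("replicate maps differ in shape", call. = FALSE)
    }
    if (m$thickness_mm != ref$thickness_mm ||
        !identical(m$frequency_ghz, ref$frequency_ghz) ||
        m$pitch_mm != ref$pitch_mm) {
      stop("replicate maps differ in thickness, pitch or frequency",
           call. = FALSE)
    }
    if (!identical(m$skin_corrected, ref$skin_corrected)) {
      stop("replicate maps differ in skin-correction state", call. = FALSE)
    }
  }
  mean_alpha <- Reduce(`+`, lapply(maps, `[[`, "alpha")) / length(maps)
  new_absorbance_map(
    alpha = mean_alpha,
    thickness_mm = ref$thickness_mm,
    pitch_mm = ref$pitch_mm,
    frequency_ghz = ref$frequency_ghz,
    skin_corrected = ref$skin_corrected,
    n_replicates_averaged = sum(vapply(maps, `[[`, integer(1),
                                       "n_replicates_averaged"))
  )
}

#' Remove the uniform skin attenuation background
#'
#' Skin attenuation is treated as uniform and position-independent, so it is
#' removed by subtracting the scalar `skin_optical_depth / d` from every
#' pixel's absorption coefficient. A map can be corrected exactly once.
#'
#' @param map An `absorbance_map` with `skin_corrected` unset.
#' @param skin_optical_depth Dimensionless ln-attenuation of skin (>= 0),
#'   either from configuration or from [estimate_skin_background()].
#' @return The corrected `absorbance_map` with `skin_corrected` set.
#' @export
calibrate_skin_background <- function(map, skin_optical_depth) {
  stopifnot(inherits(map, "absorbance_map"))
  if (isTRUE(map$skin_corrected)) {
    stop("map is already skin-corrected; refusing to correct twice",
         call. = FALSE)
  }
  if (!is.numeric(skin_optical_depth) || length(skin_optical_depth) != 1 ||
      skin_optical_depth < 0) {
    stop("`skin_optical_depth` must be a single number >= 0", call. = FALSE)
  }
  out <- map
  out$alpha <- map$alpha - skin_optical_depth / map$thickness_mm
  out$skin_corrected <- TRUE
  out
}

#' Estimate the skin optical depth from a skin-only reference region
#'
#' Given a mask over pixels known to contain only skin over fat, the skin
#' optical depth is the excess of the masked mean absorption coefficient over
#' the expected fat coefficient, scaled back to ln-units:
#' `d * (mean(alpha[mask]) - expected_reference_alpha)`, floored at 0.
#'
#' @param map An uncorrected `absorbance_map`.
#' @param reference_region Logical matrix, same shape as the map, `TRUE` over
#'   the skin-only reference area. Must select at least one pixel.
#' @param expected_reference_alpha Expected fat absorption coefficient under
#'   the reference region (mm^-1).
#' @return Scalar skin optical depth (dimensionless, >= 0).
#' @export
estimate_skin_background <- function(map, reference_region,
                                     expected_reference_alpha) {
  stopifnot(inherits(map, "absorbance_map"),
            is.logical(reference_region),
            identical(dim(reference_region), dim(map$alpha)))
  if (!any(reference_region)) {
    stop("`reference_region` selects no pixels", call. = FALSE)
  }
  excess <- mean(map$alpha[reference_region]) - expected_reference_alpha
  max(map$thickness_mm * excess, 0)
}

#' @export
print.absorbance_map <- function(x, ...) {
  cat(sprintf(
    "<absorbance_map> %d x %d px @ %.3g mm, d = %.3g mm, %g GHz\n",
    nrow(x$alpha), ncol(x$alpha), x$pitch_mm, x$thickness_mm,
    x$frequency_ghz))
  cat(sprintf("  alpha: %.4g .. %.4g mm^-1 | skin-corrected: %s | replicates: %d\n",
              min(x$alpha), max(x$alpha), x$skin_corrected,
              x$n_replicates_averaged))
  invisible(x)
}
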
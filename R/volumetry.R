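#' Volumetry calibration constants
#'
#' The absorption-cross-section model links the regional absorption change to
#' tumor volume through three constants. `alpha_ref` is the reference
#' absorption coefficient of confluent cancer tissue; the default 1.5 mm^-1 is
#' the midpoint of the 1.400-1.600 mm^-1 display band. `v_cell` is the volume
#' of a single cancer cell; the default 2e-6 mm^3 is the order of magnitude of
#' an MDA-MB-231 cell (~15 um diameter). `v_effective` is the interrogated
#' tissue volume; the default 8 mm^3 is fixed so that V = (delta_alpha /
#' alpha_ref) * v_effective reproduces the constant ratio V / delta_alpha
#' observed across the three reference animals (~5.333 mm^3 per mm^-1). The
#' reported volume does not depend on `v_cell` (it cancels); `v_cell` only
#' scales the auxiliary cross-section and cell-density outputs.
#'
#' At confluence the cell number density `N` is `1 / v_cell`; it is not stored
#' separately.
#'
#' @param alpha_ref Reference cancer absorption coefficient (mm^-1, > 0).
#' @param v_cell Single cancer-cell volume (mm^3, > 0).
#' @param v_effective Interrogated tissue volume (mm^3, > 0). Treated as an
#'   opaque calibration constant, not as scan area times thickness.
#' @return A `volumetry_calibration` object.
#' @export
volumetry_calibration <- function(alpha_ref = 1.5,
                                  v_cell = 2e-6,
                                  v_effective = 8) {
  if (!(alpha_ref > 0 && v_cell > 0 && v_effective > 0)) {
    stop("alpha_ref, v_cell and v_effective must all be > 0", call. = FALSE)
  }
  structure(
    list(alpha_ref = alpha_ref, v_cell = v_cell, v_effective = v_effective),
    class = "volumetry_calibration"
  )
}

#' Absorption cross-section of a single cancer cell
#'
#' `sigma = alpha_ref * v_cell`: the effective absorbing area per cell,
#' obtained by dividing the bulk absorption coefficient of confluent cancer
#' tissue by the cell number density `N = 1 / v_cell`.
#'
#' @param calibration A [volumetry_calibration()].
#' @return Cross-section sigma in mm^2.
#' @examples
#' absorption_cross_section(volumetry_calibration())  # 3e-6 mm^2
#' @export
absorption_cross_section <- function(calibration = volumetry_calibration()) {
  stopifnot(inherits(calibration, "volumetry_calibration"))
  calibration$alpha_ref * calibration$v_cell
}

#' Cancer-cell number density from an absorption change
#'
#' `N' = delta_alpha / sigma = delta_alpha / (alpha_ref * v_cell)`: the
#' density of absorbing cancer cells that would produce the observed regional
#' absorption excess.
#'
#' @param delta_alpha Absorption change(s) (mm^-1, >= 0). Numeric vector.
#' @param calibration A [volumetry_calibration()].
#' @return Cell density N' in mm^-3, same length as `delta_alpha`.
#' @export
cancer_cell_density <- function(delta_alpha,
                                calibration = volumetry_calibration()) {
  stopifnot(inherits(calibration, "volumetry_calibration"))
  check_delta_alpha(delta_alpha)
  delta_alpha / (calibration$alpha_ref * calibration$v_cell)
}

check_delta_alpha <- function(delta_alpha) {
  if (!is.numeric(delta_alpha) || any(is.na(delta_alpha))) {
    stop("`delta_alpha` must be numeric and non-missing", call. = FALSE)
  }
  if (any(delta_alpha < 0)) {
    stop("`delta_alpha` must be >= 0", call. = FALSE)
  }
  invisible(delta_alpha)
}

#' Estimate tumor volume from an absorption change
#'
#' Composes the absorption-cross-section model: the cell density
#' `N' = delta_alpha / (alpha_ref * v_cell)` times the cell volume gives the
#' cancer volume fraction, and multiplying by the interrogated volume yields
#' the total cancer-tissue volume
#' `V = N' * v_cell * v_effective = (delta_alpha / alpha_ref) * v_effective`.
#' `v_cell` cancels algebraically, so `V` is independent of it; the volume is
#' computed from the simplified form so the cancellation is exact.
#'
#' @param delta_alpha Absorption change(s) in mm^-1 (>= 0): a numeric vector,
#'   or a data frame containing a `delta_alpha` column (e.g. the output of
#'   [summarize_regions()]), whose columns are carried through.
#' @param calibration A [volumetry_calibration()].
#' @return A `volume_estimate` tibble with one row per input: `delta_alpha`,
#'   `sigma` (mm^2), `n_prime` (mm^-3), `volume_mm3`, plus any carried input
#'   columns. The calibration is attached as an attribute and reported by
#'   [glance.volume_estimate()].
#' @examples
#' estimate_volume(c(0.090, 0.160, 0.132))
#' @export
estimate_volume <- function(delta_alpha,
                            calibration = volumetry_calibration()) {
  stopifnot(inherits(calibration, "volumetry_calibration"))
  if (is.data.frame(delta_alpha)) {
    if (!"delta_alpha" %in% names(delta_alpha)) {
      stop("data-frame input must contain a `delta_alpha` column",
           call. = FALSE)
    }
    base <- tibble::as_tibble(delta_alpha)
    da <- base$delta_alpha
  } else {
    check_delta_alpha(delta_alpha)
    da <- delta_alpha
    base <- tibble::tibble(delta_alpha = da)
  }
  check_delta_alpha(da)
  out <- dplyr::mutate(
    base,
    sigma = absorption_cross_section(calibration),
    n_prime = cancer_cell_density(.data$delta_alpha, calibration),
    volume_mm3 = (.data$delta_alpha / calibration$alpha_ref) *
      calibration$v_effective
  )
  structure(out, calibration = calibration,
            class = c("volume_estimate", class(tibble::tibble())))
}

#' Smallest resolvable tumor volume
#'
#' The detection limit of the volumetry is the volume corresponding to the
#' smallest absorption change the system can resolve:
#' `(delta_alpha_min / alpha_ref) * v_effective`.
#'
#' @param delta_alpha_min Smallest resolvable absorption change (mm^-1, >= 0).
#' @param calibration A [volumetry_calibration()].
#' @return Detection-limit volume in mm^3.
#' @examples
#' detection_limit(0.09)  # < 1 mm^3
#' @export
detection_limit <- function(delta_alpha_min,
                            calibration = volumetry_calibration()) {
  stopifnot(inherits(calibration, "volumetry_calibration"))
  check_delta_alpha(delta_alpha_min)
  (delta_alpha_min / calibration$alpha_ref) * calibration$v_effective
}

#' Penetration depth at a given system dynamic range
#'
#' The depth at which the transmitted power of a medium with absorption
#' coefficient `alpha` falls to the system noise floor:
#' `depth = ln(dynamic_range) / alpha`.
#'
#' @param dynamic_range Ratio of full signal to noise floor (> 1).
#' @param alpha Tissue absorption coefficient (mm^-1, > 0).
#' @return Depth in mm.
#' @examples
#' penetration_depth(1e8, 1.42)  # ~13 mm
#' @export
penetration_depth <- function(dynamic_range, alpha) {
  if (!is.numeric(dynamic_range) || any(dynamic_range <= 1)) {
    stop("`dynamic_range` must be > 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || any(alpha <= 0)) {
    stop("`alpha` must be > 0", call. = FALSE)
  }
  log(dynamic_range) / alpha
}

#' Round half away from zero
#'
#' Reporting helper matching the conventional "half-up" presentation of
#' volumes and absorption changes (R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @examples
#' round_half_up(0.8535, 3)
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat("<volume_estimate>  V = (delta_alpha / alpha_ref) * v_effective\n")
  cal <- attr(x, "calibration")
  cat(sprintf("  calibration: alpha_ref = %g mm^-1, v_cell = %g mm^3, v_effective = %g mm^3\n",
              cal$alpha_ref, cal$v_cell, cal$v_effective))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
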
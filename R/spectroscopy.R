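#' Default spectroscopy frequency grid
#'
#' 108 to 143 GHz in 5 GHz steps (8 points), spanning the spectroscopy band.
#'
#' @return Numeric vector of frequencies in GHz.
#' @export
default_frequencies <- function() seq(108, 143, by = 5)

#' Compute an absorption spectrum from transmitted-power ratios
#'
#' Per-frequency Beer-Lambert inversion for one animal and tissue:
#' `alpha(f) = ln(1 / ratio(f)) / d`, where `ratio = I_s / I_b` must lie in
#' (0, 1] (a tissue cannot amplify).
#'
#' @param power_ratios Per-frequency `I_s / I_b`, in (0, 1].
#' @param d Tissue thickness (mm, > 0).
#' @return Numeric vector of absorption coefficients (mm^-1), one per input.
#' @examples
#' compute_spectrum(exp(-0.71), d = 0.5)  # 1.42 mm^-1
#' @export
compute_spectrum <- function(power_ratios, d) {
  stopifnot(is.numeric(power_ratios), length(power_ratios) >= 1, d > 0)
  if (any(power_ratios <= 0 | power_ratios > 1)) {
    stop("all power ratios must lie in (0, 1]", call. = FALSE)
  }
  log(1 / power_ratios) / d
}

#' Aggregate per-animal spectra into a cohort absorption spectrum
#'
#' Per-frequency mean and standard deviation of the mean (SEM, i.e. sample
#' SD divided by sqrt(n)) across animals. The SEM choice is deliberate:
#' cohort spectra here carry error bars that represent the standard deviation
#' of the mean, not the population spread.
#'
#' @param alpha_by_animal List of per-animal numeric alpha vectors (or a
#'   matrix with one row per animal), all on the same frequency grid.
#' @param frequencies_ghz Strictly increasing frequency grid (GHz).
#' @param tissue_label One of `"skin"`, `"fat"`, `"cancer"`.
#' @return An `absorption_spectrum` tibble: `tissue`, `frequency_ghz`,
#'   `alpha_mean`, `alpha_sd` (SEM, mm^-1), `n_animals`.
#' @export
aggregate_spectra <- function(alpha_by_animal,
                              frequencies_ghz = default_frequencies(),
                              tissue_label = c("skin", "fat", "cancer")) {
  tissue_label <- match.arg(tissue_label)
  if (is.list(alpha_by_animal)) {
    lens <- lengths(alpha_by_animal)
    if (length(unique(lens)) != 1) {
      stop("animals have mismatched frequency grids", call. = FALSE)
    }
    m <- do.call(rbind, alpha_by_animal)
  } else {
    m <- as.matrix(alpha_by_animal)
  }
  if (nrow(m) < 2) {
    stop("need >= 2 animals to aggregate", call. = FALSE)
  }
  if (ncol(m) != length(frequencies_ghz)) {
    stop("alpha vectors and `frequencies_ghz` have different lengths",
         call. = FALSE)
  }
  if (any(diff(frequencies_ghz) <= 0)) {
    stop("`frequencies_ghz` must be strictly increasing", call. = FALSE)
  }
  n <- nrow(m)
  structure(
    tibble::tibble(
      tissue = tissue_label,
      frequency_ghz = as.double(frequencies_ghz),
      alpha_mean = colMeans(m),
      alpha_sd = apply(m, 2, stats::sd) / sqrt(n),
      n_animals = n
    ),
    class = c("absorption_spectrum", class(tibble::tibble()))
  )
}

#' Tissue separability between two absorption spectra
#'
#' Per-frequency standardized gap
#' `(alpha_mean_a - alpha_mean_b) / sqrt(alpha_sd_a^2 + alpha_sd_b^2)`; the
#' two tissues are flagged as separable when the gap exceeds 2 at every
#' frequency (every band resolves the tissues at roughly two combined
#' standard errors).
#'
#' @param spec_a,spec_b `absorption_spectrum` tibbles on the same frequency
#'   grid (see [aggregate_spectra()]).
#' @return A list with `gaps` (tibble: `frequency_ghz`, `gap`) and
#'   `separable` (logical flag).
#' @export
separability <- function(spec_a, spec_b) {
  stopifnot(is.data.frame(spec_a), is.data.frame(spec_b))
  if (!isTRUE(all.equal(spec_a$frequency_ghz, spec_b$frequency_ghz))) {
    stop("spectra are on different frequency grids", call. = FALSE)
  }
  gap <- (spec_a$alpha_mean - spec_b$alpha_mean) /
    sqrt(spec_a$alpha_sd^2 + spec_b$alpha_sd^2)
  list(
    gaps = tibble::tibble(frequency_ghz = spec_a$frequency_ghz, gap = gap),
    separable = all(gap > 2)
  )
}
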
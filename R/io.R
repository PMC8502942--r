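#' Write a power raster to a delimited-text grid with a metadata sidecar
#'
#' The grid is written as tab-separated values, one line per pixel row, period
#' decimal separator; acquisition metadata (units, pitch, frequency,
#' background power, replicate index) goes to a YAML sidecar at
#' `<path>.meta.yaml`.
#'
#' @param raster A `power_raster`.
#' @param path Output path for the grid (e.g. `scan_r1.tsv`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "power_raster"))
  utils::write.table(raster$power, path, sep = "\t", dec = ".",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    kind = "power_raster",
    units = "arbitrary_power",
    background_power = raster$background_power,
    frequency_ghz = raster$frequency_ghz,
    pitch_mm = raster$pitch_mm,
    replicate_index = raster$replicate_index
  )
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a power raster written by [write_raster()]
#'
#' @param path Path to the grid file; its `<path>.meta.yaml` sidecar must
#'   exist.
#' @return A `power_raster`.
#' @export
read_raster <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  if (!identical(meta$kind, "power_raster")) {
    stop("sidecar does not describe a power_raster: ", sidecar_path(path),
         call. = FALSE)
  }
  power <- as.matrix(utils::read.table(path, sep = "\t", dec = "."))
  dimnames(power) <- NULL
  structure(
    list(
      power = power,
      background_power = meta$background_power,
      frequency_ghz = meta$frequency_ghz,
      pitch_mm = meta$pitch_mm,
      replicate_index = as.integer(meta$replicate_index)
    ),
    class = "power_raster"
  )
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write a label map as a delimited-text integer grid
#'
#' Integer codes: 0 below_range, 1 background, 2 cancer, 3 saturated; band
#' edges go to the `<path>.meta.yaml` sidecar.
#'
#' @param labels A `label_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  codes <- matrix(match(labels$labels, label_levels) - 1L,
                  nrow = nrow(labels$labels))
  utils::write.table(codes, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(
    list(kind = "label_map",
         codes = as.list(stats::setNames(0:3, label_levels)),
         bands = unclass(labels$bands),
         pitch_mm = labels$pitch_mm),
    sidecar_path(path))
  invisible(path)
}

#' Serialize a phantom/acquisition configuration to YAML
#'
#' @param spec A [phantom_spec()].
#' @param acq An [acquisition_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_phantom_config <- function(spec, acq, path) {
  validate_phantom_spec(spec)
  stopifnot(inherits(acq, "acquisition_config"))
  cfg <- list(
    phantom = c(
      unclass(spec)[setdiff(names(spec), "tumor_regions")],
      list(tumor_regions = purrr::transpose(as.list(spec$tumor_regions)))
    ),
    acquisition = unclass(acq)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a phantom/acquisition configuration written by
#' [write_phantom_config()]
#'
#' @param path YAML path.
#' @return A list with elements `spec` ([phantom_spec()]) and `acq`
#'   ([acquisition_config()]).
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ph <- cfg$phantom
  tr <- if (length(ph$tumor_regions) > 0) {
    dplyr::bind_rows(lapply(ph$tumor_regions, tibble::as_tibble))
  } else {
    tumor_disc()
  }
  spec <- phantom_spec(
    field_width_mm = ph$field_width_mm,
    field_height_mm = ph$field_height_mm,
    pixel_pitch_mm = ph$pixel_pitch_mm,
    sandwich_thickness_mm = ph$sandwich_thickness_mm,
    skin_optical_depth = ph$skin_optical_depth,
    fat_alpha = ph$fat_alpha,
    tumor_regions = tr,
    rng_seed = ph$rng_seed
  )
  acq <- do.call(acquisition_config, cfg$acquisition)
  list(spec = spec, acq = acq)
}

#' Read or write an aggregated spectrum table
#'
#' Delimited-text (TSV) with columns `tissue`, `frequency_ghz`, `alpha_mean`,
#' `alpha_sd`, `n_animals`.
#'
#' @param spectrum An `absorption_spectrum` tibble ([aggregate_spectra()]).
#' @param path File path.
#' @return `write_spectrum()`: `path`, invisibly. `read_spectrum()`: an
#'   `absorption_spectrum` tibble.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(tibble::as_tibble(spectrum), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  structure(out, class = c("absorption_spectrum", class(tibble::tibble())))
}
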
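#' Configure an end-to-end analysis run
#'
#' A pipeline run takes exactly one input source — a phantom to simulate, or
#' transmitted-power raster files to load — and carries it through absorbance
#' inversion, replicate averaging, skin calibration, classification, region
#' summary and volumetry.
#'
#' @param subject_id Label for the subject (appears in reports and file
#'   names).
#' @param phantom A [phantom_spec()] to simulate, or `NULL` when loading
#'   rasters.
#' @param raster_paths Character vector of raster grid files (written by
#'   [write_raster()]), or `NULL` when simulating a phantom. Exactly one of
#'   `phantom` / `raster_paths` must be given.
#' @param acquisition An [acquisition_config()]; used only with a phantom
#'   input.
#' @param thickness_mm Tissue slab thickness `d` (mm); required, no default.
#' @param skin Skin handling: either `skin_fixed(depth)` for a known optical
#'   depth or `skin_estimate(mask, reference_alpha)` to estimate it from a
#'   skin-only reference region.
#' @param bands A [class_bands()].
#' @param calibration A [volumetry_calibration()].
#' @param output_dir Directory for the report, label grid, rendered PNG and
#'   resolved config; `NULL` (default) skips writing.
#' @param rng_seed Integer master seed (overrides the acquisition seed).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(subject_id = "subject1",
                            phantom = NULL,
                            raster_paths = NULL,
                            acquisition = acquisition_config(),
                            thickness_mm,
                            skin = skin_fixed(0),
                            bands = class_bands(),
                            calibration = volumetry_calibration(),
                            output_dir = NULL,
                            rng_seed = 1L) {
  if (is.null(phantom) == is.null(raster_paths)) {
    stop("give exactly one input source: `phantom` or `raster_paths`",
         call. = FALSE)
  }
  if (missing(thickness_mm)) {
    if (is.null(phantom)) {
      stop("`thickness_mm` is required when loading rasters", call. = FALSE)
    }
    thickness_mm <- phantom$sandwich_thickness_mm
  }
  stopifnot(thickness_mm > 0)
  if (!is.null(phantom)) validate_phantom_spec(phantom)
  stopifnot(inherits(acquisition, "acquisition_config"),
            inherits(bands, "class_bands"),
            inherits(calibration, "volumetry_calibration"),
            inherits(skin, "skin_handling"))
  structure(
    list(subject_id = subject_id, phantom = phantom,
         raster_paths = raster_paths, acquisition = acquisition,
         thickness_mm = thickness_mm, skin = skin, bands = bands,
         calibration = calibration, output_dir = output_dir,
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

#' Skin-handling strategies for the pipeline
#'
#' `skin_fixed()` subtracts a known skin optical depth; `skin_estimate()`
#' derives the depth from a skin-only reference region via
#' [estimate_skin_background()].
#'
#' @param depth Known skin optical depth (dimensionless, >= 0).
#' @return A `skin_handling` object for [pipeline_config()].
#' @export
skin_fixed <- function(depth) {
  stopifnot(is.numeric(depth), length(depth) == 1, depth >= 0)
  structure(list(mode = "fixed", depth = depth), class = "skin_handling")
}

#' @rdname skin_fixed
#' @param mask Logical matrix marking the skin-only reference region.
#' @param reference_alpha Expected fat absorption coefficient under the mask
#'   (mm^-1).
#' @export
skin_estimate <- function(mask, reference_alpha) {
  stopifnot(is.logical(mask), is.numeric(reference_alpha))
  structure(list(mode = "estimate", mask = mask,
                 reference_alpha = reference_alpha),
            class = "skin_handling")
}

#' Run the end-to-end analysis for one subject
#'
#' Stages: simulate (or load) replicate power rasters -> Beer-Lambert
#' absorbance per replicate -> average replicates -> skin background
#' calibration -> band classification -> region summary -> absorption-
#' cross-section volumetry. With `output_dir` set, also writes the report
#' table (TSV, volumes and delta-alpha formatted to 3 decimals), the label
#' grid, the rendered PNG and a resolved-config YAML for provenance.
#' Identical config and seed give an identical report.
#'
#' @param config A [pipeline_config()].
#' @return A `thz_report` list: `report` (one-row tibble joining the region
#'   summary and volume estimate, plus `v_over_delta`), `absorbance` (the
#'   corrected `absorbance_map`), `labels` (`label_map`), `paths` (named
#'   character vector of written files, empty if `output_dir` is `NULL`).
#' @examples
#' cfg <- pipeline_config(
#'   phantom = phantom_spec(tumor_regions = tumor_disc(5, 5, 1.5, 0.16)),
#'   acquisition = acquisition_config(snr = Inf))
#' run_pipeline(cfg)$report
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s | stage %s] %s", config$subject_id, name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  rasters <- stage("input", {
    if (!is.null(config$phantom)) {
      acq <- config$acquisition
      acq$rng_seed <- config$rng_seed
      simulate_scan(build_phantom(config$phantom), acq)
    } else {
      lapply(config$raster_paths, read_raster)
    }
  })
  amaps <- stage("absorbance", lapply(rasters, compute_absorbance,
                                      thickness_mm = config$thickness_mm))
  avg <- stage("average", average_replicates(amaps))
  depth <- stage("skin", {
    if (config$skin$mode == "fixed") {
      config$skin$depth
    } else {
      estimate_skin_background(avg, config$skin$mask,
                               config$skin$reference_alpha)
    }
  })
  corrected <- stage("skin", calibrate_skin_background(avg, depth))
  labels <- stage("classify", classify_pixels(corrected, config$bands))
  regions <- stage("summarize", summarize_regions(corrected, labels))
  volume <- stage("volumetry",
                  estimate_volume(regions$delta_alpha, config$calibration))
  report <- dplyr::bind_cols(
    tibble::tibble(subject_id = config$subject_id),
    regions,
    dplyr::select(tibble::as_tibble(volume), -"delta_alpha")
  )
  report$v_over_delta <- ifelse(report$delta_alpha > 0,
                                report$volume_mm3 / report$delta_alpha,
                                NA_real_)
  paths <- character(0)
  if (!is.null(config$output_dir)) {
    paths <- stage("output",
                   write_report_files(config, corrected, labels, report))
  }
  structure(list(report = report, absorbance = corrected, labels = labels,
                 paths = paths),
            class = "thz_report")
}

write_report_files <- function(config, corrected, labels, report) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(config$output_dir, config$subject_id)
  report_path <- paste0(base, "_report.tsv")
  fmt <- report
  for (col in c("delta_alpha", "volume_mm3", "mean_background_alpha",
                "mean_cancer_alpha")) {
    fmt[[col]] <- sprintf("%.3f", round_half_up(fmt[[col]], 3))
  }
  readr::write_tsv(fmt, report_path)
  label_path <- paste0(base, "_labels.tsv")
  write_label_map(labels, label_path)
  png_path <- paste0(base, ".png")
  render_image(corrected, config$bands, png_path)
  cfg_path <- paste0(base, "_config.yaml")
  yaml::write_yaml(resolved_config_list(config), cfg_path)
  c(report = report_path, labels = label_path, image = png_path,
    config = cfg_path)
}

resolved_config_list <- function(config) {
  list(
    subject_id = config$subject_id,
    input = if (!is.null(config$phantom)) "phantom" else "rasters",
    phantom = if (!is.null(config$phantom)) {
      c(unclass(config$phantom)[setdiff(names(config$phantom),
                                        "tumor_regions")],
        list(tumor_regions =
               purrr::transpose(as.list(config$phantom$tumor_regions))))
    },
    raster_paths = config$raster_paths,
    acquisition = unclass(config$acquisition),
    thickness_mm = config$thickness_mm,
    skin = if (config$skin$mode == "fixed") {
      list(mode = "fixed", depth = config$skin$depth)
    } else {
      list(mode = "estimate", reference_alpha = config$skin$reference_alpha)
    },
    bands = unclass(config$bands),
    calibration = unclass(config$calibration),
    rng_seed = config$rng_seed
  )
}

#' Run a panel of subjects and combine the reports
#'
#' Each subject gets its own RNG stream derived as master seed plus subject
#' index, so adding a subject never perturbs the others. Per-subject failures
#' are caught and reported as a warning; the panel continues.
#'
#' @param configs List of [pipeline_config()]s (>= 1).
#' @param master_seed Integer master seed; subject `i` runs with
#'   `master_seed + i`.
#' @return A tibble with one report row per successful subject, including the
#'   `v_over_delta` ratio column (constant across subjects under one
#'   calibration).
#' @export
run_mouse_panel <- function(configs, master_seed = 1L) {
  stopifnot(length(configs) >= 1)
  rows <- purrr::imap(configs, function(cfg, i) {
    cfg$rng_seed <- as.integer(master_seed) + as.integer(i)
    tryCatch(run_pipeline(cfg)$report, error = function(e) {
      warning(sprintf("subject %s failed: %s", cfg$subject_id,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  })
  dplyr::bind_rows(rows)
}

#' @export
print.thz_report <- function(x, ...) {
  cat("<thz_report>\n")
  print(x$report, ...)
  if (length(x$paths) > 0) {
    cat("files:\n")
    for (nm in names(x$paths)) cat("  ", nm, ": ", x$paths[[nm]], "\n",
                                   sep = "")
  }
  invisible(x)
}
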
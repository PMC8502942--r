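#' Absorption-coefficient class bands
#'
#' The false-color classification uses three band edges on the absorption
#' coefficient: fatty background in `[background_low, background_high)`,
#' cancer in `[background_high, cancer_high)`, and saturation at
#' `alpha >= cancer_high`. Intervals are half-open so every pixel falls in
#' exactly one class, and a boundary value at `background_high` classifies as
#' cancer — the conservative choice for detection.
#'
#' @param background_low,background_high,cancer_high Band edges in mm^-1.
#'   Defaults 1.400 / 1.450 / 1.600: the fatty band is 1.400-1.450 mm^-1 and
#'   early cancer 1.450-1.600 mm^-1, with 1.600 mm^-1 the color-scale maximum.
#' @return A `class_bands` object.
#' @export
class_bands <- function(background_low = 1.400,
                        background_high = 1.450,
                        cancer_high = 1.600) {
  if (!(background_low < background_high && background_high < cancer_high)) {
    stop("bands must satisfy background_low < background_high < cancer_high",
         call. = FALSE)
  }
  structure(
    list(background_low = background_low,
         background_high = background_high,
         cancer_high = cancer_high),
    class = "class_bands"
  )
}

label_levels <- c("below_range", "background", "cancer", "saturated")

#' Classify absorbance-map pixels into tissue classes
#'
#' Pure per-pixel thresholding by [class_bands()]: `background` if
#' `background_low <= alpha < background_high`, `cancer` if
#' `background_high <= alpha < cancer_high`, `saturated` if
#' `alpha >= cancer_high`, and `below_range` otherwise. No morphological
#' cleanup is applied by default; see `min_component_px` for an optional
#' small-blob filter.
#'
#' @param map A skin-corrected `absorbance_map`.
#' @param bands A [class_bands()].
#' @param min_component_px Optional minimum 4-connected component size (in
#'   pixels) for cancer/saturated blobs; smaller blobs are relabelled as
#'   background. Default 0 (off): the classification is pure thresholding.
#' @return A `label_map`: list with `labels` (factor matrix with levels
#'   below_range / background / cancer / saturated), `bands`, `pitch_mm`.
#' @export
classify_pixels <- function(map, bands = class_bands(),
                            min_component_px = 0L) {
  stopifnot(inherits(map, "absorbance_map"), inherits(bands, "class_bands"))
  if (!isTRUE(map$skin_corrected)) {
    stop("map must be skin-corrected before classification", call. = FALSE)
  }
  a <- map$alpha
  lab <- matrix("below_range", nrow = nrow(a), ncol = ncol(a))
  lab[a >= bands$background_low & a < bands$background_high] <- "background"
  lab[a >= bands$background_high & a < bands$cancer_high] <- "cancer"
  lab[a >= bands$cancer_high] <- "saturated"
  if (min_component_px > 0) {
    lab <- drop_small_components(lab, min_component_px)
  }
  structure(
    list(labels = lab, bands = bands, pitch_mm = map$pitch_mm),
    class = "label_map"
  )
}

# Relabel 4-connected cancer/saturated blobs smaller than min_px as
# background. Flood fill over the lesion mask; small by design (off by
# default) so a plain stack-based fill is adequate.
drop_small_components <- function(lab, min_px) {
  lesion <- lab %in% c("cancer", "saturated")
  lesion <- matrix(lesion, nrow = nrow(lab))
  seen <- matrix(FALSE, nrow = nrow(lab), ncol = ncol(lab))
  nr <- nrow(lab); nc <- ncol(lab)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!lesion[i, j] || seen[i, j]) next
    stack <- list(c(i, j))
    comp <- integer(0)
    seen[i, j] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      comp <- c(comp, (p[2] - 1L) * nr + p[1])
      for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        q <- p + dd
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            lesion[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    if (length(comp) < min_px) lab[comp] <- "background"
  }
  lab
}

#' Summarise background and cancer regions of a labelled map
#'
#' Computes the class mean absorption coefficients and the absorption change
#' `delta_alpha = mean(cancer) - mean(background)`, where the cancer mean
#' pools cancer and saturated pixels (saturation only caps the display scale,
#' not the tissue). `delta_alpha` is a difference of means, so it is invariant
#' to any residual uniform offset left by imperfect skin calibration. A map
#' with no cancer pixels yields `delta_alpha = 0` and `cancer_detected =
#' FALSE` with a warning; a map with no background pixels has no reference
#' level and is an error.
#'
#' @param map The skin-corrected `absorbance_map` that was classified.
#' @param labels The matching [classify_pixels()] `label_map`.
#' @return A one-row tibble: `mean_background_alpha`, `mean_cancer_alpha`,
#'   `delta_alpha` (mm^-1), `n_background_pixels`, `n_cancer_pixels`
#'   (cancer + saturated), `cancer_area_mm2` (`n_cancer_pixels * pitch^2`),
#'   `cancer_detected`.
#' @export
summarize_regions <- function(map, labels) {
  stopifnot(inherits(map, "absorbance_map"), inherits(labels, "label_map"),
            identical(dim(map$alpha), dim(labels$labels)))
  lab <- labels$labels
  bg <- lab == "background"
  ca <- lab == "cancer" | lab == "saturated"
  if (!any(bg)) {
    stop("no background pixels: no reference level for delta_alpha",
         call. = FALSE)
  }
  mean_bg <- mean(map$alpha[bg])
  if (any(ca)) {
    mean_ca <- mean(map$alpha[ca])
    delta <- mean_ca - mean_bg
    detected <- TRUE
  } else {
    warning("no cancer pixels; delta_alpha set to 0", call. = FALSE)
    mean_ca <- NA_real_
    delta <- 0
    detected <- FALSE
  }
  tibble::tibble(
    mean_background_alpha = mean_bg,
    mean_cancer_alpha = mean_ca,
    delta_alpha = delta,
    n_background_pixels = sum(bg),
    n_cancer_pixels = sum(ca),
    cancer_area_mm2 = sum(ca) * labels$pitch_mm^2,
    cancer_detected = detected
  )
}

#' Render a false-color absorbance image
#'
#' Writes a PNG with a continuous blue-to-red color scale clamped to
#' `[background_low, cancer_high]`: every alpha at or above `cancer_high`
#' renders as the same red, and `background_low` maps to the lowest blue.
#' Clamping affects display only; stored alpha values are never modified.
#'
#' @param map An `absorbance_map`.
#' @param bands A [class_bands()] giving the color-scale endpoints.
#' @param out_path Output PNG path.
#' @param zoom Integer pixel-replication factor; output dimensions are grid
#'   dimensions times `zoom`.
#' @return `out_path`, invisibly.
#' @export
render_image <- function(map, bands = class_bands(), out_path, zoom = 4L) {
  stopifnot(inherits(map, "absorbance_map"), inherits(bands, "class_bands"),
            zoom >= 1)
  zoom <- as.integer(zoom)
  lo <- bands$background_low
  hi <- bands$cancer_high
  u <- (map$alpha - lo) / (hi - lo)
  u <- pmin(pmax(u, 0), 1)
  cols <- blue_red_palette(256L)
  idx <- matrix(1L + as.integer(round(u * 255)), nrow = nrow(u))
  rgb <- grDevices::col2rgb(cols[idx]) / 255
  arr <- array(0, dim = c(nrow(u), ncol(u), 3))
  arr[, , 1] <- matrix(rgb[1, ], nrow = nrow(u))
  arr[, , 2] <- matrix(rgb[2, ], nrow = nrow(u))
  arr[, , 3] <- matrix(rgb[3, ], nrow = nrow(u))
  big <- array(0, dim = c(nrow(u) * zoom, ncol(u) * zoom, 3))
  ones <- matrix(1, zoom, zoom)
  for (k in 1:3) big[, , k] <- kronecker(arr[, , k], ones)
  png::writePNG(big, target = out_path)
  invisible(out_path)
}

blue_red_palette <- function(n) {
  grDevices::colorRampPalette(
    c("#0000B0", "#0060FF", "#00D0D0", "#70E000", "#FFD000", "#FF6000",
      "#C00000"))(n)
}

#' @export
print.label_map <- function(x, ...) {
  counts <- table(factor(x$labels, levels = label_levels))
  cat(sprintf("<label_map> %d x %d px @ %.3g mm\n",
              nrow(x$labels), ncol(x$labels), x$pitch_mm))
  print(counts)
  invisible(x)
}
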
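#' Feature-extraction configuration
#'
#' Selects and parameterizes the feature blocks. The classical blocks
#' (texture, fractal, spectral) are computed on the green channel restricted
#' to the field of view; the softmax embedding block is computed on the
#' resized standardized RGB array and is disabled by default.
#'
#' @param deep Include the 1000-entry softmax filter-bank embedding block.
#' @param glcm,fractal,spectral Include the respective classical blocks.
#' @param levels Gray levels for GLCM quantization (default 16).
#' @param offsets GLCM offsets (default: the four distance-1 directions).
#' @param box_sizes Optional explicit box sizes for the fractal block.
#' @param seg_len,overlap Bispectrum segmentation parameters.
#' @param side Resize target for the embedding branch (default 224).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(deep = FALSE, glcm = TRUE, fractal = TRUE,
                           spectral = TRUE, levels = 16,
                           offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                           box_sizes = NULL, seg_len = 64, overlap = 0.5,
                           side = 224) {
  structure(
    list(deep = deep, glcm = glcm, fractal = fractal, spectral = spectral,
         levels = levels, offsets = offsets, box_sizes = box_sizes,
         seg_len = seg_len, overlap = overlap, side = side),
    class = "feature_config"
  )
}

#' Extract the full feature vector of one image
#'
#' Concatenates the configured blocks in the fixed order
#' deep || texture || fractal || spectral with stable names, so feature
#' matrices from a run are column-aligned.
#'
#' @param img RGB array (0..255) or `fundus_image`.
#' @param config A [feature_config()].
#' @param fov Optional FOV mask; estimated when NULL.
#' @return Named numeric vector.
#' @export
extract_features <- function(img, config = feature_config(), fov = NULL) {
  if (!inherits(config, "feature_config")) config <- do.call(feature_config, config)
  pp <- preprocess(img, fov = fov, side = config$side)
  out <- numeric(0)
  if (isTRUE(config$deep)) {
    out <- c(out, deep_features(pp$rgb))
  }
  if (isTRUE(config$glcm)) {
    out <- c(out, glcm_features(pp$gray, pp$mask, levels = config$levels,
                                offsets = config$offsets))
  }
  if (isTRUE(config$fractal)) {
    out <- c(out, fractal_features(pp$gray, pp$mask, box_sizes = config$box_sizes))
  }
  if (isTRUE(config$spectral)) {
    out <- c(out, bispectral_features(pp$gray, pp$mask, center = pp$center,
                                      radius = pp$radius,
                                      seg_len = config$seg_len,
                                      overlap = config$overlap))
  }
  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop(sprintf("non-finite features: %s", paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Extract features for every image of a manifest
#'
#' Reads each image, estimates its field-of-view mask and extracts the
#' configured feature vector; rows align with the manifest order.
#'
#' @param manifest Manifest tibble with a `path` column.
#' @param config A [feature_config()].
#' @param progress Print a dot every 25 images.
#' @return A tibble: `path` followed by one column per feature.
#' @export
extract_features_batch <- function(manifest, config = feature_config(),
                                   progress = FALSE) {
  stopifnot(is.data.frame(manifest), "path" %in% names(manifest))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    fv <- extract_features(read_image(manifest$path[i]), config)
    rows[[i]] <- tibble::as_tibble_row(c(list(path = manifest$path[i]),
                                         as.list(fv)))
    if (progress && i %% 25 == 0) message(sprintf("  features: %d/%d", i, nrow(manifest)))
  }
  dplyr::bind_rows(rows)
}
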
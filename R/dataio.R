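#' Read an RGB raster image
#'
#' Reads a PNG, JPEG or TIFF file into an 8-bit RGB array (height x width x 3,
#' row-major, origin top-left, values 0..255). Grayscale inputs are replicated
#' across channels; alpha channels are dropped.
#'
#' @param path File path; format inferred from the extension.
#' @return Numeric array height x width x 3 with integer values in 0..255.
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1) stop_param("path", "must be a single path")
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file not found '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = {
        if (!requireNamespace("jpeg", quietly = TRUE)) {
          stop("the 'jpeg' package is required to read JPEG files")
        }
        jpeg::readJPEG(path)
      },
      tif = ,
      tiff = {
        if (!requireNamespace("tiff", quietly = TRUE)) {
          stop("the 'tiff' package is required to read TIFF files")
        }
        tiff::readTIFF(path)
      },
      stop(sprintf("unsupported image format '.%s'", ext))
    ),
    error = function(e) {
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 1) raw <- array(rep(raw, 3), dim = c(dim(raw)[1:2], 3))
  clamp8(raw * 255)
}

#' Write an image as 8-bit RGB PNG
#'
#' @param img A `fundus_image` or a height x width x 3 array with values
#'   in 0..255.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- if (inherits(img, "fundus_image")) img$pixels else img
  if (length(dim(px)) != 3 || dim(px)[3] != 3) {
    stop_param("img", "must be a height x width x 3 array")
  }
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' The manifest is a CSV indexing a dataset: one row per image with columns
#' `path`, `label` (good | poor), `poor_subtype` (eye_abnormality | artefact |
#' none), `abnormality_kind` (optional), `seed`, and optionally `degradation`
#' and `split` (train | test).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_manifest(tibble::as_tibble(df))
}

#' @rdname read_manifest
#' @param manifest A manifest tibble/data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

.validate_manifest <- function(manifest) {
  need <- c("path", "label", "poor_subtype")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop(sprintf("manifest is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$path)) {
    stop("manifest paths must be unique", call. = FALSE)
  }
  if (!all(manifest$label %in% c("good", "poor"))) {
    stop("manifest labels must be 'good' or 'poor'", call. = FALSE)
  }
  if (!all(manifest$poor_subtype %in% c("eye_abnormality", "artefact", "none"))) {
    stop("poor_subtype must be eye_abnormality, artefact or none", call. = FALSE)
  }
  bad <- xor(manifest$label == "poor", manifest$poor_subtype != "none")
  if (any(bad)) {
    stop("label == 'poor' must coincide with poor_subtype != 'none'", call. = FALSE)
  }
  tibble::as_tibble(manifest)
}

#' Estimate the circular field-of-view mask of a fundus image
#'
#' Thresholds luminance with Otsu's method, keeps the largest connected
#' component, applies a morphological closing and fills holes. The FOV mask is
#' the reference area for the "covers more than 1/4 of the image" rule.
#'
#' @param img An RGB array (0..255) or `fundus_image`.
#' @return A logical matrix (TRUE inside the FOV) with attributes `center`
#'   (row, col centroid) and `radius` (equivalent-area circle radius).
#' @export
estimate_fov_mask <- function(img) {
  px <- if (inherits(img, "fundus_image")) img$pixels else img
  if (length(dim(px)) != 3) stop_param("img", "must be an RGB array")
  lum <- (px[, , 1] + px[, , 2] + px[, , 3]) / (3 * 255)
  if (diff(range(lum)) == 0) {
    stop("degenerate image: constant luminance", call. = FALSE)
  }
  # normalize to full range so underexposed frames still threshold cleanly
  lum <- (lum - min(lum)) / diff(range(lum))
  # clip bright outliers (optic disc, asteroid bodies) so Otsu separates the
  # retinal field from the dark exterior, not the highlights from the retina
  cl <- pmin(lum, max(stats::quantile(lum, 0.75), 0.05))
  cl <- cl / max(cl)
  th <- EBImage::otsu(cl, range = c(0, 1))
  mask <- cl > th
  if (mean(mask) < 0.25) {
    mask <- lum > 0.5 * EBImage::otsu(lum, range = c(0, 1))
  }
  if (!any(mask)) {
    stop("degenerate image: no foreground above the Otsu threshold", call. = FALSE)
  }
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  mask <- EBImage::closing(mask * 1, EBImage::makeBrush(7, "disc")) > 0
  mask <- EBImage::fillHull(mask * 1) > 0
  if (!any(mask)) {
    stop("degenerate image: empty field-of-view mask", call. = FALSE)
  }
  idx <- which(mask, arr.ind = TRUE)
  structure(mask,
            center = c(mean(idx[, 1]), mean(idx[, 2])),
            radius = sqrt(sum(mask) / pi))
}

#' Stratified train/test split of a manifest
#'
#' Assigns each record to train or test by simple random sampling within
#' strata defined by `(label, poor_subtype)`. Each stratum of size n
#' contributes exactly `floor(train_fraction * n)` training records, the
#' convention that reproduces per-class 70/30 counts used for model building
#' elsewhere in the package.
#'
#' @param manifest A manifest tibble (see [read_manifest()]).
#' @param train_fraction Fraction in (0, 1), default 0.70.
#' @param rng_seed Integer seed for the within-stratum sampling.
#' @return The manifest with a `split` column (`"train"` / `"test"`).
#' @examples
#' m <- tibble::tibble(
#'   path = sprintf("img%03d.png", 1:20),
#'   label = rep(c("good", "poor"), each = 10),
#'   poor_subtype = rep(c("none", "artefact"), each = 10)
#' )
#' table(stratified_split(m, 0.7, rng_seed = 1)[c("label", "split")])
#' @export
stratified_split <- function(manifest, train_fraction = 0.70, rng_seed = 1L) {
  manifest <- .validate_manifest(manifest)
  if (!is.numeric(train_fraction) || length(train_fraction) != 1 ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop_param("train_fraction", "must lie strictly inside (0, 1)")
  }
  if (nrow(manifest) == 0) {
    warning("empty manifest: nothing to split")
    manifest$split <- character(0)
    return(manifest)
  }
  stratum <- paste(manifest$label, manifest$poor_subtype, sep = "/")
  split <- character(nrow(manifest))
  with_seed(rng_seed, {
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      n_train <- floor(train_fraction * length(idx))
      if (n_train == 0 || n_train == length(idx)) {
        warning(sprintf(
          "stratum '%s' (n=%d) has an empty train or test side", s, length(idx)))
      }
      tr <- if (n_train > 0) sample(idx, n_train) else integer(0)
      split[idx] <- "test"
      split[tr] <- "train"
    }
  })
  manifest$split <- split
  manifest
}
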
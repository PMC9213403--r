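#' Preprocess an image for feature extraction
#'
#' Produces the two working representations used by the feature extractors:
#' the green channel restricted to the field of view (classical features; the
#' green channel carries the highest vessel contrast in fundus photography),
#' and a square resized RGB array with per-channel standardization (softmax
#' embedding branch).
#'
#' @param img RGB array (0..255) or `fundus_image`.
#' @param fov Logical FOV mask matching the image; estimated with
#'   [estimate_fov_mask()] when NULL.
#' @param side Side length of the resized RGB output (default 224).
#' @return A list with `gray` (green-channel matrix, 0..255), `mask` (logical
#'   matrix), `rgb` (side x side x 3 standardized array), `rgb_raw` (resized,
#'   0..255), `center` and `radius` of the FOV.
#' @export
preprocess <- function(img, fov = NULL, side = 224) {
  px <- if (inherits(img, "fundus_image")) img$pixels else img
  if (length(dim(px)) != 3 || dim(px)[3] != 3) {
    stop_param("img", "must be a height x width x 3 RGB array")
  }
  if (is.null(fov)) {
    if (inherits(img, "fundus_image") && !is.null(img$provenance$masks)) {
      fov <- img$provenance$masks$fov
      attr(fov, "center") <- img$provenance$masks$fov_center
      attr(fov, "radius") <- img$provenance$masks$fov_radius
    } else {
      fov <- estimate_fov_mask(px)
    }
  }
  if (!all(dim(fov) == dim(px)[1:2])) {
    stop("mask and image dimensions disagree", call. = FALSE)
  }
  center <- attr(fov, "center")
  if (is.null(center)) {
    idx <- which(fov, arr.ind = TRUE)
    center <- c(mean(idx[, 1]), mean(idx[, 2]))
  }
  radius <- attr(fov, "radius") %||% sqrt(sum(fov) / pi)

  rgb_raw <- if (all(dim(px)[1:2] == side)) {
    px
  } else {
    out <- array(0, dim = c(side, side, 3))
    for (ch in 1:3) out[, , ch] <- EBImage::resize(px[, , ch], w = side, h = side)
    out
  }
  rgb_std <- rgb_raw
  for (ch in 1:3) {
    v <- rgb_raw[, , ch]
    rgb_std[, , ch] <- (v - mean(v)) / max(stats::sd(v), 1e-6)
  }
  list(
    gray = px[, , 2],
    mask = fov & TRUE,  # strip attributes into a plain logical matrix
    rgb = rgb_std,
    rgb_raw = rgb_raw,
    center = center,
    radius = radius
  )
}
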
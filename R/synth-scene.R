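#' Scene parameters for the synthetic fundus generator
#'
#' Describes one synthetic fundus photograph before degradation: a circular
#' field of view (FOV) on a near-black frame, a branching retinal vessel tree
#' with at least three branch orders, and a bright optic disc. Third-order
#' branches stand in for the level-III vascular arches whose visibility is the
#' clinical clarity criterion, so `vessel_orders` must be at least 3.
#'
#' @param image_size Side length in pixels of the square frame (default 512).
#' @param disc_center Numeric `c(row, col)` of the optic disc center. Default
#'   places the disc on the horizontal midline, halfway between FOV center and
#'   FOV edge.
#' @param disc_radius Optic disc radius in pixels (default `0.09 * image_size`).
#' @param vessel_orders Branching depth of the vessel tree; must be >= 3 so the
#'   order-3 visibility criterion is representable (default 4).
#' @param vessel_contrast Dimensionless multiplicative vessel darkening in
#'   (0, 1]; 0 is allowed and renders invisible vessels (default 0.5).
#' @param background_luminance Green-channel gray level of the retinal
#'   background at FOV center, in \[0, 255\] (default 110).
#' @param rng_seed Integer seed controlling vessel-tree geometry and background
#'   texture.
#' @return An object of class `scene_params` (a validated list).
#' @seealso [render_fundus()]
#' @export
scene_params <- function(image_size = 512,
                         disc_center = NULL,
                         disc_radius = NULL,
                         vessel_orders = 4,
                         vessel_contrast = 0.5,
                         background_luminance = 110,
                         rng_seed = 1L) {
  if (!is.numeric(image_size) || length(image_size) != 1 || image_size < 64) {
    stop_param("image_size", "must be a single number >= 64")
  }
  image_size <- as.integer(image_size)
  fov_r <- image_size / 2 - 1
  center <- c((image_size + 1) / 2, (image_size + 1) / 2)
  if (is.null(disc_radius)) disc_radius <- round(0.09 * image_size)
  if (!is.numeric(disc_radius) || disc_radius <= 0) {
    stop_param("disc_radius", "must be a positive number of pixels")
  }
  if (is.null(disc_center)) disc_center <- c(center[1], center[2] + 0.5 * fov_r)
  if (!is.numeric(disc_center) || length(disc_center) != 2) {
    stop_param("disc_center", "must be c(row, col)")
  }
  if (sqrt(sum((disc_center - center)^2)) + disc_radius > fov_r) {
    stop_param("disc_center", "optic disc must lie fully inside the field of view")
  }
  if (!is.numeric(vessel_orders) || vessel_orders < 3) {
    stop_param("vessel_orders", "must be >= 3 (order-3 arches must exist)")
  }
  if (!is.numeric(vessel_contrast) || vessel_contrast < 0 || vessel_contrast > 1) {
    stop_param("vessel_contrast", "must lie in [0, 1]")
  }
  if (!is.numeric(background_luminance) || background_luminance < 0 ||
      background_luminance > 255) {
    stop_param("background_luminance", "must lie in [0, 255]")
  }
  structure(
    list(
      image_size = image_size,
      fov_center = center,
      fov_radius = fov_r,
      disc_center = as.numeric(disc_center),
      disc_radius = as.numeric(disc_radius),
      vessel_orders = as.integer(vessel_orders),
      vessel_contrast = as.numeric(vessel_contrast),
      background_luminance = as.numeric(background_luminance),
      rng_seed = as.integer(rng_seed)
    ),
    class = "scene_params"
  )
}

# rasterize a thick line segment into an integer order matrix (0 = empty);
# only previously-empty pixels inside `allow` are claimed
.draw_segment <- function(ord_mat, p0, p1, width, ordval, allow) {
  h <- nrow(ord_mat); w <- ncol(ord_mat)
  rad <- max(width / 2, 0.6)
  r0 <- max(1L, floor(min(p0[1], p1[1]) - rad - 1))
  r1 <- min(h, ceiling(max(p0[1], p1[1]) + rad + 1))
  c0 <- max(1L, floor(min(p0[2], p1[2]) - rad - 1))
  c1 <- min(w, ceiling(max(p0[2], p1[2]) + rad + 1))
  if (r0 > r1 || c0 > c1) return(ord_mat)
  rr <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
  cc <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  v <- p1 - p0
  len2 <- sum(v^2)
  if (len2 < 1e-9) {
    d <- sqrt((rr - p0[1])^2 + (cc - p0[2])^2)
  } else {
    t <- ((rr - p0[1]) * v[1] + (cc - p0[2]) * v[2]) / len2
    t[t < 0] <- 0; t[t > 1] <- 1
    d <- sqrt((rr - (p0[1] + t * v[1]))^2 + (cc - (p0[2] + t * v[2]))^2)
  }
  hit <- d <= rad
  sub <- ord_mat[r0:r1, c0:c1]
  al <- allow[r0:r1, c0:c1]
  claim <- hit & al & sub == 0L
  sub[claim] <- ordval
  ord_mat[r0:r1, c0:c1] <- sub
  ord_mat
}

# Recursive binary branching vessel tree. Returns an integer matrix of branch
# orders plus the list of centerline points per order (used by degradations).
.grow_vessels <- function(params) {
  n <- params$image_size
  ord_mat <- matrix(0L, n, n)
  fov <- dist_field(n, n, params$fov_center) <= params$fov_radius
  centerlines <- vector("list", params$vessel_orders)
  for (i in seq_along(centerlines)) centerlines[[i]] <- list()

  root_w <- max(2.5, 0.008 * n)
  root_len <- 0.55 * params$fov_radius
  root_angles <- c(120, 160, 200, 240) * pi / 180
  root_curv <- c(-4, -1.5, 1.5, 4) * pi / 180

  grow <- function(start, angle, len, width, order, curv) {
    nseg <- 6L
    p <- start
    a <- angle
    pts <- matrix(NA_real_, nseg + 1L, 2L)
    pts[1L, ] <- p
    for (k in seq_len(nseg)) {
      a <- a + curv + stats::runif(1, -1, 1) * 6 * pi / 180
      q <- p + (len / nseg) * c(sin(a), cos(a))
      ord_mat <<- .draw_segment(ord_mat, p, q, width, order, fov)
      p <- q
      pts[k + 1L, ] <- p
    }
    centerlines[[order]][[length(centerlines[[order]]) + 1L]] <<- pts
    if (order < params$vessel_orders) {
      split <- stats::runif(1, 20, 35) * pi / 180
      for (sgn in c(-1, 1)) {
        grow(p, a + sgn * split, len * 0.72, width * 0.72, order + 1L,
             curv + stats::runif(1, -1, 1) * 2 * pi / 180)
      }
    }
  }

  with_seed(derive_seed(params$rng_seed, 7L), {
    for (i in seq_along(root_angles)) {
      grow(params$disc_center, root_angles[i], root_len, root_w, 1L, root_curv[i])
    }
  })
  list(orders = ord_mat, centerlines = centerlines)
}

# smooth low-frequency texture field with unit-ish sd, seeded
.texture_field <- function(n, seed) {
  g <- max(8L, as.integer(n / 8))
  z <- with_seed(seed, matrix(stats::rnorm((g + 2)^2), g + 2, g + 2))
  up <- EBImage::resize(z, w = n, h = n)
  up / max(stats::sd(up), 1e-9)
}

#' Render a synthetic fundus photograph
#'
#' Deterministically renders an RGB fundus-like image from [scene_params()]:
#' a circular bright field of view on a near-black frame, a radially vignetted
#' retinal background with smooth texture, a recursive binary branching vessel
#' tree darker than the background (branch orders recorded per pixel), and a
#' bright optic disc. The returned image is labelled `good`; degradations are
#' applied afterwards with [apply_degradation()].
#'
#' @param params A [scene_params()] object.
#' @return A `fundus_image`: list with `pixels` (height x width x 3 array of
#'   8-bit values, origin top-left), `label`, `poor_subtype`,
#'   `abnormality_kind` and `provenance` (scene, degradations, per-step
#'   rendered coverage and order-3 vessel contrast, plus the FOV/vessel/disc
#'   masks used downstream).
#' @examples
#' img <- render_fundus(scene_params(image_size = 128, rng_seed = 3))
#' dim(img$pixels)
#' img$label
#' @export
render_fundus <- function(params) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  n <- params$image_size
  dfov <- dist_field(n, n, params$fov_center)
  fov <- dfov <= params$fov_radius

  # vignetted background; channel mix approximates retinal coloration
  bg_g <- params$background_luminance
  vign <- 1 - 0.25 * (dfov / params$fov_radius)^2
  vign[!fov] <- 0
  tex <- .texture_field(n, derive_seed(params$rng_seed, 11L)) * 3
  base <- list(
    r = pmin(1.75 * bg_g, 255) * vign + tex * 1.0 * fov,
    g = bg_g * vign + tex * 0.8 * fov,
    b = 0.5 * bg_g * vign + tex * 0.6 * fov
  )
  base <- lapply(base, function(ch) { ch[!fov] <- 4; ch })

  vt <- .grow_vessels(params)
  ordm <- vt$orders
  ord_fac <- c(1, 0.85, 0.7, 0.55, 0.45, 0.4, 0.35, 0.3)
  cfac <- matrix(0, n, n)
  vs <- ordm > 0L
  cfac[vs] <- params$vessel_contrast * ord_fac[pmin(ordm[vs], length(ord_fac))]
  base$r <- base$r * (1 - 0.6 * cfac)
  base$g <- base$g * (1 - cfac)
  base$b <- base$b * (1 - cfac)

  # optic disc drawn over the vessels with a soft edge
  ddisc <- dist_field(n, n, params$disc_center)
  dmask_soft <- pmin(pmax((params$disc_radius + 1.5 - ddisc) / 3, 0), 1)
  alpha <- 0.85 * dmask_soft
  disc_col <- c(r = 240, g = 210, b = 160)
  for (ch in names(base)) {
    base[[ch]] <- base[[ch]] * (1 - alpha) + disc_col[[ch]] * alpha
  }

  px <- array(0, dim = c(n, n, 3))
  px[, , 1] <- clamp8(base$r)
  px[, , 2] <- clamp8(base$g)
  px[, , 3] <- clamp8(base$b)

  vessel_masks <- lapply(seq_len(params$vessel_orders), function(o) ordm == o)
  masks <- list(
    fov = fov,
    vessels = vessel_masks,
    vessel_all = vs,
    vessel_orders = ordm,
    centerlines = vt$centerlines,
    disc = dmask_soft > 0.5,
    fov_center = params$fov_center,
    fov_radius = params$fov_radius
  )
  img <- structure(
    list(
      pixels = px,
      label = "good",
      poor_subtype = "none",
      abnormality_kind = NA_character_,
      provenance = list(
        scene = params,
        degradations = list(),
        coverage = numeric(0),
        contrast_after = numeric(0),
        masks = masks
      )
    ),
    class = "fundus_image"
  )
  img$provenance$base_contrast <- order3_contrast(img)
  img
}

#' Michelson contrast of order-3 vessel branches
#'
#' Measures the green-channel Michelson contrast `(bg - vessel)/(bg + vessel)`
#' of third-order vessel branch pixels against a local background ring
#' (dilation of the order-3 mask, excluding all vessels and the optic disc).
#' This operationalizes the clinical "level III vascular arches are visible"
#' criterion; the package's visibility threshold is 0.02.
#'
#' @param img A `fundus_image` carrying generator masks in its provenance.
#' @return A single non-negative number; 0 when the measurement is degenerate.
#' @export
order3_contrast <- function(img) {
  m <- img$provenance$masks
  if (is.null(m) || length(m$vessels) < 3) return(0)
  green <- img$pixels[, , 2]
  keep <- m$fov & !dilate_mask(m$disc, 2)
  v3 <- m$vessels[[3]] & keep
  ring <- dilate_mask(m$vessels[[3]], 5) & !dilate_mask(m$vessel_all, 1) & keep
  if (!any(v3) || !any(ring)) return(0)
  mv <- mean(green[v3])
  mb <- mean(green[ring])
  if (mb + mv <= 0) return(0)
  max(0, (mb - mv) / (mb + mv))
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image> %dx%d  label=%s", d[1], d[2], x$label))
  if (x$poor_subtype != "none") cat(sprintf("  subtype=%s", x$poor_subtype))
  if (!is.na(x$abnormality_kind)) cat(sprintf(" (%s)", x$abnormality_kind))
  nd <- length(x$provenance$degradations)
  cat(sprintf("  degradations=%d\n", nd))
  invisible(x)
}
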
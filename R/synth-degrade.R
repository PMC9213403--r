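.artefact_kinds <- c("blur", "underexposure")
.abnormality_kinds <- c("cataract", "crvo", "asteroid_hyalosis", "vitreous_opacity")

#' Construct a degradation
#'
#' A degradation is one quality-destroying transform applied to a synthetic
#' fundus image. Artefact kinds model acquisition failures (`blur`,
#' `underexposure`); abnormality kinds model ocular pathology (`cataract`,
#' `crvo`, `asteroid_hyalosis`, `vitreous_opacity`). `severity = 0` is the
#' identity transform. For occluding kinds the rendered occlusion mask is
#' calibrated to `coverage_target` (fraction of the field-of-view area).
#'
#' @param kind One of blur, underexposure, cataract, crvo, asteroid_hyalosis,
#'   vitreous_opacity.
#' @param severity Dimensionless strength in \[0, 1\].
#' @param coverage_target Target fraction of FOV area for the rendered
#'   occlusion/shadow region, in \[0, 1\] (ignored by `blur`).
#' @param rng_seed Integer seed for the degradation's own randomness
#'   (particle/patch placement).
#' @return An object of class `degradation`.
#' @export
degradation <- function(kind, severity, coverage_target = 0, rng_seed = 1L) {
  kinds <- c(.artefact_kinds, .abnormality_kinds)
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds) {
    stop_param("kind", paste("must be one of", paste(kinds, collapse = ", ")))
  }
  if (!is.numeric(severity) || length(severity) != 1 ||
      is.na(severity) || severity < 0 || severity > 1) {
    stop_param("severity", "must lie in [0, 1]")
  }
  if (!is.numeric(coverage_target) || coverage_target < 0 || coverage_target > 1) {
    stop_param("coverage_target", "must lie in [0, 1]")
  }
  structure(
    list(
      kind = kind,
      family = if (kind %in% .artefact_kinds) "artefact" else "abnormality",
      severity = as.numeric(severity),
      coverage_target = as.numeric(coverage_target),
      rng_seed = as.integer(rng_seed)
    ),
    class = "degradation"
  )
}

# soft radial blob mask centered at `center`; area of (mask > 0.5) within the
# FOV equals `coverage` exactly (radius set by the empirical quantile)
.soft_blob <- function(h, w, center, coverage, fov, edge) {
  d <- dist_field(h, w, center)
  if (coverage <= 0) return(matrix(0, h, w))
  r0 <- stats::quantile(d[fov], probs = min(coverage, 1), names = FALSE)
  stats::plogis((r0 - d) / edge)
}

# soft half-plane shadow; area of (mask > 0.5) within FOV == coverage
.soft_shadow <- function(h, w, angle, coverage, fov, edge) {
  if (coverage <= 0) return(matrix(0, h, w))
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- rr * sin(angle) + cc * cos(angle)
  q <- stats::quantile(d[fov], probs = min(coverage, 1), names = FALSE)
  stats::plogis((q - d) / edge)
}

# alpha-composite col over px where alpha field a in [0,1]
.blend <- function(px, a, col) {
  for (ch in 1:3) px[, , ch] <- px[, , ch] * (1 - a) + col[ch] * a
  px
}

.apply_blur <- function(px, masks, d) {
  n <- dim(px)[1]
  sigma <- d$severity * 0.03 * n
  if (sigma > 0.3) {
    for (ch in 1:3) px[, , ch] <- EBImage::gblur(px[, , ch], sigma = sigma)
  }
  list(pixels = clamp8(px), coverage = 0)
}

.apply_underexposure <- function(px, masks, d) {
  n <- dim(px)[1]
  fov <- masks$fov
  m <- if (d$coverage_target > 0) {
    ang <- with_seed(derive_seed(d$rng_seed, 1L), stats::runif(1, 0, 2 * pi))
    .soft_shadow(n, n, ang, d$coverage_target, fov, edge = 0.03 * n)
  } else matrix(0, n, n)
  fac <- (1 - d$severity) * (1 - 0.8 * d$severity * m)
  for (ch in 1:3) px[, , ch] <- px[, , ch] * fac
  # a region counts as covered once it is driven to near-black
  cov <- sum(fac[fov] < 0.15) / sum(fov)
  list(pixels = clamp8(px), coverage = cov)
}

.apply_cataract <- function(px, masks, d) {
  n <- dim(px)[1]
  fov <- masks$fov
  ctr <- masks$fov_center
  m <- if (d$coverage_target > 0) {
    off <- with_seed(derive_seed(d$rng_seed, 2L),
                     stats::runif(2, -0.3, 0.3) * masks$fov_radius)
    .soft_blob(n, n, ctr + off, d$coverage_target, fov, edge = 0.02 * n)
  } else matrix(1, n, n)
  # veiling luminance plus global contrast loss; opacity grows with severity
  cr <- 0.75 * d$severity * (0.25 + 0.75 * m)
  veil <- c(228, 218, 200)
  for (ch in 1:3) px[, , ch] <- px[, , ch] * (1 - cr) + veil[ch] * cr
  # the veiled region counts as covered once its peak opacity is substantial
  cov <- if (0.75 * d$severity >= 0.35 && d$coverage_target > 0) {
    sum(m[fov] > 0.5) / sum(fov)
  } else 0
  list(pixels = clamp8(px), coverage = cov)
}

# add soft elliptic blobs until the cumulative hard mask reaches the target
.accumulate_blobs <- function(px, masks, d, draw_one, stop_slack = 0.02) {
  n <- dim(px)[1]
  fov <- masks$fov
  fov_area <- sum(fov)
  occ <- matrix(FALSE, n, n)
  target <- d$coverage_target
  out <- with_seed(derive_seed(d$rng_seed, 3L), {
    it <- 0L
    while (target > 0 && sum(occ & fov) / fov_area < target - stop_slack &&
           it < 4000L) {
      it <- it + 1L
      res <- draw_one(px, occ)
      px <- res$px
      occ <- res$occ
    }
    list(px = px, occ = occ)
  })
  list(pixels = clamp8(out$px),
       coverage = sum(out$occ & fov) / fov_area,
       occ = out$occ)
}

.apply_crvo <- function(px, masks, d) {
  n <- dim(px)[1]
  fov_r <- masks$fov_radius
  # engorged, widened vessels darken along the whole tree
  wid <- dilate_mask(masks$vessel_all, 1 + round(2 * d$severity))
  dark <- 1 - 0.35 * d$severity
  px[, , 1][wid] <- px[, , 1][wid] * (1 - 0.15 * d$severity)
  px[, , 2][wid] <- px[, , 2][wid] * dark
  px[, , 3][wid] <- px[, , 3][wid] * dark
  # candidate centers: centerline points of the whole tree, jittered so the
  # haemorrhage field spreads beyond the vessels themselves
  pts <- do.call(rbind, unlist(masks$centerlines, recursive = FALSE))
  col <- c(70, 12, 12)
  it_count <- 0L
  draw_one <- function(px, occ) {
    it_count <<- it_count + 1L
    jit <- 0.03 * fov_r * (1 + it_count / 150)
    p <- pts[sample.int(nrow(pts), 1L), ] + stats::runif(2, -jit, jit)
    a <- stats::runif(1, 0.05, 0.10) * fov_r * (1 + it_count / 300)
    b <- a / 3
    th <- stats::runif(1, 0, pi)
    rr0 <- max(1, floor(p[1] - a - 2)); rr1 <- min(n, ceiling(p[1] + a + 2))
    cc0 <- max(1, floor(p[2] - a - 2)); cc1 <- min(n, ceiling(p[2] + a + 2))
    if (rr0 > rr1 || cc0 > cc1) return(list(px = px, occ = occ))
    rr <- matrix(rr0:rr1, rr1 - rr0 + 1, cc1 - cc0 + 1)
    cc <- matrix(cc0:cc1, rr1 - rr0 + 1, cc1 - cc0 + 1, byrow = TRUE)
    u <- (rr - p[1]) * cos(th) + (cc - p[2]) * sin(th)
    v <- -(rr - p[1]) * sin(th) + (cc - p[2]) * cos(th)
    q <- (u / a)^2 + (v / b)^2
    alpha <- 0.9 * stats::plogis((1 - q) * 6)
    for (ch in 1:3) {
      px[rr0:rr1, cc0:cc1, ch] <- px[rr0:rr1, cc0:cc1, ch] * (1 - alpha) +
        col[ch] * alpha
    }
    occ[rr0:rr1, cc0:cc1] <- occ[rr0:rr1, cc0:cc1] | (alpha > 0.5)
    list(px = px, occ = occ)
  }
  .accumulate_blobs(px, masks, d, draw_one, stop_slack = 0.01)[c("pixels", "coverage")]
}

.apply_asteroid <- function(px, masks, d) {
  n <- dim(px)[1]
  ctr <- masks$fov_center
  fov_r <- masks$fov_radius
  col <- c(252, 250, 235)
  draw_one <- function(px, occ) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * 0.95 * fov_r
    p <- ctr + rad * c(sin(ang), cos(ang))
    r <- stats::runif(1, 0.008, 0.022) * n
    rr0 <- max(1, floor(p[1] - r - 2)); rr1 <- min(n, ceiling(p[1] + r + 2))
    cc0 <- max(1, floor(p[2] - r - 2)); cc1 <- min(n, ceiling(p[2] + r + 2))
    if (rr0 > rr1 || cc0 > cc1) return(list(px = px, occ = occ))
    rr <- matrix(rr0:rr1, rr1 - rr0 + 1, cc1 - cc0 + 1)
    cc <- matrix(cc0:cc1, rr1 - rr0 + 1, cc1 - cc0 + 1, byrow = TRUE)
    dd <- sqrt((rr - p[1])^2 + (cc - p[2])^2)
    alpha <- 0.95 * pmin(pmax((r - dd + 0.8) / 1.2, 0), 1)
    for (ch in 1:3) {
      px[rr0:rr1, cc0:cc1, ch] <- px[rr0:rr1, cc0:cc1, ch] * (1 - alpha) +
        col[ch] * alpha
    }
    occ[rr0:rr1, cc0:cc1] <- occ[rr0:rr1, cc0:cc1] | (alpha > 0.5)
    list(px = px, occ = occ)
  }
  .accumulate_blobs(px, masks, d, draw_one, stop_slack = 0.005)[c("pixels", "coverage")]
}

.apply_vitreous <- function(px, masks, d) {
  n <- dim(px)[1]
  ctr <- masks$fov_center
  fov_r <- masks$fov_radius
  col <- c(45, 28, 18)
  peak <- 0.45 + 0.4 * d$severity
  acc <- matrix(0, n, n)  # cumulative opacity for the occlusion criterion
  draw_one <- function(px, occ) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * 0.85 * fov_r
    p <- ctr + rad * c(sin(ang), cos(ang))
    r <- stats::runif(1, 0.05, 0.10) * fov_r
    rr0 <- max(1, floor(p[1] - 2 * r)); rr1 <- min(n, ceiling(p[1] + 2 * r))
    cc0 <- max(1, floor(p[2] - 2 * r)); cc1 <- min(n, ceiling(p[2] + 2 * r))
    if (rr0 > rr1 || cc0 > cc1) return(list(px = px, occ = occ))
    rr <- matrix(rr0:rr1, rr1 - rr0 + 1, cc1 - cc0 + 1)
    cc <- matrix(cc0:cc1, rr1 - rr0 + 1, cc1 - cc0 + 1, byrow = TRUE)
    dd2 <- ((rr - p[1])^2 + (cc - p[2])^2) / r^2
    alpha <- peak * exp(-2 * dd2)
    for (ch in 1:3) {
      px[rr0:rr1, cc0:cc1, ch] <- px[rr0:rr1, cc0:cc1, ch] * (1 - alpha) +
        col[ch] * alpha
    }
    a0 <- acc[rr0:rr1, cc0:cc1]
    acc[rr0:rr1, cc0:cc1] <<- 1 - (1 - a0) * (1 - alpha)
    occ[rr0:rr1, cc0:cc1] <- acc[rr0:rr1, cc0:cc1] >= 0.4
    list(px = px, occ = occ)
  }
  .accumulate_blobs(px, masks, d, draw_one, stop_slack = 0.02)[c("pixels", "coverage")]
}

.degrade_once <- function(px, masks, d) {
  switch(d$kind,
    blur = .apply_blur(px, masks, d),
    underexposure = .apply_underexposure(px, masks, d),
    cataract = .apply_cataract(px, masks, d),
    crvo = .apply_crvo(px, masks, d),
    asteroid_hyalosis = .apply_asteroid(px, masks, d),
    vitreous_opacity = .apply_vitreous(px, masks, d)
  )
}

# quality rule shared by apply_degradation() and label_from_provenance():
# poor iff any degradation's rendered coverage exceeds 1/4 of the FOV, or the
# order-3 vessel contrast first fell below the visibility threshold at some
# step; subtype = family of the triggering degradation, ties -> eye_abnormality
.assess_quality <- function(degradations, coverage, contrast_after,
                            coverage_threshold = 0.25,
                            contrast_threshold = 0.02) {
  if (length(degradations) == 0) {
    return(list(label = "good", poor_subtype = "none",
                abnormality_kind = NA_character_))
  }
  fams <- vapply(degradations, function(d) d$family, character(1))
  kinds <- vapply(degradations, function(d) d$kind, character(1))
  trig <- coverage > coverage_threshold
  below <- which(contrast_after < contrast_threshold)
  if (length(below) > 0) trig[below[1]] <- TRUE
  if (!any(trig)) {
    return(list(label = "good", poor_subtype = "none",
                abnormality_kind = NA_character_))
  }
  tf <- fams[trig]
  if ("abnormality" %in% tf) {
    kind <- kinds[trig & fams == "abnormality"][1]
    list(label = "poor", poor_subtype = "eye_abnormality",
         abnormality_kind = kind)
  } else {
    list(label = "poor", poor_subtype = "artefact",
         abnormality_kind = NA_character_)
  }
}

#' Apply a degradation to a synthetic fundus image
#'
#' Applies one [degradation()] to a `fundus_image`, records it (with its
#' rendered coverage and the post-step order-3 vessel contrast) in the image's
#' provenance, and updates the quality label by the package's labelling rule:
#' an image is poor when any degradation's rendered region covers more than
#' 1/4 of the field of view, or when the Michelson contrast of order-3 vessel
#' branches falls below 0.02 (level-III arches invisible). When degradations
#' of both families trigger the rule, the subtype is `eye_abnormality`
#' (missing a referable abnormality is the costlier error).
#'
#' `severity = 0` returns a pixel-identical image (identity transform).
#' Degradations compose; they are applied in list order and all entries are
#' kept in provenance.
#'
#' @param img A `fundus_image` from [render_fundus()] (possibly already
#'   degraded).
#' @param d A [degradation()].
#' @return The degraded `fundus_image` with updated label and provenance.
#' @export
apply_degradation <- function(img, d) {
  if (!inherits(img, "fundus_image")) stop_param("img", "must be a fundus_image")
  if (!inherits(d, "degradation")) {
    d <- do.call(degradation, d[intersect(names(d), names(formals(degradation)))])
  }
  masks <- img$provenance$masks
  if (d$severity == 0) {
    res <- list(pixels = img$pixels, coverage = 0)
  } else {
    res <- .degrade_once(img$pixels, masks, d)
  }
  img$pixels <- res$pixels
  img$provenance$degradations <- c(img$provenance$degradations, list(d))
  img$provenance$coverage <- c(img$provenance$coverage, res$coverage)
  img$provenance$contrast_after <- c(img$provenance$contrast_after,
                                     order3_contrast(img))
  lab <- .assess_quality(img$provenance$degradations,
                         img$provenance$coverage,
                         img$provenance$contrast_after)
  img$label <- lab$label
  img$poor_subtype <- lab$poor_subtype
  img$abnormality_kind <- lab$abnormality_kind
  img
}

#' Derive the quality label implied by a degradation history
#'
#' Re-renders the scene, re-applies the degradation list in order, and returns
#' the label the rule assigns. This is a pure function of its arguments; for
#' any image produced by [render_fundus()] + [apply_degradation()] it
#' reproduces the stored label exactly.
#'
#' @param degradations A list of [degradation()] objects (possibly empty).
#' @param scene A [scene_params()] object.
#' @return A list with `label`, `poor_subtype` and `abnormality_kind`.
#' @export
label_from_provenance <- function(degradations, scene) {
  if (length(degradations) == 0) {
    return(list(label = "good", poor_subtype = "none",
                abnormality_kind = NA_character_))
  }
  img <- render_fundus(scene)
  for (d in degradations) img <- apply_degradation(img, d)
  list(label = img$label, poor_subtype = img$poor_subtype,
       abnormality_kind = img$abnormality_kind)
}
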
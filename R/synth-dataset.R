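#' Specification for a synthetic fundus dataset
#'
#' Defines the class composition and degradation severity ranges of a
#' generated dataset. Defaults give each class a realistic spread around the
#' labelling thresholds: the good class mixes pristine images with mildly
#' degraded ones that stay below the poor-quality rule, while the two poor
#' classes draw severities and coverages wide enough to cross it.
#'
#' @param n_good,n_artefact,n_eye_abnormality Per-class image counts (>= 0).
#' @param image_size Side length in pixels of each generated image.
#' @param good_degraded_fraction Fraction of good-class images that carry one
#'   mild (sub-threshold) degradation.
#' @param good_severity,artefact_severity,abnormality_severity Length-2
#'   numeric ranges for uniform severity sampling.
#' @param good_coverage,abnormality_coverage,artefact_coverage Length-2 ranges
#'   for uniform coverage-target sampling (artefact coverage applies to
#'   underexposure shadows).
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_good = 150,
                         n_artefact = 150,
                         n_eye_abnormality = 150,
                         image_size = 256,
                         good_degraded_fraction = 0.5,
                         good_severity = c(0.05, 0.35),
                         good_coverage = c(0.03, 0.18),
                         artefact_severity = c(0.30, 0.95),
                         artefact_coverage = c(0.30, 0.60),
                         abnormality_severity = c(0.30, 0.90),
                         abnormality_coverage = c(0.18, 0.45)) {
  for (nm in c("n_good", "n_artefact", "n_eye_abnormality")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      stop_param(nm, "must be a single count >= 0")
    }
  }
  structure(
    list(
      n_good = as.integer(n_good),
      n_artefact = as.integer(n_artefact),
      n_eye_abnormality = as.integer(n_eye_abnormality),
      image_size = as.integer(image_size),
      good_degraded_fraction = good_degraded_fraction,
      good_severity = good_severity,
      good_coverage = good_coverage,
      artefact_severity = artefact_severity,
      artefact_coverage = artefact_coverage,
      abnormality_severity = abnormality_severity,
      abnormality_coverage = abnormality_coverage
    ),
    class = "dataset_spec"
  )
}

# draw one candidate image for a target class; returns a fundus_image
.sample_candidate <- function(class, spec, kind, seed) {
  sc <- scene_params(
    image_size = spec$image_size,
    vessel_contrast = with_seed(derive_seed(seed, 21L), stats::runif(1, 0.4, 0.7)),
    rng_seed = seed
  )
  img <- render_fundus(sc)
  rng <- function(k, lo, hi) {
    with_seed(derive_seed(seed, k), stats::runif(1, lo, hi))
  }
  if (class == "good") {
    if (rng(22L, 0, 1) >= spec$good_degraded_fraction) return(img)
    sev <- rng(23L, spec$good_severity[1], spec$good_severity[2])
    cov <- rng(24L, spec$good_coverage[1], spec$good_coverage[2])
    d <- degradation(kind, sev, coverage_target = cov,
                     rng_seed = derive_seed(seed, 25L))
    return(apply_degradation(img, d))
  }
  if (class == "artefact") {
    sev <- rng(26L, spec$artefact_severity[1], spec$artefact_severity[2])
    cov <- if (kind == "underexposure") {
      rng(27L, spec$artefact_coverage[1], spec$artefact_coverage[2])
    } else 0
    d <- degradation(kind, sev, coverage_target = cov,
                     rng_seed = derive_seed(seed, 28L))
    return(apply_degradation(img, d))
  }
  sev <- rng(29L, spec$abnormality_severity[1], spec$abnormality_severity[2])
  cov <- rng(30L, spec$abnormality_coverage[1], spec$abnormality_coverage[2])
  d <- degradation(kind, sev, coverage_target = cov,
                   rng_seed = derive_seed(seed, 31L))
  apply_degradation(img, d)
}

.class_ok <- function(img, class) {
  switch(class,
    good = img$label == "good",
    artefact = img$label == "poor" && img$poor_subtype == "artefact",
    eye_abnormality = img$label == "poor" && img$poor_subtype == "eye_abnormality"
  )
}

#' Generate a labelled synthetic fundus dataset
#'
#' Renders `n_good + n_artefact + n_eye_abnormality` images, writes them as
#' 8-bit RGB PNGs under `out_dir`, and returns (and writes) a manifest.
#' Class counts match the spec exactly: candidate severities are drawn
#' uniformly from the spec's ranges and a candidate is re-drawn (with a new
#' derived seed) if the labelling rule assigns it a different class, so the
#' realized datasets contain borderline images on both sides of the
#' quality thresholds. Fully reproducible from `rng_seed`.
#'
#' Degradation kinds rotate deterministically within each class (artefacts:
#' blur, underexposure; abnormalities: cataract, crvo, asteroid_hyalosis,
#' vitreous_opacity), emulating a mixed clinical composition.
#'
#' @param spec A [dataset_spec()].
#' @param out_dir Output directory (created if missing).
#' @param rng_seed Integer master seed.
#' @param write_images Write PNGs (default TRUE). When FALSE only the manifest
#'   is produced (paths still filled in).
#' @return A tibble manifest with columns `path`, `label`, `poor_subtype`,
#'   `abnormality_kind`, `seed` and `degradation` (kind of the applied
#'   degradation, if any), also written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(spec, out_dir, rng_seed = 1L, write_images = TRUE) {
  if (!inherits(spec, "dataset_spec")) spec <- do.call(dataset_spec, spec)
  if (write_images && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
    }
  }
  plan <- list(
    good = spec$n_good,
    artefact = spec$n_artefact,
    eye_abnormality = spec$n_eye_abnormality
  )
  kind_cycle <- list(
    good = c(.artefact_kinds, .abnormality_kinds),
    artefact = .artefact_kinds,
    eye_abnormality = .abnormality_kinds
  )
  rows <- list()
  idx <- 0L
  for (class in names(plan)) {
    kinds <- kind_cycle[[class]]
    for (i in seq_len(plan[[class]])) {
      idx <- idx + 1L
      kind <- kinds[((i - 1L) %% length(kinds)) + 1L]
      base <- derive_seed(rng_seed, idx)
      img <- NULL
      for (attempt in 0:39) {
        cand_seed <- derive_seed(base, 1000L + attempt)
        cand <- .sample_candidate(class, spec, kind, cand_seed)
        if (.class_ok(cand, class)) { img <- cand; break }
      }
      if (is.null(img)) {
        stop(sprintf(
          "failed to realize class '%s' (kind %s) within 40 attempts", class, kind),
          call. = FALSE)
      }
      fname <- sprintf("img_%04d_%s.png", idx, class)
      path <- file.path(out_dir, fname)
      if (write_images) write_image(img, path)
      degr <- img$provenance$degradations
      rows[[idx]] <- tibble::tibble(
        path = path,
        label = img$label,
        poor_subtype = img$poor_subtype,
        abnormality_kind = img$abnormality_kind,
        seed = cand_seed,
        degradation = if (length(degr)) degr[[length(degr)]]$kind else NA_character_
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (write_images) {
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  manifest
}
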
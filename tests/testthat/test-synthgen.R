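test_that("rendering is a pure function of parameters and seed", {
  p <- scene_params(image_size = 128, rng_seed = 9)
  a <- render_fundus(p)
  b <- render_fundus(p)
  expect_identical(a$pixels, b$pixels)
  expect_equal(a$label, "good")
  # different seed moves the vessel tree
  c <- render_fundus(scene_params(image_size = 128, rng_seed = 10))
  expect_false(identical(a$pixels, c$pixels))
})

test_that("the field of view fills ~pi/4 of the square frame", {
  img <- render_fundus(scene_params(image_size = 256, rng_seed = 1))
  expect_lt(abs(mean(img$provenance$masks$fov) - pi / 4), 0.02)
})

test_that("zero vessel contrast renders invisible vessels", {
  p0 <- scene_params(image_size = 128, vessel_contrast = 0, rng_seed = 4)
  p5 <- scene_params(image_size = 128, vessel_contrast = 0.5, rng_seed = 4)
  i0 <- render_fundus(p0)
  i5 <- render_fundus(p5)
  vm <- i0$provenance$masks$vessel_all
  # identical geometry; darkening confined to the vessel mask
  expect_identical(i0$provenance$masks$vessel_all, i5$provenance$masks$vessel_all)
  out <- !vm
  expect_identical(i0$pixels[, , 2][out], i5$pixels[, , 2][out])
  expect_true(all(i0$pixels[, , 2][vm] >= i5$pixels[, , 2][vm]))
  # invisible vessels blend into the local background
  disc <- i0$provenance$masks$disc
  sel <- vm & !disc & i0$provenance$masks$fov
  ring <- i0$provenance$masks$fov & !vm & !disc
  expect_lt(abs(mean(i0$pixels[, , 2][sel]) - mean(i0$pixels[, , 2][ring])), 4)
  expect_equal(order3_contrast(i0), 0, tolerance = 5e-3)
})

test_that("invalid scene parameters raise errors naming the field", {
  expect_error(scene_params(image_size = 8), "image_size")
  expect_error(scene_params(vessel_orders = 2), "vessel_orders")
  expect_error(scene_params(disc_center = c(5, 5)), "disc_center")
  expect_error(scene_params(vessel_contrast = 2), "vessel_contrast")
  expect_error(degradation("fog", 0.5), "kind")
  expect_error(degradation("blur", 1.5), "severity")
})

test_that("severity zero is the pixel-exact identity for every kind", {
  img <- fixture_image(seed = 13, size = 128)
  for (k in c("blur", "underexposure", "cataract", "crvo",
              "asteroid_hyalosis", "vitreous_opacity")) {
    out <- apply_degradation(img, degradation(k, 0, coverage_target = 0.3))
    expect_identical(out$pixels, img$pixels)
    expect_equal(out$label, "good")
  }
})

test_that("full underexposure extinguishes the field of view", {
  img <- fixture_image(seed = 14, size = 128)
  out <- apply_degradation(img, degradation("underexposure", 1))
  expect_true(all(out$pixels[rep(img$provenance$masks$fov, 3)] == 0))
  expect_equal(out$label, "poor")
  expect_equal(out$poor_subtype, "artefact")
})

test_that("occluding kinds hit their coverage target within 0.05", {
  img <- render_fundus(scene_params(image_size = 256, rng_seed = 15))
  for (k in c("asteroid_hyalosis", "vitreous_opacity", "crvo")) {
    for (seed in 1:4) {
      target <- c(0.30, 0.20, 0.35, 0.30)[seed]
      out <- apply_degradation(img, degradation(k, 0.7, coverage_target = target,
                                                rng_seed = seed))
      cov <- utils::tail(out$provenance$coverage, 1)
      expect_lt(abs(cov - target), 0.05)
    }
  }
})

test_that("asteroid hyalosis at coverage 0.30 renders a mask fraction in [0.25, 0.35]", {
  img <- render_fundus(scene_params(image_size = 256, rng_seed = 16))
  out <- apply_degradation(img, degradation("asteroid_hyalosis", 0.8,
                                            coverage_target = 0.30, rng_seed = 2))
  cov <- utils::tail(out$provenance$coverage, 1)
  expect_gte(cov, 0.25)
  expect_lte(cov, 0.35)
})

test_that("order-3 vessel contrast is non-increasing in severity for global kinds", {
  img <- render_fundus(scene_params(image_size = 256, rng_seed = 17))
  for (k in c("blur", "underexposure", "cataract")) {
    contr <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1), function(s) {
      out <- apply_degradation(img, degradation(k, s, coverage_target = 0))
      utils::tail(out$provenance$contrast_after, 1)
    }, numeric(1))
    expect_true(all(diff(contr) <= 0.01),
                info = sprintf("%s: %s", k, paste(round(contr, 4), collapse = " ")))
  }
})

test_that("the labelling rule follows coverage and visibility thresholds", {
  img <- render_fundus(scene_params(image_size = 256, rng_seed = 18))
  # no degradation -> good
  expect_equal(label_from_provenance(list(), img$provenance$scene)$label, "good")
  # strong blur erases order-3 contrast -> poor, artefact
  hard_blur <- apply_degradation(img, degradation("blur", 0.9))
  expect_lt(utils::tail(hard_blur$provenance$contrast_after, 1), 0.02)
  expect_equal(hard_blur$poor_subtype, "artefact")
  # severe cataract covering 0.30 > 1/4 -> poor, eye_abnormality
  cat30 <- apply_degradation(img, degradation("cataract", 0.9, coverage_target = 0.30))
  expect_gt(utils::tail(cat30$provenance$coverage, 1), 0.25)
  expect_equal(cat30$poor_subtype, "eye_abnormality")
  expect_equal(cat30$abnormality_kind, "cataract")
  # mild kinds below both thresholds stay good
  mild <- apply_degradation(img, degradation("vitreous_opacity", 0.5,
                                             coverage_target = 0.10))
  expect_equal(mild$label, "good")
  # both families above threshold -> tie broken toward eye_abnormality
  both <- apply_degradation(hard_blur, degradation("cataract", 0.9,
                                                   coverage_target = 0.35))
  expect_equal(both$poor_subtype, "eye_abnormality")
})

test_that("stored labels equal the label recomputed from provenance", {
  for (seed in c(21, 22)) {
    img <- render_fundus(scene_params(image_size = 128, rng_seed = seed))
    img <- apply_degradation(img, degradation("blur", 0.6, rng_seed = seed))
    img <- apply_degradation(img, degradation("vitreous_opacity", 0.6,
                                              coverage_target = 0.2,
                                              rng_seed = seed))
    rec <- label_from_provenance(img$provenance$degradations,
                                 img$provenance$scene)
    expect_equal(rec$label, img$label)
    expect_equal(rec$poor_subtype, img$poor_subtype)
  }
})

test_that("generated datasets match requested class counts and reproduce exactly", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- dataset_spec(n_good = 6, n_artefact = 4, n_eye_abnormality = 4,
                       image_size = 128)
  m1 <- generate_dataset(spec, dir1, rng_seed = 5)
  expect_equal(sum(m1$label == "good"), 6)
  expect_equal(sum(m1$poor_subtype == "artefact"), 4)
  expect_equal(sum(m1$poor_subtype == "eye_abnormality"), 4)
  expect_equal(nrow(m1), 14)
  m2 <- generate_dataset(spec, dir2, rng_seed = 5)
  expect_identical(m1[c("label", "poor_subtype", "abnormality_kind", "seed")],
                   m2[c("label", "poor_subtype", "abnormality_kind", "seed")])
  h1 <- unname(tools::md5sum(m1$path))
  h2 <- unname(tools::md5sum(m2$path))
  expect_identical(h1, h2)
  # abnormality kind recorded iff subtype is eye_abnormality
  expect_true(all(!is.na(m1$abnormality_kind[m1$poor_subtype == "eye_abnormality"])))
  expect_true(all(is.na(m1$abnormality_kind[m1$poor_subtype != "eye_abnormality"])))
})
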
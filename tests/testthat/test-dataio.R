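test_that("PNG round trips are lossless and formats are normalized", {
  dir <- withr::local_tempdir()
  set.seed(31)
  px <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  p <- file.path(dir, "x.png")
  write_image(px, p)
  expect_identical(read_image(p), px + 0)

  # 1x1 white pixel
  p1 <- file.path(dir, "w.png")
  png::writePNG(array(1, c(1, 1, 3)), p1)
  expect_identical(read_image(p1), array(255, c(1, 1, 3)))

  # grayscale replicated across channels
  pg <- file.path(dir, "g.png")
  png::writePNG(matrix(0.5, 4, 4), pg)
  rg <- read_image(pg)
  expect_equal(dim(rg), c(4, 4, 3))
  expect_true(all(rg[, , 1] == rg[, , 2] & rg[, , 2] == rg[, , 3]))

  expect_error(read_image(file.path(dir, "missing.png")), "not found")
})

test_that("JPEG round trip at quality 95 stays within 3 gray levels on average", {
  skip_if_not_installed("jpeg")
  dir <- withr::local_tempdir()
  img <- fixture_image(seed = 32, size = 128)
  pj <- file.path(dir, "x.jpg")
  jpeg::writeJPEG(img$pixels / 255, pj, quality = 0.95)
  back <- read_image(pj)
  expect_lt(mean(abs(back - img$pixels)), 3)
})

test_that("TIFF files load through the same interface", {
  skip_if_not_installed("tiff")
  dir <- withr::local_tempdir()
  px <- array(runif(16 * 16 * 3), c(16, 16, 3))
  pt <- file.path(dir, "x.tif")
  tiff::writeTIFF(px, pt)
  back <- read_image(pt)
  expect_equal(dim(back), c(16, 16, 3))
  expect_lt(max(abs(back - px * 255)), 1)  # 8-bit quantization only
})

test_that("FOV estimation recovers the generator's analytic disc", {
  img <- render_fundus(scene_params(image_size = 256, rng_seed = 33))
  mask <- estimate_fov_mask(img)
  true_area <- pi * img$provenance$masks$fov_radius^2
  expect_lt(abs(sum(mask) - true_area) / true_area, 0.05)
  # one connected component
  lab <- EBImage::bwlabel(mask)
  expect_equal(max(lab), 1)
  # degenerate input
  expect_error(estimate_fov_mask(array(0, c(32, 32, 3))), "degenerate")
})

test_that("stratified 70/30 split reproduces the per-stratum floor counts", {
  manifest <- tibble::tibble(
    path = sprintf("img%05d.png", 1:2434),
    label = rep(c("good", "poor", "poor"), c(1439, 483, 512)),
    poor_subtype = rep(c("none", "eye_abnormality", "artefact"),
                       c(1439, 483, 512))
  )
  out <- stratified_split(manifest, 0.70, rng_seed = 3)
  tab <- table(out$label, out$poor_subtype, out$split)
  expect_equal(unname(tab["good", "none", "train"]), 1007)
  expect_equal(unname(tab["good", "none", "test"]), 432)
  expect_equal(unname(tab["poor", "eye_abnormality", "train"]), 338)
  expect_equal(unname(tab["poor", "artefact", "train"]), 358)
  expect_equal(sum(out$label == "poor" & out$split == "train"), 696)
  expect_equal(sum(out$label == "poor" & out$split == "test"), 299)
})

test_that("split is a partition, randomized within stratum, and validates input", {
  manifest <- tibble::tibble(
    path = sprintf("i%03d", 1:40),
    label = rep(c("good", "poor"), each = 20),
    poor_subtype = rep(c("none", "artefact"), each = 20)
  )
  a <- stratified_split(manifest, 0.5, rng_seed = 1)
  expect_true(all(a$split %in% c("train", "test")))
  expect_equal(sum(a$split == "train"), 20)
  b <- stratified_split(manifest, 0.5, rng_seed = 2)
  expect_false(identical(a$split, b$split))  # different seed, different draw
  expect_identical(a$split,
                   stratified_split(manifest, 0.5, rng_seed = 1)$split)

  m4 <- manifest[c(1:2, 21:22), ]
  s4 <- stratified_split(m4, 0.5, rng_seed = 1)
  expect_equal(unname(table(s4$split)["train"]), 2)

  expect_error(stratified_split(manifest, 1.0), "train_fraction")
  expect_error(stratified_split(manifest, 0), "train_fraction")
  bad <- manifest
  bad$label[1] <- "excellent"
  expect_error(stratified_split(bad), "label")
})

test_that("manifest round trip preserves records and enforces the vocabulary", {
  dir <- withr::local_tempdir()
  m <- tibble::tibble(
    path = c("a.png", "b.png"),
    label = c("good", "poor"),
    poor_subtype = c("none", "artefact"),
    abnormality_kind = c(NA_character_, NA_character_),
    seed = c(1L, 2L)
  )
  p <- file.path(dir, "m.csv")
  write_manifest(m, p)
  back <- read_manifest(p)
  expect_equal(back$path, m$path)
  expect_equal(back$label, m$label)
  dup <- m
  dup$path <- c("a.png", "a.png")
  write_manifest(dup, p)
  expect_error(read_manifest(p), "unique")
})
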
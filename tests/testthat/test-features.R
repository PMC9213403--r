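test_that("preprocess exposes the green channel and masked statistics", {
  # pure green image: masked grayscale is 255 everywhere
  px <- array(0, c(64, 64, 3))
  px[, , 2] <- 255
  mask <- matrix(TRUE, 64, 64)
  pp <- preprocess(px, fov = mask, side = 64)
  expect_true(all(pp$gray[pp$mask] == 255))

  # resize of an already-224^2 image leaves the raster unchanged
  px2 <- array(round(runif(224 * 224 * 3) * 255), c(224, 224, 3))
  pp2 <- preprocess(px2, fov = matrix(TRUE, 224, 224), side = 224)
  expect_identical(pp2$rgb_raw, px2)

  # half-black / half-white field of view averages to the midpoint
  px3 <- array(0, c(64, 64, 3))
  px3[, 33:64, ] <- 255
  mask3 <- matrix(FALSE, 64, 64)
  mask3[, 17:48] <- TRUE  # equal halves of each region
  pp3 <- preprocess(px3, fov = mask3, side = 64)
  expect_equal(mean(pp3$gray[pp3$mask]), 127.5, tolerance = 0.5)

  expect_error(preprocess(px, fov = matrix(TRUE, 32, 32)), "disagree")
})

test_that("softmax embedding behaves like a probability vector", {
  img <- fixture_image(seed = 41, size = 128)
  pp <- preprocess(img, side = 128)
  v1 <- deep_features(pp$rgb, n_out = 500)
  expect_equal(sum(v1), 1, tolerance = 1e-6)
  expect_true(all(v1 >= 0))
  v2 <- deep_features(pp$rgb, n_out = 500)
  expect_identical(v1, v2)

  dark <- apply_degradation(img, degradation("underexposure", 1))
  vd <- deep_features(preprocess(dark, side = 128)$rgb, n_out = 500)
  expect_gt(sum(abs(v1 - vd)), 0)

  expect_error(deep_features(pp$rgb, backbone = "resnet50"), "not available")
})

test_that("extract_features concatenates blocks in a fixed documented order", {
  img <- fixture_image(seed = 42, size = 128)
  cfg <- feature_config(deep = FALSE, side = 128)
  fv <- extract_features(img, cfg)
  expect_false(any(grepl("^deep_", names(fv))))
  expect_true(all(is.finite(fv)))
  # block order: texture -> fractal -> spectral
  blocks <- c(glcm = min(grep("^(glcm|fo)_", names(fv))),
              fractal = min(grep("^fd_", names(fv))),
              spectral = min(grep("^bis_", names(fv))))
  expect_true(all(diff(blocks) > 0))

  cfg_deep <- feature_config(deep = TRUE, side = 128)
  fv2 <- extract_features(img, cfg_deep)
  expect_equal(sum(grepl("^deep_", names(fv2))), 1000)
  expect_equal(which(grepl("^deep_", names(fv2))[1]), 1)

  cfg_min <- feature_config(glcm = TRUE, fractal = FALSE, spectral = FALSE,
                            side = 128)
  expect_false(any(grepl("^(fd|bis)_", names(extract_features(img, cfg_min)))))
})

test_that("batch extraction rows align with the manifest and are finite", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(
    dataset_spec(n_good = 3, n_artefact = 2, n_eye_abnormality = 2,
                 image_size = 128),
    out_dir = dir, rng_seed = 77)
  feats <- extract_features_batch(m, feature_config(side = 128))
  expect_identical(feats$path, m$path)
  expect_true(all(vapply(feats[, -1], function(x) all(is.finite(x)), logical(1))))
})
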
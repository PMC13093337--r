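test_that("preprocess_image normalizes, masks and is affine-invariant", {
  set.seed(1)
  img <- matrix(0.2, 64, 64)
  img[30:34, 30:34] <- 1
  pre <- preprocess_image(img)
  expect_gte(min(pre$pixels), 0)
  expect_lte(max(pre$pixels), 1)
  expect_equal(pre$pixels[5, 5], 0)  # uniform background removed

  noisy <- matrix(runif(64 * 64), 64, 64)
  p1 <- preprocess_image(noisy)
  p2 <- preprocess_image(3.7 * noisy + 11)
  expect_equal(p1$pixels, p2$pixels, tolerance = 1e-12)

  expect_error(preprocess_image(matrix(5, 10, 10)), "degenerate")
})

test_that("crofton_perimeter matches analytic oracles", {
  expect_gte(crofton_perimeter(matrix(c(3, 3), 1, 2)), 2)
  expect_lte(crofton_perimeter(matrix(c(3, 3), 1, 2)), 4)
  expect_equal(crofton_perimeter(disk_pixels(20)), 2 * pi * 20,
               tolerance = 0.05)
  expect_equal(crofton_perimeter(rect_pixels(10, 10)), 40, tolerance = 0.1)
  # scaling to physical units
  expect_equal(crofton_perimeter(disk_pixels(20), pixel_size = 0.863),
               2 * pi * 20 * 0.863, tolerance = 0.05 * 2 * pi * 20)
  expect_error(crofton_perimeter(matrix(numeric(0), 0, 2)), "empty")
})

test_that("nucleus_features implements the eight-feature equations", {
  ps <- 0.863
  img <- histology_image(matrix(0.5, 50, 50), pixel_size = ps)
  # single pixel: A = n * a exactly
  f1 <- nucleus_features(img, matrix(c(10, 10), 1, 2), c(10, 10), 1)
  expect_equal(f1$A, 0.744769, tolerance = 1e-6)
  expect_equal(f1$r_I, sqrt(f1$A / pi))
  expect_equal(f1$I_W, 0.5)  # single-pixel fallback

  # uniform disk: eps near 1, I_W equals the constant intensity
  px <- disk_pixels(20, center = c(25, 25))
  fd <- nucleus_features(img, px, c(25, 25), 3)
  expect_gte(fd$eps, 0.95)
  expect_lte(fd$eps, 1.10)
  expect_equal(fd$I_W, 0.5, tolerance = 1e-12)
  expect_equal(fd$I_T, fd$A * fd$I_M, tolerance = 1e-12)
  expect_equal(fd$r_I, sqrt(fd$A / pi), tolerance = 1e-12)
  expect_equal(fd$A, nrow(px) * ps^2)
  expect_error(nucleus_features(img, matrix(numeric(0), 0, 2), c(1, 1), 1),
               "empty")
})

test_that("feature equations hold to machine precision on detections", {
  cfg <- sim_config(seed = 11, n_nuclei = 30, min_separation = 10)
  g <- gen_nuclei_image(cfg)
  pre <- preprocess_image(g$image)
  det <- detect_nuclei(pre)
  feats <- nucleus_feature_table(pre, det)
  expect_equal(feats$I_T, feats$A * feats$I_M, tolerance = 1e-12)
  expect_equal(feats$r_I, sqrt(feats$A / pi), tolerance = 1e-12)
})

test_that("detection handles blank images and splits touching blobs", {
  blank <- histology_image(matrix(0, 64, 64))
  expect_equal(nrow(detect_nuclei(blank)), 0)

  # two sigma = 2 blobs 6 px apart: watershed yields 2 disjoint territories
  img <- matrix(0, 64, 64)
  rr <- 1:64
  for (ctr in list(c(32, 30), c(32, 36)))
    img <- img + 0.6 * exp(-outer((rr - ctr[1])^2, (rr - ctr[2])^2, "+") /
                             (2 * 2^2))
  det <- detect_nuclei(preprocess_image(img))
  expect_equal(nrow(det), 2)
  members <- attr(det, "members")
  both <- rbind(members[[1]], members[[2]])
  expect_equal(nrow(unique(both)), nrow(both))  # pairwise disjoint
  expect_true(all(abs(det$row - 32) <= 2))
})

test_that("member pixels partition the above-threshold foreground", {
  cfg <- sim_config(seed = 12, n_nuclei = 40, min_separation = 9)
  g <- gen_nuclei_image(cfg)
  pre <- preprocess_image(g$image)
  det <- detect_nuclei(pre)
  members <- attr(det, "members")
  all_px <- do.call(rbind, members)
  expect_equal(nrow(unique(all_px)), nrow(all_px))
  expect_lte(nrow(all_px), sum(pre$pixels > 0) + nrow(det))
})

test_that("features are invariant to positive intensity rescaling", {
  cfg <- sim_config(seed = 13, n_nuclei = 25, min_separation = 10)
  g <- gen_nuclei_image(cfg)
  pre1 <- preprocess_image(g$image)
  scaled <- g$image
  scaled$pixels <- scaled$pixels * 7.3
  pre2 <- preprocess_image(scaled)
  d1 <- detect_nuclei(pre1)
  d2 <- detect_nuclei(pre2)
  expect_equal(nrow(d1), nrow(d2))
  f1 <- nucleus_feature_table(pre1, d1)
  f2 <- nucleus_feature_table(pre2, d2)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("sigma bounds honour the micrometre interpretation", {
  img <- matrix(0, 64, 64)
  rr <- 1:64
  img <- img + exp(-outer((rr - 32)^2, (rr - 32)^2, "+") / (2 * 2^2))
  pre <- preprocess_image(img)
  d_px <- detect_nuclei(pre)
  d_um <- detect_nuclei(pre, sigma_units = "um")
  expect_equal(nrow(d_px), 1)
  expect_equal(nrow(d_um), 1)
  # um mode divides the bounds by the pixel size, widening the scale range
  expect_false(isTRUE(all.equal(d_px$sigma, d_um$sigma)))
})

test_that("pyknosis training follows the 1:3 subsample and 80:20 split", {
  feats <- synthetic_feature_table(500, d = 2, seed = 3)
  # 100 pyknotic + 1000 non-pyknotic input: pool must be 100 + 300
  sub <- rbind(feats[feats$label, ][1:100, ], feats[!feats$label, ][1:500, ])
  model <- train_pyknosis_model(sub, seed = 1)
  expect_equal(model$manifest$n_pyknotic, 100)
  expect_equal(model$manifest$n_nonpyknotic_subsampled, 300)
  expect_equal(model$manifest$cv_folds, 5)
  expect_equal(nrow(model$cv_metrics), 5)
  # fewer non-pyknotic than 3x: all available used
  sub2 <- rbind(feats[feats$label, ][1:100, ],
                feats[!feats$label, ][1:150, ])
  m2 <- train_pyknosis_model(sub2, seed = 1)
  expect_equal(m2$manifest$n_nonpyknotic_subsampled, 150)
  expect_error(train_pyknosis_model(feats[feats$label, ]), "both classes")
})

test_that("classifier separates classes and is honest under permutation", {
  feats <- synthetic_feature_table(200, d = 2, seed = 5)
  model <- train_pyknosis_model(feats, seed = 2)
  expect_gte(model$holdout$auroc, 0.95)
  p <- predict(model, feats)
  expect_gte(auroc(p$prob_pyknotic, feats$label), 0.95)
})

test_that("classify_and_count reports per-image totals and fractions", {
  train <- generator_training_features(seeds = c(31, 32))
  model <- train_pyknosis_model(train, seed = 7)
  cfg <- sim_config(seed = 33, n_nuclei = 50, pyknotic_fraction = 0.2,
                    min_separation = 10)
  g <- gen_nuclei_image(cfg)
  rep1 <- classify_and_count(model, list(g$image))
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$fraction, 0.2, tolerance = 0.05)
  expect_equal(rep1$log_fraction,
               log(rep1$fraction + 0.5 / rep1$total))
  # determinism on identical images, and the empty-image flag
  rep2 <- classify_and_count(model, list(g$image, g$image))
  expect_equal(rep2$pyknotic[1], rep2$pyknotic[2])
  blank <- histology_image(matrix(0, 32, 32))
  rep0 <- classify_and_count(model, list(blank))
  expect_true(rep0$flagged)
  expect_equal(rep0$total, 0)
  expect_true(is.na(rep0$fraction))
})
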
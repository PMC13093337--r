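test_that("segment_cells applies size, hole and border rules", {
  expect_equal(length(segment_cells(matrix(0, 32, 32))), 0)

  img <- matrix(0, 32, 32)
  img[10:14, 10:14] <- 1          # 25 px: retained
  img[20:23, 20:25] <- 1          # 24 px: removed
  img[20:23, 20] <- 0
  masks <- segment_cells(img)
  expect_equal(length(masks), 1)
  expect_equal(nrow(masks[[1]]$pixels), 25)

  img2 <- matrix(0, 32, 32)
  img2[1:10, 5:12] <- 1           # touches row 1: removed
  expect_equal(length(segment_cells(img2)), 0)

  # holes are filled
  img3 <- matrix(0, 32, 32)
  img3[5:15, 5:15] <- 1
  img3[9:11, 9:11] <- 0
  m3 <- segment_cells(img3)
  expect_equal(nrow(m3[[1]]$pixels), 11 * 11)
})

test_that("segmentation is idempotent on binary masks", {
  mg <- gen_microglia_images(sim_config(seed = 8, shape_families = c(
    rod = 2L, intermediate1 = 2L, ramified = 2L, intermediate2 = 2L,
    ameboid = 2L)))
  for (m in mg$cells[c(1, 5, 9)]) {
    s1 <- segment_cells(m)
    expect_equal(length(s1), 1)
    again <- segment_cells(mask_from_pixels(s1[[1]]$pixels, s1[[1]]$dim))
    expect_equal(again[[1]]$pixels, s1[[1]]$pixels)
  }
})

test_that("split_quadrants tiles exactly and pads odd dimensions", {
  x <- matrix(seq_len(512 * 512), 512, 512)
  q <- split_quadrants(x)
  expect_equal(dim(q[[1]]), c(256, 256))
  expect_equal(rbind(cbind(q[[1]], q[[2]]), cbind(q[[3]], q[[4]])), x)

  y <- matrix(seq_len(513 * 513), 513, 513)
  qy <- split_quadrants(y)
  expect_equal(attr(qy, "padding"), c(1L, 1L))
  reassembled <- rbind(cbind(qy[[1]], qy[[2]]), cbind(qy[[3]], qy[[4]]))
  expect_equal(reassembled[1:513, 1:513], y)
})

test_that("stratified_split holds the ratio and the per-stratum floor", {
  meta <- expand.grid(sex = c("F", "M"), region = c("ctx", "wm"),
                      group = c("control", "OGD"),
                      stringsAsFactors = FALSE)
  meta <- meta[rep(seq_len(nrow(meta)), length.out = 100), ]
  sp <- stratified_split(meta, test_frac = 0.2, seed = 1)
  expect_equal(sum(sp$partition == "test"), 20)
  strata <- interaction(sp$sex, sp$region, sp$group)
  keep <- table(strata[sp$partition == "train"])
  expect_gte(min(keep), 2)
  sp2 <- stratified_split(meta, test_frac = 0.2, seed = 1)
  expect_identical(sp$partition, sp2$partition)

  tiny <- meta[c(1, 9), ]  # a stratum with only 2 images
  expect_error(stratified_split(tiny, seed = 1), "infeasible stratum")
})

test_that("morphology_params matches shape oracles", {
  disk <- morphology_params(disk_pixels(20))
  expect_gte(disk$circularity, 0.85)
  expect_lte(disk$circularity, 1.1)
  expect_gte(disk$solidity, 0.95)
  expect_gte(disk$extent, pi / 4 - 0.05)

  rect <- morphology_params(rect_pixels(3, 30))
  expect_equal(rect$aspect_ratio, 10, tolerance = 0.2 * 10)
  expect_equal(rect$extent, 1, tolerance = 0.1)
  # orientation is measured from the column axis: a horizontal bar is 0, a
  # vertical one pi/2
  expect_equal(rect$orientation, 0, tolerance = 0.05)
  expect_equal(abs(morphology_params(rect_pixels(30, 3))$orientation),
               pi / 2, tolerance = 0.05)

  square <- morphology_params(rect_pixels(16, 16))
  disk_same_area <- morphology_params(disk_pixels(9))
  expect_lt(square$circularity, disk_same_area$circularity)
  expect_lt(square$eccentricity, 0.2)
})

test_that("shape-mode model recovers planted families and is deterministic", {
  mg <- gen_microglia_images(sim_config(seed = 9))
  model <- fit_shape_modes(mg$cells, seed = 9)
  ari <- adjusted_rand_index(model$train_labels, mg$truth$family[model$kept])
  expect_gte(ari, 0.7)

  # duplicate of a training cell gets the training cell's mode
  labs <- owhscreen:::shape_mode_labels(model, mg$cells[1:20])
  expect_equal(labs, model$train_labels[1:20])

  # registered contours: centroid 0, unit RMS scale
  reg <- owhscreen:::register_contour(
    owhscreen:::extract_contour(mg$cells[[1]], 50))
  expect_equal(colMeans(reg), c(0, 0), tolerance = 1e-10)
  expect_equal(mean(rowSums(reg^2)), 1, tolerance = 1e-10)

  expect_error(fit_shape_modes(mg$cells[1:10]), "training cells")
})

test_that("shape-mode assignment is invariant to pose and scale", {
  set.seed(42)
  mg <- gen_microglia_images(sim_config(seed = 10))
  model <- fit_shape_modes(mg$cells, seed = 10)
  fams <- c("rod", "intermediate1", "ramified", "intermediate2", "ameboid")
  agree <- 0L; total <- 0L
  for (f in fams) {
    for (k in 1:8) {
      pars <- owhscreen:::sample_cell_params(f)
      base <- owhscreen:::raster_cell(f, theta = 0.3, params = pars)
      rot <- owhscreen:::raster_cell(f, theta = 0.3 + 1.1, params = pars)
      l <- owhscreen:::shape_mode_labels(model, list(base, rot))
      agree <- agree + (l[1] == l[2])
      total <- total + 1L
    }
  }
  expect_gte(agree / total, 0.95)
  # uniform scaling: scale all linear parameters of one cell by 1.6
  pars <- owhscreen:::sample_cell_params("intermediate1")
  small <- owhscreen:::raster_cell("intermediate1", theta = 1, params = pars)
  pars2 <- pars; pars2$a <- pars$a * 1.6; pars2$b <- pars$b * 1.6
  large <- owhscreen:::raster_cell("intermediate1", canvas = 151L, theta = 1,
                                   params = pars2)
  l <- owhscreen:::shape_mode_labels(model, list(small, large))
  expect_equal(l[1], l[2])
})

test_that("assign_shape_modes tabulates proportions and x5 totals", {
  mg <- gen_microglia_images(sim_config(seed = 12))
  model <- fit_shape_modes(mg$cells, seed = 12)
  dist <- assign_shape_modes(model, mg$cells[1:37],
                             metadata = data.frame(group = "OGD",
                                                   region = "cortex")[
                                                     rep(1, 37), , drop = FALSE])
  tab <- dist$distribution
  expect_equal(nrow(tab), 1)
  expect_equal(sum(as.numeric(tab[1, grep("^SM", names(tab))])), 1,
               tolerance = 1e-9)
  expect_equal(tab$estimated_total, 185)  # 37 x 5
  expect_equal(tab$estimated_total %% 5, 0)

  # cells from a single family concentrate in one mode
  fam3 <- mg$cells[mg$truth$family == 3]
  d3 <- assign_shape_modes(model, fam3,
                           metadata = data.frame(group = "x", region = "y")[
                             rep(1, length(fam3)), , drop = FALSE])
  props <- as.numeric(d3$distribution[1, grep("^SM", names(d3$distribution))])
  expect_gte(max(props), 0.8)
})
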
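#' Simulation configuration
#'
#' Stated-world parameters for the seeded synthetic-data generators. Defaults
#' mirror the study design the pipeline targets: 512 x 512 px images at
#' 0.863 um/px, five treatment groups (control, OGD, Az, Epo, AzEpo) by three
#' regions, n = 12 slices per group for scalar outcomes, a 255-transcript
#' panel with 6 samples per group x region, and 14 planted emergent
#' transcripts.
#'
#' @param seed integer RNG seed; identical configs give identical outputs.
#' @param image_size c(rows, cols) in pixels.
#' @param pixel_size um per pixel side.
#' @param n_nuclei nuclei per generated field.
#' @param pyknotic_fraction fraction of nuclei rendered pyknotic.
#' @param min_separation minimum centre-to-centre distance (px).
#' @param background constant background offset (intensity units).
#' @param texture_sd SD of the low-frequency background texture field.
#' @param photon_budget detected photons per unit intensity (Poisson shot
#'   noise); `Inf` disables noise entirely.
#' @param shape_families named integer vector: cells per morphological family
#'   (rod, intermediate1, ramified, intermediate2, ameboid).
#' @param panel_size transcript count.
#' @param n_samples_per_cell samples per group x region cell.
#' @param n_deg planted OGD-vs-control differentially expressed transcripts.
#' @param deg_log2fc absolute planted log2 shift for DEGs.
#' @param n_emergent planted combination-only (emergent) transcripts.
#' @param emergent_offset_mult emergent offset in multiples of `noise_sd`.
#' @param noise_sd dispersion of log2 expression around group means.
#' @param recovery named fractional recovery of the OGD shift per treatment
#'   (AzEpo near 1 = normalized by the combination).
#' @param group_effects named fractional effects on the injury outcome for
#'   the treatment groups (feeds [gen_group_outcomes()]).
#' @param n_slices slices per group for scalar outcomes.
#' @param outcome_noise_sd SD of per-slice outcomes (outcome units).
#' @param control_mean,injury_mean outcome means for control and untreated OGD.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       image_size = c(512L, 512L),
                       pixel_size = 0.863,
                       n_nuclei = 150L,
                       pyknotic_fraction = 0.2,
                       min_separation = 8,
                       background = 0.05,
                       texture_sd = 0.005,
                       photon_budget = 1e5,
                       shape_families = c(rod = 200L, intermediate1 = 200L,
                                          ramified = 200L,
                                          intermediate2 = 200L,
                                          ameboid = 200L),
                       panel_size = 255L,
                       n_samples_per_cell = 6L,
                       n_deg = 40L,
                       deg_log2fc = 1,
                       n_emergent = 14L,
                       emergent_offset_mult = 6,
                       noise_sd = 0.25,
                       recovery = c(Az = 0.3, Epo = 0.3, AzEpo = 0.9),
                       group_effects = c(Az = 0, Epo = 0, AzEpo = 0.6),
                       n_slices = 12L,
                       outcome_noise_sd = 0.08,
                       control_mean = 0.4,
                       injury_mean = 1.0) {
  cfg <- list(seed = as.integer(seed), image_size = as.integer(image_size),
              pixel_size = pixel_size, n_nuclei = as.integer(n_nuclei),
              pyknotic_fraction = pyknotic_fraction,
              min_separation = min_separation,
              background = background, texture_sd = texture_sd,
              photon_budget = photon_budget,
              shape_families = shape_families,
              panel_size = as.integer(panel_size),
              n_samples_per_cell = as.integer(n_samples_per_cell),
              n_deg = as.integer(n_deg), deg_log2fc = deg_log2fc,
              n_emergent = as.integer(n_emergent),
              emergent_offset_mult = emergent_offset_mult,
              noise_sd = noise_sd, recovery = recovery,
              group_effects = group_effects, n_slices = as.integer(n_slices),
              outcome_noise_sd = outcome_noise_sd,
              control_mean = control_mean, injury_mean = injury_mean)
  counts <- c(cfg$n_nuclei, cfg$panel_size, cfg$n_samples_per_cell, cfg$n_deg,
              cfg$n_emergent, cfg$n_slices, cfg$shape_families)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$pyknotic_fraction < 0 || cfg$pyknotic_fraction > 1)
    stop("pyknotic_fraction must be in [0, 1]")
  if (cfg$panel_size < cfg$n_deg + cfg$n_emergent)
    stop("panel_size must be >= n_deg + n_emergent")
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  structure(cfg, class = "sim_config")
}

#' Read a simulation config from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @param seed optional seed overriding the file (CLI `--seed` semantics).
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  args <- yaml::read_yaml(path)
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_config, args)
}

groups5 <- c("control", "OGD", "Az", "Epo", "AzEpo")
regions3 <- c("cortex", "white matter", "deep gray")

#' Generate a DAPI-like nucleus field with ground truth
#'
#' Renders isotropic 2-D Gaussian spots on a noisy background. Pyknotic
#' nuclei (condensed apoptotic chromatin) are small and bright: sigma 1-2 px
#' with peak intensity 1.5-2x the non-pyknotic spots (sigma 3-5 px), so the
#' two classes are separable by the eight-feature nucleus descriptor. Centres
#' are placed by seeded rejection sampling with a minimum pairwise
#' separation.
#'
#' The noise model emulates confocal DAPI acquisition: a constant background
#' offset, a weak low-frequency autofluorescence texture field (Gaussian
#' field smoothed at sigma 3 px, `texture_sd` amplitude), and Poisson shot
#' noise at `photon_budget` detected photons per unit intensity. DAPI is a
#' bright stain, so the defaults put images in the structure-limited rather
#' than photon-limited regime (background-relative peak SNR far above the
#' benchmark floor of 10).
#'
#' @param config a [sim_config()].
#' @return list with `image` (a [histology_image()]) and `truth`
#'   (data.frame: id, row, col, sigma, peak, pyknotic).
#' @export
gen_nuclei_image <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  nr <- config$image_size[1]; nc <- config$image_size[2]
  n <- config$n_nuclei
  margin <- 8
  img <- matrix(0, nr, nc)
  truth <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      sigma = numeric(0), peak = numeric(0),
                      pyknotic = logical(0))
  if (n > 0) {
    centers <- matrix(NA_real_, n, 2)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 500L * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(
          "infeasible packing: placed %d of %d nuclei at separation %.1f px",
          placed, n, config$min_separation))
      cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
      if (placed > 0L) {
        d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
          (centers[seq_len(placed), 2] - cand[2])^2
        if (min(d2) < config$min_separation^2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    n_pyk <- round(config$pyknotic_fraction * n)
    pyk <- seq_len(n) <= n_pyk  # deterministic count; positions are random
    sigma <- ifelse(pyk, runif(n, 1, 2), runif(n, 3, 5))
    base_amp <- runif(n, 0.45, 0.55)
    peak <- ifelse(pyk, base_amp * runif(n, 1.5, 2), base_amp)
    for (i in seq_len(n)) {
      h <- ceiling(4 * sigma[i])
      rr <- max(1, floor(centers[i, 1] - h)):min(nr, ceiling(centers[i, 1] + h))
      cc <- max(1, floor(centers[i, 2] - h)):min(nc, ceiling(centers[i, 2] + h))
      g <- outer(rr - centers[i, 1], cc - centers[i, 2],
                 function(a, b) exp(-(a^2 + b^2) / (2 * sigma[i]^2)))
      img[rr, cc] <- img[rr, cc] + peak[i] * g
    }
    truth <- data.frame(id = seq_len(n), row = centers[, 1],
                        col = centers[, 2], sigma = sigma, peak = peak,
                        pyknotic = pyk)
  }
  img <- img + config$background
  if (config$texture_sd > 0) {
    tex <- gauss_blur(matrix(rnorm(nr * nc), nr, nc), 3)
    img <- img + tex * (config$texture_sd / sd(tex))
  }
  if (is.finite(config$photon_budget)) {
    G <- config$photon_budget
    img <- matrix(rpois(nr * nc, pmax(img, 0) * G) / G, nr, nc)
  }
  img <- pmax(img, 0)
  list(image = histology_image(img, pixel_size = config$pixel_size),
       truth = truth)
}

# Rasterize one parametric microglia-like cell on a square canvas.
# Families: rod (elongated ellipse), intermediate1 (moderate ellipse),
# ramified (disk + thin radial branches), intermediate2 (disk + short wide
# bumps), ameboid (disk).
raster_cell <- function(family, canvas = 131L, theta = 0,
                        params = list()) {
  half <- (canvas - 1) / 2
  xy <- expand.grid(r = -half:half, c = -half:half)
  # rotate coordinates into the cell frame
  u <- cos(theta) * xy$c + sin(theta) * xy$r
  v <- -sin(theta) * xy$c + cos(theta) * xy$r
  inside <- switch(
    family,
    rod = {
      a <- params$a %||% 24; b <- params$b %||% 3.5
      (u / a)^2 + (v / b)^2 <= 1
    },
    intermediate1 = {
      a <- params$a %||% 18; b <- params$b %||% 6
      (u / a)^2 + (v / b)^2 <= 1
    },
    ameboid = {
      r <- params$r %||% 12
      u^2 + v^2 <= r^2
    },
    ramified = {
      r <- params$r %||% 9
      core <- u^2 + v^2 <= r^2
      ang <- params$branch_angles
      len <- params$branch_len
      wid <- params$branch_wid
      for (k in seq_along(ang)) {
        bu <- cos(ang[k]) * u + sin(ang[k]) * v
        bv <- -sin(ang[k]) * u + cos(ang[k]) * v
        core <- core | (bu >= 0 & bu <= r + len[k] & abs(bv) <= wid[k] / 2)
      }
      core
    },
    intermediate2 = {
      r <- params$r %||% 10.5
      core <- u^2 + v^2 <= r^2
      ang <- params$branch_angles
      len <- params$branch_len
      wid <- params$branch_wid
      for (k in seq_along(ang)) {
        bu <- cos(ang[k]) * u + sin(ang[k]) * v
        bv <- -sin(ang[k]) * u + cos(ang[k]) * v
        core <- core | (bu >= 0 & bu <= r + len[k] & abs(bv) <= wid[k] / 2)
      }
      core
    },
    stop(sprintf("unknown shape family '%s'", family)))
  matrix(inside, canvas, canvas)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Jittered parameters for one sampled cell of a family.
sample_cell_params <- function(family) {
  j <- function(x, frac = 0.1) x * runif(1, 1 - frac, 1 + frac)
  switch(
    family,
    rod = list(a = j(24), b = j(3.5)),
    intermediate1 = list(a = j(18), b = j(6)),
    ameboid = list(r = j(12)),
    ramified = {
      nb <- 5L  # fixed per family: one jittered prototype, not a mixture
      base <- runif(1, 0, 2 * pi)
      list(r = j(9),
           branch_angles = base + seq(0, 2 * pi, length.out = nb + 1)[-1] +
             runif(nb, -0.15, 0.15),
           branch_len = runif(nb, 19, 25),
           branch_wid = runif(nb, 2.7, 3.6))
    },
    intermediate2 = {
      nb <- 3L
      base <- runif(1, 0, 2 * pi)
      list(r = j(10.5),
           branch_angles = base + seq(0, 2 * pi, length.out = nb + 1)[-1] +
             runif(nb, -0.2, 0.2),
           branch_len = runif(nb, 7.5, 10.5),
           branch_wid = runif(nb, 5.4, 6.6))
    })
}

#' Generate microglia-like cell masks from five morphological families
#'
#' Each cell is an independently jittered, randomly rotated rasterization of
#' its parametric family. Metadata (sex, region, group) is assigned cyclically
#' so every sex x region x treatment combination receives at least two cells,
#' keeping the stratified 80:20 split feasible.
#'
#' @param config a [sim_config()]; `config$shape_families` gives counts.
#' @return list with `cells` (list of logical masks), `images` (intensity
#'   images: mask + noise) and `truth` (data.frame: cell, family,
#'   family_name, sex, region, group).
#' @export
gen_microglia_images <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fams <- config$shape_families
  if (length(fams) != 5L) stop("exactly 5 shape families must be specified")
  set.seed(sub_seed(config$seed, 2L))
  fam_names <- names(fams)
  labels <- rep(fam_names, times = fams)
  n <- length(labels)
  combos <- expand.grid(sex = c("F", "M"), region = regions3,
                        group = groups5, stringsAsFactors = FALSE)
  meta_idx <- rep(seq_len(nrow(combos)), length.out = n)
  cells <- vector("list", n)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    m <- raster_cell(labels[i], theta = runif(1, 0, 2 * pi),
                     params = sample_cell_params(labels[i]))
    cells[[i]] <- m
    img <- m * runif(1, 0.7, 0.9) +
      matrix(rnorm(length(m), 0, 0.03), nrow(m), ncol(m))
    images[[i]] <- pmax(img, 0)
  }
  truth <- data.frame(cell = seq_len(n),
                      family = match(labels, fam_names),
                      family_name = labels,
                      sex = combos$sex[meta_idx],
                      region = combos$region[meta_idx],
                      group = combos$group[meta_idx])
  list(cells = cells, images = images, truth = truth)
}

#' Generate a targeted expression panel with planted effects
#'
#' Log2-scale expression for `panel_size` transcripts across 5 groups x 3
#' regions x `n_samples_per_cell` samples, with additive Gaussian noise
#' (`noise_sd`). Planted structure:
#' \itemize{
#'   \item DEGs: OGD mean shifted by `+-deg_log2fc` vs control; treatments
#'     recover the shift by the `recovery` fractions (AzEpo near 1 =
#'     normalized by the combination only).
#'   \item Emergent transcripts: the AzEpo mean additionally offset by
#'     `+-emergent_offset_mult * noise_sd`, an offset carried by no other
#'     group and hence unpredictable from the four predictor groups.
#' }
#'
#' @param config a [sim_config()].
#' @return list with `values` (matrix, transcripts x samples, log2 scale),
#'   `meta` (sample metadata: sample_id, group, region, slice, sex) and
#'   `truth` (per-transcript planted effects).
#' @export
gen_expression_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 3L))
  p <- config$panel_size
  transcripts <- sprintf("T%03d", seq_len(p))
  idx <- sample.int(p, config$n_deg + config$n_emergent)
  deg_idx <- idx[seq_len(config$n_deg)]
  emergent_idx <- setdiff(idx, deg_idx)
  delta <- numeric(p)
  delta[deg_idx] <- config$deg_log2fc *
    sample(c(-1, 1), config$n_deg, replace = TRUE)
  eoff <- numeric(p)
  eoff[emergent_idx] <- config$emergent_offset_mult * config$noise_sd *
    sample(c(-1, 1), config$n_emergent, replace = TRUE)
  baseline <- rnorm(p, 8, 1.5)
  region_eff <- matrix(rnorm(p * 3, 0, 0.15), p, 3,
                       dimnames = list(NULL, regions3))
  rec <- c(control = NA, OGD = 0, config$recovery)  # fraction recovered
  ns <- config$n_samples_per_cell
  meta <- expand.grid(sample = seq_len(ns), region = regions3,
                      group = groups5, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("S%03d", seq_len(nrow(meta)))
  meta$slice <- sprintf("%s_%s_%d", meta$group, meta$region, meta$sample)
  meta$sex <- rep_len(c("F", "M"), nrow(meta))
  values <- matrix(NA_real_, p, nrow(meta),
                   dimnames = list(transcripts, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    g <- meta$group[j]
    mu <- baseline + region_eff[, meta$region[j]]
    if (g != "control") mu <- mu + (1 - rec[[g]]) * delta
    if (g == "AzEpo") mu <- mu + eoff
    values[, j] <- mu + rnorm(p, 0, config$noise_sd)
  }
  type <- rep("null", p)
  type[deg_idx] <- "deg"
  type[emergent_idx] <- "emergent"
  truth <- data.frame(transcript = transcripts, type = type,
                      log2_effect = delta, emergent_offset = eoff)
  meta_out <- data.frame(sample_id = meta$sample_id, group = meta$group,
                         region = meta$region, slice = meta$slice,
                         sex = meta$sex)
  list(values = values, meta = meta_out, truth = truth)
}

#' Generate per-slice scalar outcomes with planted treatment effects
#'
#' Injury outcomes (LDH-like cytotoxicity or pyknotic fractions) per slice:
#' control at `control_mean`, untreated OGD at `injury_mean`, and each
#' treatment group X at `injury_mean - f_X * (injury_mean - control_mean)`
#' where `f_X` is the configured fractional effect. Gaussian noise with
#' `outcome_noise_sd`; `n_slices` per group with equal sex split.
#'
#' @param config a [sim_config()].
#' @param assay,region labels attached to every row.
#' @param seed_offset stream offset so multiple assays/regions from the same
#'   config are independent draws.
#' @return data.frame: slice, group, region, assay, sex, value.
#' @export
gen_group_outcomes <- function(config, assay = "LDH", region = "global",
                               seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  f <- config$group_effects
  if (!all(c("Az", "Epo", "AzEpo") %in% names(f)))
    stop("group_effects must name Az, Epo and AzEpo")
  set.seed(sub_seed(config$seed, 4L + seed_offset))
  span <- config$injury_mean - config$control_mean
  mu <- c(control = config$control_mean, OGD = config$injury_mean,
          Az = config$injury_mean - f[["Az"]] * span,
          Epo = config$injury_mean - f[["Epo"]] * span,
          AzEpo = config$injury_mean - f[["AzEpo"]] * span)
  n <- config$n_slices
  out <- do.call(rbind, lapply(groups5, function(g) {
    data.frame(slice = sprintf("%s_%s_%02d", assay, g, seq_len(n)),
               group = g, region = region, assay = assay,
               sex = rep_len(c("F", "M"), n),
               value = rnorm(n, mu[[g]], config$outcome_noise_sd))
  }))
  rownames(out) <- NULL
  out
}
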
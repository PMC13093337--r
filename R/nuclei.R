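#' Preprocess a histology image
#'
#' Min-max normalizes intensities to \[0, 1\], removes low-frequency
#' background with a high-pass Gaussian filter (identity minus a sigma = 1 px
#' Gaussian blur, negatives clipped) and rescales to unit maximum. Pixels
#' whose *relative intensity* — their min-max-normalized value, before the
#' high-pass — falls below `mask_frac` are masked to 0, which suppresses
#' isolated noise pixels while keeping nucleus interiors. The output is
#' affine-invariant: any `a * x + b` (a > 0) rescaling of the input maps to
#' the same result.
#'
#' @param img a [histology_image()] or numeric matrix.
#' @param hp_sigma high-pass Gaussian sigma in pixels.
#' @param mask_frac relative-intensity mask threshold.
#' @return a preprocessed `histology_image` with intensities in \[0, 1\].
#' @export
preprocess_image <- function(img, hp_sigma = 1, mask_frac = 0.10) {
  img <- as_histology_image(img)
  x <- img$pixels
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate image: constant intensities")
  x <- (x - rng[1]) / diff(rng)
  hp <- pmax(x - gauss_blur(x, hp_sigma), 0)
  mx <- max(hp)
  if (mx > 0) hp <- hp / mx
  masked <- hp
  masked[x < mask_frac] <- 0
  out <- img
  out$pixels <- masked
  # continuous (unmasked) high-passed image: blob detection convolves this
  # so the hard mask edge introduces no spurious responses
  attr(out, "unmasked") <- hp
  attr(out, "preprocessed") <- TRUE
  out
}

#' Detect nuclei by multi-scale Laplacian of Gaussian with watershed splitting
#'
#' Scale-normalized LoG responses (`-sigma^2 * Laplacian(G_sigma * I)`) are
#' computed over `num_sigma` scales on the continuous high-passed image (the
#' `"unmasked"` attribute set by [preprocess_image()], so the hard 10% mask
#' edge contributes no spurious responses); blob candidates are local maxima
#' over the (row, col, scale) neighbourhood above `threshold_frac` of the
#' maximum pixel intensity whose centre lies in the masked foreground,
#' pruned for overlap. The above-threshold foreground is
#' then partitioned among detections by a marker-seeded watershed so touching
#' nuclei receive disjoint member-pixel sets; each detection's territory is
#' capped at radius `2 * sigma * sqrt(2)` from its centre.
#'
#' @param img preprocessed `histology_image` (see [preprocess_image()]).
#' @param min_sigma,max_sigma,num_sigma LoG scale-space parameters. The
#'   bounds are interpreted in the units given by `sigma_units`: `"px"` uses
#'   the printed values as pixels (default), `"um"` divides by the pixel
#'   size first.
#' @param overlap blobs whose disk overlap fraction exceeds this are pruned,
#'   keeping the stronger response.
#' @param threshold_frac absolute response threshold as a fraction of the
#'   maximum pixel intensity.
#' @param sigma_units interpretation of the sigma bounds.
#' @return data.frame (id, row, col, sigma, response, n_pixels) of class
#'   `nucleus_detections`, with the per-detection member pixel sets
#'   (k x 2 matrices) in `attr(, "members")`.
#' @export
detect_nuclei <- function(img, min_sigma = 0.863, max_sigma = 5.179,
                          num_sigma = 25L, overlap = 0.7,
                          threshold_frac = 0.005,
                          sigma_units = c("px", "um")) {
  img <- as_histology_image(img)
  sigma_units <- match.arg(sigma_units)
  if (sigma_units == "um") {
    min_sigma <- min_sigma / img$pixel_size
    max_sigma <- max_sigma / img$pixel_size
  }
  x <- img$pixels
  resp_img <- attr(img, "unmasked") %||% x
  empty <- structure(
    data.frame(id = integer(0), row = integer(0), col = integer(0),
               sigma = numeric(0), response = numeric(0),
               n_pixels = integer(0)),
    members = list(), class = c("nucleus_detections", "data.frame"))
  if (max(x) <= 0) return(empty)
  sigmas <- seq(min_sigma, max_sigma, length.out = num_sigma)
  nr <- nrow(x); nc <- ncol(x)
  cube <- array(0, dim = c(nr, nc, num_sigma))
  for (k in seq_len(num_sigma))
    cube[, , k] <- -sigmas[k]^2 * laplacian4(gauss_blur(resp_img, sigmas[k]))
  thr <- threshold_frac * max(resp_img)

  # local maxima over the 3 x 3 x 3 neighbourhood (plateau-tolerant >=,
  # strictly above threshold)
  is_max <- cube >= thr
  shifts <- expand.grid(dr = -1:1, dc = -1:1, dk = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0 & shifts$dk == 0), ]
  padded <- array(-Inf, dim = dim(cube) + 2)
  padded[2:(nr + 1), 2:(nc + 1), 2:(num_sigma + 1)] <- cube
  for (s in seq_len(nrow(shifts))) {
    nb <- padded[2:(nr + 1) + shifts$dr[s], 2:(nc + 1) + shifts$dc[s],
                 2:(num_sigma + 1) + shifts$dk[s], drop = FALSE]
    is_max <- is_max & (cube >= nb)
    if (!any(is_max)) break
  }
  peaks <- which(is_max, arr.ind = TRUE)
  # a nucleus centre must lie in the unmasked (>= 10% relative intensity)
  # foreground; scale-space maxima in masked background are noise
  peaks <- peaks[x[peaks[, 1:2, drop = FALSE]] > 0, , drop = FALSE]
  if (nrow(peaks) == 0L) return(empty)
  det <- data.frame(row = peaks[, 1], col = peaks[, 2],
                    sigma = sigmas[peaks[, 3]],
                    response = cube[peaks])
  # collapse plateau duplicates at identical coordinates across scales
  det <- det[order(-det$response), ]
  det <- det[!duplicated(det[, c("row", "col")]), ]

  # overlap pruning: keep the stronger of two blobs whose disks (radius
  # sigma * sqrt(2)) overlap by more than `overlap`
  keep <- rep(TRUE, nrow(det))
  r_blob <- det$sigma * sqrt(2)
  for (i in seq_len(nrow(det))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(det)) > i)
    if (!length(j)) next
    d <- sqrt((det$row[j] - det$row[i])^2 + (det$col[j] - det$col[i])^2)
    ov <- disk_overlap_frac(r_blob[i], r_blob[j], d)
    keep[j[ov > overlap]] <- FALSE
  }
  det <- det[keep, , drop = FALSE]

  # watershed partition of the foreground among detections
  markers <- matrix(0L, nr, nc)
  markers[cbind(det$row, det$col)] <- seq_len(nrow(det))
  fg <- x > 0
  fg[cbind(det$row, det$col)] <- TRUE  # markers always belong to the domain
  lab <- watershed_cpp(x, markers, fg)
  members <- vector("list", nrow(det))
  px <- which(lab > 0, arr.ind = TRUE)
  lab_px <- lab[px]
  d_own <- sqrt((px[, 1] - det$row[lab_px])^2 + (px[, 2] - det$col[lab_px])^2)
  within <- d_own <= 2 * det$sigma[lab_px] * sqrt(2)
  px <- px[within, , drop = FALSE]
  lab_px <- lab_px[within]
  for (i in seq_len(nrow(det))) {
    m <- px[lab_px == i, , drop = FALSE]
    if (nrow(m) == 0L)
      m <- matrix(c(det$row[i], det$col[i]), 1, 2)
    colnames(m) <- c("row", "col")
    members[[i]] <- m
  }
  det$id <- seq_len(nrow(det))
  det$n_pixels <- vapply(members, nrow, integer(1))
  det <- det[, c("id", "row", "col", "sigma", "response", "n_pixels")]
  rownames(det) <- NULL
  structure(det, members = members,
            class = c("nucleus_detections", "data.frame"))
}

# Overlap area fraction of two disks at centre distance d, relative to the
# smaller disk (the scikit-image blob pruning convention).
disk_overlap_frac <- function(r1, r2, d) {
  r2 <- rep_len(r2, length(d))
  r1 <- rep_len(r1, length(d))
  lo <- pmin(r1, r2); hi <- pmax(r1, r2)
  out <- numeric(length(d))
  inside <- d <= (hi - lo)
  out[inside] <- 1
  lens <- !inside & d < (r1 + r2)
  if (any(lens)) {
    dd <- d[lens]; a <- hi[lens]; b <- lo[lens]
    alpha <- acos(pmin(pmax((dd^2 + a^2 - b^2) / (2 * dd * a), -1), 1))
    beta <- acos(pmin(pmax((dd^2 + b^2 - a^2) / (2 * dd * b), -1), 1))
    area <- a^2 * (alpha - sin(2 * alpha) / 2) +
      b^2 * (beta - sin(2 * beta) / 2)
    out[lens] <- area / (pi * b^2)
  }
  out
}

#' Eight-feature descriptor of a detected nucleus
#'
#' For a nucleus of `n` member pixels with pixel area `a = pixel_size^2`,
#' normalized intensities `I_i` and distances `d_i` (pixels) from the
#' detection centre:
#' area `A = n * a`; Crofton perimeter `P`; ideal radius `r_I = sqrt(A / pi)`;
#' eccentricity `eps = P / (2 * pi * r_I)`; average normalized intensity
#' `I_M = (1/n) * sum(I_i * d_i)` (the distance factor is part of the
#' descriptor's definition and is computed exactly as stated); total
#' normalized intensity `I_T = A * I_M`; weighted intensity
#' `I_W = sum(I_i * d_i) / sum(d_i)` (for a single-pixel nucleus, where all
#' distances vanish, `I_W` falls back to that pixel's intensity); plus the
#' detection scale `sigma`.
#'
#' @param img preprocessed `histology_image` (normalized intensities).
#' @param members k x 2 (row, col) member pixel matrix.
#' @param center numeric (row, col) detection centre.
#' @param sigma detection scale.
#' @return one-row data.frame: A, P, r_I, eps, I_M, I_T, I_W, sigma.
#' @export
nucleus_features <- function(img, members, center, sigma) {
  img <- as_histology_image(img)
  members <- as.matrix(members)
  if (nrow(members) == 0L) stop("empty member pixel set")
  n <- nrow(members)
  a <- img$pixel_size^2
  A <- n * a
  P <- crofton_perimeter(members, pixel_size = img$pixel_size)
  r_I <- sqrt(A / pi)
  eps <- P / (2 * pi * r_I)
  I <- img$pixels[members]
  d <- sqrt((members[, 1] - center[1])^2 + (members[, 2] - center[2])^2)
  I_M <- sum(I * d) / n
  I_T <- A * I_M
  I_W <- if (sum(d) > 0) sum(I * d) / sum(d) else I[1]
  data.frame(A = A, P = P, r_I = r_I, eps = eps, I_M = I_M, I_T = I_T,
             I_W = I_W, sigma = sigma)
}

#' Feature table for all detections in an image
#'
#' @param img preprocessed `histology_image`.
#' @param detections result of [detect_nuclei()].
#' @return data.frame with one row per detection (id + the eight features).
#' @export
nucleus_feature_table <- function(img, detections) {
  members <- attr(detections, "members")
  if (nrow(detections) == 0L)
    return(cbind(data.frame(id = integer(0)),
                 nucleus_features(histology_image(matrix(1, 2, 2)),
                                  matrix(1, 1, 2), c(1, 1), 1)[0, ]))
  feats <- lapply(seq_len(nrow(detections)), function(i)
    nucleus_features(img, members[[i]],
                     c(detections$row[i], detections$col[i]),
                     detections$sigma[i]))
  cbind(data.frame(id = detections$id), do.call(rbind, feats))
}

pyknosis_feature_cols <- c("A", "P", "r_I", "eps", "I_M", "I_T", "I_W",
                           "sigma")

#' Train the pyknosis random-forest classifier
#'
#' Handles class imbalance by keeping every pyknotic nucleus and subsampling
#' three times as many non-pyknotic nuclei (or all available if fewer), then
#' fits a random forest on an 80:20 split with 5-fold cross-validation inside
#' the training partition. All subsampling, splitting and tree growth is
#' driven by `seed`.
#'
#' @param labeled data.frame with the eight feature columns and a logical (or
#'   "pyknotic"/"non-pyknotic") `label` column.
#' @param seed integer seed.
#' @param ntree trees in the forest.
#' @param subsample_ratio non-pyknotic per pyknotic in the training pool.
#' @param holdout_frac held-out fraction (0.2 = the 80:20 split).
#' @param cv_folds cross-validation folds within the training partition.
#' @return an object of class `pyknosis_model`: fitted forest, training
#'   manifest, per-fold CV metrics, holdout metrics.
#' @export
train_pyknosis_model <- function(labeled, seed = 1L, ntree = 200L,
                                 subsample_ratio = 3, holdout_frac = 0.2,
                                 cv_folds = 5L) {
  lab <- labeled$label
  if (is.character(lab) || is.factor(lab)) lab <- as.character(lab) == "pyknotic"
  lab <- as.logical(lab)
  if (length(unique(lab)) < 2L)
    stop("both classes must be present to train the classifier")
  X <- as.matrix(labeled[, pyknosis_feature_cols])
  set.seed(sub_seed(seed, 11L))
  pyk <- which(lab)
  non <- which(!lab)
  n_sub <- min(length(non), round(subsample_ratio * length(pyk)))
  non_sub <- sample(non, n_sub)
  pool <- c(pyk, non_sub)
  y <- lab[pool]
  Xp <- X[pool, , drop = FALSE]
  n <- length(pool)
  test_idx <- sample.int(n, round(holdout_frac * n))
  train_idx <- setdiff(seq_len(n), test_idx)
  folds <- sample(rep_len(seq_len(cv_folds), length(train_idx)))
  cv <- do.call(rbind, lapply(seq_len(cv_folds), function(f) {
    tr <- train_idx[folds != f]
    te <- train_idx[folds == f]
    fit <- owh_forest(Xp[tr, , drop = FALSE], y[tr], ntree = ntree)
    p <- predict(fit, Xp[te, , drop = FALSE])
    data.frame(fold = f,
               accuracy = mean((p > 0.5) == y[te]),
               auroc = if (length(unique(y[te])) == 2L)
                 auroc(p, y[te]) else NA_real_)
  }))
  forest <- owh_forest(Xp[train_idx, , drop = FALSE], y[train_idx],
                       ntree = ntree)
  p_test <- predict(forest, Xp[test_idx, , drop = FALSE])
  holdout <- data.frame(
    accuracy = mean((p_test > 0.5) == y[test_idx]),
    auroc = if (length(unique(y[test_idx])) == 2L)
      auroc(p_test, y[test_idx]) else NA_real_)
  structure(list(
    forest = forest,
    manifest = list(n_pyknotic = length(pyk),
                    n_nonpyknotic_subsampled = n_sub,
                    split = c(train = 1 - holdout_frac, test = holdout_frac),
                    cv_folds = cv_folds, ntree = ntree, seed = seed),
    cv_metrics = cv, holdout = holdout), class = "pyknosis_model")
}

#' @export
print.pyknosis_model <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("pyknosis_model: %d pyknotic + %d non-pyknotic ",
                     "(1:%g subsample), %d-fold CV\n"),
              m$n_pyknotic, m$n_nonpyknotic_subsampled,
              m$n_nonpyknotic_subsampled / max(m$n_pyknotic, 1), m$cv_folds))
  cat(sprintf("  CV AUROC %.3f, holdout AUROC %.3f\n",
              mean(x$cv_metrics$auroc, na.rm = TRUE), x$holdout$auroc))
  invisible(x)
}

#' @param object a `pyknosis_model`.
#' @param features data.frame/matrix with the eight feature columns.
#' @param ... unused.
#' @rdname train_pyknosis_model
#' @export
predict.pyknosis_model <- function(object, features, ...) {
  p <- predict(object$forest,
               as.matrix(as.data.frame(features)[, pyknosis_feature_cols]))
  data.frame(prob_pyknotic = p, pyknotic = p > 0.5)
}

#' Detect, classify and count nuclei across images
#'
#' Runs preprocessing, detection, the eight-feature descriptor and the
#' pyknosis classifier over a set of images and reports per-image totals.
#' The pyknotic fraction is log-transformed (fractions of dying cells are
#' right-skewed) with a half-count pseudo-fraction offset
#' `log(fraction + 0.5 / total)`; images with zero detections are flagged and
#' carry `NA` fractions.
#'
#' @param model a trained [train_pyknosis_model()] object.
#' @param images list of `histology_image`s (raw; preprocessing is applied).
#' @param ... passed to [detect_nuclei()].
#' @return data.frame of class `count_report`: image, region, group, slice,
#'   total, pyknotic, fraction, log_fraction, flagged.
#' @export
classify_and_count <- function(model, images, ...) {
  stopifnot(inherits(model, "pyknosis_model"))
  if (inherits(images, "histology_image")) images <- list(images)
  rows <- lapply(seq_along(images), function(i) {
    img <- as_histology_image(images[[i]])
    md <- img$metadata
    # degenerate (constant) images carry no nuclei: flagged empty report
    pre <- tryCatch(preprocess_image(img), error = function(e) NULL)
    det <- if (is.null(pre)) NULL else detect_nuclei(pre, ...)
    if (is.null(det) || nrow(det) == 0L)
      return(data.frame(image = i, region = md$region, group = md$group,
                        slice = md$slice, total = 0L, pyknotic = 0L,
                        fraction = NA_real_, log_fraction = NA_real_,
                        flagged = TRUE))
    feats <- nucleus_feature_table(pre, det)
    cls <- predict(model, feats)
    total <- nrow(det)
    npyk <- sum(cls$pyknotic)
    frac <- npyk / total
    data.frame(image = i, region = md$region, group = md$group,
               slice = md$slice, total = total, pyknotic = npyk,
               fraction = frac, log_fraction = log(frac + 0.5 / total),
               flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("count_report", "data.frame")
  out
}
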
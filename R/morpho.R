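#' Segment cells from a grayscale image
#'
#' Otsu thresholding followed by the standard cleanup: holes filled, objects
#' smaller than `min_size` pixels removed (strict: a 24-px object goes, a
#' 25-px object stays with the default), and cells touching the image border
#' removed.
#'
#' @param img `histology_image` or numeric matrix; a binary/logical matrix is
#'   accepted and used as the foreground directly (segmentation is then
#'   idempotent).
#' @param min_size minimum object size in pixels.
#' @return list of `cell_mask` objects (fields: pixels = k x 2 (row, col)
#'   matrix, dim, metadata inherited from the image).
#' @export
segment_cells <- function(img, min_size = 25L) {
  md <- list(region = NA, group = NA, slice = NA, sex = NA, quadrant = NA)
  if (inherits(img, "histology_image")) {
    md[names(img$metadata)] <- img$metadata
    x <- img$pixels
  } else x <- as.matrix(img)
  if (is.logical(x)) {
    fg <- x
  } else if (all(x %in% c(0, 1))) {
    fg <- x > 0.5
  } else {
    if (diff(range(x)) == 0) return(list())
    fg <- x > otsu_threshold(x)
  }
  if (!any(fg)) return(list())
  fg <- fill_holes(fg)
  lab <- label_components_cpp(fg, 8L)
  nr <- nrow(fg); nc <- ncol(fg)
  out <- list()
  for (l in seq_len(max(lab))) {
    px <- which(lab == l, arr.ind = TRUE)
    if (nrow(px) < min_size) next
    if (any(px[, 1] %in% c(1L, nr)) || any(px[, 2] %in% c(1L, nc))) next
    colnames(px) <- c("row", "col")
    out[[length(out) + 1L]] <- structure(
      list(pixels = px, dim = c(nr, nc), metadata = md), class = "cell_mask")
  }
  out
}

# Fill interior holes: background components not connected to the border
# become foreground (4-connectivity on background).
fill_holes <- function(fg) {
  bg <- !fg
  lab <- label_components_cpp(bg, 4L)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  fg | !(lab %in% border_labels & lab > 0) & bg
}

#' Split an image into four equal quadrants
#'
#' Odd dimensions are padded by edge replication before splitting (padding is
#' recorded in the `padding` attribute); the quadrants tile the (padded)
#' image exactly.
#'
#' @param img `histology_image` or matrix.
#' @return list of four matrices (or `histology_image`s) in reading order
#'   (top-left, top-right, bottom-left, bottom-right) with quadrant metadata.
#' @export
split_quadrants <- function(img) {
  is_hist <- inherits(img, "histology_image")
  x <- if (is_hist) img$pixels else as.matrix(img)
  pad <- c(nrow(x) %% 2L, ncol(x) %% 2L)
  if (pad[1]) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (pad[2]) x <- cbind(x, x[, ncol(x), drop = FALSE])
  hr <- nrow(x) / 2L; hc <- ncol(x) / 2L
  quads <- list(x[1:hr, 1:hc], x[1:hr, (hc + 1):(2 * hc)],
                x[(hr + 1):(2 * hr), 1:hc],
                x[(hr + 1):(2 * hr), (hc + 1):(2 * hc)])
  if (is_hist)
    quads <- lapply(seq_along(quads), function(i) {
      q <- img
      q$pixels <- quads[[i]]
      q$metadata$quadrant <- i
      q
    })
  attr(quads, "padding") <- pad
  quads
}

#' Stratified 80:20 train/test split of image metadata
#'
#' Assigns images to train/test at the requested global ratio (within one
#' image) while guaranteeing that each sex x region x treatment stratum keeps
#' at least `min_per_stratum` images in the training partition. Strata with
#' fewer than `min_per_stratum + 1` images are infeasible and raise an error
#' naming the stratum.
#'
#' @param meta data.frame with columns `sex`, `region`, `group` (one row per
#'   image).
#' @param test_frac test fraction (0.2 = 80:20).
#' @param seed integer seed; same seed, same assignment.
#' @param min_per_stratum minimum images retained per stratum.
#' @return `meta` with a `partition` column ("train"/"test").
#' @export
stratified_split <- function(meta, test_frac = 0.2, seed = 1L,
                             min_per_stratum = 2L) {
  stopifnot(all(c("sex", "region", "group") %in% names(meta)))
  stratum <- interaction(meta$sex, meta$region, meta$group, drop = TRUE)
  sizes <- table(stratum)
  bad <- names(sizes)[sizes < min_per_stratum + 1L]
  if (length(bad))
    stop(sprintf("infeasible stratum (need >= %d images): %s",
                 min_per_stratum + 1L, paste(bad, collapse = ", ")))
  set.seed(sub_seed(seed, 21L))
  n <- nrow(meta)
  target <- round(test_frac * n)
  # per-stratum base allocation, capped so train keeps min_per_stratum
  ns <- as.vector(sizes)
  cap <- ns - min_per_stratum
  base <- pmin(floor(test_frac * ns), cap)
  rem <- target - sum(base)
  frac <- test_frac * ns - floor(test_frac * ns)
  ord <- order(-frac)
  for (k in ord) {
    if (rem <= 0) break
    if (base[k] < cap[k]) {
      base[k] <- base[k] + 1L
      rem <- rem - 1L
    }
  }
  partition <- rep("train", n)
  lev <- levels(stratum)
  for (k in seq_along(lev)) {
    idx <- which(stratum == lev[k])
    if (base[k] > 0)
      partition[sample(idx, base[k])] <- "test"
  }
  meta$partition <- partition
  meta
}

#' Nine morphology parameters of a cell mask
#'
#' Standard definitions: area (px), Crofton perimeter (px), circularity
#' `4 * pi * A / P^2`, eccentricity of the second-moment ellipse, solidity
#' `A / convex hull area` (hull over pixel corners), extent
#' `A / bounding box area`, major axis length `4 * sqrt(lambda_max)` of the
#' coordinate covariance, aspect ratio (major / minor axis length), and
#' orientation (major-axis angle, radians, measured from the column axis).
#'
#' @param mask a `cell_mask`, logical matrix or k x 2 pixel matrix.
#' @return one-row data.frame with the nine parameters.
#' @export
morphology_params <- function(mask) {
  px <- if (inherits(mask, "cell_mask")) mask$pixels
  else if (is.logical(mask)) mask_to_pixels(mask)
  else as.matrix(mask)
  if (nrow(px) == 0L) stop("empty cell mask")
  n <- nrow(px)
  P <- crofton_perimeter(px)
  area <- n
  circularity <- 4 * pi * area / P^2
  # second moments (pixel-as-point; 1/12 term for single-pixel degeneracy)
  mu_r <- mean(px[, 1]); mu_c <- mean(px[, 2])
  dr <- px[, 1] - mu_r; dc <- px[, 2] - mu_c
  srr <- mean(dr^2) + 1 / 12; scc <- mean(dc^2) + 1 / 12; src <- mean(dr * dc)
  tr2 <- (srr + scc) / 2
  det_ <- srr * scc - src^2
  disc <- sqrt(max(tr2^2 - det_, 0))
  l1 <- tr2 + disc; l2 <- max(tr2 - disc, 1e-12)
  eccentricity <- sqrt(1 - l2 / l1)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  orientation <- 0.5 * atan2(2 * src, scc - srr)
  bbox <- (diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1)
  extent <- area / bbox
  # solidity counts lattice points inside the convex hull of pixel centres
  # (the regionprops convention): a convex digital shape has solidity 1
  solidity <- min(area / convex_pixel_count(px), 1)
  data.frame(area = area, perimeter = P, circularity = circularity,
             eccentricity = eccentricity, solidity = solidity,
             extent = extent, major_axis_length = major,
             aspect_ratio = major / minor, orientation = orientation)
}

# Number of integer lattice points inside (or on) the convex hull of the
# pixel centres: per-row intersection of the hull polygon with each lattice
# row.
convex_pixel_count <- function(px) {
  if (nrow(px) <= 2L) return(nrow(px))
  h <- grDevices::chull(px)
  hr <- px[h, 1]; hc <- px[h, 2]
  k <- length(h)
  total <- 0L
  eps <- 1e-9
  for (r in seq(min(hr), max(hr))) {
    xs <- c()
    for (e in seq_len(k)) {
      r1 <- hr[e]; c1 <- hc[e]
      r2 <- hr[if (e == k) 1L else e + 1L]; c2 <- hc[if (e == k) 1L else e + 1L]
      if (r1 == r2) {
        if (r1 == r) xs <- c(xs, c1, c2)
      } else if ((r >= min(r1, r2) - eps) && (r <= max(r1, r2) + eps)) {
        xs <- c(xs, c1 + (r - r1) * (c2 - c1) / (r2 - r1))
      }
    }
    if (length(xs))
      total <- total + max(0L, floor(max(xs) + eps) - ceiling(min(xs) - eps) + 1L)
  }
  max(total, nrow(px))
}

# Closed outer contour of a mask, resampled to n_points equally spaced
# (by arc length) boundary points. Returns n_points x 2 (row, col).
extract_contour <- function(mask, n_points = 50L) {
  m <- if (inherits(mask, "cell_mask")) pixels_to_mask(mask$pixels)
  else if (is.logical(mask)) mask else pixels_to_mask(as.matrix(mask))
  b <- trace_boundary_cpp(m)
  if (nrow(b) < 3L) return(NULL)
  pts <- rbind(b, b[1, , drop = FALSE])  # close the polygon
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(NULL)
  at <- seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  cbind(approx(s, pts[, 1], xout = at)$y, approx(s, pts[, 2], xout = at)$y)
}

# Registration step 1: translate to centroid, scale to unit RMS radius,
# orient counterclockwise (in x = col, y = -row screen coordinates).
canonicalize_contour <- function(pts) {
  pts <- sweep(pts, 2, colMeans(pts))
  sc <- sqrt(mean(rowSums(pts^2)))
  if (sc <= 1e-9) return(NULL)
  pts <- pts / sc
  xy <- cbind(pts[, 2], -pts[, 1])
  area2 <- sum(xy[, 1] * c(xy[-1, 2], xy[1, 2]) -
               c(xy[-1, 1], xy[1, 1]) * xy[, 2])
  if (area2 < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  xy
}

# Registration step 2: the starting point is the boundary point of maximal
# distance from the centroid; the contour is rotated so that point lies at
# angle 0. This locks both the cyclic phase and the rotation to the
# longest protrusion (for an ellipse: the major axis; for a disk the choice
# is arbitrary but the resulting sequence is rotation-equivalent anyway),
# so near-symmetric shapes do not scatter over arbitrary phases.
anchor_frame <- function(xy) {
  d <- rowSums(xy^2)
  start <- which.max(d)
  theta <- atan2(xy[start, 2], xy[start, 1])
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  z <- xy %*% R  # rotate by -theta: start point moves to angle 0
  z[c(start:nrow(z), seq_len(start - 1L)), , drop = FALSE]
}

register_contour <- function(pts, ...) {
  xy <- canonicalize_contour(pts)
  if (is.null(xy)) return(NULL)
  anchor_frame(xy)
}

#' Fit the shape-mode model
#'
#' Contour-registration morphometrics: each training mask's closed outer
#' contour is resampled to `n_points` boundary coordinates, registered
#' (centroid-centred, scale-normalized, principal-axis aligned, deterministic
#' starting point), flattened and decomposed by PCA; k-means (seeded,
#' `nstart` restarts) on the principal components explaining
#' `variance_target` of the variance yields `n_modes` shape modes.
#' Registration removes size, so modes encode shape; size effects are carried
#' by [morphology_params()].
#'
#' @param masks list of `cell_mask`s / logical matrices.
#' @param n_modes number of shape modes (SM1..SM5 by default).
#' @param n_points registration coordinates per contour.
#' @param seed integer seed.
#' @param variance_target cumulative explained-variance cutoff for the PCs
#'   fed to k-means.
#' @param nstart k-means restarts.
#' @return an object of class `shape_mode_model`.
#' @export
fit_shape_modes <- function(masks, n_modes = 5L, n_points = 50L, seed = 1L,
                            variance_target = 0.95, nstart = 20L) {
  contours <- lapply(masks, function(m) {
    ct <- extract_contour(m, n_points)
    if (is.null(ct)) return(NULL)
    register_contour(ct)
  })
  ok <- !vapply(contours, is.null, logical(1))
  if (any(!ok))
    warning(sprintf("%d degenerate contour(s) skipped", sum(!ok)))
  contours <- contours[ok]
  if (length(contours) < 5L * n_modes)
    stop(sprintf("need >= %d usable training cells, got %d", 5L * n_modes,
                 length(contours)))
  mean_contour <- Reduce(`+`, contours) / length(contours)
  X <- do.call(rbind, lapply(contours, as.vector))
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pca$sdev^2 / sum(pca$sdev^2)
  k <- which(cumsum(evr) >= variance_target)[1]
  k <- max(k, 2L)
  set.seed(sub_seed(seed, 31L))
  km <- kmeans(pca$x[, seq_len(k), drop = FALSE], centers = n_modes,
               nstart = nstart, iter.max = 100L)
  # stable mode numbering: order clusters by size (largest = SM1)
  ord <- order(-tabulate(km$cluster, n_modes))
  relabel <- match(seq_len(n_modes), ord)
  structure(list(
    n_modes = n_modes, n_points = n_points, center = pca$center,
    mean_contour = mean_contour,
    rotation = pca$rotation[, seq_len(k), drop = FALSE],
    centroids = km$centers[ord, , drop = FALSE],
    explained = evr, n_pcs = k,
    train_labels = relabel[km$cluster],
    kept = which(ok),
    manifest = list(seed = seed, variance_target = variance_target,
                    nstart = nstart, n_train = length(contours))),
    class = "shape_mode_model")
}

#' @export
print.shape_mode_model <- function(x, ...) {
  cat(sprintf(
    "shape_mode_model: %d modes, %d registration points, %d PCs (%d cells)\n",
    x$n_modes, x$n_points, x$n_pcs, x$manifest$n_train))
  invisible(x)
}

# Project masks into the model's PC space and return the nearest mode.
shape_mode_labels <- function(model, masks) {
  vapply(masks, function(m) {
    ct <- extract_contour(m, model$n_points)
    if (is.null(ct)) return(NA_integer_)
    reg <- register_contour(ct)
    if (is.null(reg)) return(NA_integer_)
    z <- (as.vector(reg) - model$center) %*% model$rotation
    d2 <- rowSums(sweep(model$centroids, 2, z)^2)
    which.min(d2)
  }, integer(1))
}

#' Assign shape modes and tabulate their distribution
#'
#' Classifies each cell into one of the fitted shape modes and reports, per
#' stratum (default group x region), the SM1..SMk proportions plus the
#' scaled total cell count (test-partition counts multiplied by
#' `count_scale`, the x5 estimate of totals from the 20% test images).
#'
#' @param model a [fit_shape_modes()] model.
#' @param masks list of cell masks.
#' @param metadata optional data.frame (one row per mask) with stratum
#'   columns; defaults to each mask's own metadata.
#' @param strata character vector of metadata columns defining strata.
#' @param count_scale factor applied to test counts to estimate totals.
#' @return list of class `shape_mode_distribution`: `labels` (per cell),
#'   `distribution` (per-stratum proportions, counts, scaled totals).
#' @export
assign_shape_modes <- function(model, masks, metadata = NULL,
                               strata = c("group", "region"),
                               count_scale = 5) {
  stopifnot(inherits(model, "shape_mode_model"))
  labels <- shape_mode_labels(model, masks)
  if (is.null(metadata)) {
    metadata <- do.call(rbind, lapply(masks, function(m) {
      md <- if (inherits(m, "cell_mask")) m$metadata else list()
      data.frame(group = md$group %||% NA, region = md$region %||% NA)
    }))
  }
  strata <- intersect(strata, names(metadata))
  key <- if (length(strata))
    interaction(metadata[strata], drop = TRUE, sep = " / ")
  else factor(rep("all", length(labels)))
  ok <- !is.na(labels)
  dist <- do.call(rbind, lapply(levels(key), function(s) {
    li <- labels[ok & key == s]
    counts <- tabulate(li, model$n_modes)
    props <- if (length(li)) counts / length(li) else rep(NA_real_,
                                                          model$n_modes)
    row <- data.frame(stratum = s, n_cells = length(li),
                      estimated_total = length(li) * count_scale)
    for (m in seq_len(model$n_modes))
      row[[sprintf("SM%d", m)]] <- props[m]
    row
  }))
  structure(list(labels = labels, distribution = dist,
                 count_scale = count_scale),
            class = "shape_mode_distribution")
}

#' @export
print.shape_mode_distribution <- function(x, ...) {
  print(x$distribution)
  invisible(x)
}
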
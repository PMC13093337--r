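#' Histology image container
#'
#' A 2-D grayscale intensity grid with physical pixel size and acquisition
#' metadata. All pipeline functions also accept a plain numeric matrix, which
#' is coerced with default metadata.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_size physical pixel side in micrometres (default 0.863).
#' @param region,group,slice,sex acquisition metadata.
#' @return an object of class `histology_image`.
#' @export
histology_image <- function(pixels, pixel_size = 0.863, region = NA_character_,
                            group = NA_character_, slice = NA_character_,
                            sex = NA_character_) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(dim(pixels)) != 2L)
    stop("pixels must be a numeric matrix")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 metadata = list(region = region, group = group,
                                 slice = slice, sex = sex)),
            class = "histology_image")
}

as_histology_image <- function(img, pixel_size = 0.863) {
  if (inherits(img, "histology_image")) img
  else histology_image(img, pixel_size = pixel_size)
}

#' @export
print.histology_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("histology_image %d x %d px (%.3f um/px), group=%s region=%s\n",
              d[1], d[2], x$pixel_size, x$metadata$group, x$metadata$region))
  invisible(x)
}

# Separable Gaussian blur with replicate (edge) padding, implemented as
# banded-matrix products so 512 x 512 images go through BLAS.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  h <- max(1L, ceiling(3 * sigma))
  w <- exp(-(-h:h)^2 / (2 * sigma^2))
  w <- w / sum(w)
  conv_mat <- function(n) {
    K <- matrix(0, n, n)
    i <- seq_len(n)
    for (k in -h:h) {
      j <- pmin(pmax(i + k, 1L), n)
      K[cbind(i, j)] <- K[cbind(i, j)] + w[k + h + 1L]
    }
    K
  }
  conv_mat(nrow(x)) %*% x %*% t(conv_mat(ncol(x)))
}

# 5-point discrete Laplacian, replicate padding.
laplacian4 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  up <- x[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- x[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- x[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- x[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up + dn + lf + rt - 4 * x
}

#' Otsu threshold
#'
#' Histogram-based threshold maximising between-class variance.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins number of histogram bins.
#' @return threshold value; foreground is `x > threshold`.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate image: constant intensities")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w1 <- cumsum(h)
  mu1 <- cumsum(h * mids)
  w2 <- w1[nbins] - w1
  mu2 <- mu1[nbins] - mu1
  valid <- w1 > 0 & w2 > 0
  bc <- rep(-Inf, nbins)
  bc[valid] <- w1[valid] * w2[valid] *
    (mu1[valid] / w1[valid] - mu2[valid] / w2[valid])^2
  mids[which.max(bc)]
}

# Coerce a pixel set (k x 2 matrix of row, col) or logical mask to a mask,
# cropped to the bounding box (shape measures are translation-invariant).
pixels_to_mask <- function(pixels) {
  if (is.logical(pixels) && is.matrix(pixels)) return(pixels)
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L) stop("pixel set must be a k x 2 (row, col) matrix")
  if (nrow(pixels) == 0L) stop("empty pixel set")
  r <- pixels[, 1] - min(pixels[, 1]) + 1L
  c <- pixels[, 2] - min(pixels[, 2]) + 1L
  m <- matrix(FALSE, max(r), max(c))
  m[cbind(r, c)] <- TRUE
  m
}

mask_to_pixels <- function(mask) {
  which(mask, arr.ind = TRUE)
}

#' Crofton four-direction perimeter
#'
#' Cauchy-Crofton perimeter estimate from boundary-crossing counts along the
#' four lattice directions (0, 45, 90, 135 degrees):
#' `P = (pi / 8) * (I0 + I90 + (I45 + I135) / sqrt(2)) * pixel_size`.
#'
#' @param pixels a k x 2 matrix of (row, col) member pixels, or a logical mask.
#' @param pixel_size physical pixel side (micrometres); 1 gives pixels.
#' @return perimeter estimate in `pixel_size` units.
#' @export
crofton_perimeter <- function(pixels, pixel_size = 1) {
  mask <- pixels_to_mask(pixels)
  if (!any(mask)) stop("empty pixel set")
  # pad so every run has a background transition on both sides
  nr <- nrow(mask) + 2L; nc <- ncol(mask) + 2L
  m <- matrix(FALSE, nr, nc)
  m[2:(nr - 1L), 2:(nc - 1L)] <- mask
  crossings <- function(mm) {
    # transitions along each row of mm
    d <- mm[, -1L, drop = FALSE] != mm[, -ncol(mm), drop = FALSE]
    sum(d)
  }
  i0 <- crossings(m)      # along rows (0 degrees)
  i90 <- crossings(t(m))  # along columns
  diag_crossings <- function(mm, anti = FALSE) {
    d <- dim(mm)
    idx <- if (anti) .row(d) + .col(d) else .col(d) - .row(d)
    segs <- split(as.vector(mm), as.vector(idx))
    sum(vapply(segs, function(v) {
      k <- length(v)
      inner <- if (k > 1L) sum(v[-1L] != v[-k]) else 0L
      inner + v[1L] + v[k]
    }, numeric(1)))
  }
  i45 <- diag_crossings(m, anti = TRUE)
  i135 <- diag_crossings(m, anti = FALSE)
  (pi / 8) * (i0 + i90 + (i45 + i135) / sqrt(2)) * pixel_size
}

#' Read / write grayscale images
#'
#' 16-bit grayscale PNG I/O (the installed imaging stack has no TIFF writer;
#' PNG is the supported on-disk format). Intensities are scaled to the
#' \[0, 1\] range on write by `max_value`.
#'
#' @param img a `histology_image` or numeric matrix.
#' @param path file path.
#' @param max_value intensity mapped to white; defaults to the image maximum.
#' @return `read_image` returns a numeric matrix in \[0, 1\] scaled units.
#' @export
write_image <- function(img, path, max_value = NULL) {
  m <- if (inherits(img, "histology_image")) img$pixels else as.matrix(img)
  if (is.null(max_value)) max_value <- max(m, 1e-12)
  png::writePNG(pmin(pmax(m / max_value, 0), 1), target = path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a
}
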
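# Shared fixtures, all built in code.

# Pixel set (row, col) of a digital disk of radius r centred in a canvas.
disk_pixels <- function(r, center = c(r + 5, r + 5)) {
  span <- seq(-r - 2, r + 2)
  xy <- expand.grid(dr = span, dc = span)
  xy <- xy[xy$dr^2 + xy$dc^2 <= r^2, ]
  cbind(row = xy$dr + center[1], col = xy$dc + center[2])
}

rect_pixels <- function(h, w, origin = c(5, 5)) {
  cbind(row = rep(origin[1] + seq_len(h) - 1L, w),
        col = rep(origin[2] + seq_len(w) - 1L, each = h))
}

mask_from_pixels <- function(px, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[px] <- TRUE
  m
}

# Multivariate normal draw via Cholesky (independent oracle for GGM tests).
rmvnorm_chol <- function(n, sigma) {
  p <- ncol(sigma)
  matrix(rnorm(n * p), n, p) %*% chol(sigma)
}

# Two-class nucleus-feature table: the pyknotic class is shifted by d SDs on
# the size/intensity features, mirroring how condensed nuclei differ.
synthetic_feature_table <- function(n_per_class, d = 2, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_class
  lab <- rep(c(TRUE, FALSE), each = n_per_class)
  shift <- function(delta) ifelse(lab, delta, 0)
  data.frame(
    A = rnorm(n, 20, 4) - shift(d * 4),
    P = rnorm(n, 16, 3) - shift(d * 3),
    r_I = rnorm(n, 2.5, 0.5) - shift(d * 0.5),
    eps = rnorm(n, 1, 0.05),
    I_M = rnorm(n, 1, 0.3) + shift(d * 0.3),
    I_T = rnorm(n, 20, 5),
    I_W = rnorm(n, 0.4, 0.1) + shift(d * 0.1),
    sigma = rnorm(n, 3, 0.8) - shift(d * 0.8),
    label = lab)
}

# Match detections to a truth table by nearest centre; returns per-truth and
# per-detection matched flags (brute-force pairwise distances).
match_detections <- function(det, truth, tol = 3) {
  if (nrow(det) == 0L || nrow(truth) == 0L)
    return(list(truth_matched = logical(nrow(truth)),
                det_matched = logical(nrow(det)),
                det_truth_idx = integer(nrow(det))))
  d <- sqrt(outer(truth$row, det$row, "-")^2 +
            outer(truth$col, det$col, "-")^2)
  list(truth_matched = apply(d, 1, min) <= tol,
       det_matched = apply(d, 2, min) <= tol,
       det_truth_idx = apply(d, 2, which.min))
}

# Labelled feature table harvested from generated nucleus fields: detections
# matched to ground truth within 3 px inherit the planted pyknosis label.
generator_training_features <- function(seeds, n_nuclei = 120L) {
  out <- list()
  for (s in seeds) {
    cfg <- sim_config(seed = s, n_nuclei = n_nuclei,
                      pyknotic_fraction = 0.25, min_separation = 10)
    g <- gen_nuclei_image(cfg)
    pre <- preprocess_image(g$image)
    det <- detect_nuclei(pre)
    feats <- nucleus_feature_table(pre, det)
    m <- match_detections(det, g$truth)
    keep <- m$det_matched
    feats <- feats[keep, , drop = FALSE]
    feats$label <- g$truth$pyknotic[m$det_truth_idx[keep]]
    out[[length(out) + 1L]] <- feats
  }
  do.call(rbind, out)
}
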
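#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of a score for a binary label.
#'
#' @param scores numeric scores, larger = more likely positive.
#' @param labels logical (or 0/1) vector, `TRUE` = positive class.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("auroc needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster label vectors of equal length.
#' @return adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(0)
  (sum_ij - expected) / (maxidx - expected)
}

# Geometric mean of strictly positive values.
geomean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires positive values")
  exp(mean(log(x)))
}

# Derive a 32-bit sub-seed from a base seed and a stream offset.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}
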
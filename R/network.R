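#' Maximum-likelihood precision matrix
#'
#' Inverse of the n-denominator (MLE) sample covariance. No regularization:
#' with fewer observations than variables, or a singular covariance, this is
#' an error rather than a silent ridge fallback.
#'
#' @param x numeric matrix or data.frame (rows = observations, columns =
#'   variables).
#' @return the p x p precision matrix.
#' @export
precision_mle <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (n <= p)
    stop("insufficient observations for MLE precision (need n > p)")
  if (any(apply(x, 2, sd) == 0))
    stop("constant column(s) in the observation matrix")
  S <- cov(x) * (n - 1) / n
  theta <- tryCatch(solve(S), error = function(e)
    stop("insufficient observations for MLE precision: singular covariance"))
  dimnames(theta) <- dimnames(S)
  theta
}

#' Partial correlations from a precision matrix
#'
#' `rho_ij = -theta_ij / sqrt(theta_ii * theta_jj)`, diagonal set to 1.
#'
#' @param theta precision matrix.
#' @return partial correlation matrix.
#' @export
partial_correlations <- function(theta) {
  d <- sqrt(diag(theta))
  p <- -theta / tcrossprod(d)
  diag(p) <- 1
  p
}

#' Fisher-Z edge selection for a partial-correlation network
#'
#' For each variable pair, `z = atanh(rho)` with standard error
#' `1 / sqrt(n - (p - 2) - 3)` (the partial-correlation degrees-of-freedom
#' correction with `p - 2` conditioned variables); the confidence interval is
#' transformed back by `tanh` and an edge is significant iff it excludes 0.
#'
#' @param pcors partial correlation matrix.
#' @param n number of observations.
#' @param p number of variables (defaults to `ncol(pcors)`).
#' @param level confidence level.
#' @return object of class `pcor_network`: the matrix plus an `edges`
#'   data.frame (i, j, var_i, var_j, pcor, ci_low, ci_high, significant).
#' @export
fisher_z_edges <- function(pcors, n, p = ncol(pcors), level = 0.95) {
  df <- n - (p - 2) - 3
  if (df <= 0)
    stop("too few observations for the Fisher-Z interval (need n > p + 1)")
  vars <- colnames(pcors)
  if (is.null(vars)) vars <- sprintf("V%d", seq_len(ncol(pcors)))
  se <- 1 / sqrt(df)
  zc <- qnorm(1 - (1 - level) / 2)
  idx <- which(upper.tri(pcors), arr.ind = TRUE)
  r <- pmin(pmax(pcors[idx], -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r)
  lo <- tanh(z - zc * se)
  hi <- tanh(z + zc * se)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      var_i = vars[idx[, 1]], var_j = vars[idx[, 2]],
                      pcor = pcors[idx], ci_low = lo, ci_high = hi,
                      significant = lo > 0 | hi < 0)
  structure(list(pcors = pcors, n = n, p = p, level = level, edges = edges),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  cat(sprintf("pcor_network: %d variables, n = %d, %d/%d significant edges at %.0f%%\n",
              x$p, x$n, sum(x$edges$significant), nrow(x$edges),
              100 * x$level))
  invisible(x)
}

#' Gaussian graphical network from an observation table
#'
#' Convenience wrapper: MLE precision, partial correlations, Fisher-Z edges.
#'
#' @param x observation matrix/data.frame.
#' @param level confidence level.
#' @return a `pcor_network`.
#' @export
ggm_network <- function(x, level = 0.95) {
  x <- as.matrix(x)
  fisher_z_edges(partial_correlations(precision_mle(x)), n = nrow(x),
                 p = ncol(x), level = level)
}

#' Condition-vs-variables network
#'
#' Appends a binary 0/1 condition indicator (e.g. OGD vs control) as a node
#' and computes the partial-correlation network; edges incident to the
#' condition node are reported as condition effects.
#'
#' @param data data.frame of continuous variables plus one condition column.
#' @param condition name of the condition column.
#' @param levels optional length-2 character vector giving the (0, 1)
#'   coding order; defaults to order of first appearance in the data.
#' @param level confidence level.
#' @return a `pcor_network` with a `condition_effects` element (edges
#'   touching the condition node).
#' @export
condition_network <- function(data, condition, levels = NULL, level = 0.95) {
  stopifnot(condition %in% names(data))
  cl <- data[[condition]]
  u <- if (is.null(levels)) unique(as.character(cl)) else levels
  if (length(u) != 2L)
    stop("condition must have exactly two levels (compare pairwise)")
  num <- as.numeric(as.character(cl) == u[2])
  vars <- data[, setdiff(names(data), condition), drop = FALSE]
  X <- cbind(as.matrix(vars), setNames(data.frame(num), condition))
  net <- ggm_network(as.matrix(X), level = level)
  ce <- net$edges[net$edges$var_i == condition |
                    net$edges$var_j == condition, ]
  net$condition_effects <- ce
  net$condition <- condition
  net$coding <- setNames(c(0, 1), u)
  net
}

#' Export a partial-correlation network
#'
#' `network_to_igraph` builds an igraph graph (edge attributes: pcor, sign,
#' weight = |pcor|, significant); `write_network_graphml` writes GraphML for
#' network viewers, `write_network_edges` the edge-list CSV.
#'
#' @param net a `pcor_network`.
#' @param significant_only keep only significant edges.
#' @return an igraph object / the path, invisibly.
#' @export
network_to_igraph <- function(net, significant_only = TRUE) {
  e <- net$edges
  if (significant_only) e <- e[e$significant, , drop = FALSE]
  vars <- colnames(net$pcors)
  if (is.null(vars)) vars <- sprintf("V%d", seq_len(ncol(net$pcors)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$var_i, to = e$var_j, pcor = e$pcor,
               weight = abs(e$pcor), sign = sign(e$pcor),
               significant = e$significant),
    directed = FALSE, vertices = data.frame(name = vars))
  g
}

#' @param path output file path.
#' @rdname network_to_igraph
#' @export
write_network_graphml <- function(net, path, significant_only = TRUE) {
  igraph::write_graph(network_to_igraph(net, significant_only), path,
                      format = "graphml")
  invisible(path)
}

#' @rdname network_to_igraph
#' @export
write_network_edges <- function(net, path) {
  write.csv(net$edges, path, row.names = FALSE)
  invisible(path)
}
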
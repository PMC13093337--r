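#' Normalize a targeted expression panel
#'
#' Per-sample geometric-mean scaling followed by `log2(x + 1)`. Each sample's
#' counts are divided by the geometric mean of its housekeeping transcripts
#' (or of all transcripts positive in every sample, when no housekeeping
#' list is supplied), making the result invariant to global per-sample
#' scaling. Matrices already on the log2 scale should skip this step.
#'
#' @param counts matrix, transcripts x samples, non-negative counts.
#' @param housekeeping optional character vector of housekeeping transcript
#'   names (rownames of `counts`).
#' @return log2-scale matrix of the same shape.
#' @export
normalize_expression <- function(counts, housekeeping = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("all-zero sample(s) present")
  if (is.null(housekeeping)) {
    hk <- rowSums(counts <= 0) == 0L
    if (!any(hk)) stop("no transcript is positive in all samples")
    hk_counts <- counts[hk, , drop = FALSE]
  } else {
    miss <- setdiff(housekeeping, rownames(counts))
    if (length(miss))
      stop(sprintf("housekeeping transcripts not in panel: %s",
                   paste(miss, collapse = ", ")))
    hk_counts <- counts[housekeeping, , drop = FALSE]
    if (any(hk_counts <= 0))
      stop("housekeeping transcripts must be positive in every sample")
  }
  g <- apply(hk_counts, 2, geomean)
  log2(sweep(counts, 2, g, "/") + 1)
}

#' Differential expression between two groups
#'
#' Per-transcript Welch t-test on log2 values with
#' `log2FC = mean(groupA) - mean(groupB)`; antisymmetric under swapping the
#' groups. Direction follows volcano semantics for `groupA` vs `groupB`
#' (positive = up in `groupA`). Raw p-values are thresholded at `p_cut`
#' (no multiple-testing correction by default; set `adjust = "BH"` to add
#' one).
#'
#' @param values log2 expression matrix (transcripts x samples).
#' @param meta sample metadata with a `group` column (and optionally
#'   `region`).
#' @param group_a,group_b group labels; `group_b` is the reference.
#' @param region optional region to restrict samples to.
#' @param p_cut significance threshold on the (possibly adjusted) p-value.
#' @param lfc_cut optional absolute log2-fold-change threshold.
#' @param adjust `"none"` (default) or a [p.adjust()] method.
#' @return data.frame of class `deg_table`: transcript, log2fc, t, p,
#'   significant, direction.
#' @export
differential_expression <- function(values, meta, group_a, group_b,
                                    region = NULL, p_cut = 0.05,
                                    lfc_cut = NULL, adjust = "none") {
  values <- as.matrix(values)
  stopifnot(ncol(values) == nrow(meta))
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(region)) keep <- meta$region == region
  ia <- which(keep & meta$group == group_a)
  ib <- which(keep & meta$group == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs >= 2 samples (group missing or too small)")
  A <- values[, ia, drop = FALSE]
  B <- values[, ib, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, var); vb <- apply(B, 1, var)
  na <- length(ia); nb <- length(ib)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p_use <- if (adjust == "none") p else p.adjust(p, method = adjust)
  lfc <- ma - mb
  sig <- p_use < p_cut
  if (!is.null(lfc_cut)) sig <- sig & abs(lfc) >= abs(lfc_cut)
  out <- data.frame(transcript = rownames(values), log2fc = lfc, t = tstat,
                    p = p, significant = sig,
                    direction = ifelse(lfc > 0, "up", "down"),
                    row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' PCA with 95%-variance component selection
#'
#' PCA of samples on transcript-wise-centred normalized values (no
#' unit-variance scaling, keeping contributions on the expression scale).
#' The selected component count `k` is the smallest number of leading PCs
#' whose cumulative explained variance reaches `variance_target`.
#'
#' @param values log2 expression matrix (transcripts x samples).
#' @param variance_target cumulative explained-variance target.
#' @return object of class `pc_model`: rotation (loadings, transcripts x
#'   PCs), scores (samples x PCs), explained-variance ratios, contributions
#'   (%, per PC), selected `k`.
#' @export
pca_select <- function(values, variance_target = 0.95) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("PCA needs >= 2 samples")
  pca <- prcomp(t(values), center = TRUE, scale. = FALSE)
  evr <- pca$sdev^2 / sum(pca$sdev^2)
  k <- which(cumsum(evr) >= variance_target)[1]
  contrib <- 100 * sweep(pca$rotation^2, 2, colSums(pca$rotation^2), "/")
  structure(list(rotation = pca$rotation, scores = pca$x,
                 explained = evr, contributions = contrib, k = k,
                 center = pca$center,
                 variance_target = variance_target),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model: %d PCs reach %.0f%% variance (of %d components)\n",
              x$k, 100 * x$variance_target, length(x$explained)))
  invisible(x)
}

#' Top contributing transcripts of a principal component
#'
#' Contribution of transcript i to a PC is `100 * loading_i^2 / sum(loading^2)`.
#'
#' @param model a [pca_select()] model.
#' @param pc component index.
#' @param k number of top transcripts (clamped to the panel size).
#' @return data.frame: transcript, contribution, loading, descending by
#'   contribution.
#' @export
top_contributors <- function(model, pc, k = 25L) {
  stopifnot(inherits(model, "pc_model"))
  if (pc > ncol(model$rotation)) stop("pc exceeds fitted components")
  contrib <- model$contributions[, pc]
  ord <- order(-contrib)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(transcript = rownames(model$rotation)[ord],
             contribution = contrib[ord],
             loading = model$rotation[ord, pc], row.names = NULL)
}

#' Venn partition of named DEG sets
#'
#' Assigns every transcript appearing in at least one set to exactly one of
#' the 2^m - 1 non-empty membership regions.
#'
#' @param sets named list of character vectors.
#' @return data.frame: transcript, region (e.g. `"A&B"`), plus one logical
#'   column per set.
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  all_t <- sort(unique(unlist(sets)))
  if (!length(all_t))
    return(data.frame(transcript = character(0), region = character(0)))
  memb <- vapply(sets, function(s) all_t %in% s, logical(length(all_t)))
  memb <- matrix(memb, nrow = length(all_t),
                 dimnames = list(NULL, names(sets)))
  region <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  cbind(data.frame(transcript = all_t, region = region), as.data.frame(memb))
}

#' Transcripts normalized by the combination only
#'
#' The combination-subthresholding transcript filter: transcripts that are
#' (i) significantly dysregulated by OGD vs control, (ii) no longer
#' significant under the combination (normalized by AzEpo), yet (iii, iv)
#' still significant under each monotherapy. With
#' `definition = "reversed"`, treatment tables must instead be vs-OGD
#' comparisons and "normalized" means a significant shift opposite in sign
#' to the OGD effect (combination significant-and-reversed, monotherapies
#' not).
#'
#' @param deg_ogd OGD vs control [differential_expression()] table.
#' @param deg_az,deg_epo,deg_azepo treatment DEG tables (vs control for the
#'   default definition, vs OGD for `"reversed"`).
#' @param definition `"not_significant"` (default) or `"reversed"`.
#' @return character vector of transcript names.
#' @export
combo_normalized_transcripts <- function(deg_ogd, deg_az, deg_epo, deg_azepo,
                                         definition = c("not_significant",
                                                        "reversed")) {
  definition <- match.arg(definition)
  tabs <- list(deg_ogd, deg_az, deg_epo, deg_azepo)
  ids <- lapply(tabs, function(t) t$transcript)
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("DEG tables are not on the same panel")
  ogd_sig <- deg_ogd$significant
  if (definition == "not_significant") {
    sel <- ogd_sig & !deg_azepo$significant & deg_az$significant &
      deg_epo$significant
  } else {
    reversed <- function(t) t$significant & sign(t$log2fc) == -sign(deg_ogd$log2fc)
    sel <- ogd_sig & reversed(deg_azepo) & !reversed(deg_az) &
      !reversed(deg_epo)
  }
  deg_ogd$transcript[sel]
}

#' Hypergeometric gene-set enrichment
#'
#' Local substitute for web gene-set enrichment tools: one-sided
#' hypergeometric tail p per set with Benjamini-Hochberg adjustment across
#' sets, plus fold enrichment
#' `(overlap / query) / (set size / universe size)`.
#'
#' @param query character vector of hit transcripts (subset of `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all testable transcripts.
#' @return data.frame: set, set_size, overlap, fold_enrichment, p,
#'   p_adjusted; ascending by p.
#' @export
geneset_enrichment <- function(query, gene_sets, universe) {
  if (!length(query)) stop("empty query")
  if (!all(query %in% universe)) stop("query must be a subset of universe")
  if (any(!vapply(gene_sets, length, integer(1)))) stop("empty gene set")
  N <- length(universe)
  q <- length(unique(query))
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    m <- length(s)
    k <- length(intersect(query, s))
    p <- phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    fe <- if (m > 0) (k / q) / (m / N) else NA_real_
    data.frame(set = nm, set_size = m, overlap = k, fold_enrichment = fe,
               p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line (need name, desc, genes)")
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @param gene_sets named list of character vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path) {
  writeLines(vapply(names(gene_sets), function(nm)
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}
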
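#' Build the emergence-analysis input
#'
#' Per transcript: mean log-transformed normalized expression in the four
#' predictor groups (control, OGD, Az, Epo) and the combination target
#' (AzEpo), within a scope (global pools all regions; otherwise one region).
#'
#' @param values log2 expression matrix (transcripts x samples).
#' @param meta sample metadata with `group` and `region` columns.
#' @param scope `"global"` or a region name present in `meta$region`.
#' @param target combination group label.
#' @return data.frame of class `emergence_input`: transcript, control, OGD,
#'   Az, Epo, target columns.
#' @export
build_emergence_input <- function(values, meta, scope = "global",
                                  target = "AzEpo") {
  values <- as.matrix(values)
  stopifnot(ncol(values) == nrow(meta))
  keep <- if (identical(scope, "global")) rep(TRUE, nrow(meta))
  else meta$region == scope
  if (!any(keep)) stop(sprintf("scope '%s' has zero samples", scope))
  groups <- c("control", "OGD", "Az", "Epo", target)
  means <- sapply(groups, function(g) {
    idx <- which(keep & meta$group == g)
    if (!length(idx)) stop(sprintf("group '%s' missing in scope '%s'", g,
                                   scope))
    rowMeans(values[, idx, drop = FALSE])
  })
  out <- data.frame(transcript = rownames(values), means[, 1:4],
                    target = means[, 5], row.names = NULL)
  names(out)[2:5] <- groups[1:4]
  attr(out, "scope") <- scope
  class(out) <- c("emergence_input", "data.frame")
  out
}

#' Pre-validated (out-of-fold) predictions of combination expression
#'
#' Transcripts are partitioned into `folds` seeded folds; each fold's target
#' (mean combination-group expression) is predicted by a bagged-tree
#' regressor trained only on the other folds, so no transcript's own target
#' influences its prediction.
#'
#' @param input an [build_emergence_input()] table.
#' @param folds number of cross-validation folds.
#' @param seed integer seed (folds and tree growth).
#' @param ntree trees per fold model.
#' @param ... passed to [owh_forest()].
#' @return `input` with `predicted` and `fold` columns.
#' @export
cv_predict <- function(input, folds = 10L, seed = 1L, ntree = 100L, ...) {
  n <- nrow(input)
  if (n < folds) stop("fewer transcripts than folds")
  X <- as.matrix(input[, c("control", "OGD", "Az", "Epo")])
  y <- input$target
  set.seed(sub_seed(seed, 51L))
  fold <- sample(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- owh_forest(X[tr, , drop = FALSE], y[tr], ntree = ntree,
                      minsplit = 5L, ...)
    pred[fold == f] <- predict(fit, X[fold == f, , drop = FALSE])
  }
  input$predicted <- pred
  input$fold <- fold
  input
}

#' Prediction-interval outlier flags
#'
#' OLS of measured on predicted expression, with standard prediction
#' intervals evaluated at each transcript's predicted value. Transcripts
#' outside the 95% / 99% intervals are flagged; `z_diff` is the absolute
#' predicted-measured difference in SD units (`sd_reference = "measured"`:
#' SD of the measured values across transcripts in scope, the default;
#' `"residual"`: the regression residual SD).
#'
#' @param predicted numeric vector of pre-validated predictions (or a
#'   [cv_predict()] result, in which case `measured` is taken from it).
#' @param measured numeric vector of measured combination-group means.
#' @param levels prediction-interval levels (larger must nest inside
#'   smaller's complement; flags are named `flag95`, `flag99` for the
#'   defaults).
#' @param sd_reference reference SD for `z_diff`.
#' @return data.frame of class `emergence_report`: transcript, predicted,
#'   measured, residual, flag columns, z_diff, direction.
#' @export
prediction_interval_flags <- function(predicted, measured = NULL,
                                      levels = c(0.95, 0.99),
                                      sd_reference = c("measured",
                                                       "residual")) {
  sd_reference <- match.arg(sd_reference)
  transcript <- NULL
  if (is.data.frame(predicted)) {
    transcript <- predicted$transcript
    measured <- predicted$target
    predicted <- predicted$predicted
  }
  stopifnot(length(predicted) == length(measured))
  n <- length(predicted)
  if (n < 10L) stop("need >= 10 transcripts for prediction intervals")
  if (sd(predicted) == 0) stop("zero variance in predictions")
  fit <- lm(measured ~ predicted)
  res <- measured - fitted(fit)
  s <- sqrt(sum(res^2) / (n - 2))
  # numerically exact fit: no residual scale, nothing can be an outlier
  if (s <= 1e-10 * max(1, sd(measured))) res[] <- 0
  xbar <- mean(predicted)
  sxx <- sum((predicted - xbar)^2)
  se_pred <- s * sqrt(1 + 1 / n + (predicted - xbar)^2 / sxx)
  out <- data.frame(
    transcript = transcript %||% sprintf("T%03d", seq_len(n)),
    predicted = predicted, measured = measured, residual = res)
  for (lv in sort(levels)) {
    tc <- qt(1 - (1 - lv) / 2, df = n - 2)
    out[[sprintf("flag%g", 100 * lv)]] <- abs(res) > tc * se_pred
  }
  ref_sd <- if (sd_reference == "measured") sd(measured) else s
  out$z_diff <- abs(measured - predicted) / ref_sd
  out$direction <- ifelse(measured >= predicted, "over", "under")
  class(out) <- c("emergence_report", "data.frame")
  out
}

#' Summarise emergence reports across scopes
#'
#' Collects flagged transcripts from per-scope reports, sorted by `z_diff`
#' within scope, with their interval tier (99% tier nests inside 95%) and
#' direction.
#'
#' @param reports a single `emergence_report` or a named list of them (names
#'   = scopes).
#' @return data.frame: scope, transcript, predicted, measured, z_diff,
#'   direction, tier ("95%" or "99%").
#' @export
emergence_summary <- function(reports) {
  if (is.data.frame(reports)) reports <- list(global = reports)
  rows <- lapply(names(reports), function(sc) {
    r <- reports[[sc]]
    flagged <- r[r$flag95, , drop = FALSE]
    if (!nrow(flagged)) return(NULL)
    flagged <- flagged[order(-flagged$z_diff), ]
    data.frame(scope = sc, transcript = flagged$transcript,
               predicted = flagged$predicted, measured = flagged$measured,
               z_diff = flagged$z_diff, direction = flagged$direction,
               tier = ifelse(flagged$flag99, "99%", "95%"))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(scope = character(0), transcript = character(0),
                      predicted = numeric(0), measured = numeric(0),
                      z_diff = numeric(0), direction = character(0),
                      tier = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
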
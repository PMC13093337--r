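#' Bagged CART forest
#'
#' Random forest built from bagged CART regression trees with per-node
#' feature subsampling (`mtry`). Binary classification uses the
#' probability-machine formulation: trees are grown on the 0/1 label with
#' variance splits (equivalent to Gini up to a constant factor) and the
#' forest average is the class-1 probability.
#'
#' Tree growth consumes R's RNG stream, so `set.seed()` before fitting makes
#' the forest fully reproducible.
#'
#' @param x numeric matrix or data frame of predictors (rows = observations).
#' @param y numeric response, or logical/factor for binary classification.
#' @param ntree number of trees.
#' @param mtry features tried per split; default `floor(sqrt(p))` for
#'   classification, `max(1, floor(p / 3))` for regression.
#' @param minsplit minimum node size eligible for splitting.
#' @param maxdepth maximum tree depth.
#' @return an object of class `owh_forest`.
#' @export
owh_forest <- function(x, y, ntree = 200L, mtry = NULL, minsplit = 5L,
                       maxdepth = 25L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  classification <- is.logical(y) || is.factor(y)
  lev <- NULL
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2L)
      stop("owh_forest classification requires exactly two classes")
    y <- droplevels(y)
    lev <- levels(y)
    y <- as.numeric(y == lev[2L])
  } else if (is.logical(y)) {
    lev <- c("FALSE", "TRUE")
    y <- as.numeric(y)
  }
  stopifnot(length(y) == nrow(x))
  p <- ncol(x)
  if (is.null(mtry))
    mtry <- if (classification) max(1L, floor(sqrt(p))) else
      max(1L, floor(p / 3))
  n <- nrow(x)
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    rows <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree_cpp(x, y, rows, as.integer(mtry),
                                as.integer(minsplit), as.integer(maxdepth))
  }
  structure(list(trees = trees, classification = classification,
                 levels = lev, mtry = mtry, ntree = ntree,
                 features = colnames(x)),
            class = "owh_forest")
}

#' @param object an `owh_forest`.
#' @param newdata matrix/data frame with the training columns.
#' @param type `"response"` (regression value or class-1 probability) or
#'   `"class"` (classification only).
#' @param ... unused.
#' @rdname owh_forest
#' @export
predict.owh_forest <- function(object, newdata, type = c("response", "class"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  storage.mode(newdata) <- "double"
  acc <- numeric(nrow(newdata))
  for (tr in object$trees) acc <- acc + predict_tree_cpp(tr, newdata)
  resp <- acc / length(object$trees)
  if (type == "class") {
    if (!object$classification) stop("type = 'class' requires a classifier")
    factor(object$levels[1L + (resp > 0.5)], levels = object$levels)
  } else resp
}

#' @export
print.owh_forest <- function(x, ...) {
  cat(sprintf("Bagged CART forest: %d trees, mtry = %d (%s)\n", x$ntree,
              x$mtry, if (x$classification) "classification" else
                "regression"))
  invisible(x)
}
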
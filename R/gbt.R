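#' Default gradient-boosted tree hyperparameters
#'
#' Small-sample-safe defaults: 200 rounds, learning rate 0.1, depth-3 trees,
#' L2 regularization 1, softmax multiclass objective over the 6 severity
#' classes.
#'
#' @return named list of hyperparameters.
#' @export
gbt_params <- function(nrounds = 200L, eta = 0.1, max_depth = 3L,
                       lambda = 1, min_child_weight = 1e-3, n_classes = 6L) {
  list(nrounds = as.integer(nrounds), eta = eta, max_depth = as.integer(max_depth),
       lambda = lambda, min_child_weight = min_child_weight,
       n_classes = as.integer(n_classes))
}

#' Train the gradient-boosted tree ensemble
#'
#' Multiclass (severity 0-5) boosted trees with exact greedy splits and
#' Newton leaf weights; training is fully deterministic for identical inputs.
#' Per-tree gain records are retained for [feature_importance()].
#'
#' @param X numeric feature matrix (rows = assessments) with column names.
#' @param y integer labels 0-5, one per row.
#' @param params hyperparameters from [gbt_params()].
#' @param seed accepted for interface symmetry; the exact greedy builder uses
#'   no randomness.
#' @return a `gbt_model`.
#' @export
train_gbt <- function(X, y, params = gbt_params(), seed = 0L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y))
    abort_input("train_gbt: X rows and labels differ in length")
  if (any(y < 0L | y >= params$n_classes))
    abort_input(sprintf("train_gbt: labels must lie in 0-%d", params$n_classes - 1L))
  if (length(unique(y)) < 2L)
    abort_input("train_gbt: training set has a single label; cannot fit")
  if (is.null(colnames(X)))
    abort_input("train_gbt: feature matrix must have column names")

  fit <- gbt_train_cpp(X, y, params$n_classes, params$nrounds, params$eta,
                       params$max_depth, params$lambda, params$min_child_weight)
  structure(list(trees = fit$trees, tree_class = fit$tree_class,
                 tree_gain = fit$tree_gain, feature_names = colnames(X),
                 params = params, seed = as.integer(seed)),
            class = "gbt_model")
}

align_features <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || !setequal(colnames(X), model$feature_names))
    abort_consistency("predict: feature names do not match the training schema")
  X <- X[, model$feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  X
}

#' Predict severity labels
#'
#' @param object a `gbt_model`.
#' @param newdata feature matrix with the training column names (any order).
#' @param type `"class"` (integer labels) or `"margin"` (raw per-class scores).
#' @param ... unused.
#' @return integer labels 0..K-1, or a margin matrix.
#' @export
predict.gbt_model <- function(object, newdata, type = c("class", "margin"), ...) {
  type <- match.arg(type)
  if (NROW(newdata) == 0L)
    return(if (type == "class") integer(0) else
      matrix(numeric(0), 0, object$params$n_classes))
  X <- align_features(object, newdata)
  margin <- gbt_margin_cpp(object$trees, object$tree_class, X,
                           object$params$n_classes)
  if (type == "margin") return(margin)
  as.integer(max.col(margin, ties.method = "first") - 1L)
}

#' Gain-based feature importance averaged over folds
#'
#' Within each fold's model: for each feature, the mean gain over the trees
#' in which that feature was used (0 if never used). The per-fold values are
#' then averaged across folds and sorted in decreasing order.
#'
#' @param models list of `gbt_model` objects (one per fold).
#' @return named numeric, sorted decreasing.
#' @export
feature_importance <- function(models) {
  if (inherits(models, "gbt_model")) models <- list(models)
  if (length(models) == 0L)
    abort_input("feature_importance: need at least one fitted model")
  fnames <- models[[1]]$feature_names
  per_fold <- vapply(models, function(m) {
    if (is.null(m$tree_gain))
      abort_capability("feature_importance: model lacks gain records")
    if (!identical(m$feature_names, fnames))
      abort_consistency("feature_importance: models disagree on feature names")
    gain <- m$tree_gain                       # trees x features
    used <- gain > 0
    total <- colSums(gain)
    n_used <- colSums(used)
    ifelse(n_used > 0, total / pmax(n_used, 1L), 0)
  }, numeric(length(fnames)))
  imp <- rowMeans(per_fold)
  names(imp) <- fnames
  sort(imp, decreasing = TRUE)
}
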
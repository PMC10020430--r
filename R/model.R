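# Dataset assembly, subject-grouped stratified splitting, metrics with
# bootstrap and permutation inference, and the full train/evaluate experiment.

#' Assemble a labeled dataset
#'
#' @param features data.frame or matrix of feature values with a
#'   `subject_id` column (data.frame) or rownames (matrix), 141 named feature
#'   columns.
#' @param labels data.frame with `subject_id` and `label` (integers 0-5;
#'   label 6, anarthria, is rejected as it is excluded from modeling).
#' @return a `labeled_dataset`: `X` (matrix), `labels`, `subject_id`.
#' @export
labeled_dataset <- function(features, labels) {
  if (is.data.frame(features)) {
    if (!"subject_id" %in% names(features))
      abort_input("labeled_dataset: features need a subject_id column")
    sid <- as.character(features$subject_id)
    X <- as.matrix(features[, setdiff(names(features), "subject_id"), drop = FALSE])
  } else {
    X <- as.matrix(features)
    sid <- rownames(X)
    if (is.null(sid)) abort_input("labeled_dataset: feature matrix needs rownames")
  }
  storage.mode(X) <- "double"
  lab_map <- stats::setNames(as.integer(labels$label), as.character(labels$subject_id))
  if (any(is.na(lab_map)))
    abort_input("labeled_dataset: non-integer labels")
  if (any(lab_map > 5L | lab_map < 0L))
    abort_input(paste("labeled_dataset: labels must lie in 0-5; label 6",
                      "(anarthria) is excluded from the modeling range"))
  if (!all(sid %in% names(lab_map)))
    abort_input("labeled_dataset: some assessments have no label")
  structure(list(X = X, labels = unname(lab_map[sid]), subject_id = sid),
            class = "labeled_dataset")
}

#' Subject-grouped, label-stratified split into hold-out + k folds
#'
#' All assessments of one subject travel together; allocation is stratified
#' by the subject's (first) label where group sizes permit; deterministic
#' given the seed.
#'
#' @param ds a `labeled_dataset`.
#' @param holdout_n number of subjects in the hold-out set (0 for pure CV).
#' @param n_folds number of cross-validation folds (>= 2).
#' @param seed integer seed.
#' @return a `split_plan`: `holdout_ids`, `folds` (list of subject-id
#'   vectors), `seed`.
#' @export
make_split <- function(ds, holdout_n, n_folds = 6L, seed = 1L) {
  holdout_n <- as.integer(holdout_n)
  n_folds <- as.integer(n_folds)
  if (holdout_n < 0L) abort_param("make_split: holdout_n must be >= 0")
  if (n_folds < 2L) abort_param("make_split: n_folds must be >= 2")

  subj <- unique(ds$subject_id)
  subj_label <- vapply(subj, function(s)
    ds$labels[match(s, ds$subject_id)], integer(1))
  if (length(subj) < holdout_n + n_folds)
    abort_input(sprintf(
      "make_split: %d subjects cannot fill holdout %d + %d folds",
      length(subj), holdout_n, n_folds))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  # shuffle within label, concatenate by label, then deal:
  # first holdout_n positions of a label-balanced deal -> holdout,
  # remainder dealt round-robin over folds.
  by_label <- split(subj, subj_label)
  shuffled <- unlist(lapply(by_label, function(g) g[sample.int(length(g))]),
                     use.names = FALSE)
  # interleave labels so both holdout and folds see the label spectrum
  order_idx <- order(unlist(lapply(by_label, function(g) seq_along(g)),
                            use.names = FALSE))
  dealt <- shuffled[order_idx]

  holdout_ids <- if (holdout_n > 0L) dealt[seq_len(holdout_n)] else character(0)
  rest <- dealt[setdiff(seq_along(dealt), seq_len(holdout_n))]
  folds <- split(rest, rep_len(seq_len(n_folds), length(rest)))
  names(folds) <- NULL

  structure(list(holdout_ids = holdout_ids, folds = folds,
                 seed = as.integer(seed)),
            class = "split_plan")
}

subset_ds <- function(ds, ids) {
  keep <- ds$subject_id %in% ids
  structure(list(X = ds$X[keep, , drop = FALSE],
                 labels = ds$labels[keep],
                 subject_id = ds$subject_id[keep]),
            class = "labeled_dataset")
}

#' Accuracy within a tolerance
#'
#' Fraction of predictions within `tol` scale points of the truth; `tol = 0`
#' is exact accuracy, `tol = 1` the clinical +-1-tolerance accuracy.
#'
#' @param true,pred integer label vectors of equal length.
#' @param tol non-negative integer tolerance.
#' @return proportion in \[0, 1\].
#' @export
accuracy_tol <- function(true, pred, tol = 0L) {
  if (length(true) != length(pred) || length(true) == 0L)
    abort_input("accuracy_tol: need equal non-empty label vectors")
  mean(abs(true - pred) <= tol)
}

#' Spearman rank correlation (average ranks for ties)
#'
#' @param true,pred numeric vectors, length >= 2.
#' @return correlation in \[-1, 1\]; `NA` with attribute `degenerate = TRUE`
#'   if either input is constant.
#' @export
spearman_r <- function(true, pred) {
  if (length(true) != length(pred) || length(true) < 2L)
    abort_input("spearman_r: need equal vectors of length >= 2")
  rt <- rank(true)
  rp <- rank(pred)
  if (stats::sd(rt) == 0 || stats::sd(rp) == 0)
    return(structure(NA_real_, degenerate = TRUE))
  stats::cor(rt, rp)
}

#' Percentile bootstrap confidence interval for a paired metric
#'
#' @param true,pred label vectors.
#' @param metric function(true, pred) -> scalar, e.g.
#'   `function(t, p) accuracy_tol(t, p, 1L)`.
#' @param n_boot number of resamples (>= 100; default 2000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(low, high)`; attribute `n_degenerate` counts resamples
#'   where the metric was undefined (skipped).
#' @export
bootstrap_ci <- function(true, pred, metric, n_boot = 2000L, seed = 1L,
                         conf = 0.95) {
  if (n_boot < 100L) abort_param("bootstrap_ci: n_boot must be >= 100")
  n <- length(true)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric(true[idx], pred[idx])
  }, numeric(1))
  n_deg <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(ci, n_degenerate = n_deg)
}

#' Label-permutation test for the +-1-tolerance accuracy
#'
#' Permutes the true labels `n_perm` times and reports
#' `p = (1 + #\{permuted accuracy >= observed\}) / (1 + n_perm)` together with
#' a normal-approximation z from the permutation null's mean and SD.
#'
#' @param true,pred label vectors.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @param tol tolerance used in the accuracy (default 1).
#' @return list with `p_value`, `z`, `observed`, `null_mean`, `null_sd`,
#'   `null_q975` (97.5th percentile of the null).
#' @export
permutation_test <- function(true, pred, n_perm = 999L, seed = 1L, tol = 1L) {
  if (n_perm < 99L) abort_param("permutation_test: n_perm must be >= 99")
  obs <- accuracy_tol(true, pred, tol)
  n <- length(true)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b)
    accuracy_tol(true[sample.int(n)], pred, tol), numeric(1))
  nsd <- stats::sd(null)
  list(p_value = (1 + sum(null >= obs)) / (1 + n_perm),
       z = if (nsd > 0) (obs - mean(null)) / nsd else Inf,
       observed = obs,
       null_mean = mean(null),
       null_sd = nsd,
       null_q975 = stats::quantile(null, 0.975, names = FALSE))
}

#' Confusion matrix over the 6 severity classes
#'
#' @param true,pred integer labels in 0-5.
#' @return 6x6 integer matrix, rows = true label, columns = predicted.
#' @export
confusion_matrix <- function(true, pred) {
  if (any(c(true, pred) < 0L | c(true, pred) > 5L))
    abort_input("confusion_matrix: labels must lie in 0-5")
  tab <- table(factor(true, levels = 0:5), factor(pred, levels = 0:5))
  m <- matrix(as.integer(tab), 6, 6,
              dimnames = list(true = 0:5, predicted = 0:5))
  m
}

metric_set <- function(true, pred, n_boot, seed) {
  acc <- accuracy_tol(true, pred, 0L)
  tol1 <- accuracy_tol(true, pred, 1L)
  rho <- spearman_r(true, pred)
  list(
    n = length(true),
    accuracy = acc,
    accuracy_tol1 = tol1,
    spearman_r = as.numeric(rho),
    ci95 = list(
      accuracy = as.numeric(bootstrap_ci(
        true, pred, function(t, p) accuracy_tol(t, p, 0L), n_boot, seed)),
      accuracy_tol1 = as.numeric(bootstrap_ci(
        true, pred, function(t, p) accuracy_tol(t, p, 1L), n_boot, seed + 1L)),
      spearman_r = as.numeric(bootstrap_ci(
        true, pred, function(t, p) as.numeric(spearman_r(t, p)), n_boot, seed + 2L))
    ),
    confusion = confusion_matrix(true, pred)
  )
}

#' Run the full cross-validation + hold-out experiment
#'
#' Trains one model per fold (on the other folds), pools the out-of-fold
#' predictions into the pooled-CV report, then trains on all CV data and
#' evaluates once on the hold-out set. Reports exact and +-1 accuracy,
#' Spearman r, bootstrap CIs, a label-permutation test on the pooled CV
#' predictions, confusion matrices, and fold-averaged gain importance.
#'
#' @param ds a `labeled_dataset`.
#' @param holdout_n subjects held out (0 skips the hold-out report).
#' @param n_folds CV folds (default 6).
#' @param params GBM hyperparameters ([gbt_params()]).
#' @param seed master seed (splitting, bootstrap, permutations).
#' @param n_boot bootstrap resamples (default 2000).
#' @param n_perm permutations (default 999).
#' @return an `evaluation_report`: `pooled_cv`, `holdout` (NULL if none),
#'   `permutation`, `importance`, `split`, `config`.
#' @export
run_experiment <- function(ds, holdout_n, n_folds = 6L, params = gbt_params(),
                           seed = 1L, n_boot = 2000L, n_perm = 999L) {
  plan <- make_split(ds, holdout_n, n_folds, seed)

  oof_true <- integer(0)
  oof_pred <- integer(0)
  models <- vector("list", length(plan$folds))
  for (f in seq_along(plan$folds)) {
    val_ids <- plan$folds[[f]]
    train_ids <- unlist(plan$folds[-f], use.names = FALSE)
    stopifnot(length(intersect(val_ids, train_ids)) == 0L,
              length(intersect(val_ids, plan$holdout_ids)) == 0L)
    tr <- subset_ds(ds, train_ids)
    va <- subset_ds(ds, val_ids)
    models[[f]] <- train_gbt(tr$X, tr$labels, params, seed)
    oof_true <- c(oof_true, va$labels)
    oof_pred <- c(oof_pred, predict(models[[f]], va$X))
  }

  pooled <- metric_set(oof_true, oof_pred, n_boot, seed)
  perm <- permutation_test(oof_true, oof_pred, n_perm, seed + 10L)

  holdout <- NULL
  if (length(plan$holdout_ids)) {
    cv_ids <- unlist(plan$folds, use.names = FALSE)
    stopifnot(length(intersect(cv_ids, plan$holdout_ids)) == 0L)
    final <- train_gbt(subset_ds(ds, cv_ids)$X, subset_ds(ds, cv_ids)$labels,
                       params, seed)
    ho <- subset_ds(ds, plan$holdout_ids)
    holdout <- metric_set(ho$labels, predict(final, ho$X), n_boot, seed + 20L)
  }

  structure(list(
    pooled_cv = pooled,
    holdout = holdout,
    permutation = perm,
    importance = feature_importance(models),
    split = plan,
    config = list(holdout_n = holdout_n, n_folds = n_folds, params = params,
                  seed = seed, n_boot = n_boot, n_perm = n_perm)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  pooled CV  (n=%d): accuracy %.3f, +-1 accuracy %.3f, Spearman r %.3f\n",
              x$pooled_cv$n, x$pooled_cv$accuracy, x$pooled_cv$accuracy_tol1,
              x$pooled_cv$spearman_r))
  cat(sprintf("  permutation: p = %.4f, z = %.2f\n",
              x$permutation$p_value, x$permutation$z))
  if (!is.null(x$holdout))
    cat(sprintf("  hold-out   (n=%d): accuracy %.3f, +-1 accuracy %.3f, Spearman r %.3f\n",
                x$holdout$n, x$holdout$accuracy, x$holdout$accuracy_tol1,
                x$holdout$spearman_r))
  top <- utils::head(x$importance[x$importance > 0], 5)
  cat("  top features:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

report_to_list <- function(rep) {
  ms <- function(m) if (is.null(m)) NULL else {
    m$confusion <- unname(apply(m$confusion, 1, as.integer, simplify = FALSE))
    m
  }
  list(
    pooled_cv = ms(rep$pooled_cv),
    holdout = ms(rep$holdout),
    permutation = rep$permutation,
    importance = as.list(rep$importance),
    split = list(holdout_ids = rep$split$holdout_ids, folds = rep$split$folds,
                 seed = rep$split$seed),
    config = rep$config
  )
}

#' Serialize an evaluation report
#'
#' Writes `report.json`, per-set confusion CSVs and `importance.tsv`.
#'
#' @param rep an `evaluation_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(rep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(rep), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(rep$pooled_cv$confusion,
                   file.path(out_dir, "confusion_cv.csv"))
  if (!is.null(rep$holdout))
    utils::write.csv(rep$holdout$confusion,
                     file.path(out_dir, "confusion_holdout.csv"))
  imp <- data.frame(feature = names(rep$importance),
                    mean_gain = as.numeric(rep$importance))
  utils::write.table(imp, file.path(out_dir, "importance.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
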
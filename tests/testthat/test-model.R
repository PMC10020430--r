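test_that("make_split reproduces the 70 = 60 + 10 design", {
  ds <- dummy_dataset(70, seed = 71)
  plan <- make_split(ds, holdout_n = 10, n_folds = 6, seed = 1)
  expect_length(plan$holdout_ids, 10L)
  expect_equal(sum(lengths(plan$folds)), 60L)
  expect_true(all(lengths(plan$folds) == 10L))
  expect_length(intersect(plan$holdout_ids, unlist(plan$folds)), 0L)
  expect_setequal(c(plan$holdout_ids, unlist(plan$folds)), ds$subject_id)

  # pure CV partitions everything
  plan0 <- make_split(ds, holdout_n = 0, n_folds = 6, seed = 1)
  expect_length(plan0$holdout_ids, 0L)
  expect_setequal(unlist(plan0$folds), ds$subject_id)

  # deterministic given seed
  expect_identical(make_split(ds, 10, 6, seed = 9),
                   make_split(ds, 10, 6, seed = 9))
  expect_error(make_split(dummy_dataset(5), 10, 6),
               class = "ataxvoice_input_error")
})

test_that("repeat assessments of one subject never straddle groups", {
  sids <- c(sprintf("P%02d", 1:20), "P01", "P05") # two follow-ups
  set.seed(72)
  X <- matrix(rnorm(22 * 3), 22, 3, dimnames = list(NULL, paste0("f", 1:3)))
  feats <- data.frame(subject_id = sids, X, check.names = FALSE)
  labels <- data.frame(subject_id = sprintf("P%02d", 1:20),
                       label = rep(0:5, length.out = 20))
  ds <- labeled_dataset(feats, labels)
  for (seed in 1:5) {
    plan <- make_split(ds, holdout_n = 4, n_folds = 4, seed = seed)
    groups <- c(list(plan$holdout_ids), plan$folds)
    membership <- vapply(c("P01", "P05"), function(s)
      sum(vapply(groups, function(g) s %in% g, logical(1))), integer(1))
    expect_true(all(membership == 1L))
  }
})

test_that("accuracy_tol matches the printed examples", {
  expect_equal(accuracy_tol(c(2, 3, 1), c(3, 3, 3), 1L), 2 / 3)
  expect_equal(accuracy_tol(0:5, 0:5, 0L), 1.0)
  expect_equal(accuracy_tol(c(0, 1, 2), c(2, 3, 4), 1L), 0.0)
  expect_error(accuracy_tol(1:3, 1:2), class = "ataxvoice_input_error")
})

test_that("spearman_r agrees with a brute-force rank computation", {
  expect_equal(spearman_r(0:5, 0:5), 1.0)
  expect_equal(spearman_r(0:5, 5:0), -1.0)

  # independent oracle: Pearson formula applied to explicitly computed ranks
  brute_spearman <- function(a, b) {
    ra <- vapply(seq_along(a), function(i)
      sum(a < a[i]) + (1 + sum(a == a[i])) / 2, numeric(1))
    rb <- vapply(seq_along(b), function(i)
      sum(b < b[i]) + (1 + sum(b == b[i])) / 2, numeric(1))
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  expect_equal(spearman_r(c(0, 1, 2, 3), c(1, 0, 2, 3)), 0.8)
  expect_equal(brute_spearman(c(0, 1, 2, 3), c(1, 0, 2, 3)), 0.8)
  set.seed(73)
  for (i in 1:10) {
    a <- sample(0:5, 12, replace = TRUE)
    b <- sample(0:5, 12, replace = TRUE)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    expect_equal(spearman_r(a, b), brute_spearman(a, b))
  }

  const <- spearman_r(rep(2, 5), 1:5)
  expect_true(is.na(const))
  expect_true(isTRUE(attr(const, "degenerate")))
})

test_that("bootstrap_ci behaves on exact and imperfect predictions", {
  truth <- rep(0:4, 2)
  ci <- bootstrap_ci(truth, truth, function(t, p) accuracy_tol(t, p, 0L),
                     n_boot = 200L, seed = 74)
  expect_equal(as.numeric(ci), c(1, 1))

  pred <- truth; pred[1] <- 4
  ci2 <- bootstrap_ci(truth, pred, function(t, p) accuracy_tol(t, p, 0L),
                      n_boot = 500L, seed = 74)
  expect_gt(ci2[2] - ci2[1], 0)
  expect_error(bootstrap_ci(truth, pred, identity, n_boot = 50L),
               class = "ataxvoice_param_error")
})

test_that("permutation_test matches its stated formula at the extremes", {
  truth <- rep(0:5, 10)
  pt <- permutation_test(truth, truth, n_perm = 199L, seed = 75)
  expect_equal(pt$p_value, 1 / 200)
  expect_gt(pt$z, 3)

  # constant predictions: every permutation ties the observed accuracy
  pt2 <- permutation_test(truth, rep(2L, 60), n_perm = 99L, seed = 75)
  expect_equal(pt2$p_value, 1.0)
})

test_that("confusion_matrix counts and marginals", {
  truth <- c(0, 0, 1, 5, 3)
  cm <- confusion_matrix(truth, truth)
  expect_equal(diag(cm), c(`0` = 2L, `1` = 1L, `2` = 0L, `3` = 1L,
                           `4` = 0L, `5` = 1L))
  one <- confusion_matrix(2, 4)
  expect_equal(one["2", "4"], 1L)
  expect_equal(sum(one), 1L)

  set.seed(76)
  t <- sample(0:5, 40, replace = TRUE)
  p <- sample(0:5, 40, replace = TRUE)
  cm2 <- confusion_matrix(t, p)
  expect_equal(rowSums(cm2), vapply(0:5, function(k) sum(t == k), numeric(1)),
               ignore_attr = TRUE)
  expect_error(confusion_matrix(6, 2), class = "ataxvoice_input_error")
})

test_that("run_experiment produces a coherent report without leakage", {
  # informative features so the pooled metrics are meaningful
  set.seed(77)
  n <- 48
  labels <- rep(0:5, each = 8)
  sids <- sprintf("R%03d", seq_len(n))
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(sids, paste0("f", 1:6)))
  X[, 1] <- labels + rnorm(n, sd = 0.3)
  ds <- labeled_dataset(X, data.frame(subject_id = sids, label = labels))

  rep1 <- run_experiment(ds, holdout_n = 6, n_folds = 6, seed = 2,
                         n_boot = 200L, n_perm = 199L)
  expect_lte(rep1$pooled_cv$accuracy, rep1$pooled_cv$accuracy_tol1)
  expect_lte(rep1$pooled_cv$accuracy_tol1, 1)
  expect_equal(rep1$pooled_cv$n, 42)
  expect_equal(rep1$holdout$n, 6)
  expect_equal(sum(rep1$pooled_cv$confusion), 42)
  expect_length(rep1$importance, 6L)
  expect_true(all(rep1$importance >= 0))
  expect_length(intersect(rep1$split$holdout_ids, unlist(rep1$split$folds)), 0L)

  # byte-identical artifacts on rerun with the same config + seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep1, d1)
  rep2 <- run_experiment(ds, holdout_n = 6, n_folds = 6, seed = 2,
                         n_boot = 200L, n_perm = 199L)
  write_report(rep2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("label 6 is rejected at dataset assembly", {
  sids <- sprintf("A%02d", 1:6)
  X <- matrix(0, 6, 2, dimnames = list(sids, c("f1", "f2")))
  err <- tryCatch(
    labeled_dataset(X, data.frame(subject_id = sids, label = c(0:4, 6))),
    error = identity)
  expect_s3_class(err, "ataxvoice_input_error")
  expect_match(conditionMessage(err), "0-5")
})
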
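# Random-forest prediction of binary spatial neglect from tract-wise
# lesion loads. Out-of-sample performance is the mean ROC AUC over
# repeated stratified train/test splits; significance comes from a
# permutation test that shuffles the labels and reruns the identical
# cross-validation procedure. Forests are fitted with ranger, whose
# max.depth and min.node.size ("minimal node size to split at") mirror the
# usual scikit-learn max_depth / min_samples_split controls.

#' Classifier configuration
#'
#' Defaults mirror the reference design: 100 trees, maximum depth 3, minimum
#' node size to split 5, 100 stratified 80/20 splits, 2500 permutations.
#' Calibration suites scale `n_splits` and `n_perm` down through this
#' config; tree hyperparameters are left at their defaults.
#'
#' @param n_trees trees per forest.
#' @param max_depth maximum tree depth.
#' @param min_samples_split minimum samples in a node for it to be split.
#' @param n_splits repeated cross-validation splits.
#' @param test_fraction held-out share per split, in (0, 1).
#' @param n_perm label permutations for the significance test.
#' @param seed RNG seed for the whole procedure.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(n_trees = 100, max_depth = 3,
                              min_samples_split = 5, n_splits = 100,
                              test_fraction = 0.2, n_perm = 2500,
                              seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1, min_samples_split >= 1,
            n_splits >= 1, n_perm >= 1,
            test_fraction > 0, test_fraction < 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 n_splits = as.integer(n_splits),
                 test_fraction = test_fraction,
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' ROC AUC by the rank (Mann-Whitney) formula
#'
#' @param scores predicted scores (higher = more positive).
#' @param labels binary labels (0/1 or logical); both classes required.
#' @return AUC in `[0, 1]`; ties in scores contribute 1/2.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("auc_rank: both classes required")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified test indices: round(test_fraction * n_c) per class, clamped so
# both train and test contain at least one member of each class
stratified_test_indices <- function(labels, test_fraction) {
  labels <- as.logical(labels)
  idx <- seq_along(labels)
  unlist(lapply(c(TRUE, FALSE), function(cl) {
    pool <- idx[labels == cl]
    n_test <- min(max(1L, round(test_fraction * length(pool))),
                  length(pool) - 1L)
    sample(pool, n_test)
  }), use.names = FALSE)
}

fit_forest_auc <- function(features, labels, test_idx, cfg) {
  df <- as.data.frame(features)
  df$.y <- factor(as.integer(labels), levels = c(0L, 1L))
  fit <- ranger::ranger(
    dependent.variable.name = ".y",
    data = df[-test_idx, , drop = FALSE],
    num.trees = cfg$n_trees,
    max.depth = cfg$max_depth,
    min.node.size = cfg$min_samples_split,
    probability = TRUE,
    num.threads = 1L,
    seed = sample.int(.Machine$integer.max, 1L),
    verbose = FALSE)
  pred <- stats::predict(fit, data = df[test_idx, , drop = FALSE],
                         num.threads = 1L)$predictions[, "1"]
  auc_rank(pred, labels[test_idx])
}

#' Repeated stratified cross-validated AUC
#'
#' For each of `cfg$n_splits` stratified splits into training and test
#' data, fits a fresh random forest on the training part and scores the
#' held-out part; the summary statistic is the mean of the per-split test
#' AUCs. Stratification guarantees both classes in every fold.
#'
#' @param features patients x predictors matrix or data.frame (tract-wise
#'   lesion loads).
#' @param labels binary neglect labels; both classes must be present.
#' @param cfg a [classifier_config()]. The RNG state is taken as-is; seed
#'   upstream (e.g. in [permutation_test_auc()]) for reproducibility.
#' @return List with `mean_auc` and `per_split_auc`.
#' @export
repeated_cv_auc <- function(features, labels, cfg = classifier_config()) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("repeated_cv_auc: both classes required")
  if (min(table(labels)) < 2)
    stop("repeated_cv_auc: need at least 2 patients per class")
  aucs <- vapply(seq_len(cfg$n_splits), function(s) {
    test_idx <- stratified_test_indices(labels, cfg$test_fraction)
    fit_forest_auc(features, labels, test_idx, cfg)
  }, numeric(1))
  list(mean_auc = mean(aucs), per_split_auc = aucs)
}

#' Permutation test of the cross-validated AUC
#'
#' Shuffles the labels `cfg$n_perm` times and reruns the full repeated
#' cross-validation procedure (fresh stratified splits on the shuffled
#' labels, fresh forests) each time; the p-value is
#' `(1 + #permutation mean AUCs >= observed) / (1 + n_perm)`, bounded
#' below by `1/(1 + n_perm)`.
#'
#' @inheritParams repeated_cv_auc
#' @return Object of class `classifier_result`: `mean_auc`,
#'   `per_split_auc`, `perm_aucs`, `p_value`, `config`.
#' @export
permutation_test_auc <- function(features, labels,
                                 cfg = classifier_config()) {
  set.seed(cfg$seed)
  obs <- repeated_cv_auc(features, labels, cfg)
  perm_aucs <- vapply(seq_len(cfg$n_perm), function(b) {
    y_perm <- sample(labels)
    repeated_cv_auc(features, y_perm, cfg)$mean_auc
  }, numeric(1))
  p <- (1 + sum(perm_aucs >= obs$mean_auc)) / (1 + cfg$n_perm)
  structure(list(mean_auc = obs$mean_auc,
                 per_split_auc = obs$per_split_auc,
                 perm_aucs = perm_aucs, p_value = p, config = cfg),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat("<classifier_result> mean test AUC ", round(x$mean_auc, 3),
      " over ", x$config$n_splits, " splits; permutation p = ",
      signif(x$p_value, 3), " (", x$config$n_perm, " permutations)\n",
      sep = "")
  invisible(x)
}
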
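#' Classifier specification
#'
#' Describes one of the three supported algorithms and its parameters:
#' `svm_rbf` (RBF-kernel SVM; `C`, `sigma`), `random_forest` (`ntree`,
#' `mtry`) and `knn` (`k`). Fractional `mtry` values (as printed in
#' published parameter tables) are rounded to the nearest positive integer
#' with a warning.
#'
#' @param algorithm One of `"svm_rbf"`, `"random_forest"`, `"knn"`.
#' @param C,sigma SVM cost and RBF kernel width.
#' @param ntree,mtry Random Forest tree count and candidate features per split.
#' @param k Neighbour count for k-NN (odd values avoid voting ties on two
#'   classes).
#' @param label Optional display label (defaults to the algorithm name).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("svm_rbf", "random_forest", "knn"),
                            C = 1, sigma = 0.001, ntree = 500, mtry = NULL,
                            k = 9, label = NULL) {
  algorithm <- match.arg(algorithm)
  params <- switch(algorithm,
    svm_rbf = {
      if (C <= 0 || sigma <= 0) stop("'C' and 'sigma' must be positive")
      list(C = C, sigma = sigma)
    },
    random_forest = {
      if (ntree <= 0) stop("'ntree' must be positive")
      if (!is.null(mtry)) {
        if (mtry <= 0) stop("'mtry' must be positive")
        if (mtry != round(mtry)) {
          warning(sprintf("fractional mtry %.3g rounded to %d",
                          mtry, max(1L, as.integer(round(mtry)))))
        }
        mtry <- max(1L, as.integer(round(mtry)))
      }
      list(ntree = as.integer(ntree), mtry = mtry)
    },
    knn = {
      if (k < 1) stop("'k' must be >= 1")
      list(k = as.integer(k))
    })
  structure(list(algorithm = algorithm, parameters = params,
                 label = if (is.null(label)) algorithm else label),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  ps <- x$parameters[!vapply(x$parameters, is.null, TRUE)]
  cat(sprintf("<classifier_spec> %s (%s)\n", x$label,
              paste(sprintf("%s=%g", names(ps), unlist(ps)), collapse = ", ")))
  invisible(x)
}

# published per-dataset tuning results, shipped as configuration defaults
TABLE3_DEFAULTS <- data.frame(
  dataset  = c("10-1","10-3","10-5","10-10","10-20","10-30","10-40","10-50",
               "20-50","30-50","40-50","50-50","100-50","150-50","200-50","250-50"),
  knn_k    = c(9,9,9,9,9,9,9,9,9,9,9,7,9,9,9,9),
  rf_ntree = rep(500L, 16),
  rf_mtry  = c(3.45,3.59,6.95,8.03,19.7,4.77,25.5,55.8,30.1,64.4,17.1,72.1,
               88.3,102,114,125),
  svm_C    = c(1,0.5,0.5,2,1,1,1,1,1,0.5,0.5,0.5,1,0.5,1,1),
  svm_sigma= c(3.64e-3,3.05e-3,1e-2,1e-3,1e-3,1e-3,7.84e-4,1e-3,1e-3,1e-3,
               1e-3,1e-3,1e-3,1.96e-4,1.56e-4,1e-4),
  stringsAsFactors = FALSE
)

#' Default classifier parameters per window dataset
#'
#' Returns the shipped per-dataset default parameters (the tuned values for
#' the sixteen `U-D` window datasets) as a list of three
#' [classifier_spec()]s. No parameter search is performed by this package;
#' these are configuration defaults only.
#'
#' @param dataset Dataset name, e.g. `"10-30"` or `"250-50"`.
#' @return Named list with elements `knn`, `random_forest`, `svm_rbf`.
#' @export
table3_defaults <- function(dataset) {
  row <- TABLE3_DEFAULTS[TABLE3_DEFAULTS$dataset == dataset, ]
  if (nrow(row) != 1) {
    stop(sprintf("no shipped defaults for dataset '%s'", dataset))
  }
  list(
    knn = classifier_spec("knn", k = row$knn_k),
    random_forest = suppressWarnings(
      classifier_spec("random_forest", ntree = row$rf_ntree, mtry = row$rf_mtry)),
    svm_rbf = classifier_spec("svm_rbf", C = row$svm_C, sigma = row$svm_sigma)
  )
}

#' Stratified fold assignment for cross-validation
#'
#' Partitions rows into `n_folds` folds so that, within each class, fold
#' sizes differ by at most one. The assignment is deterministic per seed and
#' is intended to be shared across classifiers, so every classifier is
#' evaluated on identical test partitions.
#'
#' @param labels Class vector (factor or character).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Object of class `fold_assignment`: list with `fold` (integer
#'   vector, one entry per row), `n_folds`, `seed`.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.factor(labels)
  n_folds <- as.integer(n_folds)
  small <- table(labels) < n_folds
  if (any(small)) {
    stop(sprintf("class '%s' has fewer members than folds (%d < %d)",
                 names(which(small))[1], min(table(labels)), n_folds))
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  structure(list(fold = fold, n_folds = n_folds, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Build a 2x2 confusion matrix
#'
#' Rows are actual classes, columns predicted, both ordered
#' (`promoter`, `non-promoter`).
#'
#' @param actual,predicted Class vectors of equal length.
#' @param levels Class level order.
#' @return Integer 2x2 matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(actual, predicted,
                             levels = c("promoter", "non-promoter")) {
  cm <- table(factor(actual, levels = levels),
              factor(predicted, levels = levels))
  structure(matrix(as.integer(cm), 2, 2, dimnames = dimnames(cm)),
            class = c("confusion_matrix", "matrix"))
}

#' Per-class F-measure from a confusion matrix
#'
#' `F = 2PR / (P + R)` with precision `P = TP / (TP + FP)` and recall
#' `R = TP / (TP + FN)`; degenerate cases (no predictions and/or no members
#' of the class) return 0 by convention.
#'
#' @param cm 2x2 confusion matrix (actual rows, predicted columns).
#' @param class_index Row/column index of the class scored as positive.
#' @return F-measure in \[0, 1\].
#' @export
f_measure <- function(cm, class_index = 1L) {
  tp <- cm[class_index, class_index]
  fp <- sum(cm[, class_index]) - tp
  fn <- sum(cm[class_index, ]) - tp
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Macro-averaged F-measure (mean of the two per-class F-measures)
#' @rdname f_measure
#' @export
macro_f_measure <- function(cm) {
  mean(c(f_measure(cm, 1L), f_measure(cm, 2L)))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace / total` and expected agreement
#' `p_e = sum_c row_c * col_c / total^2`; returns 0 when `p_e = 1`.
#'
#' @param cm Square confusion matrix.
#' @return Kappa in \[-1, 1\].
#' @export
kappa_statistic <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (p_e == 1) return(0)
  (p_o - p_e) / (1 - p_e)
}

train_predict <- function(spec, x_train, y_train, x_test, fit_seed) {
  switch(spec$algorithm,
    svm_rbf = {
      fit <- kernlab::ksvm(x_train, y_train, type = "C-svc",
                           kernel = "rbfdot",
                           kpar = list(sigma = spec$parameters$sigma),
                           C = spec$parameters$C, scaled = FALSE)
      kernlab::predict(fit, x_test)
    },
    random_forest = {
      mtry <- spec$parameters$mtry
      if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x_train))))
      with_seed(fit_seed, {
        fit <- randomForest::randomForest(x_train, y_train,
                                          ntree = spec$parameters$ntree,
                                          mtry = min(mtry, ncol(x_train)))
        predict(fit, x_test)
      })
    },
    knn = with_seed(fit_seed, {
      class::knn(x_train, x_test, y_train, k = spec$parameters$k)
    })
  )
}

#' Cross-validated evaluation of one classifier on one feature matrix
#'
#' For each fold, the model is trained on the complement and applied to the
#' fold. When `scale = TRUE` (default), features are z-score standardized
#' with means and standard deviations fitted on the training rows only
#' (constant features get unit scale). Per-fold and pooled confusion
#' matrices, per-class precision/recall/F, macro F and kappa are reported;
#' the per-fold macro-F vector feeds [compare_report()].
#'
#' @param fm A `feature_matrix` from [encode_dataset()].
#' @param spec A [classifier_spec()].
#' @param folds A [stratified_folds()] assignment matching `nrow(fm$x)`.
#' @param scale Standardize features per training fold.
#' @param dataset Dataset name recorded in the report.
#' @return Object of class `metrics_report`: list with `per_fold` (data
#'   frame), `pooled` (list of metrics), `pooled_cm`, `spec`, `dataset`.
#' @export
run_cv <- function(fm, spec, folds, scale = TRUE, dataset = "dataset") {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "classifier_spec"),
            inherits(folds, "fold_assignment"))
  n <- nrow(fm$x)
  if (length(folds$fold) != n) stop("fold assignment does not match row count")
  per_fold <- vector("list", folds$n_folds)
  pooled_cm <- matrix(0L, 2, 2,
                      dimnames = list(levels(fm$labels), levels(fm$labels)))
  for (f in seq_len(folds$n_folds)) {
    test_idx <- which(folds$fold == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    y_train <- droplevels(fm$labels[train_idx])
    if (nlevels(y_train) < 2) {
      stop(sprintf("fold %d has a single-class training set", f))
    }
    x_train <- fm$x[train_idx, , drop = FALSE]
    x_test <- fm$x[test_idx, , drop = FALSE]
    if (scale) {
      mu <- colMeans(x_train)
      sdv <- apply(x_train, 2, stats::sd)
      sdv[sdv == 0] <- 1
      x_train <- sweep(sweep(x_train, 2, mu), 2, sdv, "/")
      x_test <- sweep(sweep(x_test, 2, mu), 2, sdv, "/")
    }
    pred <- train_predict(spec, x_train, factor(fm$labels[train_idx]),
                          x_test, fit_seed = folds$seed * 1000L + f)
    cm <- confusion_matrix(fm$labels[test_idx], pred)
    pooled_cm <- pooled_cm + cm
    per_fold[[f]] <- data.frame(
      fold = f,
      f_promoter = f_measure(cm, 1L), f_nonpromoter = f_measure(cm, 2L),
      f_macro = macro_f_measure(cm), kappa = kappa_statistic(cm))
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- list(
    f_promoter = f_measure(pooled_cm, 1L),
    f_nonpromoter = f_measure(pooled_cm, 2L),
    f_macro = macro_f_measure(pooled_cm),
    f_macro_fold_mean = mean(per_fold$f_macro),
    kappa = kappa_statistic(pooled_cm))
  structure(list(per_fold = per_fold, pooled = pooled, pooled_cm = pooled_cm,
                 spec = spec, dataset = dataset, folds = folds),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s on %s: macro F = %.4f (fold mean %.4f), kappa = %.4f\n",
              x$spec$label, x$dataset, x$pooled$f_macro,
              x$pooled$f_macro_fold_mean, x$pooled$kappa))
  print(x$pooled_cm)
  invisible(x)
}

#' Evaluate several classifiers over several datasets under shared folds
#'
#' Runs [run_cv()] for every (dataset, classifier) pair. Fold assignments
#' are computed once per dataset and shared across classifiers, so all
#' classifiers see identical test partitions.
#'
#' @param datasets Named list of `feature_matrix` objects.
#' @param specs Named list of [classifier_spec()]s (or a function
#'   `dataset_name -> list of specs` for per-dataset defaults).
#' @param n_folds Folds per dataset.
#' @param fold_seed Seed for every dataset's fold assignment.
#' @param scale Passed to [run_cv()].
#' @return Long-format data frame with one row per (dataset, classifier,
#'   fold): columns `dataset`, `classifier`, `fold`, `f_promoter`,
#'   `f_nonpromoter`, `f_macro`, `kappa`; attribute `reports` keeps the full
#'   `metrics_report` objects.
#' @export
sweep_datasets <- function(datasets, specs, n_folds = 10L, fold_seed = 1L,
                           scale = TRUE) {
  stopifnot(length(names(datasets)) == length(datasets))
  rows <- list(); reports <- list()
  for (ds in names(datasets)) {
    fm <- datasets[[ds]]
    folds <- stratified_folds(fm$labels, n_folds, seed = fold_seed)
    ds_specs <- if (is.function(specs)) specs(ds) else specs
    for (cl in names(ds_specs)) {
      rep <- run_cv(fm, ds_specs[[cl]], folds, scale = scale, dataset = ds)
      reports[[paste(ds, cl, sep = "/")]] <- rep
      rows[[length(rows) + 1]] <- cbind(
        data.frame(dataset = ds, classifier = cl), rep$per_fold)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
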
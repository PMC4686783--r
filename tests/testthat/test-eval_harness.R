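test_that("stratified folds balance both classes to within one member", {
  labels <- rep(c("promoter", "non-promoter"), each = 50)
  f <- stratified_folds(labels, 10, seed = 1)
  tab <- table(labels, f$fold)
  expect_true(all(tab == 5L))
  # uneven case over several seeds: per-class fold sizes differ by <= 1
  labels2 <- rep(c("promoter", "non-promoter"), c(53, 47))
  for (s in 1:5) {
    f2 <- stratified_folds(labels2, 10, seed = s)
    tab2 <- table(labels2, f2$fold)
    expect_lte(max(tab2["promoter", ]) - min(tab2["promoter", ]), 1L)
    expect_lte(max(tab2["non-promoter", ]) - min(tab2["non-promoter", ]), 1L)
  }
  expect_identical(stratified_folds(labels, 10, seed = 3)$fold,
                   stratified_folds(labels, 10, seed = 3)$fold)
  expect_false(identical(stratified_folds(labels, 10, seed = 3)$fold,
                         stratified_folds(labels, 10, seed = 4)$fold))
  expect_error(stratified_folds(rep(c("a", "b"), c(5, 50)), 10),
               "fewer members than folds")
})

test_that("F-measure and kappa match their defining formulas", {
  perfect <- matrix(c(50L, 0L, 0L, 50L), 2, 2)
  expect_equal(f_measure(perfect, 1), 1)
  expect_equal(kappa_statistic(perfect), 1)
  # hand-worked example: TP=45, FP=10, FN=5
  cm <- matrix(c(45L, 10L, 5L, 40L), 2, 2)  # rows actual, cols predicted
  expect_equal(f_measure(cm, 1), 2 * (45 / 55) * 0.9 / ((45 / 55) + 0.9),
               tolerance = 1e-12)
  expect_equal(f_measure(cm, 1), 0.857142857, tolerance = 1e-6)
  # chance-level agreement and the worked kappa example
  expect_equal(kappa_statistic(matrix(c(50, 50, 50, 50), 2, 2)), 0)
  expect_equal(kappa_statistic(matrix(c(45, 10, 5, 40), 2, 2)), 0.7)
  # degenerate: empty class and no predictions of it
  expect_equal(f_measure(matrix(c(0L, 0L, 0L, 10L), 2, 2), 1), 0)
})

test_that("metrics agree with brute-force evaluation on random confusion matrices", {
  withr::local_seed(2024)
  for (i in 1:200) {
    cm <- random_cm()
    if (sum(cm) == 0) next
    expect_equal(f_measure(cm, 1), oracle_f(cm, 1))
    expect_equal(f_measure(cm, 2), oracle_f(cm, 2))
    expect_equal(kappa_statistic(cm), oracle_kappa(cm))
    expect_equal(macro_f_measure(cm), mean(c(oracle_f(cm, 1), oracle_f(cm, 2))))
  }
})

test_that("classifier specs validate parameters and round fractional mtry", {
  expect_warning(s <- classifier_spec("random_forest", mtry = 3.45),
                 "fractional mtry 3.45 rounded to 3")
  expect_identical(s$parameters$mtry, 3L)
  expect_error(classifier_spec("svm_rbf", C = -1), "positive")
  expect_error(classifier_spec("knn", k = 0), "k")
})

test_that("shipped per-dataset defaults load for all sixteen windows", {
  for (ds in promstruct:::TABLE3_DEFAULTS$dataset) {
    specs <- table3_defaults(ds)
    expect_named(specs, c("knn", "random_forest", "svm_rbf"))
  }
  d <- table3_defaults("250-50")
  expect_equal(d$svm_rbf$parameters$sigma, 1e-4)
  expect_equal(d$svm_rbf$parameters$C, 1)
  expect_identical(d$knn$parameters$k, 9L)
  expect_identical(table3_defaults("50-50")$knn$parameters$k, 7L)
  expect_identical(d$random_forest$parameters$mtry, 125L)
  expect_error(table3_defaults("999-1"), "no shipped defaults")
})

test_that("cross-validation trains on the complement and reuses shared folds", {
  set <- synth_labeled_set(synth_config(n_per_class = 60, effect = 1, seed = 12))
  ds <- assemble_dataset(set[set$label == "promoter", ],
                         set[set$label == "non-promoter", ], seed = 13)
  fm <- encode_dataset(ds, builtin_registry())
  folds <- stratified_folds(fm$labels, 10, seed = 5)
  r1 <- run_cv(fm, classifier_spec("knn", k = 3), folds)
  expect_identical(nrow(r1$per_fold), 10L)
  expect_identical(sum(r1$pooled_cm), 120L)
  expect_true(all(r1$per_fold$f_macro >= 0 & r1$per_fold$f_macro <= 1))
  expect_true(abs(r1$pooled$kappa) <= 1)
  # strong signal: clearly better than chance
  expect_gt(r1$pooled$f_macro, 0.8)
  # identical folds object reused by a second classifier: same partitions,
  # so per-fold test counts agree exactly
  r2 <- run_cv(fm, classifier_spec("random_forest", ntree = 30), folds)
  expect_identical(r2$folds$fold, r1$folds$fold)
  expect_error(run_cv(fm, classifier_spec("knn"),
                      stratified_folds(rep(c("promoter", "non-promoter"), 30),
                                       10, 1)),
               "does not match row count")
})

test_that("permuted labels drive kappa to chance level", {
  set <- synth_labeled_set(synth_config(n_per_class = 200, effect = 1, seed = 14))
  fm <- encode_dataset(set, builtin_registry())
  withr::local_seed(15)
  fm$labels <- sample(fm$labels)
  folds <- stratified_folds(fm$labels, 10, seed = 16)
  r <- run_cv(fm, classifier_spec("knn", k = 9), folds)
  expect_lt(abs(r$pooled$kappa), 0.15)
})

test_that("sweeps produce one row per dataset-classifier-fold with shared partitions", {
  mk <- function(seed) {
    s <- synth_labeled_set(synth_config(n_per_class = 30, effect = 1, seed = seed))
    encode_dataset(s, builtin_registry())
  }
  dsets <- list(a = mk(1), b = mk(2))
  specs <- list(knn = classifier_spec("knn", k = 3),
                rf = classifier_spec("random_forest", ntree = 20))
  res <- sweep_datasets(dsets, specs, n_folds = 5, fold_seed = 9)
  expect_identical(nrow(res), 2L * 2L * 5L)
  expect_setequal(unique(res$classifier), c("knn", "rf"))
  # shared-partition contract: identical fold vector within a dataset
  reps <- attr(res, "reports")
  expect_identical(reps[["a/knn"]]$folds$fold, reps[["a/rf"]]$folds$fold)
})
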
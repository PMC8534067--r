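test_that("confusion-table metrics match hand-computed values", {
  m <- computeMetrics(tp = 3, fn = 1, tn = 2, fp = 2)
  expect_equal(unname(m["accuracy"]), 62.5)
  expect_equal(unname(m["sensitivity"]), 75)
  expect_equal(unname(m["specificity"]), 50)
  expect_equal(unname(computeMetrics(5, 0, 5, 0)), c(100, 100, 100))
  # everything predicted positive
  allPos <- computeMetrics(tp = 4, fn = 0, tn = 0, fp = 6)
  expect_equal(unname(allPos["sensitivity"]), 100)
  expect_equal(unname(allPos["specificity"]), 0)
  # empty positive class: sensitivity undefined, flagged as NA
  noPos <- computeMetrics(tp = 0, fn = 0, tn = 5, fp = 1)
  expect_true(is.na(noPos["sensitivity"]))
  expect_false(is.na(noPos["specificity"]))
  expect_error(computeMetrics(0, 0, 0, 0), "positive total")
})

makeEval <- function(id, acc, sens, spec) {
  new("CVEvaluation", model = id, foldAssignments = 1L,
      confusions = list(),
      perFold = matrix(c(acc, sens, spec), 1, 3,
                       dimnames = list(NULL, c("accuracy", "sensitivity",
                                               "specificity"))),
      means = c(accuracy = acc, sensitivity = sens, specificity = spec),
      predictions = factor(character(0),
                           levels = c("control", "dyslexic")),
      standardizers = list(), seed = 1L)
}

test_that("model selection is lexicographic on accuracy, sensitivity, specificity", {
  # the two published saccade-column score triples: accuracy decides
  a <- makeEval("svmSacc", 80.0, 82.5, 77.5)
  b <- makeEval("svmRead", 71.57, 54.29, 76.67)
  expect_identical(selectBest(list(a, b)), "svmSacc")
  expect_identical(selectBest(list(b, a)), "svmSacc")
  # equal accuracy: sensitivity decides
  c1 <- makeEval("m1", 75, 85, 60)
  c2 <- makeEval("m2", 75, 80, 95)
  expect_identical(selectBest(list(c2, c1)), "m1")
  # full tie: first in roster order wins, deterministically
  d1 <- makeEval("first", 70, 70, 70)
  d2 <- makeEval("second", 70, 70, 70)
  expect_identical(selectBest(list(d1, d2)), "first")
  expect_identical(selectBest(list(d2, d1)), "second")
})

test_that("a perfectly separating feature yields 100% for linear models", {
  fm <- gaussianFeatures(n = 40, p = 5, seed = 3, separation = 20)
  x <- featureValues(cleanForClassification(fm))
  evals <- runCV(x, subjectGroups(fm),
                 classifierRoster()[c("logistic", "svmLinear", "lda")],
                 k = 5, seed = 1)
  for (e in evals) expect_equal(unname(meanMetrics(e)["accuracy"]), 100)
})

test_that("standardization and models tolerate constant columns", {
  fm <- gaussianFeatures(n = 30, p = 4, seed = 4, separation = 10)
  x <- featureValues(fm)
  x[, 3] <- 7  # constant feature
  evals <- suppressWarnings(
    runCV(x, subjectGroups(fm), classifierRoster(), k = 5, seed = 2))
  for (e in evals) expect_false(any(is.na(meanMetrics(e)["accuracy"])))
})

test_that("cross-validation refuses degenerate splits", {
  fm <- gaussianFeatures(n = 8, p = 3, seed = 5)
  x <- featureValues(fm)
  expect_error(runCV(x, subjectGroups(fm), classifierRoster()["logistic"],
                     k = 5, seed = 1), "at least k subjects")
  # explicit single-class training fold
  folds <- c(1, 1, 1, 1, 2, 2, 2, 2)  # alternating labels: fine
  lab <- factor(rep(c("control", "dyslexic"), each = 4),
                levels = c("control", "dyslexic"))
  badFolds <- c(2, 2, 2, 2, 1, 1, 1, 2)  # fold 1 trains on one class only
  expect_error(runCV(x, lab, classifierRoster()["logistic"],
                     folds = badFolds), "degenerate")
})

test_that("test-fold labels never influence standardization or the fitted model", {
  fm <- gaussianFeatures(n = 30, p = 6, seed = 6, separation = 3)
  x <- featureValues(fm)
  labels <- subjectGroups(fm)
  folds <- stratifiedFolds(labels, 5, seed = 7)
  ref <- runCV(x, labels, classifierRoster()[c("logistic", "svmRBF")],
               folds = folds, seed = 7)
  # flip every label inside fold 1 (a pure test-fold mutation for fold 1)
  mutated <- labels
  flip <- folds == 1
  mutated[flip] <- ifelse(labels[flip] == "control", "dyslexic", "control")
  alt <- runCV(x, mutated, classifierRoster()[c("logistic", "svmRBF")],
               folds = folds, seed = 7)
  for (m in names(ref)) {
    # fold-1 standardization identical (fitted on training rows only)
    expect_identical(ref[[m]]@standardizers[[1]], alt[[m]]@standardizers[[1]])
    # fold-1 out-of-fold predictions identical
    expect_identical(ref[[m]]@predictions[flip], alt[[m]]@predictions[flip])
  }
})

test_that("reported fold means equal the average of per-fold metrics", {
  fm <- gaussianFeatures(n = 40, p = 5, seed = 8, separation = 2)
  x <- featureValues(fm)
  ev <- runCV(x, subjectGroups(fm), classifierRoster()["knn"], k = 5,
              seed = 3)[[1]]
  expect_equal(unname(ev@means["accuracy"]),
               mean(ev@perFold[, "accuracy"]))
  # metric identities on every stored confusion table
  for (f in seq_along(ev@confusions)) {
    cc <- ev@confusions[[f]]
    expect_equal(unname(ev@perFold[f, ]),
                 unname(computeMetrics(cc["tp"], cc["fn"], cc["tn"],
                                       cc["fp"])))
  }
})

test_that("permutation p is the exceedance fraction with sane bounds", {
  fm <- gaussianFeatures(n = 30, p = 4, seed = 9, separation = 20)
  x <- featureValues(fm)
  labels <- subjectGroups(fm)
  pt <- permutationTest(x, labels, classifierRoster()$logistic, R = 25,
                        seed = 11)
  expect_equal(pt@pValue, mean(pt@permuted >= pt@observed))
  expect_gte(pt@pValue, 0)
  expect_lte(pt@pValue, 1)
  # separable data: observed 100%, permutations cannot beat it often
  expect_equal(pt@observed, 100)
  expect_lt(pt@pValue, 0.2)
  expect_error(permutationTest(x, labels, classifierRoster()$logistic, R = 0),
               "R must be")
  # bias-corrected estimator never reports exactly zero
  pt2 <- permutationTest(x, labels, classifierRoster()$logistic, R = 10,
                         seed = 12, biasCorrected = TRUE)
  expect_gt(pt2@pValue, 0)
})

test_that("permutation test is deterministic given its seed", {
  fm <- gaussianFeatures(n = 20, p = 3, seed = 10)
  x <- featureValues(fm)
  labels <- subjectGroups(fm)
  a <- permutationTest(x, labels, classifierRoster()$logistic, R = 8,
                       seed = 5)
  b <- permutationTest(x, labels, classifierRoster()$logistic, R = 8,
                       seed = 5)
  expect_identical(a@permuted, b@permuted)
  expect_identical(a@pValue, b@pValue)
})
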
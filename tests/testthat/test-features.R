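test_that("subject aggregation computes mean, SD, CoV and count exactly", {
  tab <- data.frame(a = c(2, 2, 2), b = c(1, 2, 3), valid = TRUE)
  agg <- aggregateSubject(tab)
  g <- function(d, s) agg$value[agg$descriptor == d & agg$statistic == s]
  expect_equal(g("a", "mean"), 2)
  expect_equal(g("a", "sd"), 0)
  expect_equal(g("a", "cov"), 0)
  expect_equal(g("a", "n"), 3)
  expect_equal(g("b", "mean"), 2)
  expect_equal(g("b", "sd"), 1)      # sample (n-1) convention
  expect_equal(g("b", "cov"), 50)
})

test_that("aggregation marks empty and undefined cells aberrant", {
  none <- aggregateSubject(data.frame(a = c(1, 2), valid = c(FALSE, FALSE)))
  expect_true(all(none$aberrant[none$statistic != "n"]))
  expect_equal(none$value[none$statistic == "n"], 0)
  # zero mean: CoV undefined
  zm <- aggregateSubject(data.frame(a = c(-1, 0, 1), valid = TRUE))
  expect_true(zm$aberrant[zm$statistic == "cov"])
  # invalid rows are excluded from the statistics
  mix <- aggregateSubject(data.frame(a = c(1, 2, 3, 99),
                                     valid = c(TRUE, TRUE, TRUE, FALSE)))
  expect_equal(mix$value[mix$statistic == "mean"], 2)
  expect_equal(mix$value[mix$statistic == "n"], 3)
})

test_that("aggregation is invariant to trial order", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  a <- aggregateSubject(data.frame(a = x, valid = TRUE))
  b <- aggregateSubject(data.frame(a = rev(x), valid = TRUE))
  expect_equal(a, b)
})

test_that("classification cleaning zeroes aberrant cells and reports the fraction", {
  fm <- gaussianFeatures(n = 10, p = 4, seed = 2)
  clean <- cleanForClassification(fm)
  expect_equal(featureValues(clean), featureValues(fm))
  expect_equal(S4Vectors::metadata(clean)$aberrantFraction, 0)
  # plant aberrant cells
  v <- t(featureValues(fm)); m <- t(aberrantMask(fm))
  v[2, 3] <- 99; m[2, 3] <- TRUE
  fm2 <- featureMatrix(v, m, group = as.character(subjectGroups(fm)))
  clean2 <- cleanForClassification(fm2)
  expect_equal(t(featureValues(clean2))[2, 3], 0)
  expect_equal(S4Vectors::metadata(clean2)$aberrantFraction, 1 / length(v))
})

test_that("regression cleaning follows the percentile rule per class", {
  # two classes with known ordered values 1..100
  vals <- rbind(f1 = c(1:100, 1001:1100))
  grp <- rep(c("control", "dyslexic"), each = 100)
  colnames(vals) <- sprintf("S%03d", 1:200)
  fm <- featureMatrix(vals, group = grp, readingSpeed = 100)
  clean <- cleanForRegression(fm)
  x <- t(featureValues(clean))[1, ]
  # brute-force oracle: type-7 quantiles of each class
  q <- quantile(1:100, c(0.03, 0.97), type = 7)
  outliers <- which(1:100 < q[1] | 1:100 > q[2])
  expect_equal(sort(unique(x[1:100][outliers])), mean(1:100))
  expect_equal(x[1:100][-outliers], setNames(seq_along((1:100)[-outliers]) +
    min((1:100)[-outliers]) - 1, names(x[1:100][-outliers])), tolerance = 1e-12)
  # second class cleaned independently, replacement value is its own mean
  expect_equal(sort(unique(x[101:200][outliers])), mean(1001:1100))
  expect_equal(S4Vectors::metadata(clean)$replacedFraction,
               2 * length(outliers) / 200)
  # constant column untouched
  vals2 <- rbind(f1 = rep(5, 20))
  colnames(vals2) <- sprintf("S%03d", 1:20)
  fm2 <- featureMatrix(vals2, group = rep(c("control", "dyslexic"), 10),
                       readingSpeed = 100)
  expect_equal(unname(t(featureValues(cleanForRegression(fm2)))[1, ]),
               rep(5, 20))
})

test_that("regression cleaning never mixes information across classes", {
  withr::with_seed(7, {
    vals <- matrix(rnorm(300), nrow = 3,
                   dimnames = list(c("a.x.mean", "b.y.mean", "c.z.mean"),
                                   sprintf("S%03d", 1:100)))
    vals[, 51:100] <- vals[, 51:100] + 100  # disjoint class ranges
  })
  grp <- rep(c("control", "dyslexic"), each = 50)
  fm <- featureMatrix(vals, group = grp, readingSpeed = 100)
  clean <- cleanForRegression(fm)
  x <- t(featureValues(clean))
  # every control cell stays in the control range, far from the other class
  expect_true(all(x[, 1:50] < 50))
  expect_true(all(x[, 51:100] > 50))
})

test_that("subject shuffling is a seeded permutation preserving row-label pairs", {
  fm <- gaussianFeatures(n = 12, p = 3, seed = 5)
  s1 <- shuffleSubjects(fm, seed = 9)
  s2 <- shuffleSubjects(fm, seed = 9)
  expect_identical(colnames(s1), colnames(s2))
  expect_false(identical(colnames(s1), colnames(fm)))
  # multiset of (subject, group, speed, values) preserved
  ord <- match(colnames(fm), colnames(s1))
  expect_equal(featureValues(s1)[ord, ], featureValues(fm))
  expect_identical(as.character(subjectGroups(s1))[ord],
                   as.character(subjectGroups(fm)))
  # single-subject matrix is unchanged
  one <- fm[, 1]
  expect_identical(colnames(shuffleSubjects(one, seed = 3)), colnames(one))
})

test_that("a cohort-built matrix is rectangular with a consistent mask", {
  co <- generateCohort(cohortSpec(nControl = 2, nDyslexic = 2,
                                  readingWords = 15,
                                  vergenceProtocol = vergenceProtocol(3, 3),
                                  saccadeProtocol = saccadeProtocol(3, 3),
                                  seed = 55))
  fm <- buildFeatureMatrix(co)
  expect_identical(dim(featureValues(fm)), dim(aberrantMask(fm)))
  expect_identical(ncol(fm), 4L)
  rd <- SummarizedExperiment::rowData(fm)
  expect_true(all(rd$dataset %in% c("vergence", "saccade", "reading")))
  # aberrant cells are exactly the NA cells before cleaning
  expect_identical(unname(is.na(featureValues(fm))), unname(aberrantMask(fm)))
  # feature naming scheme is stable
  expect_true(all(grepl("^[a-zA-Z]+\\.[a-zA-Z0-9]+\\.(mean|sd|cov|n|value)$",
                        rownames(fm))))
})
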
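#' Classifier roster
#'
#' The model families evaluated in the dyslexia-screening analysis, each with
#' its complete hyperparameter record (no hidden defaults): L2 logistic
#' regression, linear SVM, RBF SVM with kernel width (gamma) 0.01, Gaussian
#' naive Bayes, linear discriminant, regularized quadratic discriminant,
#' k-nearest neighbours, Gaussian process classifier, a small multi-layer
#' perceptron and the two tree-based models (random forest, decision tree).
#' `lasso = TRUE` switches the logistic penalty from ridge to L1.
#'
#' @param lasso use L1 instead of L2 regularization for logistic regression.
#' @return named list of model specifications (lists with `id`, `family`,
#'   `linear` and hyperparameters).
#' @export
classifierRoster <- function(lasso = FALSE) {
  list(
    logistic = list(id = "logistic", family = "logistic", linear = TRUE,
                    alpha = if (lasso) 1 else 0, cost = 1),
    svmLinear = list(id = "svmLinear", family = "svm", linear = TRUE,
                     kernel = "linear", cost = 1),
    svmRBF = list(id = "svmRBF", family = "svm", linear = FALSE,
                  kernel = "radial", cost = 1, gamma = 0.01),
    naiveBayes = list(id = "naiveBayes", family = "naiveBayes",
                      linear = FALSE, sdFloor = 1e-6),
    lda = list(id = "lda", family = "lda", linear = TRUE),
    qda = list(id = "qda", family = "qda", linear = FALSE, reg = 1e-3),
    knn = list(id = "knn", family = "knn", linear = FALSE, k = 5),
    gaussianProcess = list(id = "gaussianProcess", family = "gp",
                           linear = FALSE, sigma = 0.5),
    mlp = list(id = "mlp", family = "mlp", linear = FALSE, size = 5,
               decay = 0.1, maxit = 300),
    randomForest = list(id = "randomForest", family = "randomForest",
                        linear = FALSE, ntree = 300),
    decisionTree = list(id = "decisionTree", family = "decisionTree",
                        linear = FALSE)
  )
}

# Standardization fitted on the training rows only; constant columns get a
# divisor floored at 1e-12 so they standardize to exactly zero.
fitStandardizer <- function(x) {
  list(mean = colMeans(x),
       sd = pmax(apply(x, 2, sd), 1e-12))
}

applyStandardizer <- function(std, x) {
  sweep(sweep(x, 2, std$mean, "-"), 2, std$sd, "/")
}

.dropConstant <- function(xtr, xte) {
  keep <- apply(xtr, 2, function(c) sd(c) > 0)
  if (!any(keep)) keep[1] <- TRUE
  list(train = xtr[, keep, drop = FALSE], test = xte[, keep, drop = FALSE])
}

# Regularized Gaussian quadratic discriminant: class-conditional Gaussians
# with covariance S_c + reg * mean(diag(S_c)) * I, equal priors from the
# training frequencies.
.qdaFit <- function(x, y, reg) {
  lapply(levels(y), function(lv) {
    xi <- x[y == lv, , drop = FALSE]
    mu <- colMeans(xi)
    S <- cov(xi)
    S <- S + diag(reg * mean(diag(S)) + 1e-10, ncol(x))
    ch <- chol(S)
    list(level = lv, mu = mu, chol = ch,
         logdet = 2 * sum(log(diag(ch))),
         logprior = log(nrow(xi) / nrow(x)))
  })
}

.qdaPredict <- function(fit, x, levels) {
  scores <- vapply(fit, function(f) {
    d <- sweep(x, 2, f$mu, "-")
    z <- backsolve(f$chol, t(d), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * f$logdet + f$logprior
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  factor(levels[max.col(scores)], levels = levels)
}

# Fit one roster model on standardized training data and predict the test
# rows. Stochastic learners are seeded for determinism.
fitPredictClassifier <- function(spec, xtr, ytr, xte, seed = 1L) {
  lv <- levels(ytr)
  withSeed(seed, switch(
    spec$family,
    logistic = {
      fit <- suppressWarnings(
        glmnet::glmnet(xtr, ytr, family = "binomial", alpha = spec$alpha,
                       lambda = 1 / (nrow(xtr) * spec$cost),
                       standardize = FALSE))
      p <- predict(fit, xte, type = "response")[, 1]
      factor(ifelse(p > 0.5, lv[2], lv[1]), levels = lv)
    },
    svm = {
      fit <- if (spec$kernel == "radial")
        e1071::svm(xtr, ytr, kernel = "radial", cost = spec$cost,
                   gamma = spec$gamma, scale = FALSE)
      else e1071::svm(xtr, ytr, kernel = "linear", cost = spec$cost,
                      scale = FALSE)
      predict(fit, xte)
    },
    naiveBayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], spec$sdFloor); tb
      })
      predict(fit, xte)
    },
    lda = {
      d <- .dropConstant(xtr, xte)
      fit <- suppressWarnings(MASS::lda(d$train, ytr))
      predict(fit, d$test)$class
    },
    qda = {
      d <- .dropConstant(xtr, xte)
      .qdaPredict(.qdaFit(d$train, ytr, spec$reg), d$test, lv)
    },
    knn = class::knn(xtr, xte, ytr, k = spec$k),
    gp = {
      fit <- kernlab::gausspr(xtr, ytr, kernel = "rbfdot",
                              kpar = list(sigma = spec$sigma),
                              type = "classification")
      kernlab::predict(fit, xte)
    },
    mlp = {
      y01 <- as.numeric(ytr == lv[2])
      fit <- nnet::nnet(xtr, y01, size = spec$size, decay = spec$decay,
                        maxit = spec$maxit, trace = FALSE, MaxNWts = 20000)
      p <- predict(fit, xte)[, 1]
      factor(ifelse(p > 0.5, lv[2], lv[1]), levels = lv)
    },
    randomForest = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = spec$ntree)
      predict(fit, xte)
    },
    decisionTree = {
      df <- data.frame(xtr, check.names = FALSE)
      df$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      predict(fit, data.frame(xte, check.names = FALSE), type = "class")
    },
    stop("unknown model family: ", spec$family)
  ))
}

#' Stratified cross-validation folds
#'
#' Shuffles subjects within each class with the given seed and deals them
#' into k folds round-robin, so every fold holds both classes whenever each
#' class has at least k members.
#'
#' @param labels class factor.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold assignment per subject.
#' @export
stratifiedFolds <- function(labels, k = 5, seed = 1L) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Confusion-table metrics
#'
#' Accuracy, sensitivity (true-positive rate, detection of the condition)
#' and specificity (true-negative rate), in percent. A metric whose
#' denominator is empty is returned as `NA` rather than silently zero.
#'
#' @param tp,fn,tn,fp confusion counts (positives = dyslexic).
#' @return named numeric vector (accuracy, sensitivity, specificity), %.
#' @export
computeMetrics <- function(tp, fn, tn, fp) {
  stopIfNot(all(c(tp, fn, tn, fp) >= 0) && (tp + fn + tn + fp) > 0,
            "counts must be non-negative with a positive total")
  c(accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Cross-validated evaluation of a classifier roster
#'
#' For each fold, the standardization parameters are fitted on the training
#' rows only and applied to both partitions; each roster model is then fitted
#' on the standardized training rows and evaluated on the held-out fold
#' (positive class = dyslexic). No hyperparameter tuning is performed.
#' Reported metrics are means over the k per-fold values.
#'
#' @param x subjects x features matrix.
#' @param labels factor with levels control, dyslexic.
#' @param roster model list from [classifierRoster()] (subset freely).
#' @param k number of folds.
#' @param seed run seed (fold construction and stochastic learners).
#' @param folds optional precomputed fold assignment (overrides `k`/seed
#'   stratification).
#' @return named list of [CVEvaluation], one per roster model.
#' @export
runCV <- function(x, labels, roster = classifierRoster(), k = 5, seed = 1L,
                  folds = NULL) {
  labels <- factor(labels, levels = c("control", "dyslexic"))
  stopIfNot(nrow(x) == length(labels), "one label per subject is required")
  stopIfNot(all(table(labels) >= if (is.null(folds)) k else 1),
            "each class needs at least k subjects")
  if (is.null(folds)) folds <- stratifiedFolds(labels, k, seed)
  k <- max(folds)
  stds <- vector("list", k)
  parts <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2)
      stop("degenerate split: training fold ", f, " holds a single class")
    std <- fitStandardizer(x[tr, , drop = FALSE])
    stds[[f]] <- std
    parts[[f]] <- list(
      xtr = applyStandardizer(std, x[tr, , drop = FALSE]),
      xte = applyStandardizer(std, x[!tr, , drop = FALSE]),
      ytr = labels[tr], yte = labels[!tr], te = which(!tr))
  }
  lapply(roster, function(spec) {
    perFold <- matrix(NA_real_, k, 3,
                      dimnames = list(NULL, c("accuracy", "sensitivity",
                                              "specificity")))
    confusions <- vector("list", k)
    preds <- factor(rep(NA, length(labels)), levels = levels(labels))
    for (f in seq_len(k)) {
      p <- parts[[f]]
      yhat <- fitPredictClassifier(spec, p$xtr, p$ytr, p$xte,
                                   seed = substreamSeed(seed, f))
      preds[p$te] <- yhat
      tp <- sum(yhat == "dyslexic" & p$yte == "dyslexic")
      fn <- sum(yhat == "control" & p$yte == "dyslexic")
      tn <- sum(yhat == "control" & p$yte == "control")
      fp <- sum(yhat == "dyslexic" & p$yte == "control")
      confusions[[f]] <- c(tp = tp, fn = fn, tn = tn, fp = fp)
      perFold[f, ] <- computeMetrics(tp, fn, tn, fp)
    }
    new("CVEvaluation", model = spec$id, foldAssignments = as.integer(folds),
        confusions = confusions, perFold = perFold,
        means = colMeans(perFold, na.rm = TRUE),
        predictions = preds, standardizers = stds, seed = as.integer(seed))
  })
}

#' Mean metrics of an evaluation
#' @param evaluation a [CVEvaluation].
#' @return named numeric vector (%, means over folds).
#' @export
meanMetrics <- function(evaluation) evaluation@means

#' Lexicographic model selection
#'
#' Picks the model with the highest mean accuracy; ties are broken by
#' sensitivity, then specificity, then by the (recorded) roster order.
#'
#' @param evaluations list of [CVEvaluation] (roster order preserved).
#' @return the winning model id.
#' @export
selectBest <- function(evaluations) {
  stopIfNot(length(evaluations) >= 1, "at least one evaluation is required")
  scores <- t(vapply(evaluations, function(e)
    e@means[c("accuracy", "sensitivity", "specificity")], numeric(3)))
  scores[is.na(scores)] <- -Inf
  ord <- order(-scores[, 1], -scores[, 2], -scores[, 3],
               seq_len(nrow(scores)))
  evaluations[[ord[1]]]@model
}

#' Label-permutation significance test
#'
#' Repeats the full cross-validation procedure R times with labels randomly
#' permuted over the entire dataset, records each permuted mean accuracy, and
#' reports the exceedance probability p = (# permuted >= observed) / R
#' (Monte-Carlo estimate; with `biasCorrected = TRUE` the
#' (1 + #) / (1 + R) estimator is used instead). With `refit = FALSE` the
#' observed fold assignment is reused for every permutation instead of
#' re-stratifying.
#'
#' @param x subjects x features matrix.
#' @param labels class factor.
#' @param spec one model specification from [classifierRoster()].
#' @param R number of permutations (default 1000).
#' @param k folds.
#' @param seed run seed.
#' @param refit re-derive stratified folds for each permutation.
#' @param biasCorrected use the add-one p estimator.
#' @return a [PermutationResult].
#' @export
permutationTest <- function(x, labels, spec, R = 1000, k = 5, seed = 1L,
                            refit = TRUE, biasCorrected = FALSE) {
  stopIfNot(R >= 1, "R must be >= 1")
  labels <- factor(labels, levels = c("control", "dyslexic"))
  obs <- runCV(x, labels, roster = list(spec), k = k,
               seed = seed)[[1]]@means["accuracy"]
  folds0 <- stratifiedFolds(labels, k, seed)
  permuted <- vapply(seq_len(R), function(r) {
    permSeed <- substreamSeed(seed, 1000 + r)
    yperm <- withSeed(permSeed, labels[sample(length(labels))])
    runCV(x, yperm, roster = list(spec), k = k,
          seed = substreamSeed(seed, 2000 + r),
          folds = if (refit) NULL else folds0)[[1]]@means["accuracy"]
  }, numeric(1))
  p <- if (biasCorrected) (1 + sum(permuted >= obs)) / (1 + R) else
    sum(permuted >= obs) / R
  new("PermutationResult", model = spec$id, observed = unname(obs),
      permuted = unname(permuted), pValue = p, seed = as.integer(seed))
}

#' @rdname permutationTest
#' @param result a [PermutationResult].
#' @export
pValue <- function(result) result@pValue
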
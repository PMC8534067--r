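#' Regression model roster
#'
#' The three reading-speed regression families: ordinary linear regression, a
#' small two-layer neural network (one hidden layer of 5 units, ~61 trainable
#' parameters with the 10 selected inputs) and support-vector regression with
#' an RBF kernel of width (gamma) 0.01.
#'
#' @return named list of model specifications.
#' @export
regressionRoster <- function() {
  list(
    linear = list(id = "linear", family = "linear"),
    neuralNet = list(id = "neuralNet", family = "neuralNet", size = 5,
                     decay = 0.01, maxit = 500),
    svr = list(id = "svr", family = "svr", kernel = "radial", gamma = 0.01,
               cost = 1, epsilon = 0.1)
  )
}

#' Mean absolute percentage error
#'
#' `100 * mean(|y - yhat| / y)`; defined only for strictly positive observed
#' values.
#'
#' @param truth observed values (> 0).
#' @param predictions predicted values.
#' @return MAPE in percent.
#' @export
mape <- function(truth, predictions) {
  stopIfNot(length(truth) == length(predictions),
            "truth and predictions must have equal length")
  stopIfNot(all(truth > 0), "MAPE requires strictly positive observed values")
  100 * mean(abs(truth - predictions) / truth)
}

#' Correlation-based feature selection on training rows
#'
#' Returns the `m` features with the largest absolute Pearson correlation
#' with the response, computed on the supplied (training) rows only.
#' Constant features have undefined correlation and are excluded. Ties are
#' broken deterministically by feature name; with `absolute = FALSE` the
#' ranking is by signed correlation, descending.
#'
#' @param x train-rows x features matrix (column names required).
#' @param y train responses.
#' @param m number of features to keep (all, if fewer are available).
#' @param absolute rank by |r| (default) or signed r.
#' @return data.frame `feature`, `r`, ordered by rank.
#' @export
selectFeatures <- function(x, y, m = 10, absolute = TRUE) {
  stopIfNot(nrow(x) >= 2, "feature selection needs at least 2 training rows")
  sds <- apply(x, 2, sd)
  usable <- which(sds > 0 & !is.na(sds))
  if (!length(usable))
    return(data.frame(feature = character(0), r = numeric(0)))
  r <- as.numeric(cor(x[, usable, drop = FALSE], y))
  names(r) <- colnames(x)[usable]
  key <- if (absolute) -abs(r) else -r
  ord <- order(key, names(r))
  sel <- ord[seq_len(min(m, length(ord)))]
  data.frame(feature = names(r)[sel], r = unname(r[sel]))
}

fitPredictRegressor <- function(spec, xtr, ytr, xte, seed = 1L) {
  withSeed(seed, switch(
    spec$family,
    linear = {
      fit <- lm.fit(cbind(1, xtr), ytr)
      b <- fit$coefficients
      b[is.na(b)] <- 0
      as.numeric(cbind(1, xte) %*% b)
    },
    neuralNet = {
      sc <- sd(ytr); if (sc == 0) sc <- 1
      mu <- mean(ytr)
      fit <- nnet::nnet(xtr, (ytr - mu) / sc, size = spec$size, linout = TRUE,
                        decay = spec$decay, maxit = spec$maxit, trace = FALSE)
      as.numeric(predict(fit, xte)) * sc + mu
    },
    svr = {
      fit <- e1071::svm(xtr, ytr, type = "eps-regression", kernel = "radial",
                        gamma = spec$gamma, cost = spec$cost,
                        epsilon = spec$epsilon, scale = FALSE)
      as.numeric(predict(fit, xte))
    },
    stop("unknown regression family: ", spec$family)
  ))
}

#' Plain cross-validation folds
#' @param n number of subjects.
#' @param k folds.
#' @param seed integer seed.
#' @return integer fold assignment.
#' @export
plainFolds <- function(n, k = 5, seed = 1L) {
  withSeed(seed, sample(rep_len(seq_len(k), n)))
}

#' Cross-validated reading-speed regression with fold-internal selection
#'
#' Per fold: the 10 most speed-correlated features are selected on the
#' training rows only, standardization is fitted on the training rows and
#' applied to both partitions, the model is fitted and the held-out fold
#' predicted. Out-of-fold predictions are pooled across folds before
#' computing MAPE and the Pearson correlation with the true speeds. The best
#' model is the one with the lowest MAPE.
#'
#' @param x subjects x features matrix.
#' @param speeds reading speeds (words/min, > 0).
#' @param roster models from [regressionRoster()].
#' @param m features selected per fold.
#' @param k folds.
#' @param seed run seed.
#' @param folds optional precomputed fold assignment.
#' @param absolute rank features by |r| (see [selectFeatures()]).
#' @return named list of [RegressionEvaluation].
#' @export
runCVRegression <- function(x, speeds, roster = regressionRoster(), m = 10,
                            k = 5, seed = 1L, folds = NULL, absolute = TRUE) {
  stopIfNot(nrow(x) == length(speeds), "one speed per subject is required")
  stopIfNot(all(speeds > 0), "speeds must be strictly positive")
  if (is.null(folds)) folds <- plainFolds(length(speeds), k, seed)
  k <- max(folds)
  parts <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    sel <- selectFeatures(x[tr, , drop = FALSE], speeds[tr], m, absolute)
    xtr <- x[tr, sel$feature, drop = FALSE]
    xte <- x[!tr, sel$feature, drop = FALSE]
    std <- fitStandardizer(xtr)
    parts[[f]] <- list(
      xtr = applyStandardizer(std, xtr), xte = applyStandardizer(std, xte),
      ytr = speeds[tr], te = which(!tr), selection = sel)
  }
  selection <- lapply(parts, `[[`, "selection")
  lapply(roster, function(spec) {
    preds <- numeric(length(speeds))
    for (f in seq_len(k)) {
      p <- parts[[f]]
      preds[p$te] <- fitPredictRegressor(spec, p$xtr, p$ytr, p$xte,
                                         seed = substreamSeed(seed, f))
    }
    new("RegressionEvaluation", model = spec$id, predictions = preds,
        truth = as.numeric(speeds), mape = mape(speeds, preds),
        pearson = cor(preds, speeds), foldAssignments = as.integer(folds),
        selection = selection, seed = as.integer(seed))
  })
}

#' Pooled out-of-fold predictions
#' @param evaluation a [RegressionEvaluation].
#' @return numeric vector of predictions (words/min).
#' @export
pooledPredictions <- function(evaluation) evaluation@predictions

#' Select the regression model with the lowest MAPE
#' @param evaluations list of [RegressionEvaluation].
#' @return model id.
#' @export
selectBestRegression <- function(evaluations) {
  stopIfNot(length(evaluations) >= 1, "at least one evaluation is required")
  mapes <- vapply(evaluations, function(e) e@mape, numeric(1))
  evaluations[[which.min(mapes)]]@model
}

#' Feature-selection stability report
#'
#' Features selected in at least `minFolds` of the cross-validation folds,
#' with their Pearson correlation against reading speed computed on the
#' entire dataset and the two-sided p-value of the standard t-transform.
#'
#' @param evaluation a [RegressionEvaluation] (carries the selection record).
#' @param x full subjects x features matrix.
#' @param speeds reading speeds.
#' @param minFolds minimum number of folds (default 4).
#' @return data.frame `feature`, `folds`, `r`, `p`, ordered by |r|.
#' @export
stabilityReport <- function(evaluation, x, speeds, minFolds = 4) {
  sel <- unlist(lapply(evaluation@selection, `[[`, "feature"))
  counts <- table(sel)
  keep <- names(counts)[counts >= minFolds]
  if (!length(keep))
    return(data.frame(feature = character(0), folds = integer(0),
                      r = numeric(0), p = numeric(0)))
  rows <- lapply(keep, function(f) {
    ct <- cor.test(x[, f], speeds)
    data.frame(feature = f, folds = as.integer(counts[f]),
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$r)), ]
}
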
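#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   rowData colData
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' Aggregate per-trial descriptors into per-subject statistics
#'
#' For each descriptor column, computes the mean, the sample (n-1) standard
#' deviation, the coefficient of variation (SD/mean x 100) and the number of
#' valid trials, over valid trials only. A cell is marked aberrant when no
#' valid trial contributes, when the SD is undefined (single trial), or, for
#' the CoV, when the mean is zero.
#'
#' @param trialTable data.frame with a logical `valid` column and numeric
#'   descriptor columns.
#' @param descriptors descriptor column names (default: all numeric columns
#'   except `valid`).
#' @return data.frame with columns `descriptor`, `statistic`
#'   (mean/sd/cov/n), `value`, `aberrant`.
#' @export
aggregateSubject <- function(trialTable, descriptors = NULL) {
  if (is.null(descriptors)) {
    descriptors <- setdiff(names(trialTable)[vapply(trialTable, is.numeric,
                                                    logical(1))], "valid")
  }
  rows <- lapply(descriptors, function(d) {
    x <- trialTable[[d]][trialTable$valid]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0) {
      value <- c(mean = NA_real_, sd = NA_real_, cov = NA_real_, n = 0)
      aber <- c(TRUE, TRUE, TRUE, FALSE)
    } else {
      m <- mean(x)
      s <- if (n > 1) sd(x) else NA_real_
      cv <- if (!is.na(s) && m != 0) s / m * 100 else NA_real_
      value <- c(mean = m, sd = s, cov = cv, n = n)
      aber <- c(FALSE, is.na(s), is.na(cv), FALSE)
    }
    data.frame(descriptor = d, statistic = names(value), value = unname(value),
               aberrant = aber, row.names = NULL)
  })
  do.call(rbind, rows)
}

.movementDescriptors <- function(test) {
  base <- c("latency", "phasicAmplitude", "amp80", "amp160", "totalAmplitude",
            "phasicDuration", "totalDuration", "peakVelocity",
            "averageVelocity", "drift1", "drift2")
  if (test == "saccade") c(base, "disconjugacy") else base
}

# Aggregate one subject's three recordings into a long feature table.
.subjectFeatureTable <- function(subject, config) {
  out <- list()
  verg <- extractTrials(subject$traces$vergence, config, "vergence")
  for (dir in c("convergence", "divergence")) {
    agg <- aggregateSubject(verg[verg$kind == dir, , drop = FALSE],
                            .movementDescriptors("vergence"))
    agg$test <- dir; agg$dataset <- "vergence"
    out[[dir]] <- agg
  }
  sacc <- extractTrials(subject$traces$saccade, config, "saccade")
  for (dir in c("saccadeLeft", "saccadeRight")) {
    agg <- aggregateSubject(sacc[sacc$kind == dir, , drop = FALSE],
                            .movementDescriptors("saccade"))
    agg$test <- dir; agg$dataset <- "saccade"
    out[[dir]] <- agg
  }
  rd <- computeReadingDescriptors(subject$traces$reading, config)
  runits <- rd$units
  if (nrow(runits)) {
    runits$valid <- TRUE
    ragg <- do.call(rbind, lapply(unique(runits$descriptor), function(d) {
      sub <- data.frame(value = runits$value[runits$descriptor == d],
                        valid = TRUE)
      a <- aggregateSubject(sub, "value")
      a$descriptor <- d
      a
    }))
  } else {
    ragg <- NULL
  }
  scal <- data.frame(descriptor = names(rd$scalars), statistic = "value",
                     value = unname(rd$scalars),
                     aberrant = is.na(rd$scalars) | !rd$valid)
  ragg <- rbind(ragg, scal)
  ragg$test <- "reading"; ragg$dataset <- "reading"
  out$reading <- ragg
  tab <- do.call(rbind, out)
  tab$feature <- paste(tab$test, tab$descriptor, tab$statistic, sep = ".")
  rownames(tab) <- NULL
  tab
}

#' Build the subjects-by-features matrix of a cohort
#'
#' Runs descriptor extraction and per-subject aggregation for every subject
#' and assembles the [FeatureMatrix]: features in rows (named
#' `<test>.<descriptor>.<statistic>`), subjects in columns, with the
#' aberrant-cell mask as a parallel assay and group label plus reading speed
#' in `colData`.
#'
#' @param cohort an [OculoCohort].
#' @param config an [extractionConfig()].
#' @return a [FeatureMatrix].
#' @export
buildFeatureMatrix <- function(cohort, config = extractionConfig()) {
  tabs <- lapply(cohort@subjects, .subjectFeatureTable, config = config)
  featNames <- unique(unlist(lapply(tabs, `[[`, "feature")))
  n <- length(cohort@subjects)
  values <- matrix(NA_real_, nrow = length(featNames), ncol = n,
                   dimnames = list(featNames,
                                   vapply(cohort@subjects, `[[`, "",
                                          "subject")))
  aberrant <- matrix(TRUE, nrow = length(featNames), ncol = n,
                     dimnames = dimnames(values))
  for (j in seq_len(n)) {
    tab <- tabs[[j]]
    idx <- match(tab$feature, featNames)
    values[idx, j] <- tab$value
    aberrant[idx, j] <- tab$aberrant | is.na(tab$value)
  }
  meta <- tabs[[1]][match(featNames, tabs[[1]]$feature),
                    c("test", "dataset", "descriptor", "statistic")]
  se <- SummarizedExperiment(
    assays = list(values = values, aberrant = aberrant),
    rowData = DataFrame(meta, row.names = featNames),
    colData = DataFrame(
      subject = colnames(values),
      group = vapply(cohort@subjects, `[[`, "", "group"),
      readingSpeed = vapply(cohort@subjects, `[[`, 0, "readingSpeed"),
      row.names = colnames(values))
  )
  new("FeatureMatrix", se)
}

#' Construct a FeatureMatrix from plain matrices
#'
#' Lower-level constructor used by the file readers and by tests.
#'
#' @param values features x subjects numeric matrix (dimnames required).
#' @param aberrant logical mask, same shape (default: `is.na(values)`).
#' @param group group label per subject.
#' @param readingSpeed reading speed per subject (words/min).
#' @param rowMeta optional data.frame with test/dataset/descriptor/statistic.
#' @return a [FeatureMatrix].
#' @export
featureMatrix <- function(values, aberrant = is.na(values), group,
                          readingSpeed = NA_real_, rowMeta = NULL) {
  stopIfNot(all(dim(values) == dim(aberrant)),
            "mask must have the shape of the value matrix")
  stopIfNot(length(group) == ncol(values),
            "one group label per subject is required")
  if (is.null(rowMeta)) {
    parts <- strsplit(rownames(values), ".", fixed = TRUE)
    ok <- all(lengths(parts) == 3)
    rowMeta <- if (ok) data.frame(
      test = vapply(parts, `[`, "", 1),
      dataset = ifelse(vapply(parts, `[`, "", 1) %in%
                         c("convergence", "divergence"), "vergence",
                ifelse(grepl("^saccade", vapply(parts, `[`, "", 1)),
                       "saccade", "reading")),
      descriptor = vapply(parts, `[`, "", 2),
      statistic = vapply(parts, `[`, "", 3)
    ) else data.frame(test = NA, dataset = NA, descriptor = NA,
                      statistic = NA)[rep(1, nrow(values)), ]
  }
  se <- SummarizedExperiment(
    assays = list(values = values, aberrant = aberrant),
    rowData = DataFrame(rowMeta, row.names = rownames(values)),
    colData = DataFrame(subject = colnames(values), group = group,
                        readingSpeed = rep(readingSpeed,
                                           length.out = ncol(values)),
                        row.names = colnames(values))
  )
  new("FeatureMatrix", se)
}

#' Accessors for FeatureMatrix
#'
#' `featureValues` returns the subjects x features numeric matrix (optionally
#' restricted to one dataset), `aberrantMask` the corresponding logical mask,
#' `subjectGroups` the group factor (levels control, dyslexic) and
#' `readingSpeeds` the speed vector.
#'
#' @param fm a [FeatureMatrix].
#' @param dataset optional dataset name ("vergence", "saccade", "reading").
#' @return see description.
#' @export
featureValues <- function(fm, dataset = NULL) {
  keep <- if (is.null(dataset)) rep(TRUE, nrow(fm)) else
    rowData(fm)$dataset %in% dataset
  t(assay(fm, "values")[keep, , drop = FALSE])
}

#' @rdname featureValues
#' @export
aberrantMask <- function(fm, dataset = NULL) {
  keep <- if (is.null(dataset)) rep(TRUE, nrow(fm)) else
    rowData(fm)$dataset %in% dataset
  t(assay(fm, "aberrant")[keep, , drop = FALSE])
}

#' @rdname featureValues
#' @export
subjectGroups <- function(fm) {
  factor(colData(fm)$group, levels = c("control", "dyslexic"))
}

#' @rdname featureValues
#' @export
readingSpeeds <- function(fm) {
  setNames(colData(fm)$readingSpeed, colnames(fm))
}

#' Replace aberrant cells by zero (classification preprocessing)
#'
#' Aberrant cells carry information (blinks, recording artifacts do not occur
#' at random), so they are encoded as 0 rather than imputed with an average.
#' The aberrant fraction is recorded in `metadata(fm)$aberrantFraction`.
#'
#' @param fm a [FeatureMatrix].
#' @return the cleaned [FeatureMatrix].
#' @export
cleanForClassification <- function(fm) {
  v <- assay(fm, "values")
  m <- assay(fm, "aberrant")
  v[m] <- 0
  assay(fm, "values") <- v
  metadata(fm)$aberrantFraction <- mean(m)
  fm
}

#' Winsorize tails to the class mean (regression preprocessing)
#'
#' Within each class and each feature, values strictly below the 3rd
#' percentile or strictly above the 97th percentile (linear-interpolation
#' quantiles) are replaced by the within-class feature mean computed before
#' replacement. Aberrant cells are likewise replaced by that mean so the
#' regression input is complete. No information crosses the class boundary.
#' The replaced-cell fraction is recorded in
#' `metadata(fm)$replacedFraction`.
#'
#' @param fm a [FeatureMatrix].
#' @param lower,upper tail probabilities (defaults 0.03 and 0.97).
#' @return the cleaned [FeatureMatrix].
#' @export
cleanForRegression <- function(fm, lower = 0.03, upper = 0.97) {
  v <- assay(fm, "values")
  m <- assay(fm, "aberrant")
  grp <- subjectGroups(fm)
  replaced <- 0L
  for (g in levels(grp)) {
    cols <- which(grp == g)
    if (!length(cols)) next
    for (i in seq_len(nrow(v))) {
      x <- v[i, cols]
      ok <- !m[i, cols] & !is.na(x)
      if (!any(ok)) next
      mu <- mean(x[ok])
      q <- quantile(x[ok], c(lower, upper), type = 7, names = FALSE)
      out <- ok & (x < q[1] | x > q[2])
      x[out | !ok] <- mu
      replaced <- replaced + sum(out)
      v[i, cols] <- x
    }
  }
  assay(fm, "values") <- v
  metadata(fm)$replacedFraction <- replaced / length(v)
  fm
}

#' Randomly permute subject order
#'
#' Applies one random permutation to the subject (column) order, carrying the
#' labels and speeds along; deterministic given the seed.
#'
#' @param fm a [FeatureMatrix].
#' @param seed integer seed.
#' @return the permuted [FeatureMatrix].
#' @export
shuffleSubjects <- function(fm, seed = 1L) {
  perm <- withSeed(seed, sample(ncol(fm)))
  fm[, perm]
}
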
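# File formats: locale-independent delimited text (tab-separated, dot
# decimal, UTF-8, one header line).

.readTable <- function(path, expected) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected))
    stop("malformed header in ", path, ": expected '",
         paste(expected, collapse = "\t"), "'", call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(nf != length(expected))
  if (length(bad))
    stop("parse error in ", path, " at line ", bad[1], ": expected ",
         length(expected), " fields, found ", nf[bad[1]], call. = FALSE)
  read.delim(path, sep = "\t", check.names = FALSE)
}

#' Read and write binocular trace files
#'
#' Traces are stored as tab-separated text with columns `time_s`,
#' `left_deg`, `right_deg`; stimulus events live in a sidecar file with
#' columns `onset_s`, `event_kind`. Writing then reading reproduces the
#' object exactly up to numeric text precision (15 significant digits).
#'
#' @param trace a [BinocularTrace].
#' @param path trace file path.
#' @param eventsPath sidecar event file path (default: `path` with an
#'   `.events.tsv` suffix).
#' @return `readTrace` returns a [BinocularTrace]; `writeTrace` the paths,
#'   invisibly.
#' @export
writeTrace <- function(trace, path, eventsPath = paste0(path, ".events.tsv")) {
  df <- data.frame(time_s = trace@time, left_deg = trace@left,
                   right_deg = trace@right)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- data.frame(onset_s = trace@events$onset,
                   event_kind = trace@events$kind)
  write.table(ev, eventsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, eventsPath))
}

#' @rdname writeTrace
#' @param sampleRate Hz; inferred from the median time step when NULL.
#' @export
readTrace <- function(path, eventsPath = paste0(path, ".events.tsv"),
                      sampleRate = NULL) {
  df <- .readTable(path, c("time_s", "left_deg", "right_deg"))
  ev <- .readTable(eventsPath, c("onset_s", "event_kind"))
  if (is.null(sampleRate))
    sampleRate <- 1 / stats::median(diff(df$time_s))
  new("BinocularTrace", time = df$time_s, left = df$left_deg,
      right = df$right_deg, sampleRate = sampleRate,
      events = data.frame(onset = ev$onset_s, kind = ev$event_kind))
}

#' Read and write feature-matrix files
#'
#' The feature matrix is stored with one row per subject: columns `subject`,
#' `group`, `readingSpeed`, then one column per feature; the aberrant mask
#' is a sidecar of the same shape with 0/1 cells.
#'
#' @param fm a [FeatureMatrix].
#' @param path matrix file path.
#' @param maskPath sidecar mask path (default `path` + `.mask.tsv`).
#' @return `readFeatureMatrix` returns a [FeatureMatrix]; the writer returns
#'   the paths invisibly.
#' @export
writeFeatureMatrix <- function(fm, path,
                               maskPath = paste0(path, ".mask.tsv")) {
  v <- featureValues(fm)
  df <- data.frame(subject = colnames(fm),
                   group = as.character(subjectGroups(fm)),
                   readingSpeed = readingSpeeds(fm), v,
                   check.names = FALSE)
  write.table(format(df, digits = 15, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  mk <- data.frame(subject = colnames(fm), aberrantMask(fm) * 1L,
                   check.names = FALSE)
  write.table(mk, maskPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, maskPath))
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path, maskPath = paste0(path, ".mask.tsv")) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  stopIfNot(identical(header[1:3], c("subject", "group", "readingSpeed")),
            paste0("malformed header in ", path))
  df <- .readTable(path, header)
  stopIfNot(nrow(df) > 0, "empty feature matrix: no subject rows")
  feats <- header[-(1:3)]
  values <- t(as.matrix(df[, feats, drop = FALSE]))
  colnames(values) <- df$subject
  mheader <- strsplit(readLines(maskPath, n = 1), "\t", fixed = TRUE)[[1]]
  mk <- .readTable(maskPath, mheader)
  mask <- t(as.matrix(mk[, feats, drop = FALSE])) == 1
  colnames(mask) <- mk$subject
  values[mask] <- NA_real_
  suppressWarnings(storage.mode(values) <- "double")
  featureMatrix(values, mask, group = df$group,
                readingSpeed = df$readingSpeed)
}

#' Pipeline configuration
#'
#' A plain named list fully determining a pipeline run; it round-trips
#' losslessly through its YAML file form ([writePipelineConfig()] /
#' [readPipelineConfig()]).
#'
#' @param nControl,nDyslexic cohort sizes.
#' @param seed master seed for the whole run.
#' @param readingWords words in the reading text.
#' @param datasets datasets to analyse.
#' @param classify,regress stage switches.
#' @param permutations label permutations per selected model (0 disables the
#'   permutation test).
#' @param folds cross-validation folds.
#' @param featureCount features selected per regression fold.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(nControl = 41, nDyslexic = 46, seed = 1L,
                           readingWords = 150,
                           datasets = c("vergence", "saccade", "reading"),
                           classify = TRUE, regress = TRUE,
                           permutations = 0L, folds = 5L,
                           featureCount = 10L) {
  structure(list(nControl = nControl, nDyslexic = nDyslexic,
                 seed = as.integer(seed), readingWords = readingWords,
                 datasets = datasets, classify = classify, regress = regress,
                 permutations = as.integer(permutations),
                 folds = as.integer(folds),
                 featureCount = as.integer(featureCount)),
            class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

.writeReport <- function(df, path) {
  write.table(format(df, digits = 6, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> extract -> features -> classify and/or regress with
#' everything determined by the configuration: generates the cohort, builds
#' and writes the feature matrix, evaluates the classifier roster per dataset
#' on the zero-imputed matrix (optionally with the label-permutation test on
#' the lexicographically best model), evaluates the regression roster on the
#' winsorized matrix, and writes per-stage reports plus an md5 manifest of
#' every output file.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @param verbose print stage messages.
#' @return (invisibly) list with the cohort, feature matrix and per-dataset
#'   results.
#' @export
runPipeline <- function(config, outDir, verbose = FALSE) {
  stopIfNot(inherits(config, "PipelineConfig"), "config must be a PipelineConfig")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  written <- character(0)

  say("simulate: generating cohort")
  spec <- cohortSpec(nControl = config$nControl, nDyslexic = config$nDyslexic,
                     readingWords = config$readingWords, seed = config$seed)
  cohort <- generateCohort(spec)

  say("extract/features: building feature matrix")
  fm <- buildFeatureMatrix(cohort)
  fmPath <- file.path(outDir, "features.tsv")
  writeFeatureMatrix(fm, fmPath)
  written <- c(written, fmPath, paste0(fmPath, ".mask.tsv"))

  results <- list(cohort = cohort, features = fm)
  labels <- subjectGroups(fm)

  if (isTRUE(config$classify)) {
    fmC <- cleanForClassification(fm)
    cls <- list()
    for (ds in config$datasets) {
      say("classify: ", ds)
      x <- featureValues(fmC, ds)
      evals <- runCV(x, labels, classifierRoster(), k = config$folds,
                     seed = config$seed)
      best <- selectBest(evals)
      rep <- do.call(rbind, lapply(evals, function(e)
        data.frame(model = e@model, t(e@means))))
      rep$best <- rep$model == best
      if (config$permutations > 0) {
        pt <- permutationTest(x, labels, classifierRoster()[[best]],
                              R = config$permutations, k = config$folds,
                              seed = config$seed)
        rep$pValue <- ifelse(rep$best, pt@pValue, NA)
        cls[[ds]] <- list(evaluations = evals, best = best,
                          permutation = pt)
      } else {
        cls[[ds]] <- list(evaluations = evals, best = best)
      }
      written <- c(written, .writeReport(
        rep, file.path(outDir, paste0("classification_", ds, ".tsv"))))
    }
    results$classification <- cls
  }

  if (isTRUE(config$regress)) {
    fmR <- cleanForRegression(fm)
    reg <- list()
    for (ds in config$datasets) {
      say("regress: ", ds)
      x <- featureValues(fmR, ds)
      evals <- runCVRegression(x, readingSpeeds(fm),
                               m = config$featureCount, k = config$folds,
                               seed = config$seed)
      best <- selectBestRegression(evals)
      rep <- do.call(rbind, lapply(evals, function(e)
        data.frame(model = e@model, mape = e@mape, pearson = e@pearson)))
      rep$best <- rep$model == best
      stab <- stabilityReport(evals[[best]], x, readingSpeeds(fm))
      reg[[ds]] <- list(evaluations = evals, best = best, stability = stab)
      written <- c(written, .writeReport(
        rep, file.path(outDir, paste0("regression_", ds, ".tsv"))))
      written <- c(written, .writeReport(
        stab, file.path(outDir, paste0("stability_", ds, ".tsv"))))
    }
    results$regression <- reg
  }

  say("manifest")
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  .writeReport(manifest, file.path(outDir, "manifest.tsv"))
  writePipelineConfig(config, file.path(outDir, "config.yaml"))
  invisible(results)
}

#' Verify a pipeline manifest
#'
#' Recomputes the md5 checksum of every file listed in `manifest.tsv` and
#' fails with the offending file name on any mismatch.
#'
#' @param outDir a directory written by [runPipeline()].
#' @return TRUE invisibly when all checksums match.
#' @export
verifyManifest <- function(outDir) {
  man <- .readTable(file.path(outDir, "manifest.tsv"), c("file", "md5"))
  for (i in seq_len(nrow(man))) {
    path <- file.path(outDir, man$file[i])
    stopIfNot(file.exists(path), paste0("missing pipeline output: ", man$file[i]))
    cur <- unname(tools::md5sum(path))
    if (!identical(cur, man$md5[i]))
      stop("checksum mismatch for ", man$file[i],
           ": the file changed after the pipeline wrote it", call. = FALSE)
  }
  invisible(TRUE)
}
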
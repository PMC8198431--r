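#' The full normalization chain
#'
#' Runs the preprocessing pipeline in its fixed order: missingness profiling,
#' analyte partition (exclude / binary / quantitative), kNN imputation of
#' calibrant-error cells, truncated-normal replacement of below-LOD cells,
#' log2 transform and parametric empirical-Bayes batch correction (plate =
#' batch). Sample metadata are never altered; analyte sets only shrink at the
#' partition step.
#'
#' With \code{trainIdx}, every estimated statistic (missingness fractions,
#' kNN donor pools, batch parameters) is computed on the training samples
#' only and applied to all samples — the leakage-free mode.
#'
#' @param x a linear-scale \linkS4class{MetabExperiment}.
#' @param calibrantTol,lodTol partition tolerances (defaults 0.10 / 0.50).
#' @param k kNN imputation neighbours (default 3).
#' @param seed seed for the truncated-normal replacement draws.
#' @param strata stratification for the missingness rules
#'   (\code{"cohort_group"} or \code{"group"}).
#' @param trainIdx optional sample indices for leakage-free estimation.
#' @return list of class \code{preprocessResult}: \code{corrected} (log2,
#'   batch-corrected quantitative experiment), \code{linear} (quantitative
#'   experiment on the linear scale after replacement, for class
#'   aggregation), \code{binaryCodes} (cell codes of the binary-set analytes,
#'   unreplaced), \code{partition}, \code{profile}, \code{log} (parameters
#'   and imputation fallbacks).
#' @export
preprocess <- function(x, calibrantTol = 0.10, lodTol = 0.50, k = 3,
                       seed = 1L, strata = c("cohort_group", "group"),
                       trainIdx = NULL) {
  strata <- match.arg(strata)
  profile <- profileMissingness(x, strata = strata, idx = trainIdx)
  partition <- partitionAnalytes(profile, calibrantTol, lodTol)
  kept <- x[c(partition$quantitative, partition$binary), ]
  imputed <- imputeCalibrantKNN(kept, k = k, donorIdx = trainIdx)
  binaryCodes <- cellCodes(imputed)[partition$binary, , drop = FALSE]
  quant <- replaceBelowLOD(imputed[partition$quantitative, ], seed = seed)
  logged <- log2Transform(quant)
  corrected <- batchCorrectEB(logged, trainIdx = trainIdx)
  structure(list(corrected = corrected, linear = quant,
                 binaryCodes = binaryCodes, partition = partition,
                 profile = profile,
                 log = list(calibrantTol = calibrantTol, lodTol = lodTol,
                            k = k, seed = seed, strata = strata,
                            strict = !is.null(trainIdx),
                            imputeFallbacks = metadata(imputed)$imputeLog)),
            class = "preprocessResult")
}

#' @export
print.preprocessResult <- function(x, ...) {
  print(x$partition)
  cat("corrected matrix:", nrow(x$corrected), "analytes x",
      ncol(x$corrected), "samples (log2, batch-corrected)\n")
  invisible(x)
}

#' Run the complete screening analysis
#'
#' One reproducible end-to-end run: simulate (or accept) a two-cohort
#' experiment, preprocess it, run the statistics battery pooled and per
#' cohort with cross-cohort concordance, aggregate metabolite classes,
#' embed the samples in 2-D, and train/evaluate the nested cross-validated
#' signature classifier (training + test on MOLTEST, validation on SMAC).
#' All stage seeds are fanned out deterministically from \code{seed}.
#'
#' In \code{mode = "strict"} the classifier additionally re-estimates all
#' preprocessing statistics without each outer fold's test samples
#' (leakage-guard); \code{mode = "paper"} preprocesses once on all samples,
#' which is the faithful reading of the original design.
#'
#' @param x a linear-scale \linkS4class{MetabExperiment} (e.g. from
#'   \code{\link{simulateCohort}} or \code{\link{readConcentrationCSV}}).
#' @param outDir optional directory; when given, the corrected matrix, the
#'   partition, the statistics and concordance tables, the classifier metric
#'   table, the embedding and a JSON run log are written there.
#' @param mode \code{"paper"} or \code{"strict"}.
#' @param calibrantTol,lodTol,k preprocessing parameters.
#' @param alpha significance level for reporting flags.
#' @param folds,perGroupTest,mrcvReps,trainFrac,delta,candidateCap classifier
#'   parameters (defaults 10, 10, 100, 0.70, 2, 60).
#' @param trainCohort,valCohort cohort labels used for training/validation.
#' @param runClassifier,runEmbedding set \code{FALSE} to skip the expensive
#'   stages.
#' @param seed master seed.
#' @return list of class \code{pipelineResult} with elements \code{prep},
#'   \code{batteryPooled}, \code{batteryPerCohort}, \code{concordance},
#'   \code{aggregates}, \code{embedding}, \code{classifier}, \code{config}.
#' @export
runPipeline <- function(x, outDir = NULL, mode = c("paper", "strict"),
                        calibrantTol = 0.10, lodTol = 0.50, k = 3,
                        alpha = 0.05, folds = 10, perGroupTest = 10,
                        mrcvReps = 100, trainFrac = 0.70, delta = 2,
                        candidateCap = 60, trainCohort = "MOLTEST",
                        valCohort = "SMAC", runClassifier = TRUE,
                        runEmbedding = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  seeds <- splitSeed(seed, 4L)
  config <- list(mode = mode, calibrantTol = calibrantTol, lodTol = lodTol,
                 k = k, alpha = alpha, folds = folds,
                 perGroupTest = perGroupTest, mrcvReps = mrcvReps,
                 trainFrac = trainFrac, delta = delta,
                 candidateCap = candidateCap, seed = seed,
                 stageSeeds = seeds)

  prep <- preprocess(x, calibrantTol, lodTol, k, seed = seeds[1])
  batteryPooled <- runBattery(prep$corrected, prep$partition,
                              mode = "pooled", alpha = alpha,
                              binaryCodes = prep$binaryCodes)
  batteryPC <- runBattery(prep$corrected, prep$partition,
                          mode = "per_cohort", alpha = alpha)
  conc <- concordance(batteryPC, alpha = alpha)
  aggregates <- aggregateClasses(prep$linear)
  embedding <- if (runEmbedding)
    embed2D(prep$corrected, seed = seeds[2]) else NULL

  classifier <- NULL
  if (runClassifier) {
    isTr <- sampleCohort(prep$corrected) == trainCohort
    isVa <- sampleCohort(prep$corrected) == valCohort
    Xall <- t(concentrations(prep$corrected))
    ytr <- sampleGroup(prep$corrected)[isTr]
    strictPrep <- NULL
    if (mode == "strict") {
      trainPos <- which(isTr)
      strictPrep <- function(testIdx) {
        keepIdx <- setdiff(seq_len(ncol(x)), trainPos[testIdx])
        sp <- preprocess(x, calibrantTol, lodTol, k, seed = seeds[1],
                         trainIdx = keepIdx)
        Xs <- t(concentrations(sp$corrected))
        feats <- intersect(colnames(Xall), colnames(Xs))
        list(Xpool = Xs[setdiff(which(isTr), trainPos[testIdx]), feats,
                        drop = FALSE],
             Xtest = Xs[trainPos[testIdx], feats, drop = FALSE],
             Xval = Xs[isVa, feats, drop = FALSE])
      }
    }
    classifier <- outerCV(Xall[isTr, , drop = FALSE], ytr,
                          Xall[isVa, , drop = FALSE],
                          sampleGroup(prep$corrected)[isVa],
                          folds = folds, perGroupTest = perGroupTest,
                          mrcvReps = mrcvReps, trainFrac = trainFrac,
                          delta = delta, candidateCap = candidateCap,
                          seed = seeds[3], strictPrep = strictPrep)
  }

  out <- structure(list(prep = prep, batteryPooled = batteryPooled,
                        batteryPerCohort = batteryPC, concordance = conc,
                        aggregates = aggregates, embedding = embedding,
                        classifier = classifier, config = config),
                   class = "pipelineResult")
  if (!is.null(outDir)) writeBundle(out, outDir)
  out
}

# write the artifact bundle: tables as TSV, corrected matrix as CSV, log JSON
writeBundle <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  writeConcentrationCSV(unlog2ForExport(res$prep$corrected),
                        p("corrected_matrix.csv"))
  part <- res$prep$partition
  writeResultTable(
    data.frame(analyte_id = c(part$quantitative, part$binary, part$excluded),
               set = rep(c("quantitative", "binary", "excluded"),
                         c(length(part$quantitative), length(part$binary),
                           length(part$excluded)))),
    p("partition.tsv"))
  writeResultTable(res$batteryPooled$quantitative, p("stats_pooled.tsv"))
  for (ch in names(res$batteryPerCohort$perCohort))
    writeResultTable(res$batteryPerCohort$perCohort[[ch]],
                     p(sprintf("stats_%s.tsv", ch)))
  writeResultTable(res$batteryPerCohort$quantitative, p("stats_combined.tsv"))
  writeResultTable(res$concordance, p("concordance.tsv"))
  writeResultTable(res$aggregates, p("class_aggregates.tsv"))
  if (!is.null(res$embedding))
    writeResultTable(res$embedding, p("embedding.tsv"))
  if (!is.null(res$classifier))
    writeResultTable(metricsTable(res$classifier), p("classifier_metrics.tsv"))
  jsonlite::write_json(res$config, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outDir)
}

# corrected log2 values exported on the linear scale for the CSV dialect
unlog2ForExport <- function(x) {
  out <- unlog2Transform(x)
  codes <- cellCodes(out)
  codes[codes %in% c("IMP", "REP")] <- "OBS"
  SummarizedExperiment::assay(out, "code", withDimnames = FALSE) <- codes
  out
}

#' Human-readable summary of a pipeline run
#'
#' Markdown summary with the classifier metrics table (Training / Test /
#' Validation rows), the per-group class-aggregate medians and the
#' cross-cohort concordance list.
#'
#' @param res a \code{pipelineResult}.
#' @param path optional file to write the markdown to.
#' @return the markdown text, invisibly when written to a file.
#' @export
makeReport <- function(res, path = NULL) {
  if (!inherits(res, "pipelineResult")) stop("incomplete bundle")
  L <- c("# Screening metabolomics run", "",
         sprintf("Mode: %s; seed %d; alpha %.2f.", res$config$mode,
                 res$config$seed, res$config$alpha), "")
  part <- res$prep$partition
  L <- c(L, sprintf(
    "Partition: %d quantitative, %d binary, %d excluded analytes.",
    length(part$quantitative), length(part$binary), length(part$excluded)),
    "")
  nSig <- sum(res$batteryPooled$quantitative$significant)
  L <- c(L, sprintf(
    "Pooled battery: %d of %d quantitative analytes FDR-significant at %.2f.",
    nSig, nrow(res$batteryPooled$quantitative), res$config$alpha), "")
  common <- res$concordance$analyte_id[res$concordance$common]
  L <- c(L, "## Cross-cohort concordance", "",
         if (length(common)) paste0("- ", common) else
           "No analyte is significant with a concordant direction in both cohorts.",
         "")
  if (!is.null(res$classifier)) {
    mt <- metricsTable(res$classifier)
    acc <- res$classifier$aggregate$test["accuracy", "mean"]
    L <- c(L, "## Classifier", "",
           paste0("| ", paste(colnames(mt), collapse = " | "), " |"),
           paste0("|", paste(rep("---", ncol(mt)), collapse = "|"), "|"),
           apply(mt, 1, function(r)
             paste0("| ", paste(r, collapse = " | "), " |")),
           "",
           sprintf(paste0("Mean held-out test accuracy %.1f%% ",
                          "(chance level in a three-class design: 33.3%%%s)."),
                   100 * acc,
                   if (abs(acc - 1 / 3) < 0.05)
                     "; performance is at chance level" else ""),
           "")
  }
  md <- paste(L, collapse = "\n")
  if (!is.null(path)) { writeLines(md, path); return(invisible(md)) }
  md
}
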
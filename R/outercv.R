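#' Nested cross-validated signature classifier
#'
#' The full three-class signature construction: an outer 10-fold CV over the
#' training cohort (MOLTEST) in which each fold's test set is a stratified
#' draw of \code{perGroupTest} samples per group (the folds partition 10 x 10
#' samples per group without replacement; surplus samples always train); on
#' the remaining pool, 100 repetitions of inner MRCV with forward-BIC
#' selection; consensus feature ranking with elbow cut; a final multinomial
#' logit refit on the whole pool with the consensus features; and evaluation
#' on the fold's held-out test set and on the entire validation cohort
#' (SMAC). Fold metrics are aggregated as means with normal-approximation
#' 95\% confidence intervals.
#'
#' To keep desk-scale runs tractable the candidate set is pre-screened per
#' fold to the \code{candidateCap} analytes with the smallest Kruskal-Wallis
#' p-values on that fold's pool; \code{candidateCap = Inf} disables the cap.
#'
#' @param Xtrain,ytrain training-cohort samples x features matrix and labels.
#' @param Xval,yval validation-cohort matrix (same features) and labels;
#'   optional.
#' @param folds number of outer folds (default 10).
#' @param perGroupTest test samples drawn per group per fold (default 10).
#' @param mrcvReps inner MRCV repetitions per fold (default 100).
#' @param trainFrac inner split fraction (default 0.70).
#' @param delta BIC stop parameter (default 2).
#' @param candidateCap per-fold candidate pre-screen size (default 60).
#' @param maxFeatures signature-length cap inside forward selection.
#' @param seed master seed; the whole procedure is deterministic given it.
#' @param strictPrep optional leakage-guard hook: a function taking the
#'   fold's test-sample indices and returning \code{list(Xpool, Xtest,
#'   Xval)} matrices whose preprocessing statistics were estimated without
#'   those test samples. When supplied, these matrices replace the
#'   (paper-faithful, jointly preprocessed) inputs fold by fold.
#' @return object of class \code{classifierReport}: per-fold results
#'   (consensus features, per-set metrics), aggregate mean/CI per metric and
#'   set, signature-size range, per-feature selection frequency across folds.
#' @export
outerCV <- function(Xtrain, ytrain, Xval = NULL, yval = NULL, folds = 10,
                    perGroupTest = 10, mrcvReps = 100, trainFrac = 0.70,
                    delta = 2, candidateCap = 60, maxFeatures = 25,
                    seed = 1L, strictPrep = NULL) {
  Xtrain <- as.matrix(Xtrain)
  ytrain <- factor(ytrain)
  if (!is.null(Xval)) {
    Xval <- as.matrix(Xval)
    if (!identical(colnames(Xval), colnames(Xtrain)))
      stop("training and validation feature sets differ")
    yval <- factor(yval, levels = levels(ytrain))
  }
  strata <- split(seq_along(ytrain), ytrain)
  if (any(vapply(strata, length, integer(1)) < folds * perGroupTest))
    stop("a group is too small for ", folds, " folds of ", perGroupTest)
  seeds <- splitSeed(seed, folds + 1L)
  # stratified partition: shuffled first folds*perGroupTest samples per group
  foldOf <- withSeed(seeds[folds + 1L], {
    f <- rep(NA_integer_, length(ytrain))
    for (s in strata) {
      chosen <- sample(s, folds * perGroupTest)
      f[chosen] <- rep(seq_len(folds), each = perGroupTest)
    }
    f
  })

  foldResults <- vector("list", folds)
  for (f in seq_len(folds)) {
    testIdx <- which(foldOf == f)
    poolIdx <- setdiff(seq_along(ytrain), testIdx)
    if (is.null(strictPrep)) {
      Xp <- Xtrain[poolIdx, , drop = FALSE]
      Xte <- Xtrain[testIdx, , drop = FALSE]
      Xva <- Xval
    } else {
      sp <- strictPrep(testIdx)
      Xp <- sp$Xpool; Xte <- sp$Xtest; Xva <- sp$Xval
    }
    yp <- droplevels(ytrain[poolIdx])
    cand <- colnames(Xp)
    if (is.finite(candidateCap) && candidateCap < ncol(Xp)) {
      pkw <- vapply(cand, function(a)
        kruskalWallis(Xp[, a], yp)$p, numeric(1))
      cand <- cand[order(pkw)][seq_len(candidateCap)]
    }
    inner <- mrcv(Xp, yp, reps = mrcvReps, trainFrac = trainFrac,
                  delta = delta, candidates = cand, seed = seeds[f],
                  maxFeatures = maxFeatures)
    consensus <- rankAndCut(inner)
    if (!length(consensus)) consensus <- cand[1]   # degenerate null pool
    fit <- fitMLR(Xp[, consensus, drop = FALSE], yp)
    res <- list(
      fold = f, consensus = consensus,
      train = evaluateModel(fit, Xp[, consensus, drop = FALSE], yp),
      test = evaluateModel(fit, Xte[, consensus, drop = FALSE],
                           ytrain[testIdx]))
    if (!is.null(Xva))
      res$validation <- evaluateModel(fit, Xva[, consensus, drop = FALSE],
                                      yval)
    foldResults[[f]] <- res
  }

  sets <- c("train", "test", if (!is.null(Xval)) "validation")
  metrics <- c("accuracy", "auc", "balanced_accuracy")
  agg <- lapply(sets, function(s) {
    t(vapply(metrics, function(m) {
      v <- vapply(foldResults, function(fr) fr[[s]][[m]], numeric(1))
      se <- stats::sd(v) / sqrt(length(v))
      c(mean = mean(v), lo = mean(v) - 1.96 * se, hi = mean(v) + 1.96 * se)
    }, numeric(3)))
  })
  names(agg) <- sets
  sizes <- vapply(foldResults, function(fr) length(fr$consensus), integer(1))
  freq <- sort(table(unlist(lapply(foldResults, `[[`, "consensus"))),
               decreasing = TRUE)
  structure(list(folds = foldResults, aggregate = agg,
                 signatureSizes = sizes, selectionFrequency = freq,
                 levels = levels(ytrain), seed = seed),
            class = "classifierReport")
}

#' @export
print.classifierReport <- function(x, ...) {
  cat("classifierReport:", length(x$folds), "outer folds; signature sizes",
      min(x$signatureSizes), "-", max(x$signatureSizes), "\n")
  for (s in names(x$aggregate)) {
    a <- x$aggregate[[s]]
    cat(sprintf("  %-10s accuracy %5.1f%% (%4.1f-%4.1f)  AUC %.2f (%.2f-%.2f)\n",
                s, 100 * a["accuracy", "mean"], 100 * a["accuracy", "lo"],
                100 * a["accuracy", "hi"], a["auc", "mean"],
                a["auc", "lo"], a["auc", "hi"]))
  }
  invisible(x)
}

#' Metrics table in the reporting shape of the study design
#'
#' One row per evaluation set (Training / Test / Validation), columns for
#' overall accuracy, overall AUC and balanced accuracy, each as
#' \code{mean (95\% CI)} over the outer folds.
#'
#' @param report a \code{classifierReport}.
#' @return \code{data.frame}.
#' @export
metricsTable <- function(report) {
  rows <- lapply(names(report$aggregate), function(s) {
    a <- report$aggregate[[s]]
    fmt <- function(m, pct) {
      v <- a[m, ]
      if (pct) sprintf("%.1f (%.1f-%.1f)", 100 * v["mean"], 100 * v["lo"],
                       100 * v["hi"])
      else sprintf("%.2f (%.2f-%.2f)", v["mean"], v["lo"], v["hi"])
    }
    data.frame(Set = c(train = "Training", test = "Test",
                       validation = "Validation")[s],
               `Overall Accuracy %` = fmt("accuracy", TRUE),
               `Overall AUC` = fmt("auc", FALSE),
               `Balanced Accuracy %` = fmt("balanced_accuracy", TRUE),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
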
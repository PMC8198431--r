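#' Forward feature selection under a BIC improvement rule
#'
#' Greedy forward selection for the multinomial logit: at each step the
#' candidate whose addition gives the lowest BIC is considered, and accepted
#' only while it improves the current BIC by more than \code{delta} (the
#' evidence-grade reading of a BIC difference of 2). The trace records the
#' addition order and the BIC after each accepted step; accepted BICs
#' therefore decrease by more than \code{delta} at every step.
#'
#' @param X samples x features matrix (candidate features are its columns).
#' @param y class labels.
#' @param delta BIC improvement required to continue (default 2).
#' @param candidates candidate feature names or column indices (default all).
#' @param maxFeatures safety cap on the signature length.
#' @return list of class \code{selectionTrace}: \code{features} (in addition
#'   order), \code{bic} (after each addition), \code{bic0} (intercept-only),
#'   \code{stop} reason.
#' @export
forwardSelect <- function(X, y, delta = 2, candidates = NULL,
                          maxFeatures = 25) {
  X <- as.matrix(X)
  y <- factor(y)
  if (is.null(candidates)) candidates <- seq_len(ncol(X))
  if (is.character(candidates)) candidates <- match(candidates, colnames(X))
  if (!length(candidates)) stop("zero candidate features")
  res <- cpp_forward_select(X, as.integer(y) - 1L, nlevels(y),
                            as.integer(candidates) - 1L, delta,
                            as.integer(maxFeatures), 1e-8, 200L)
  structure(list(features = colnames(X)[res$order + 1L],
                 indices = res$order + 1L,
                 bic = res$bic, bic0 = res$bic0, stop = res$stop),
            class = "selectionTrace")
}

#' @export
print.selectionTrace <- function(x, ...) {
  cat("selectionTrace:", length(x$features), "features [",
      paste(x$features, collapse = ", "), "] stop:", x$stop, "\n")
  invisible(x)
}

#' Multiple random cross-validation (MRCV)
#'
#' Repeats \code{reps} times: a stratified random split of the pool into
#' train (70\%) and test (30\%), forward-BIC selection and model fit on the
#' train part, MAP classification and accuracy on both parts.
#'
#' @param X pool samples x features matrix.
#' @param y pool class labels.
#' @param reps number of random splits (default 100).
#' @param trainFrac train fraction (default 0.70).
#' @param delta BIC stop parameter.
#' @param candidates candidate feature names/indices passed to
#'   \code{\link{forwardSelect}}.
#' @param seed RNG seed; the split sequence is deterministic given it.
#' @param maxFeatures signature-length cap.
#' @return list of class \code{mrcvResult}: \code{traces} (one
#'   \code{selectionTrace} per rep), \code{trainAcc}, \code{testAcc}.
#' @export
mrcv <- function(X, y, reps = 100, trainFrac = 0.70, delta = 2,
                 candidates = NULL, seed = 1L, maxFeatures = 25) {
  X <- as.matrix(X)
  y <- factor(y)
  strata <- split(seq_along(y), y)
  if (any(vapply(strata, length, integer(1)) < 2))
    stop("a stratum is too small to split")
  seeds <- splitSeed(seed, reps)
  traces <- vector("list", reps)
  trainAcc <- testAcc <- numeric(reps)
  for (r in seq_len(reps)) {
    trainIdx <- withSeed(seeds[r], unlist(lapply(strata, function(i)
      sample(i, round(trainFrac * length(i))))))
    testIdx <- setdiff(seq_along(y), trainIdx)
    tr <- forwardSelect(X[trainIdx, , drop = FALSE], y[trainIdx],
                        delta = delta, candidates = candidates,
                        maxFeatures = maxFeatures)
    fit <- fitMLR(X[trainIdx, tr$features, drop = FALSE], y[trainIdx])
    predTr <- mapClass(predictProbMLR(fit, X[trainIdx, tr$features,
                                             drop = FALSE]))
    predTe <- mapClass(predictProbMLR(fit, X[testIdx, tr$features,
                                             drop = FALSE]))
    traces[[r]] <- tr
    trainAcc[r] <- mean(predTr == y[trainIdx])
    testAcc[r] <- mean(predTe == y[testIdx])
  }
  structure(list(traces = traces, trainAcc = trainAcc, testAcc = testAcc),
            class = "mrcvResult")
}

#' Consensus feature ranking with elbow cut
#'
#' Features are scored by selection frequency across the traces, ties broken
#' by mean addition position (earlier is better). The sorted frequency curve
#' is cut at its elbow: the point of maximum perpendicular distance from the
#' chord joining the curve's first and last points; features at or before the
#' elbow form the consensus. With fewer than three scored features, all are
#' returned.
#'
#' @param traces list of \code{selectionTrace}s (or an \code{mrcvResult}).
#' @return character vector of consensus feature ids (may be empty when all
#'   traces are empty).
#' @export
rankAndCut <- function(traces) {
  if (inherits(traces, "mrcvResult")) traces <- traces$traces
  if (!length(traces)) stop("no traces")
  feats <- unlist(lapply(traces, `[[`, "features"))
  if (!length(feats)) return(character(0))
  pos <- unlist(lapply(traces, function(t) seq_along(t$features)))
  freq <- table(feats)
  meanPos <- tapply(pos, feats, mean)
  ord <- order(-as.vector(freq), as.vector(meanPos), names(freq))
  score <- as.vector(freq)[ord]
  ids <- names(freq)[ord]
  m <- length(ids)
  if (m <= 2) return(ids)
  # chord from (1, s1) to (m, sm); perpendicular distance per point
  dx <- m - 1; dy <- score[m] - score[1]
  d <- abs(dx * (score - score[1]) - dy * (seq_len(m) - 1)) /
    sqrt(dx ^ 2 + dy ^ 2)
  ids[seq_len(which.max(d))]
}
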
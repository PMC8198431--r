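#' Parametric empirical-Bayes batch correction
#'
#' Location/scale batch adjustment of a log2 concentration matrix, with one
#' 96-well plate treated as one batch. Per analyte the matrix is standardized
#' against the (batch-size-weighted) grand mean and pooled variance; per
#' batch, additive (\eqn{\gamma}) and multiplicative (\eqn{\delta^2}) batch
#' parameters are estimated per analyte, shrunk towards method-of-moments
#' normal / inverse-gamma priors shared across analytes within the batch
#' (iterative EB solution), and removed; finally the grand mean and pooled
#' variance are restored.
#'
#' With \code{trainIdx} the standardization and the EB batch parameters are
#' estimated on the training samples only and applied to all samples
#' (leakage-free mode); a batch with no training samples falls back to its
#' own samples for the batch-parameter estimate.
#'
#' @param x a log2-scale \linkS4class{MetabExperiment}, or a numeric matrix
#'   (analytes x samples) if \code{batch} is supplied.
#' @param batch batch labels per sample; defaults to the plate id.
#' @param trainIdx optional sample indices used for parameter estimation.
#' @return Object of the same type with corrected values.
#' @examples
#' spec <- cohortSpec(groupSizes = list(A = c(8, 8, 8)), seed = 4)
#' m <- log2Transform(replaceBelowLOD(simulateCohort(spec), seed = 1))
#' mc <- batchCorrectEB(m)
#' @export
batchCorrectEB <- function(x, batch = NULL, trainIdx = NULL) {
  isME <- methods::is(x, "MetabExperiment")
  if (isME) {
    if (!isTRUE(metadata(x)$logScale))
      stop("batch correction expects a log2-scale experiment")
    if (is.null(batch)) batch <- samplePlate(x)
    X <- concentrations(x)
  } else X <- as.matrix(x)
  if (is.null(batch)) stop("batch labels required for a plain matrix")
  if (anyNA(X)) stop("batch correction requires complete values")
  batch <- as.character(batch)
  if (length(batch) != ncol(X)) stop("batch length != number of samples")

  est <- if (is.null(trainIdx)) seq_len(ncol(X)) else sort(unique(trainIdx))
  tabAll <- table(batch)
  if (any(tabAll < 2)) stop("every batch needs >= 2 samples")
  batches <- names(tabAll)
  if (length(batches) == 1L) return(x)        # nothing to correct

  # estimation set per batch; a batch unseen in training uses its own samples
  estIdx <- lapply(batches, function(b) {
    i <- intersect(est, which(batch == b))
    if (length(i) < 2) i <- which(batch == b)
    i
  })
  names(estIdx) <- batches
  nEst <- vapply(estIdx, length, integer(1))

  # standardization from the estimation samples
  batchMeans <- vapply(estIdx, function(i) rowMeans(X[, i, drop = FALSE]),
                       numeric(nrow(X)))                       # G x B
  grandMean <- as.vector(batchMeans %*% (nEst / sum(nEst)))
  resid <- X[, unlist(estIdx), drop = FALSE] -
    batchMeans[, rep(batches, nEst), drop = FALSE]
  varPooled <- rowMeans(resid ^ 2)
  if (any(varPooled <= 0))
    stop("zero-variance analyte: ", rownames(X)[which(varPooled <= 0)[1]])
  sdPooled <- sqrt(varPooled)
  Z <- (X - grandMean) / sdPooled

  Zadj <- Z
  for (b in batches) {
    iEst <- estIdx[[b]]
    iAll <- which(batch == b)
    Zb <- Z[, iEst, drop = FALSE]
    gammaHat <- rowMeans(Zb)
    deltaHat <- matrixStats::rowVars(Zb)
    nb <- length(iEst)
    # method-of-moments hyperpriors across analytes
    gBar <- mean(gammaHat); tau2 <- stats::var(gammaHat)
    m <- mean(deltaHat); s2 <- stats::var(deltaHat)
    aPrior <- (2 * s2 + m ^ 2) / s2
    bPrior <- (m * s2 + m ^ 3) / s2
    gStar <- gammaHat; dStar <- deltaHat
    for (it in 1:200) {
      gNew <- (tau2 * nb * gammaHat + dStar * gBar) / (tau2 * nb + dStar)
      ssq <- rowSums((Zb - gNew) ^ 2)
      dNew <- (0.5 * ssq + bPrior) / (nb / 2 + aPrior - 1)
      if (max(abs(gNew - gStar) / (abs(gStar) + 1e-8),
              abs(dNew - dStar) / (abs(dStar) + 1e-8)) < 1e-6) {
        gStar <- gNew; dStar <- dNew; break
      }
      gStar <- gNew; dStar <- dNew
    }
    Zadj[, iAll] <- (Z[, iAll, drop = FALSE] - gStar) / sqrt(dStar)
  }
  Xadj <- Zadj * sdPooled + grandMean
  if (!isME) return(Xadj)
  out <- x
  SummarizedExperiment::assay(out, "conc", withDimnames = FALSE) <- Xadj
  metadata(out)$batchCorrected <- TRUE
  validObject(out)
  out
}

#' 2-D UMAP embedding for dataset-structure visualization
#'
#' Uniform manifold approximation and projection of the samples of a
#' corrected experiment into two dimensions; used only for visual inspection
#' of cohort/group/plate structure, never in the statistics.
#'
#' @param x log2-scale, complete \linkS4class{MetabExperiment} or numeric
#'   matrix (analytes x samples).
#' @param seed RNG seed (the embedding is deterministic given it).
#' @param nNeighbors,minDist UMAP hyperparameters.
#' @return \code{data.frame} with \code{sample_id}, \code{x}, \code{y}.
#' @export
embed2D <- function(x, seed = 1L, nNeighbors = 15, minDist = 0.1) {
  X <- if (methods::is(x, "MetabExperiment")) concentrations(x) else
    as.matrix(x)
  if (anyNA(X)) stop("embedding requires complete values")
  if (ncol(X) <= nNeighbors)
    stop("fewer samples than the neighbourhood size")
  emb <- withSeed(seed,
                  uwot::umap(t(X), n_neighbors = nNeighbors,
                             min_dist = minDist, n_threads = 1,
                             n_sgd_threads = 0, batch = FALSE))
  data.frame(sample_id = colnames(X), x = emb[, 1], y = emb[, 2],
             stringsAsFactors = FALSE)
}
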
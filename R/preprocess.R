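#' Per-stratum missingness profile
#'
#' Computes, for every analyte and every stratum of samples, the fraction of
#' calibrant-error missing cells (\code{MISS}) and of below-LOD cells
#' (\code{BLOD}). Strata are cohort x group by default (the stricter
#' "each patient's group" reading); \code{strata = "group"} pools cohorts.
#'
#' @param x a \linkS4class{MetabExperiment}.
#' @param strata \code{"cohort_group"} (default) or \code{"group"}.
#' @param idx optional column (sample) indices to restrict the profile to,
#'   e.g. a training set in leakage-free mode.
#' @return \code{data.frame} with columns \code{analyte_id}, \code{cohort},
#'   \code{group}, \code{n}, \code{frac_missing}, \code{frac_blod}.
#' @export
profileMissingness <- function(x, strata = c("cohort_group", "group"),
                               idx = NULL) {
  strata <- match.arg(strata)
  if (ncol(x) == 0 || nrow(x) == 0) stop("empty experiment")
  if (!is.null(idx)) x <- x[, idx]
  codes <- cellCodes(x)
  key <- if (strata == "cohort_group")
    paste(sampleCohort(x), as.character(sampleGroup(x)), sep = "\r")
  else paste("pooled", as.character(sampleGroup(x)), sep = "\r")
  out <- lapply(split(seq_len(ncol(x)), key), function(cols) {
    cc <- codes[, cols, drop = FALSE]
    data.frame(analyte_id = rownames(x),
               n = length(cols),
               frac_missing = rowMeans(cc == "MISS"),
               frac_blod = rowMeans(cc == "BLOD"),
               stringsAsFactors = FALSE)
  })
  keys <- do.call(rbind, strsplit(rep(names(out),
                                      each = nrow(x)), "\r", fixed = TRUE))
  res <- do.call(rbind, out)
  res$cohort <- keys[, 1]
  res$group <- keys[, 2]
  rownames(res) <- NULL
  res[, c("analyte_id", "cohort", "group", "n", "frac_missing", "frac_blod")]
}

#' Partition analytes by missingness burden
#'
#' Applies the exclusion rules of the normalization chain: an analyte is
#' \emph{excluded} if its calibrant-missing fraction exceeds
#' \code{calibrantTol} in any stratum; otherwise it goes to the
#' \emph{binary} (presence/absence) set if its below-LOD fraction exceeds
#' \code{lodTol} in any stratum; otherwise it is \emph{quantitative}.
#'
#' @param profile output of \code{\link{profileMissingness}} on the full
#'   dataset.
#' @param calibrantTol tolerated calibrant-missing fraction per stratum
#'   (default 0.10).
#' @param lodTol tolerated below-LOD fraction per stratum (default 0.50).
#' @return list of class \code{analytePartition} with character vectors
#'   \code{quantitative}, \code{binary}, \code{excluded} (disjoint, union =
#'   input analytes).
#' @export
partitionAnalytes <- function(profile, calibrantTol = 0.10, lodTol = 0.50) {
  if (calibrantTol < 0 || calibrantTol > 1 || lodTol < 0 || lodTol > 1)
    stop("tolerances must lie in [0, 1]")
  maxMiss <- tapply(profile$frac_missing, profile$analyte_id, max)
  maxBlod <- tapply(profile$frac_blod, profile$analyte_id, max)
  ids <- unique(profile$analyte_id)        # preserve input order
  maxMiss <- maxMiss[ids]; maxBlod <- maxBlod[ids]
  excluded <- ids[maxMiss > calibrantTol]
  binary <- ids[maxMiss <= calibrantTol & maxBlod > lodTol]
  quantitative <- setdiff(ids, c(excluded, binary))
  structure(list(quantitative = quantitative, binary = binary,
                 excluded = excluded,
                 calibrantTol = calibrantTol, lodTol = lodTol),
            class = "analytePartition")
}

#' @export
print.analytePartition <- function(x, ...) {
  cat("analytePartition:", length(x$quantitative), "quantitative /",
      length(x$binary), "binary /", length(x$excluded), "excluded\n")
  invisible(x)
}

#' k-nearest-neighbour imputation of calibrant-error missing cells
#'
#' Fills every \code{MISS} cell with the mean of the \code{k} nearest donor
#' samples' values for that analyte. Donors are drawn from the same group and
#' the same plate; nearness is correlation distance (1 - Pearson r) over
#' analytes observed in both samples, requiring at least \code{minShared}
#' shared observations. When fewer than \code{k} eligible donors exist the
#' pool widens to the same group across plates, and finally to the stratum
#' median for that analyte; every fallback is logged.
#'
#' @param x a \linkS4class{MetabExperiment} (linear scale, after
#'   partitioning).
#' @param k number of neighbours averaged (default 3).
#' @param minShared minimum shared observed analytes for a donor's
#'   correlation to count (default 10).
#' @param donorIdx optional sample indices donors may be drawn from (training
#'   set in leakage-free mode); recipients outside it are still filled.
#' @return The experiment with \code{MISS} cells recoded \code{IMP}; the
#'   fallback log is in \code{metadata(.)$imputeLog}.
#' @export
imputeCalibrantKNN <- function(x, k = 3, minShared = 10, donorIdx = NULL) {
  conc <- concentrations(x)
  codes <- cellCodes(x)
  grp <- as.character(sampleGroup(x))
  plate <- samplePlate(x)
  donorOK <- rep(TRUE, ncol(x))
  if (!is.null(donorIdx)) {
    donorOK <- rep(FALSE, ncol(x)); donorOK[donorIdx] <- TRUE
  }
  obs <- codes == "OBS"                # only true observations inform donors
  concObs <- conc
  concObs[!obs] <- NA_real_
  # donor ranking works on log2 profiles so that a handful of high-abundance
  # analytes cannot dominate the correlation; imputed values stay linear
  distObs <- log2(pmax(concObs, .Machine$double.xmin))

  fallbacks <- list()
  targets <- which(codes == "MISS", arr.ind = TRUE)
  if (nrow(targets)) {
    for (s in unique(targets[, "col"])) {
      rows <- targets[targets[, "col"] == s, "row"]
      samePlate <- which(grp == grp[s] & plate == plate[s] & donorOK &
                           seq_len(ncol(x)) != s)
      sameGroup <- which(grp == grp[s] & donorOK & seq_len(ncol(x)) != s)
      dPlate <- .corDistances(distObs, s, samePlate, minShared)
      dGroup <- NULL
      for (a in rows) {
        cand <- samePlate[obs[a, samePlate] & is.finite(dPlate)]
        dd <- dPlate[match(cand, samePlate)]
        usedFallback <- NA_character_
        if (length(cand) < k) {
          if (is.null(dGroup))
            dGroup <- .corDistances(distObs, s, sameGroup, minShared)
          cand <- sameGroup[obs[a, sameGroup] & is.finite(dGroup)]
          dd <- dGroup[match(cand, sameGroup)]
          usedFallback <- "same_group_any_plate"
        }
        if (length(cand) >= k) {
          nn <- cand[order(dd)][seq_len(k)]
          conc[a, s] <- mean(conc[a, nn])
        } else {
          pool <- concObs[a, grp == grp[s] & donorOK]
          conc[a, s] <- stats::median(pool, na.rm = TRUE)
          usedFallback <- "group_median"
          if (!is.finite(conc[a, s]))
            stop("no observed donor value for analyte ", rownames(x)[a],
                 " in group ", grp[s])
        }
        if (!is.na(usedFallback))
          fallbacks[[length(fallbacks) + 1L]] <-
            data.frame(analyte_id = rownames(x)[a],
                       sample_id = colnames(x)[s],
                       fallback = usedFallback, stringsAsFactors = FALSE)
        codes[a, s] <- "IMP"
      }
    }
  }
  out <- x
  SummarizedExperiment::assay(out, "conc", withDimnames = FALSE) <- conc
  SummarizedExperiment::assay(out, "code", withDimnames = FALSE) <- codes
  metadata(out)$imputeLog <- if (length(fallbacks))
    do.call(rbind, fallbacks) else NULL
  validObject(out)
  out
}

# correlation distance (1 - Pearson) from sample s to each donor, NA when
# fewer than minShared analytes are observed in both
.corDistances <- function(concObs, s, donors, minShared) {
  if (!length(donors)) return(numeric(0))
  xs <- concObs[, s]
  vapply(donors, function(dn) {
    both <- which(!is.na(xs) & !is.na(concObs[, dn]))
    if (length(both) < minShared) return(NA_real_)
    r <- suppressWarnings(stats::cor(xs[both], concObs[both, dn]))
    if (!is.finite(r)) return(NA_real_)
    1 - r
  }, numeric(1))
}

#' Replace below-LOD cells by truncated-normal draws
#'
#' Every \code{BLOD} cell receives an independent draw from a normal
#' distribution with mean LOD/2 and SD LOD/4, truncated to [0, LOD], where
#' LOD is the limit of detection of the cell's plate for that analyte.
#' Reproducible given \code{seed}.
#'
#' @param x a \linkS4class{MetabExperiment} with \code{plateLimits}.
#' @param seed RNG seed.
#' @param meanFrac,sdFrac location and scale of the replacement distribution
#'   as fractions of the LOD (defaults 1/2 and 1/4).
#' @return The experiment with \code{BLOD} cells recoded \code{REP}.
#' @export
replaceBelowLOD <- function(x, seed = 1L, meanFrac = 0.5, sdFrac = 0.25) {
  codes <- cellCodes(x)
  cells <- which(codes == "BLOD", arr.ind = TRUE)
  if (!nrow(cells)) return(x)
  pl <- plateLimits(x)
  if (is.null(pl)) stop("plateLimits required to replace below-LOD cells")
  key <- paste(pl$plate_id, pl$analyte_id, sep = "\r")
  lookup <- stats::setNames(pl$lod, key)
  cellKey <- paste(samplePlate(x)[cells[, "col"]],
                   rownames(x)[cells[, "row"]], sep = "\r")
  lod <- lookup[cellKey]
  if (anyNA(lod))
    stop("missing LOD entry for ",
         sub("\r", " / ", cellKey[which(is.na(lod))[1]]))
  conc <- concentrations(x)
  draws <- withSeed(seed,
                    rtruncn(length(lod), mean = meanFrac * lod,
                            sd = sdFrac * lod, lo = 0, hi = lod))
  conc[cells] <- draws
  codes[cells] <- "REP"
  out <- x
  SummarizedExperiment::assay(out, "conc", withDimnames = FALSE) <- conc
  SummarizedExperiment::assay(out, "code", withDimnames = FALSE) <- codes
  validObject(out)
  out
}

#' Log2 transform of the concentration matrix
#'
#' @param x a \linkS4class{MetabExperiment} with strictly positive observed
#'   values (guaranteed after \code{\link{replaceBelowLOD}}).
#' @return The experiment on the log2 scale (\code{metadata(.)$logScale}).
#' @export
log2Transform <- function(x) {
  if (isTRUE(metadata(x)$logScale)) stop("already log2-transformed")
  conc <- concentrations(x)
  bad <- which(!is.na(conc) & conc <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("nonpositive value at analyte ", rownames(x)[bad[1, 1]],
         ", sample ", colnames(x)[bad[1, 2]])
  out <- x
  SummarizedExperiment::assay(out, "conc", withDimnames = FALSE) <- log2(conc)
  metadata(out)$logScale <- TRUE
  validObject(out)
  out
}

#' Inverse of \code{\link{log2Transform}}
#' @param x a log2-scale \linkS4class{MetabExperiment}.
#' @return The experiment back on the linear scale.
#' @export
unlog2Transform <- function(x) {
  if (!isTRUE(metadata(x)$logScale)) stop("not on the log2 scale")
  out <- x
  SummarizedExperiment::assay(out, "conc", withDimnames = FALSE) <-
    2 ^ concentrations(x)
  metadata(out)$logScale <- FALSE
  validObject(out)
  out
}
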
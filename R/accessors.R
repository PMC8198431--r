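#' Accessors for MetabExperiment
#'
#' Small accessor family for the \linkS4class{MetabExperiment} container:
#' \code{concentrations} and \code{cellCodes} return the two parallel assay
#' matrices (analytes x samples); \code{plateLimits} the per-plate LOD table;
#' \code{sampleGroup}, \code{sampleCohort} and \code{samplePlate} the column
#' annotations as factors/character; \code{analyteClass} and \code{isLipid}
#' the row annotations; \code{groundTruth} the planted truth of a synthetic
#' experiment (or \code{NULL}).
#'
#' @param x a \linkS4class{MetabExperiment}
#' @param value replacement value
#' @return matrix, data.frame or vector as described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
concentrations <- function(x) SummarizedExperiment::assay(x, "conc")

#' @rdname accessors
#' @export
`concentrations<-` <- function(x, value) {
  SummarizedExperiment::assay(x, "conc", withDimnames = FALSE) <- value
  validObject(x)
  x
}

#' @rdname accessors
#' @export
cellCodes <- function(x) SummarizedExperiment::assay(x, "code")

#' @rdname accessors
#' @export
`cellCodes<-` <- function(x, value) {
  SummarizedExperiment::assay(x, "code", withDimnames = FALSE) <- value
  validObject(x)
  x
}

#' @rdname accessors
#' @export
plateLimits <- function(x) metadata(x)$plateLimits

#' @rdname accessors
#' @export
sampleGroup <- function(x) factor(x$group, levels = c("Ctr", "LN", "LC"))

#' @rdname accessors
#' @export
sampleCohort <- function(x) as.character(x$cohort)

#' @rdname accessors
#' @export
samplePlate <- function(x) as.character(x$plate_id)

#' @rdname accessors
#' @export
analyteClass <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::rowData(x)$analyte_class),
                  rownames(x))
}

#' @rdname accessors
#' @export
isLipid <- function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$is_lipid, rownames(x))
}

#' @rdname accessors
#' @export
groundTruth <- function(x) metadata(x)$groundTruth

#' Is a cell observed?
#'
#' Codes \code{OBS}, \code{IMP} and \code{REP} count as observed.
#' @param codes character matrix or vector of cell codes
#' @return logical of the same shape
#' @export
isObservedCode <- function(codes) {
  m <- codes %in% .OBSERVED_CODES
  if (is.matrix(codes)) m <- matrix(m, nrow(codes), ncol(codes),
                                    dimnames = dimnames(codes))
  m
}
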
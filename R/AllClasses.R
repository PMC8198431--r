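#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

# cell codes: OBS observed, MISS calibrant-error missing, BLOD below limit of
# detection (value 0 until replacement), IMP knn-imputed (counts as observed),
# REP truncated-normal replacement of a BLOD cell (counts as observed)
.CODES <- c("OBS", "MISS", "BLOD", "IMP", "REP")
.OBSERVED_CODES <- c("OBS", "IMP", "REP")

#' MetabExperiment: targeted-metabolomics concentration container
#'
#' S4 container for a plate-exported targeted-metabolomics experiment,
#' extending \link[SummarizedExperiment]{SummarizedExperiment}. Rows are
#' analytes, columns are samples. Two assays are carried in parallel:
#' \code{conc} (concentrations, \eqn{\mu}M on the linear scale, or log2 after
#' \code{\link{log2Transform}}) and \code{code}, a character matrix of per-cell
#' measurement codes: \code{OBS} (observed), \code{MISS} (calibrant-error
#' missing, value \code{NA}), \code{BLOD} (below the plate's limit of
#' detection, value 0 until replacement), \code{IMP} (filled by kNN
#' imputation) and \code{REP} (truncated-normal below-LOD replacement).
#'
#' \code{rowData} carries \code{analyte_class} and \code{is_lipid};
#' \code{colData} carries \code{cohort}, \code{group}, \code{plate_id} and the
#' optional covariates \code{age}, \code{sex}, \code{pack_years}. The
#' per-plate, per-analyte limits of detection live in
#' \code{metadata(x)$plateLimits}; a synthetic experiment's planted truth in
#' \code{metadata(x)$groundTruth}; \code{metadata(x)$logScale} records whether
#' \code{conc} is on the log2 scale.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}.
#' @seealso \code{\link{MetabExperiment}} (constructor),
#'   \code{\link{concentrations}}, \code{\link{cellCodes}},
#'   \code{\link{plateLimits}}
#' @name MetabExperiment-class
#' @exportClass MetabExperiment
setClass("MetabExperiment", contains = "SummarizedExperiment")

setValidity("MetabExperiment", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("conc", "code") %in% a))
    return("assays 'conc' and 'code' are required")
  conc <- SummarizedExperiment::assay(object, "conc")
  code <- SummarizedExperiment::assay(object, "code")
  if (!identical(dim(conc), dim(code)))
    return("'conc' and 'code' dimensions disagree")
  if (!all(code %in% .CODES))
    return(paste0("invalid cell codes: ",
                  paste(unique(code[!code %in% .CODES]), collapse = ", ")))
  if (any(!is.na(conc[code == "MISS"])))
    return("MISS cells must carry NA values")
  logScale <- isTRUE(metadata(object)$logScale)
  obs <- conc[code %in% .OBSERVED_CODES]
  if (any(!is.finite(obs)))
    return("observed values must be finite")
  if (!logScale) {
    if (any(obs < 0)) return("observed linear-scale values must be >= 0")
    if (any(conc[code == "BLOD"] != 0))
      return("BLOD cells must carry value 0 before replacement")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("cohort", "group", "plate_id")
  if (!all(need %in% colnames(cd)))
    return("colData must contain cohort, group and plate_id")
  if (!all(c("analyte_class", "is_lipid") %in%
           colnames(SummarizedExperiment::rowData(object))))
    return("rowData must contain analyte_class and is_lipid")
  pl <- metadata(object)$plateLimits
  if (!is.null(pl)) {
    if (!all(c("plate_id", "analyte_id", "lod") %in% colnames(pl)))
      return("plateLimits needs columns plate_id, analyte_id, lod")
    if (any(pl$lod <= 0)) return("plate LODs must be > 0")
  }
  TRUE
})

#' Construct a MetabExperiment
#'
#' @param conc numeric matrix, analytes x samples, concentrations in
#'   \eqn{\mu}M (linear scale unless \code{logScale}).
#' @param codes character matrix of per-cell codes, same dimensions as
#'   \code{conc}; see \linkS4class{MetabExperiment}.
#' @param sampleData \code{data.frame} (one row per sample) with at least
#'   \code{sample_id}, \code{cohort}, \code{group}, \code{plate_id}.
#' @param analyteData \code{data.frame} (one row per analyte) with
#'   \code{analyte_id}, \code{analyte_class}, \code{is_lipid}, e.g. a subset
#'   of \code{\link{defaultPanel}()}.
#' @param plateLimits optional \code{data.frame} with \code{plate_id},
#'   \code{analyte_id}, \code{lod} (\eqn{\mu}M).
#' @param groundTruth optional list of planted effects (synthetic data).
#' @param logScale logical; \code{TRUE} when \code{conc} is log2-transformed.
#' @return A \linkS4class{MetabExperiment}.
#' @export
MetabExperiment <- function(conc, codes, sampleData, analyteData,
                            plateLimits = NULL, groundTruth = NULL,
                            logScale = FALSE) {
  conc <- as.matrix(conc)
  codes <- as.matrix(codes)
  rownames(conc) <- rownames(codes) <- analyteData$analyte_id
  colnames(conc) <- colnames(codes) <- sampleData$sample_id
  se <- SummarizedExperiment(
    assays = SimpleList(conc = conc, code = codes),
    rowData = DataFrame(analyteData, row.names = analyteData$analyte_id),
    colData = DataFrame(sampleData, row.names = sampleData$sample_id))
  metadata(se)$plateLimits <- plateLimits
  metadata(se)$groundTruth <- groundTruth
  metadata(se)$logScale <- logScale
  new("MetabExperiment", se)
}

#' @describeIn MetabExperiment-class compact display
#' @param object a \code{MetabExperiment}
#' @export
setMethod("show", "MetabExperiment", function(object) {
  code <- SummarizedExperiment::assay(object, "code")
  cat("MetabExperiment:", nrow(object), "analytes x", ncol(object),
      "samples\n")
  cat("  cohorts:",
      paste(sprintf("%s=%d", names(table(object$cohort)),
                    table(object$cohort)), collapse = " "), "\n")
  cat("  groups: ",
      paste(sprintf("%s=%d", names(table(object$group)),
                    table(object$group)), collapse = " "), "\n")
  tab <- table(factor(code, levels = .CODES))
  cat("  cells:  ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat("  scale:  ", if (isTRUE(metadata(object)$logScale)) "log2" else
      "linear (uM)", "\n")
  invisible(NULL)
})
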
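.META_COLS <- c("sample_id", "cohort", "group", "plate_id", "age", "sex",
                "pack_years")

#' Read a plate-exported concentration CSV
#'
#' Reads a wide concentration table (one row per sample) together with its
#' companion LOD table. The CSV dialect mirrors a plate-wise export from a
#' targeted kit: header \code{sample_id,cohort,group,plate_id,age,sex,
#' pack_years,<analyte ids...>}; an empty cell denotes a calibrant-error
#' missing measurement, a literal \code{0} a below-LOD measurement, and a
#' positive number an observed concentration in \eqn{\mu}M.
#'
#' @param path concentration CSV path.
#' @param lodPath companion LOD CSV (\code{plate_id,analyte_id,lod}); optional.
#' @param registry analyte registry the columns are validated against;
#'   defaults to \code{\link{defaultPanel}()}. Unknown analyte columns are an
#'   error.
#' @return A \linkS4class{MetabExperiment} (analytes x samples) with
#'   \code{plateLimits} attached when \code{lodPath} is given.
#' @seealso \code{\link{writeConcentrationCSV}}
#' @export
readConcentrationCSV <- function(path, lodPath = NULL,
                                 registry = defaultPanel()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(.META_COLS %in% colnames(df)))
    stop("malformed header: missing metadata columns ",
         paste(setdiff(.META_COLS, colnames(df)), collapse = ", "))
  analyteCols <- setdiff(colnames(df), .META_COLS)
  unknown <- setdiff(analyteCols, registry$analyte_id)
  if (length(unknown))
    stop("unknown analyte columns: ", paste(utils::head(unknown, 5),
                                            collapse = ", "))
  bad <- df$sample_id == "" | is.na(df$sample_id) | df$cohort == "" |
    df$group == "" | df$plate_id == ""
  if (any(bad))
    stop("sample without metadata in row(s) ",
         paste(which(bad), collapse = ", "))

  raw <- as.matrix(df[, analyteCols, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  codes <- matrix("OBS", nrow(raw), ncol(raw))
  codes[raw == "" | is.na(raw)] <- "MISS"
  vals[codes == "MISS"] <- NA_real_
  codes[!is.na(vals) & vals == 0] <- "BLOD"
  if (any(vals < 0, na.rm = TRUE))
    stop("negative concentration in ", path)

  sampleData <- data.frame(
    sample_id = df$sample_id, cohort = df$cohort, group = df$group,
    plate_id = df$plate_id,
    age = suppressWarnings(as.numeric(df$age)),
    sex = df$sex,
    pack_years = suppressWarnings(as.numeric(df$pack_years)),
    stringsAsFactors = FALSE)
  analyteData <- registry[match(analyteCols, registry$analyte_id), ,
                          drop = FALSE]
  limits <- NULL
  if (!is.null(lodPath)) {
    limits <- utils::read.csv(lodPath, stringsAsFactors = FALSE)
    if (!all(c("plate_id", "analyte_id", "lod") %in% colnames(limits)))
      stop("malformed LOD table header in ", lodPath)
  }
  MetabExperiment(t(vals), t(codes), sampleData, analyteData,
                  plateLimits = limits)
}

#' Write a MetabExperiment to the concentration CSV dialect
#'
#' Inverse of \code{\link{readConcentrationCSV}}: observed cells are written
#' as numbers (12 significant digits), below-LOD cells as \code{0} and
#' calibrant-missing cells as empty strings.
#'
#' @param x a \linkS4class{MetabExperiment} on the linear scale.
#' @param path output CSV path.
#' @param lodPath optional path for the companion LOD CSV.
#' @return \code{path}, invisibly.
#' @export
writeConcentrationCSV <- function(x, path, lodPath = NULL) {
  conc <- t(concentrations(x))
  codes <- t(cellCodes(x))
  chr <- matrix(format(conc, digits = 12, trim = TRUE, scientific = FALSE),
                nrow(conc), ncol(conc))
  chr[codes == "MISS"] <- ""
  chr[codes == "BLOD"] <- "0"
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  meta <- data.frame(sample_id = cd$sample_id, cohort = cd$cohort,
                     group = cd$group, plate_id = cd$plate_id,
                     age = cd$age, sex = cd$sex, pack_years = cd$pack_years,
                     stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(chr, stringsAsFactors = FALSE))
  colnames(out) <- c(.META_COLS, rownames(x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(lodPath) && !is.null(plateLimits(x)))
    utils::write.csv(plateLimits(x), lodPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a result table as TSV
#'
#' Result tables (e.g. the output of \code{\link{runBattery}}) are written as
#' UTF-8 tab-separated text with a \code{.} decimal separator; numeric columns
#' round-trip to 12 significant digits.
#'
#' @param results a \code{data.frame} of per-analyte results.
#' @param path output path.
#' @return \code{path} invisibly (writer); a \code{data.frame} (reader).
#' @export
writeResultTable <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA, format(v, digits = 12, trim = TRUE))
  })
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
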
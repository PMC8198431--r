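#' Specification of a synthetic two-cohort experiment
#'
#' Collects everything \code{\link{simulateCohort}} needs: group sizes per
#' cohort, plate geometry, class-level abundance hyperparameters, planted
#' batch effects, the two missingness mechanisms and the planted group
#' effects. Defaults describe a neutral small design; use
#' \code{\link{defaultCohortSpec}} for the screening-study-scale design.
#'
#' @param groupSizes named list of cohorts, each an integer triple
#'   \code{c(Ctr=, LN=, LC=)}.
#' @param plateSize samples per plate (96-well occupancy).
#' @param classAbundance \code{data.frame} with one row per analyte class:
#'   \code{analyte_class}, \code{log2_mean} (class-level log2 baseline, log2
#'   \eqn{\mu}M), \code{log2_between} (between-analyte SD of baselines within
#'   the class) and \code{log2_within} (within-analyte biological SD).
#' @param sampleEffectSd SD of per-sample, per-class log2 shifts shared by
#'   all analytes of a class, emulating interindividual variation in overall
#'   serum composition (e.g. lipoprotein status moving whole lipid classes).
#' @param batchShiftSd SD of the per-plate additive shift on the log2 scale.
#' @param batchScaleSd SD of the per-plate log2 scale factor; the plate's
#'   residual SD is multiplied by \code{2^rnorm(1, 0, batchScaleSd)}.
#' @param calibrantRate per-cell probability of a calibrant-error missing
#'   value; scalar or one value per analyte.
#' @param lodQuantile quantile of an analyte's baseline distribution used as
#'   its plate LOD; scalar or one value per analyte, in [0, 1).
#' @param lodPlateJitterSd SD of a small per-plate log2 jitter on the LOD.
#' @param effects \code{data.frame} of planted group effects:
#'   \code{analyte_id}, \code{cohort_scope} (\code{both},
#'   \code{MOLTEST_only}, \code{SMAC_only}), \code{lfc_LC}, \code{lfc_LN}
#'   (log2 fold changes vs Ctr). May have zero rows.
#' @param confounded if \code{TRUE}, plates are filled group-by-group so that
#'   plate and group are confounded (stress-testing only); by default groups
#'   are interleaved across plates.
#' @param seed RNG seed; the whole simulation is a deterministic function of
#'   the spec.
#' @return A list of class \code{cohortSpec}.
#' @export
cohortSpec <- function(groupSizes = list(MOLTEST = c(Ctr = 20, LN = 20, LC = 20)),
                       plateSize = 96,
                       classAbundance = defaultClassAbundance(),
                       sampleEffectSd = 0.35,
                       batchShiftSd = 0.3,
                       batchScaleSd = 0.15,
                       calibrantRate = 0.01,
                       lodQuantile = 0.05,
                       lodPlateJitterSd = 0.05,
                       effects = emptyEffects(),
                       confounded = FALSE,
                       seed = 1L) {
  stopifnot(all(unlist(groupSizes) >= 1),
            all(calibrantRate >= 0 & calibrantRate < 1),
            all(lodQuantile >= 0 & lodQuantile < 1),
            plateSize >= 2)
  gs <- lapply(groupSizes, function(g) {
    stopifnot(length(g) == 3)
    names(g) <- c("Ctr", "LN", "LC")
    g
  })
  structure(list(groupSizes = gs, plateSize = plateSize,
                 classAbundance = classAbundance,
                 sampleEffectSd = sampleEffectSd,
                 batchShiftSd = batchShiftSd, batchScaleSd = batchScaleSd,
                 calibrantRate = calibrantRate, lodQuantile = lodQuantile,
                 lodPlateJitterSd = lodPlateJitterSd,
                 effects = effects, confounded = confounded,
                 seed = as.integer(seed)),
            class = "cohortSpec")
}

#' @rdname cohortSpec
#' @export
emptyEffects <- function() {
  data.frame(analyte_id = character(0), cohort_scope = character(0),
             lfc_LC = numeric(0), lfc_LN = numeric(0),
             stringsAsFactors = FALSE)
}

#' Class-level abundance hyperparameters
#'
#' Log2 baselines chosen so that aggregate class masses reproduce the serum
#' lipidome composition the package targets: cholesteryl esters carry a bit
#' over half of total lipid mass, choline phospholipids about a quarter and
#' glycerides about 14 percent, with hexose near 5 mM and amino acids in the
#' tens of \eqn{\mu}M.
#'
#' @return \code{data.frame} with one row per analyte class.
#' @export
defaultClassAbundance <- function() {
  data.frame(
    analyte_class = .ALL_CLASSES,
    log2_mean    = c(5.0, 2.0, 1.5, 2.7, 2.7, 3.5, 3.5, 1.7, 7.6, 12.3),
    log2_between = c(1.0, 1.2, 1.0, 0.8, 0.8, 0.8, 0.8, 0.8, 0.6, 0.0),
    log2_within  = c(0.35, 0.4, 0.4, 0.4, 0.4, 0.45, 0.45, 0.4, 0.35, 0.25),
    stringsAsFactors = FALSE)
}

#' Screening-study-scale default specification
#'
#' Two cohorts at the screening-study sizes (MOLTEST 123/123/123, SMAC
#' 31/31/31 for Ctr/LN/LC), 96-well plates filled sequentially within cohort
#' with interleaved groups, and planted effects mirroring the qualitative
#' pattern the analysis is designed to detect: four lipids —
#' \code{LPC(18:0)}, \code{PC(32:3)}, \code{DG(39:0)}, \code{CE(20:5)} —
#' shifted down in lung cancer in \emph{both} cohorts, and a triglyceride
#' shift of opposite sign per cohort (down in MOLTEST, up in SMAC).
#'
#' Missingness defaults plant all three analyte fates: most analytes have a
#' low LOD (quantile 0.05), about 30\% a high LOD (quantile 0.75, destined
#' for the presence/absence branch), and a 5\% tranche carries an elevated
#' calibrant failure rate (0.15, destined for exclusion); all remaining cells
#' fail the calibrant independently at 1\%.
#'
#' @param seed master RNG seed.
#' @param registry analyte registry (defaults to the full panel).
#' @return A \code{cohortSpec}.
#' @export
defaultCohortSpec <- function(seed = 1L, registry = defaultPanel()) {
  nA <- nrow(registry)
  named <- c("LPC(18:0)", "PC(32:3)", "DG(39:0)", "CE(20:5)")
  fates <- withSeed(seed + 101L, {
    fate <- sample(c("quant", "binary", "excl"), nA, replace = TRUE,
                   prob = c(0.65, 0.30, 0.05))
    fate[registry$analyte_id %in% named] <- "quant"
    fate[registry$analyte_class == "triglyceride"] <- "quant"
    fate
  })
  lodQ <- ifelse(fates == "binary", 0.75, 0.05)
  calR <- ifelse(fates == "excl", 0.15, 0.01)
  eff <- rbind(
    data.frame(analyte_id = named, cohort_scope = "both",
               lfc_LC = -0.45, lfc_LN = 0, stringsAsFactors = FALSE),
    data.frame(analyte_id = registry$analyte_id[
                 registry$analyte_class == "triglyceride"],
               cohort_scope = "MOLTEST_only", lfc_LC = -0.25, lfc_LN = 0,
               stringsAsFactors = FALSE),
    data.frame(analyte_id = registry$analyte_id[
                 registry$analyte_class == "triglyceride"],
               cohort_scope = "SMAC_only", lfc_LC = 0.25, lfc_LN = 0,
               stringsAsFactors = FALSE))
  cohortSpec(
    groupSizes = list(MOLTEST = c(Ctr = 123, LN = 123, LC = 123),
                      SMAC = c(Ctr = 31, LN = 31, LC = 31)),
    calibrantRate = calR, lodQuantile = lodQ,
    effects = eff, seed = seed)
}

# plate assignment: groups interleaved, plates filled sequentially per cohort
.assignPlates <- function(cohort, groups, plateSize, confounded) {
  ord <- if (confounded) order(groups)
         else order(ave(seq_along(groups), groups, FUN = seq_along))
  plate <- character(length(groups))
  plate[ord] <- sprintf("%s_P%d", cohort,
                        (seq_along(ord) - 1L) %/% plateSize + 1L)
  plate
}

#' Generate a synthetic two-cohort experiment
#'
#' Draws per-analyte log-normal baselines from class-level hyperparameters,
#' applies planted group effects (log2 shifts scoped per cohort), per-plate
#' additive and multiplicative batch effects on the log2 scale, then censors
#' cells below their plate LOD (code \code{BLOD}, value 0) and finally masks
#' independent calibrant failures (code \code{MISS}, overriding censoring).
#' Fully deterministic given the spec's seed.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param registry analyte registry.
#' @return A \linkS4class{MetabExperiment} with \code{plateLimits} and a
#'   \code{groundTruth} list (planted effect table, per-plate batch
#'   parameters, per-cell censoring/masking indicators and the uncensored
#'   concentration matrix).
#' @export
simulateCohort <- function(spec, registry = defaultPanel()) {
  stopifnot(inherits(spec, "cohortSpec"))
  if (nrow(spec$effects) &&
      !all(spec$effects$analyte_id %in% registry$analyte_id))
    stop("effects reference analytes absent from the registry")
  nA <- nrow(registry)
  ca <- spec$classAbundance[match(registry$analyte_class,
                                  spec$classAbundance$analyte_class), ]
  if (anyNA(ca$log2_mean)) stop("classAbundance misses a class")
  calR <- rep_len(spec$calibrantRate, nA)
  lodQ <- rep_len(spec$lodQuantile, nA)

  withSeed(spec$seed, {
    baseline <- stats::rnorm(nA, ca$log2_mean, ca$log2_between)

    sampleData <- do.call(rbind, lapply(names(spec$groupSizes), function(ch) {
      g <- spec$groupSizes[[ch]]
      grp <- rep(names(g), times = g)
      data.frame(cohort = ch, group = grp, stringsAsFactors = FALSE)
    }))
    sampleData$sample_id <- sprintf("%s_%s_%03d", sampleData$cohort,
                                    sampleData$group,
                                    ave(seq_len(nrow(sampleData)),
                                        sampleData$cohort, sampleData$group,
                                        FUN = seq_along))
    sampleData$plate_id <- unlist(lapply(split(seq_len(nrow(sampleData)),
                                               sampleData$cohort)[
                                         unique(sampleData$cohort)],
      function(idx) .assignPlates(sampleData$cohort[idx[1]],
                                  sampleData$group[idx],
                                  spec$plateSize, spec$confounded)),
      use.names = FALSE)
    nS <- nrow(sampleData)
    sampleData$age <- round(stats::rnorm(nS, 62, 6))
    sampleData$sex <- sample(c("F", "M"), nS, replace = TRUE)
    sampleData$pack_years <- round(pmax(0, stats::rnorm(nS, 30, 12)), 1)

    # planted group effects, per analyte x sample, on the log2 scale
    shift <- matrix(0, nA, nS)
    if (nrow(spec$effects)) {
      for (r in seq_len(nrow(spec$effects))) {
        e <- spec$effects[r, ]
        ai <- match(e$analyte_id, registry$analyte_id)
        inScope <- switch(e$cohort_scope,
                          both = rep(TRUE, nS),
                          MOLTEST_only = sampleData$cohort == "MOLTEST",
                          SMAC_only = sampleData$cohort == "SMAC",
                          stop("bad cohort_scope: ", e$cohort_scope))
        shift[ai, inScope & sampleData$group == "LC"] <-
          shift[ai, inScope & sampleData$group == "LC"] + e$lfc_LC
        shift[ai, inScope & sampleData$group == "LN"] <-
          shift[ai, inScope & sampleData$group == "LN"] + e$lfc_LN
      }
    }

    # batch effects follow the EB correction model: per analyte and per
    # plate, an additive shift and a multiplicative residual scale
    plates <- unique(sampleData$plate_id)
    nP <- length(plates)
    gamma <- matrix(stats::rnorm(nA * nP, 0, spec$batchShiftSd), nA, nP,
                    dimnames = list(registry$analyte_id, plates))
    delta <- matrix(2 ^ stats::rnorm(nA * nP, 0, spec$batchScaleSd), nA, nP,
                    dimnames = list(registry$analyte_id, plates))
    g <- gamma[, sampleData$plate_id, drop = FALSE]
    d <- delta[, sampleData$plate_id, drop = FALSE]

    # interindividual variation: per-sample, per-class log2 shifts (lipid
    # classes co-vary within a person, amino acids move independently)
    classes <- unique(registry$analyte_class)
    sampEff <- matrix(stats::rnorm(length(classes) * nS, 0,
                                   spec$sampleEffectSd),
                      length(classes), nS,
                      dimnames = list(classes, NULL))
    eps <- matrix(stats::rnorm(nA * nS), nA, nS) * ca$log2_within
    logConc <- baseline + shift + g +
      sampEff[registry$analyte_class, , drop = FALSE] +
      eps * d
    conc <- 2 ^ logConc

    # plate LODs: per-analyte baseline quantile, small per-plate jitter
    lodBase <- 2 ^ (baseline + stats::qnorm(lodQ) * ca$log2_within)
    lodBase[lodQ == 0] <- 2 ^ (baseline[lodQ == 0] - 10 * ca$log2_within[lodQ == 0])
    lodJit <- matrix(2 ^ stats::rnorm(nA * length(plates), 0,
                                      spec$lodPlateJitterSd),
                     nA, length(plates), dimnames = list(NULL, plates))
    lodMat <- lodBase * lodJit          # analyte x plate
    limits <- data.frame(
      plate_id = rep(plates, each = nA),
      analyte_id = rep(registry$analyte_id, length(plates)),
      lod = as.vector(lodMat), stringsAsFactors = FALSE)

    lodPerCell <- lodMat[, sampleData$plate_id, drop = FALSE]
    censored <- conc < lodPerCell
    masked <- matrix(stats::runif(nA * nS), nA, nS) < calR

    codes <- matrix("OBS", nA, nS)
    vals <- conc
    codes[censored] <- "BLOD"
    vals[censored] <- 0
    codes[masked] <- "MISS"            # calibrant failure overrides censoring
    vals[masked] <- NA_real_

    dimnames(conc) <- dimnames(censored) <- dimnames(masked) <-
      list(registry$analyte_id, sampleData$sample_id)
    truth <- list(effects = spec$effects,
                  differential = unique(spec$effects$analyte_id),
                  plateShift = gamma, plateScale = delta,
                  censored = censored, masked = masked,
                  baselineLog2 = stats::setNames(baseline,
                                                 registry$analyte_id),
                  uncensored = conc)
    MetabExperiment(vals, codes, sampleData[, c(.META_COLS)], registry,
                    plateLimits = limits, groundTruth = truth)
  })
}
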
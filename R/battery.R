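#' Per-sample class aggregates
#'
#' Sums linear-scale concentrations per metabolite class (10 classes) and a
#' \code{total_lipids} aggregate over the seven lipid classes, per sample.
#'
#' @param x a linear-scale \linkS4class{MetabExperiment} after imputation and
#'   below-LOD replacement (no NA cells among included analytes).
#' @return \code{data.frame}: one row per sample, one column per class plus
#'   \code{total_lipids}, concentrations in \eqn{\mu}M.
#' @export
aggregateClasses <- function(x) {
  if (isTRUE(metadata(x)$logScale))
    stop("class aggregation works on the linear scale")
  conc <- concentrations(x)
  cls <- analyteClass(x)
  if (anyNA(cls)) stop("analyte without class")
  agg <- t(rowsum(conc, cls, na.rm = TRUE))        # samples x classes
  out <- as.data.frame(agg)
  missingCls <- setdiff(.ALL_CLASSES, colnames(out))
  for (mc in missingCls) out[[mc]] <- 0
  out <- out[, .ALL_CLASSES]
  out$total_lipids <- unname(rowSums(out[, .LIPID_CLASSES, drop = FALSE]))
  data.frame(sample_id = colnames(conc), out, check.names = FALSE,
             stringsAsFactors = FALSE)
}

.PAIRS <- rbind(c("Ctr", "LN"), c("Ctr", "LC"), c("LN", "LC"))

# one analyte's full univariate record
.analyteBattery <- function(v, grp, rDenom) {
  kw <- kruskalWallis(v, grp)
  eta <- etaSquaredKW(kw$H, kw$k, kw$n)
  cv <- conoverPosthoc(v, grp, rDenom = rDenom)
  jt <- jonckheereTerpstra(v, grp)
  med <- tapply(v, grp, stats::median)
  out <- data.frame(H = kw$H, p_kw = kw$p, eta_sq = eta,
                    jt_z = jt$z, p_jt = jt$p,
                    direction_LC = sign(med["LC"] - med["Ctr"]),
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(.PAIRS))) {
    i <- which(cv$group_i == .PAIRS[r, 1] & cv$group_j == .PAIRS[r, 2])
    tag <- paste(.PAIRS[r, ], collapse = "_")
    out[[paste0("conover_p_", tag)]] <- cv$p[i]
    out[[paste0("conover_r_", tag)]] <- cv$r[i]
  }
  out
}

#' Univariate statistics battery over the quantitative analytes
#'
#' For every quantitative analyte: tie-corrected Kruskal-Wallis H across the
#' three groups with BH-FDR across analytes and eta-squared effect size;
#' Conover-Iman pairwise contrasts (unadjusted within analyte) with Pallant r;
#' the Jonckheere-Terpstra trend over Ctr < LN < LC; and effect-magnitude
#' labels. In \code{mode = "per_cohort"} the battery runs per cohort and adds
#' a Lancaster-combined p across cohorts, weighted by cohort sample size
#' scaled to mean 2 (so equal cohorts reduce to Fisher), itself BH-adjusted.
#' Binary-set analytes are tested for group-related presence/absence with the
#' chi-square independence test.
#'
#' @param x a preprocessed (log2, batch-corrected) \linkS4class{MetabExperiment}.
#' @param partition an \code{\link{partitionAnalytes}} result; analytes
#'   outside its quantitative set are skipped (binary ones go to the
#'   presence/absence branch when \code{binaryCodes} is given).
#' @param mode \code{"pooled"} (cohorts together) or \code{"per_cohort"}.
#' @param rDenom Pallant r denominator convention, see
#'   \code{\link{conoverPosthoc}}.
#' @param alpha significance level used for the reporting flags.
#' @param binaryCodes optional cell-code matrix of the \emph{unreplaced}
#'   data, used to test the binary set's presence/absence distribution.
#' @return list of class \code{batteryResult}: \code{quantitative}
#'   (data.frame, one row per analyte), \code{binary} (or NULL), plus the
#'   per-cohort tables in per-cohort mode.
#' @export
runBattery <- function(x, partition, mode = c("pooled", "per_cohort"),
                       rDenom = c("pair", "total"), alpha = 0.05,
                       binaryCodes = NULL) {
  mode <- match.arg(mode)
  rDenom <- match.arg(rDenom)
  quant <- intersect(rownames(x), partition$quantitative)
  if (!length(quant)) stop("no quantitative analytes in the experiment")
  conc <- concentrations(x)[quant, , drop = FALSE]
  grp <- sampleGroup(x)

  batteryTable <- function(cols) {
    rows <- lapply(quant, function(a)
      .analyteBattery(conc[a, cols], droplevels(grp[cols]), rDenom))
    tab <- do.call(rbind, rows)
    tab <- data.frame(analyte_id = quant, tab, stringsAsFactors = FALSE,
                      row.names = NULL)
    tab$p_kw_fdr <- bhFDR(tab$p_kw)
    tab$eta_label <- as.character(effectMagnitude(tab$eta_sq, "eta_sq"))
    tab$significant <- tab$p_kw_fdr < alpha
    tab
  }

  out <- list(mode = mode, alpha = alpha)
  if (mode == "pooled") {
    out$quantitative <- batteryTable(seq_len(ncol(x)))
  } else {
    cohorts <- unique(sampleCohort(x))
    perCohort <- lapply(cohorts, function(ch)
      batteryTable(which(sampleCohort(x) == ch)))
    names(perCohort) <- cohorts
    sizes <- vapply(cohorts, function(ch) sum(sampleCohort(x) == ch),
                    numeric(1))
    w <- sizes / mean(sizes) * 2          # equal-size case reduces to Fisher
    comb <- data.frame(analyte_id = quant, stringsAsFactors = FALSE)
    comb$p_lancaster <- vapply(seq_along(quant), function(i)
      lancasterCombine(vapply(perCohort,
                              function(tb) tb$p_kw[i], numeric(1)), w),
      numeric(1))
    comb$p_lancaster_fdr <- bhFDR(comb$p_lancaster)
    out$perCohort <- perCohort
    out$lancasterWeights <- stats::setNames(w, cohorts)
    out$quantitative <- comb
  }

  if (!is.null(binaryCodes) && length(partition$binary)) {
    bin <- intersect(rownames(binaryCodes), partition$binary)
    pres <- lapply(bin, function(a) {
      cc <- binaryCodes[a, ]
      chiSquarePresence(isObservedCode(cc), grp)
    })
    out$binary <- data.frame(
      analyte_id = bin,
      p_chisq = vapply(pres, `[[`, numeric(1), "p"),
      exact = vapply(pres, `[[`, logical(1), "exact"),
      stringsAsFactors = FALSE)
    out$binary$p_chisq_fdr <- bhFDR(out$binary$p_chisq)
  }
  class(out) <- "batteryResult"
  out
}

#' @export
print.batteryResult <- function(x, ...) {
  cat("batteryResult (", x$mode, " mode): ", nrow(x$quantitative),
      " quantitative analytes", sep = "")
  if (!is.null(x$quantitative$significant))
    cat(", ", sum(x$quantitative$significant), " FDR-significant", sep = "")
  if (!is.null(x$binary)) cat("; ", nrow(x$binary), " binary", sep = "")
  cat("\n")
  invisible(x)
}

#' Cross-cohort concordance of differential analytes
#'
#' An analyte is \emph{common} to both cohorts when it is significant in each
#' cohort's battery and its lung-cancer direction (sign of the LC vs Ctr
#' median difference) agrees. Per-cohort significance uses the unadjusted
#' Kruskal-Wallis p-value by default -- the coherence reading, intended to be
#' applied on top of a pooled FDR-controlled candidate list; set
#' \code{adjusted = TRUE} to demand per-cohort FDR significance instead.
#'
#' @param battery a per-cohort \code{\link{runBattery}} result.
#' @param alpha significance level.
#' @param adjusted use each cohort's BH-adjusted p-values for the
#'   significance flags.
#' @return \code{data.frame} with per-cohort significance, directions and the
#'   \code{common} flag, one row per analyte.
#' @export
concordance <- function(battery, alpha = 0.05, adjusted = FALSE) {
  if (battery$mode != "per_cohort")
    stop("concordance needs a per-cohort battery")
  cohorts <- names(battery$perCohort)
  if (length(cohorts) != 2) stop("concordance is defined for two cohorts")
  a <- battery$perCohort[[1]]; b <- battery$perCohort[[2]]
  pcol <- if (adjusted) "p_kw_fdr" else "p_kw"
  out <- data.frame(analyte_id = a$analyte_id, stringsAsFactors = FALSE)
  out[[paste0("sig_", cohorts[1])]] <- a[[pcol]] < alpha
  out[[paste0("sig_", cohorts[2])]] <- b[[pcol]] < alpha
  out[[paste0("dir_", cohorts[1])]] <- a$direction_LC
  out[[paste0("dir_", cohorts[2])]] <- b$direction_LC
  out$common <- out[[2]] & out[[3]] & out[[4]] == out[[5]] & out[[4]] != 0
  out
}
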
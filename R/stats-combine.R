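#' Lancaster combination of p-values
#'
#' Weighted generalization of Fisher's method: each p-value is converted to
#' an upper-tail chi-square quantile with its weight as degrees of freedom,
#' the quantiles are summed, and the sum is referred to a chi-square with the
#' total degrees of freedom. With all weights equal to 2 this is exactly
#' Fisher's combination. Zero p-values are clamped to machine epsilon so the
#' quantiles stay finite.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param weights positive weights (degrees of freedom), recycled to
#'   \code{length(p)}; default 2 (Fisher).
#' @return combined p-value.
#' @examples
#' lancasterCombine(c(0.5, 0.5))            # Fisher
#' lancasterCombine(c(0.01, 0.2), c(3.5, 0.9))
#' @export
lancasterCombine <- function(p, weights = 2) {
  weights <- rep_len(weights, length(p))
  if (any(weights <= 0)) stop("weights must be positive")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  keep <- !is.na(p)
  p <- pmax(p[keep], .Machine$double.eps)
  w <- weights[keep]
  if (!length(p)) return(NA_real_)
  T <- sum(stats::qchisq(p, df = w, lower.tail = FALSE))
  stats::pchisq(T, df = sum(w), lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (a thin, name-stable wrapper around
#' \code{\link[stats]{p.adjust}} with \code{method = "BH"}).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, monotone and capped at 1.
#' @export
bhFDR <- function(p) stats::p.adjust(p, method = "BH")

#' Chi-square presence/absence test
#'
#' Tests independence between a binary presence flag (observed vs below LOD)
#' and group membership on the 2 x k contingency table. When any expected
#' count falls below 5 the exact test replaces the chi-square approximation
#' and the result is flagged.
#'
#' @param present logical vector (TRUE = observed).
#' @param groups group labels.
#' @return list with \code{p}, \code{statistic} (NA for the exact branch)
#'   and \code{exact}.
#' @export
chiSquarePresence <- function(present, groups) {
  groups <- factor(groups)
  if (any(table(groups) == 0)) stop("group with zero samples")
  tab <- table(factor(present, levels = c(FALSE, TRUE)), groups)
  if (all(rowSums(tab) > 0)) {
    suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
    if (all(ct$expected >= 5))
      return(list(p = unname(ct$p.value), statistic = unname(ct$statistic),
                  exact = FALSE))
    return(list(p = stats::fisher.test(tab)$p.value, statistic = NA_real_,
                exact = TRUE))
  }
  list(p = 1, statistic = 0, exact = FALSE)  # constant flag: no information
}

#' Magnitude label for an effect size
#'
#' Conventional cut-offs: for Pallant r, negligible < 0.1 <= small < 0.3 <=
#' medium < 0.5 <= large; for Kruskal-Wallis eta-squared, 0.01 / 0.06 / 0.14.
#'
#' @param value effect size (negative eta-squared values, possible under the
#'   null, are treated as 0).
#' @param kind \code{"r"} or \code{"eta_sq"}.
#' @return factor label in \code{N < S < M < L}.
#' @export
effectMagnitude <- function(value, kind = c("r", "eta_sq")) {
  kind <- match.arg(kind)
  if (any(value < 0 & kind == "r")) stop("negative r")
  value <- pmax(value, 0)
  cuts <- if (kind == "r") c(0.1, 0.3, 0.5) else c(0.01, 0.06, 0.14)
  cut(value, breaks = c(-Inf, cuts, Inf), labels = c("N", "S", "M", "L"),
      right = FALSE)
}
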
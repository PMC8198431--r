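#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution on
#' k - 1 degrees of freedom. When every observation is tied (no rank
#' variation) the statistic is defined as 0 with p = 1 rather than 0/0.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with \code{H}, \code{p}, \code{k}, \code{n}.
#' @examples
#' kruskalWallis(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2))
#' @export
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  n <- length(values)
  r <- rank(values)
  k <- nlevels(groups)
  meanRanks <- tapply(r, groups, mean)
  ni <- tabulate(groups)
  H <- 12 / (n * (n + 1)) * sum(ni * (meanRanks - (n + 1) / 2) ^ 2)
  ties <- table(values)
  tieCorr <- 1 - sum(ties ^ 3 - ties) / (n ^ 3 - n)
  H <- if (tieCorr <= 0) 0 else H / tieCorr       # all tied: no information
  p <- if (H == 0 && tieCorr <= 0) 1 else
    stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  list(H = H, p = p, k = k, n = n)
}

#' Eta-squared effect size for the Kruskal-Wallis test
#'
#' \eqn{\eta^2 = (H - k + 1) / (n - k)}: the H statistic centred at its null
#' expectation and scaled by the residual degrees of freedom.
#'
#' @param H Kruskal-Wallis statistic.
#' @param k number of groups.
#' @param n total sample size (must exceed \code{k}).
#' @return numeric effect size (can be slightly negative under the null).
#' @export
etaSquaredKW <- function(H, k, n) {
  if (n <= k) stop("n must exceed k")
  (H - k + 1) / (n - k)
}

#' Conover-Iman post hoc pairwise comparisons
#'
#' Rank-based pairwise tests on the pooled Kruskal-Wallis ranks: for groups i
#' and j, \eqn{t = (\bar R_i - \bar R_j) / \sqrt{S^2 \frac{n-1-H}{n-k}
#' (1/n_i + 1/n_j)}} with the tie-aware pooled rank variance \eqn{S^2}; p is
#' two-sided from a t distribution on n - k degrees of freedom. The effect
#' size r standardizes |t| by the square root of the compared pair's total
#' size (\code{rDenom = "pair"}) or of the full sample (\code{"total"}).
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param rDenom denominator convention for the Pallant r effect size.
#' @return \code{data.frame} with one row per unordered group pair:
#'   \code{group_i}, \code{group_j}, \code{t}, \code{p}, \code{r}.
#' @export
conoverPosthoc <- function(values, groups, rDenom = c("pair", "total")) {
  rDenom <- match.arg(rDenom)
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  n <- length(values)
  r <- rank(values)
  kw <- kruskalWallis(values, groups)
  meanRanks <- tapply(r, groups, mean)
  ni <- tabulate(groups)
  S2 <- (sum(r ^ 2) - n * (n + 1) ^ 2 / 4) / (n - 1)
  pairs <- utils::combn(levels(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- match(pr[1], levels(groups)); j <- match(pr[2], levels(groups))
    se2 <- S2 * ((n - 1 - kw$H) / (n - k)) * (1 / ni[i] + 1 / ni[j])
    tstat <- if (se2 <= 0) 0 else
      unname((meanRanks[i] - meanRanks[j]) / sqrt(se2))
    denom <- if (rDenom == "pair") ni[i] + ni[j] else n
    c(t = tstat,
      p = 2 * stats::pt(abs(tstat), df = n - k, lower.tail = FALSE),
      r = abs(tstat) / sqrt(denom))
  })
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
             t = res["t", ], p = pmin(res["p", ], 1), r = res["r", ],
             stringsAsFactors = FALSE)
}

#' Jonckheere-Terpstra trend test across ordered groups
#'
#' The JT statistic is the sum of pairwise Mann-Whitney counts over all
#' ordered pairs of groups (ties counted one half); its null mean and
#' tie-adjusted variance give a two-sided normal-approximation p-value.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param order the hypothesized group ordering (default Ctr < LN < LC).
#' @return list with \code{JT}, \code{z}, \code{p}.
#' @export
jonckheereTerpstra <- function(values, groups,
                               order = c("Ctr", "LN", "LC")) {
  groups <- factor(groups, levels = order)
  if (anyNA(groups)) stop("group label outside the given order")
  ni <- tabulate(groups, nbins = length(order))
  if (sum(ni > 0) < 2) stop("need at least 2 nonempty groups")
  vs <- split(values, groups)
  k <- length(order)
  JT <- 0
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!ni[i] || !ni[j]) next
    JT <- JT + sum(vapply(vs[[i]], function(u)
      sum(vs[[j]] > u) + 0.5 * sum(vs[[j]] == u), numeric(1)))
  }
  n <- sum(ni)
  mu <- (n ^ 2 - sum(ni ^ 2)) / 4
  ties <- table(values)
  # tie-adjusted null variance (Hollander & Wolfe form)
  t1 <- n * (n - 1) * (2 * n + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(ties * (ties - 1) * (2 * ties + 5))
  t2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(ties * (ties - 1) * (ties - 2))
  t3 <- sum(ni * (ni - 1)) * sum(ties * (ties - 1))
  v <- t1 / 72 + t2 / (36 * n * (n - 1) * (n - 2)) +
    t3 / (8 * n * (n - 1))
  z <- if (v <= 0) 0 else (JT - mu) / sqrt(v)
  p <- if (v <= 0) 1 else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(JT = JT, z = z, p = min(p, 1))
}
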
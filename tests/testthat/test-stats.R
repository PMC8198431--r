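test_that("Kruskal-Wallis H matches the hand-computed example and guards ties", {
  kw <- kruskalWallis(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2))
  expect_equal(kw$H, 192 / 42, tolerance = 1e-12)
  expect_equal(kw$p, pchisq(192 / 42, 2, lower.tail = FALSE))
  allTied <- kruskalWallis(rep(5, 9), rep(1:3, each = 3))
  expect_equal(allTied$H, 0)
  expect_equal(allTied$p, 1)
  expect_error(kruskalWallis(1:4, c(1, 1, 1, 2)), ">= 2")
})

test_that("rank statistics match brute-force oracles on random instances", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    ni <- sample(3:8, k, replace = TRUE)
    g <- rep(seq_len(k), ni)
    v <- sample(1:6, sum(ni), replace = TRUE)   # heavy ties
    expect_equal(kruskalWallis(v, g)$H, bruteKW(v, g), tolerance = 1e-10)
    if (length(unique(v)) > 1) {
      ref <- kruskal.test(v, factor(g))
      expect_equal(kruskalWallis(v, g)$H, unname(ref$statistic),
                   tolerance = 1e-10)
      expect_equal(kruskalWallis(v, g)$p, ref$p.value, tolerance = 1e-10)
    }
    ord <- as.character(seq_len(k))
    jt <- jonckheereTerpstra(v, as.character(g), order = ord)
    expect_equal(jt$JT, bruteJT(v, as.character(g), ord), tolerance = 1e-10)
  }
})

test_that("eta-squared centres H at its null expectation", {
  expect_equal(etaSquaredKW(192 / 42, 3, 6), (192 / 42 - 2) / 3,
               tolerance = 1e-12)
  expect_equal(etaSquaredKW(2, 3, 10), 0)
  hs <- seq(0, 10, 0.5)
  expect_true(all(diff(etaSquaredKW(hs, 3, 30)) > 0))
  expect_error(etaSquaredKW(1, 3, 3), "exceed")
})

test_that("Conover statistics vanish for identical groups and follow ranks", {
  v <- c(1, 2, 3, 1, 2, 3, 9, 9, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  cv <- conoverPosthoc(v, g)
  ab <- cv[cv$group_i == "a" & cv$group_j == "b", ]
  expect_equal(ab$t, 0); expect_equal(ab$r, 0); expect_equal(ab$p, 1)
  # rank-based: invariant to strictly monotone transforms
  set.seed(7)
  v2 <- rnorm(24); g2 <- rep(1:3, each = 8)
  expect_equal(conoverPosthoc(v2, g2)[, c("t", "p", "r")],
               conoverPosthoc(exp(v2), g2)[, c("t", "p", "r")],
               tolerance = 1e-12)
  # Pallant r denominator conventions
  rPair <- conoverPosthoc(v2, g2, rDenom = "pair")$r
  rTot <- conoverPosthoc(v2, g2, rDenom = "total")$r
  expect_equal(rTot * sqrt(24), rPair * sqrt(16), tolerance = 1e-12)
})

test_that("Conover p-values agree with a permutation null", {
  set.seed(8)
  v <- c(2.1, 3.4, 1.2, 5.6, 4.4, 3.3, 2.8, 6.1,
         4.0, 4.2, 5.1, 6.3, 2.2, 7.4, 5.5, 3.9,
         7.1, 8.2, 6.6, 9.0, 5.9, 7.7, 8.8, 6.4)
  g <- rep(c("a", "b", "c"), each = 8)
  obs <- conoverPosthoc(v, g)
  nPerm <- 4000
  permT <- replicate(nPerm, {
    cv <- conoverPosthoc(v, sample(g))
    abs(cv$t)
  })
  for (i in 1:3) {
    pPerm <- mean(permT[i, ] >= abs(obs$t[i]) - 1e-12)
    se <- sqrt(max(pPerm * (1 - pPerm), 1e-4) / nPerm)
    expect_lt(abs(obs$p[i] - pPerm), 4 * se + 0.02)
  }
})

test_that("Jonckheere-Terpstra counts ordered pairs and is calibrated", {
  up <- jonckheereTerpstra(c(1, 2, 3, 4, 5, 6), rep(c("Ctr", "LN", "LC"),
                                                    each = 2))
  expect_equal(up$JT, 12)                        # maximum = sum ni nj
  down <- jonckheereTerpstra(c(5, 6, 3, 4, 1, 2), rep(c("Ctr", "LN", "LC"),
                                                      each = 2))
  expect_equal(down$JT, 0)
  expect_equal(up$z, -down$z, tolerance = 1e-12)
  # type-I error under the null
  set.seed(9)
  rej <- mean(replicate(2000, {
    jonckheereTerpstra(rnorm(30), rep(c("Ctr", "LN", "LC"), each = 10))$p
  }) < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("Lancaster combination reduces to Fisher at equal weights 2", {
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(2:5, 1))
    fisher <- pchisq(-2 * sum(log(p)), df = 2 * length(p),
                     lower.tail = FALSE)
    expect_equal(lancasterCombine(p, 2), fisher, tolerance = 1e-10)
  }
  expect_equal(lancasterCombine(c(0.5, 0.5), c(2, 2)),
               pchisq(-2 * log(0.25), 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(round(lancasterCombine(c(0.5, 0.5), c(2, 2)), 4), 0.5966)
  # monotone in each input; zero p-values stay finite
  expect_gt(lancasterCombine(c(0.5, 0.5)), lancasterCombine(c(0.3, 0.5)))
  expect_gt(lancasterCombine(c(0, 0.5), c(3, 1)), 0)
  expect_error(lancasterCombine(c(0.5, 0.5), c(-1, 2)), "positive")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(0.37), 0.37)
  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(bhFDR(p), bruteBH(p), tolerance = 1e-12)
  }
  p <- runif(50)
  adj <- bhFDR(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
})

test_that("presence/absence chi-square matches the textbook computation", {
  # groups of 20/20/20 with 20, 0 and 10 present
  pres <- c(rep(TRUE, 20), rep(FALSE, 20), rep(TRUE, 10), rep(FALSE, 10))
  g <- rep(c("a", "b", "c"), each = 20)
  res <- chiSquarePresence(pres, g)
  expect_false(res$exact)
  expect_equal(res$statistic, 40)                # hand-computed chi-square
  expect_equal(res$p, pchisq(40, 2, lower.tail = FALSE))
  # equal proportions: statistic 0, p 1
  resEq <- chiSquarePresence(rep(c(TRUE, FALSE), 30), rep(c("a", "b", "c"), 20))
  expect_equal(resEq$statistic, 0, tolerance = 1e-12)
  expect_equal(resEq$p, 1, tolerance = 1e-12)
  # permutation of group labels leaves p unchanged
  set.seed(12)
  perm <- sample(60)
  expect_equal(chiSquarePresence(pres[perm], g[perm])$p, res$p)
  # expected-count guard triggers the exact test
  small <- chiSquarePresence(c(TRUE, rep(FALSE, 5), rep(TRUE, 6)),
                             rep(c("a", "b"), each = 6))
  expect_true(small$exact)
})

test_that("effect magnitude labels follow the conventional cut-offs", {
  expect_identical(as.character(effectMagnitude(c(0.05, 0.1, 0.35, 0.6), "r")),
                   c("N", "S", "M", "L"))
  expect_identical(as.character(effectMagnitude(c(0.005, 0.03, 0.1, 0.2),
                                                "eta_sq")),
                   c("N", "S", "M", "L"))
  labs <- effectMagnitude(seq(0, 0.8, 0.01), "r")
  expect_true(all(diff(as.integer(labs)) >= 0))
  expect_error(effectMagnitude(-0.1, "r"), "negative")
})

test_that("class aggregation sums concentrations and partitions lipid mass", {
  m <- tinyME()
  m <- replaceBelowLOD(m, seed = 3)
  m <- imputeCalibrantKNN(m, k = 1, minShared = 2)
  agg <- aggregateClasses(m)
  expect_equal(agg$cholesteryl_ester[1],
               sum(concentrations(m)[c("CE(20:5)", "CE(14:0)"), 1]))
  expect_equal(agg$total_lipids,
               unname(rowSums(agg[, lipidClasses()])))
  shares <- agg[, lipidClasses()] / agg$total_lipids
  expect_equal(unname(rowSums(shares)), rep(1, nrow(agg)))
  expect_error(aggregateClasses(log2Transform(m)), "linear")
})

test_that("rank statistics are invariant to monotone transforms of the data", {
  set.seed(13)
  v <- rnorm(36); g <- rep(c("Ctr", "LN", "LC"), each = 12)
  f <- function(x) x^3 + 2 * x                    # strictly monotone
  expect_equal(kruskalWallis(v, g)$H, kruskalWallis(f(v), g)$H,
               tolerance = 1e-12)
  expect_equal(jonckheereTerpstra(v, g)$z, jonckheereTerpstra(f(v), g)$z,
               tolerance = 1e-12)
})
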
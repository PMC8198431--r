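test_that("missingness profile counts codes exactly per stratum", {
  m <- tinyME()
  pr <- profileMissingness(m)                     # cohort x group strata
  # CE(14:0): BLOD in s2 (MOLTEST LN), MISS in s4 (SMAC Ctr)
  row <- pr[pr$analyte_id == "CE(14:0)" & pr$cohort == "MOLTEST" &
              pr$group == "LN", ]
  expect_equal(row$frac_blod, 1)
  row <- pr[pr$analyte_id == "CE(14:0)" & pr$cohort == "SMAC" &
              pr$group == "Ctr", ]
  expect_equal(row$frac_missing, 1)
  # all-observed analyte has zero fractions everywhere
  ce <- pr[pr$analyte_id == "CE(20:5)", ]
  expect_true(all(ce$frac_missing == 0 & ce$frac_blod == 0))
  # pooled fractions are the sample-size-weighted mean of stratified ones
  pooled <- profileMissingness(m, strata = "group")
  for (g in c("Ctr", "LN", "LC")) {
    a <- pr[pr$analyte_id == "Ala" & pr$group == g, ]
    b <- pooled[pooled$analyte_id == "Ala" & pooled$group == g, ]
    expect_equal(b$frac_missing, weighted.mean(a$frac_missing, a$n))
    expect_equal(b$frac_blod, weighted.mean(a$frac_blod, a$n))
  }
})

test_that("partition applies the 10%/50% rules per stratum", {
  prof <- data.frame(
    analyte_id = rep(c("clean", "lostCal", "lowAbund"), each = 2),
    cohort = "A", group = rep(c("Ctr", "LC"), 3), n = 10,
    frac_missing = c(0, 0, 0.11, 0, 0, 0),
    frac_blod = c(0, 0, 0, 0, 0.6, 0.1))
  part <- partitionAnalytes(prof)
  expect_identical(part$quantitative, "clean")
  expect_identical(part$excluded, "lostCal")       # 11% calibrant in one group
  expect_identical(part$binary, "lowAbund")        # 60% below LOD in one group
  # boundary: exactly at tolerance stays in
  prof$frac_missing[3] <- 0.10
  expect_identical(partitionAnalytes(prof)$excluded, character(0))
  expect_error(partitionAnalytes(prof, calibrantTol = 1.2), "tolerance")
  # three sets always disjoint and exhaustive
  m <- simulateCohort(defaultCohortSpec(seed = 4))
  p2 <- partitionAnalytes(profileMissingness(m))
  all3 <- c(p2$quantitative, p2$binary, p2$excluded)
  expect_setequal(all3, rownames(m))
  expect_false(anyDuplicated(all3) > 0)
})

test_that("kNN imputation averages the k nearest same-group same-plate donors", {
  # 12 analytes x 5 samples, one group/plate; s1 missing analyte a1;
  # donors s2..s4 correlate with s1 in that order, s5 anticorrelates
  reg <- data.frame(analyte_id = paste0("a", 1:12),
                    analyte_class = "amino_acid", is_lipid = FALSE)
  sdat <- data.frame(sample_id = paste0("s", 1:5), cohort = "A",
                     group = "Ctr", plate_id = "P1", age = 60, sex = "F",
                     pack_years = 0)
  base <- seq(1, 12)
  conc <- cbind(base,
                base + 0.01 * seq(-1, 1, length.out = 12),
                base + c(rep(0.4, 6), rep(-0.4, 6)),
                base + c(rep(-0.9, 4), rep(0.9, 8)),
                rev(base))
  conc[1, 1] <- NA
  conc[1, 2:5] <- c(1, 2, 3, 100)        # donor values for analyte a1
  codes <- matrix("OBS", 12, 5); codes[1, 1] <- "MISS"
  m <- MetabExperiment(conc, codes, sdat, reg)
  out <- imputeCalibrantKNN(m, k = 3)
  # s5 is perfectly anticorrelated, so the 3 nearest are s2, s3, s4
  expect_equal(unname(concentrations(out)["a1", "s1"]), mean(c(1, 2, 3)))
  expect_identical(unname(cellCodes(out)["a1", "s1"]), "IMP")
  expect_null(metadata(out)$imputeLog)
  # a perfectly correlated donor has correlation distance 0
  d <- metabscreen:::.corDistances(concentrations(m), 1, 2:5, minShared = 5)
  expect_equal(which.min(d), 1)
  expect_lt(d[1], 1e-4)
})

test_that("imputation falls back when the plate has too few donors", {
  reg <- data.frame(analyte_id = paste0("a", 1:12),
                    analyte_class = "amino_acid", is_lipid = FALSE)
  sdat <- data.frame(sample_id = paste0("s", 1:4), cohort = "A",
                     group = "Ctr", plate_id = c("P1", "P1", "P2", "P2"),
                     age = 60, sex = "F", pack_years = 0)
  set.seed(1)
  conc <- matrix(rexp(48) + 1, 12, 4)
  conc[1, 1] <- NA
  codes <- matrix("OBS", 12, 4); codes[1, 1] <- "MISS"
  m <- MetabExperiment(conc, codes, sdat, reg)
  out <- imputeCalibrantKNN(m, k = 3, minShared = 5)
  expect_identical(unname(cellCodes(out)["a1", "s1"]), "IMP")
  expect_identical(metadata(out)$imputeLog$fallback, "same_group_any_plate")
})

test_that("kNN imputation beats group-mean imputation on masked data", {
  m <- simulateCohort(cohortSpec(groupSizes = list(A = c(32, 32, 32)),
                                 calibrantRate = 0, lodQuantile = 0,
                                 seed = 14))
  conc <- concentrations(m); codes <- cellCodes(m)
  set.seed(77)
  cells <- cbind(sample(nrow(m), 200, replace = TRUE),
                 sample(ncol(m), 200, replace = TRUE))
  cells <- cells[!duplicated(cells), ]
  truth <- conc[cells]
  conc[cells] <- NA; codes[cells] <- "MISS"
  masked <- MetabExperiment(conc, codes,
                            as.data.frame(SummarizedExperiment::colData(m)),
                            as.data.frame(SummarizedExperiment::rowData(m)),
                            plateLimits = plateLimits(m))
  out <- imputeCalibrantKNN(masked, k = 3)
  knnErr <- concentrations(out)[cells] - truth
  grp <- as.character(sampleGroup(m))
  groupMean <- t(apply(conc, 1, function(v) tapply(v, grp, mean, na.rm = TRUE)))
  gmErr <- groupMean[cbind(cells[, 1], match(grp[cells[, 2]],
                                             colnames(groupMean)))] - truth
  expect_lt(sqrt(mean((knnErr / truth)^2)), sqrt(mean((gmErr / truth)^2)))
})

test_that("below-LOD replacement draws truncated normals inside [0, LOD]", {
  skip_if_not_installed("truncnorm")
  # one analyte, one plate, LOD = 1, 10,000 censored cells
  nS <- 10000
  reg <- data.frame(analyte_id = "a1", analyte_class = "hexose",
                    is_lipid = FALSE)
  sdat <- data.frame(sample_id = paste0("s", 1:nS), cohort = "A",
                     group = rep(c("Ctr", "LN", "LC"), length.out = nS),
                     plate_id = "P1", age = 60, sex = "F", pack_years = 0)
  conc <- matrix(0, 1, nS); codes <- matrix("BLOD", 1, nS)
  lod <- data.frame(plate_id = "P1", analyte_id = "a1", lod = 1)
  m <- MetabExperiment(conc, codes, sdat, reg, plateLimits = lod)
  out <- replaceBelowLOD(m, seed = 6)
  v <- concentrations(out)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(cellCodes(out) == "REP"))
  mu <- truncnorm::etruncnorm(0, 1, 0.5, 0.25)
  sdRef <- sqrt(truncnorm::vtruncnorm(0, 1, 0.5, 0.25))
  expect_lt(abs(mean(v) - mu), 3 * sdRef / sqrt(nS))
  # reproducible given the seed; untouched without BLOD cells
  expect_equal(concentrations(replaceBelowLOD(m, seed = 6)), v)
  clean <- tinyME()[1, ]                 # CE(20:5): fully observed
  expect_identical(concentrations(replaceBelowLOD(clean, seed = 1)),
                   concentrations(clean))
})

test_that("log2 transform is exact, invertible and guards nonpositives", {
  m <- tinyME()[1, ]                     # all observed, positive
  lg <- log2Transform(m)
  expect_equal(unname(concentrations(lg)[1, 1]), log2(3))
  expect_equal(concentrations(unlog2Transform(lg)), concentrations(m),
               tolerance = 1e-12)
  bad <- m
  cc <- concentrations(bad); cc[1, 2] <- 0
  concentrations(bad) <- cc
  expect_error(log2Transform(bad), "CE\\(20:5\\).*s2")
})

test_that("the chain preserves metadata and shrinks analytes only at partition", {
  m <- simulateCohort(smallSpec(seed = 8))
  pr <- preprocess(m, seed = 2)
  expect_identical(as.data.frame(SummarizedExperiment::colData(pr$corrected)),
                   as.data.frame(SummarizedExperiment::colData(m)))
  expect_setequal(rownames(pr$corrected), pr$partition$quantitative)
  expect_true(isTRUE(S4Vectors::metadata(pr$corrected)$logScale))
  expect_false(any(is.na(concentrations(pr$corrected))))
})
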
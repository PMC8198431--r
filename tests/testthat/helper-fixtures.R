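# shared fixtures, all generated in code

# tiny single-cohort spec for fast unit tests
smallSpec <- function(seed = 3, n = 8, ...) {
  cohortSpec(groupSizes = list(MOLTEST = c(Ctr = n, LN = n, LC = n)),
             seed = seed, ...)
}

# hand-built 3-analyte x 6-sample experiment with every code type
tinyME <- function() {
  reg <- data.frame(
    analyte_id = c("CE(20:5)", "CE(14:0)", "Ala"),
    analyte_class = c("cholesteryl_ester", "cholesteryl_ester", "amino_acid"),
    is_lipid = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  sd <- data.frame(
    sample_id = paste0("s", 1:6),
    cohort = rep(c("MOLTEST", "SMAC"), each = 3),
    group = rep(c("Ctr", "LN", "LC"), 2),
    plate_id = rep(c("P1", "P2"), each = 3),
    age = 60:65, sex = rep(c("F", "M"), 3), pack_years = seq(10, 35, 5),
    stringsAsFactors = FALSE)
  conc <- matrix(c(3, 4, 5, 6, 7, 8,
                   1, 0, 2, NA, 3, 4,
                   10, 11, 0, 12, NA, 13), nrow = 3, byrow = TRUE)
  codes <- matrix("OBS", 3, 6)
  codes[conc == 0] <- "BLOD"
  codes[is.na(conc)] <- "MISS"
  lod <- expand.grid(plate_id = c("P1", "P2"),
                     analyte_id = reg$analyte_id,
                     stringsAsFactors = FALSE)
  lod$lod <- 0.5
  MetabExperiment(conc, codes, sd, reg, plateLimits = lod)
}

# brute-force tie-corrected Kruskal-Wallis from the definition
bruteKW <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  num <- sum(tapply(r, groups, function(ri)
    length(ri) * (mean(ri) - (n + 1) / 2)^2))
  H <- 12 / (n * (n + 1)) * num
  tj <- table(values)
  H / (1 - sum(tj^3 - tj) / (n^3 - n))
}

# brute-force Jonckheere-Terpstra statistic (pairwise count definition)
bruteJT <- function(values, groups, order) {
  groups <- factor(groups, levels = order)
  vs <- split(values, groups)
  JT <- 0
  k <- length(vs)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    for (u in vs[[i]]) for (v in vs[[j]])
      JT <- JT + (v > u) + 0.5 * (v == u)
  JT
}

# brute-force BH from the step-up definition: min over j >= i of m * p_(j) / j
bruteBH <- function(p) {
  m <- length(p)
  ps <- sort(p)
  adjSorted <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  adjSorted[rank(p, ties.method = "first")]
}
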
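test_that("intercept-only model recovers class frequencies exactly", {
  y <- factor(rep(c("Ctr", "LN", "LC"), times = c(10, 20, 30)),
              levels = c("Ctr", "LN", "LC"))
  X <- matrix(numeric(0), nrow = 60, ncol = 0)
  fit <- fitMLR(X, y)
  P <- predictProbMLR(fit, X)
  expect_equal(unname(P[1, ]), c(1 / 6, 1 / 3, 1 / 2), tolerance = 1e-8)
  expect_true(all(abs(rowSums(P) - 1) < 1e-10))
  # closed-form intercept-only likelihood
  expect_equal(fit$logLik, sum(c(10, 20, 30) * log(c(10, 20, 30) / 60)),
               tolerance = 1e-8)
})

test_that("the fit matches the reference multinomial logit", {
  skip_if_not_installed("nnet")
  set.seed(21)
  n <- 250
  X <- matrix(rnorm(n * 4), n); colnames(X) <- paste0("f", 1:4)
  lin <- X[, 1] - 0.5 * X[, 2]
  y <- factor(sapply(lin, function(l)
    sample(c("Ctr", "LN", "LC"), 1,
           prob = exp(c(0, l, -l)) / sum(exp(c(0, l, -l))))),
    levels = c("Ctr", "LN", "LC"))
  fit <- fitMLR(X, y)
  ref <- nnet::multinom(y ~ X, trace = FALSE, reltol = 1e-12, maxit = 500)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$coef), unname(t(coef(ref))), tolerance = 1e-4)
})

test_that("noise features get near-zero coefficients", {
  set.seed(22)
  for (i in 1:5) {
    X <- matrix(rnorm(300), ncol = 1); colnames(X) <- "noise"
    y <- factor(sample(c("Ctr", "LN", "LC"), 300, TRUE))
    fit <- fitMLR(X, y)
    expect_lt(max(abs(fit$coef["noise", ])), 0.4)
  }
})

test_that("BIC arithmetic is exact", {
  y <- factor(rep(c("Ctr", "LN", "LC"), each = 30))
  X0 <- matrix(numeric(0), nrow = 90, ncol = 0)
  fit0 <- fitMLR(X0, y)
  expect_equal(bicMLR(fit0), 2 * 90 * log(3) + 2 * log(90), tolerance = 1e-6)
  # a feature that cannot move the likelihood costs exactly 2 log(n)
  Xz <- matrix(0, 90, 1); colnames(Xz) <- "zero"
  fitz <- fitMLR(Xz, y)
  expect_equal(bicMLR(fitz) - bicMLR(fit0), 2 * log(90), tolerance = 1e-6)
  # a strong planted feature lowers BIC
  set.seed(23)
  Xs <- matrix(rnorm(90, mean = 2 * (as.integer(y) - 2)), 90, 1)
  colnames(Xs) <- "strong"
  expect_lt(bicMLR(fitMLR(Xs, y)), bicMLR(fit0))
})

test_that("perfect separation triggers the ridge fallback, not failure", {
  y <- factor(rep(c("Ctr", "LN", "LC"), each = 10))
  X <- matrix(as.integer(y), 30, 1) + matrix(rnorm(30, 0, 1e-4), 30, 1)
  colnames(X) <- "sep"
  fit <- fitMLR(X, y)
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coef)))
  expect_gt(evaluateModel(fit, X, y)$accuracy, 0.95)
})

test_that("forward selection finds a planted feature and respects the stop rule", {
  set.seed(24)
  firstPick <- replicate(100, {
    n <- 200
    X <- matrix(rnorm(n * 50), n); colnames(X) <- paste0("f", 1:50)
    y <- factor(rep(c("Ctr", "LN", "LC"), length.out = n))
    X[, 7] <- X[, 7] + 2 * (as.integer(y) - 2)    # planted log2FC = 2 scale
    forwardSelect(X, y)$features[1]
  })
  expect_gte(mean(firstPick == "f7"), 0.95)
})

test_that("forward selection on pure noise stays short and BICs decrease by > delta", {
  set.seed(25)
  lens <- replicate(20, {
    X <- matrix(rnorm(150 * 30), 150); colnames(X) <- paste0("f", 1:30)
    y <- factor(rep(c("Ctr", "LN", "LC"), each = 50))
    tr <- forwardSelect(X, y, delta = 2)
    if (length(tr$bic) > 0)
      expect_true(all(diff(c(tr$bic0, tr$bic)) < -2))
    length(tr$features)
  })
  expect_lte(mean(lens), 2)
})

test_that("MRCV produces the requested reproducible stratified splits", {
  set.seed(26)
  X <- matrix(rnorm(90 * 10), 90); colnames(X) <- paste0("f", 1:10)
  y <- factor(rep(c("Ctr", "LN", "LC"), times = c(40, 30, 20)))
  r1 <- mrcv(X, y, reps = 25, seed = 5)
  expect_length(r1$traces, 25)
  r2 <- mrcv(X, y, reps = 25, seed = 5)
  expect_identical(lapply(r1$traces, `[[`, "features"),
                   lapply(r2$traces, `[[`, "features"))
  expect_identical(r1$testAcc, r2$testAcc)
  # stratification: split preserves group proportions within one sample
  strata <- split(seq_along(y), y)
  seeds <- metabscreen:::splitSeed(5, 25)
  tr <- metabscreen:::withSeed(seeds[1], unlist(lapply(strata, function(i)
    sample(i, round(0.7 * length(i))))))
  expect_equal(unname(c(table(y[tr]))),
               unname(round(0.7 * c(table(y)))))
})

test_that("consensus ranking cuts the score curve at its elbow", {
  mk <- function(feats) list(features = feats, bic = seq_along(feats),
                             bic0 = 0, stop = "no_improvement")
  # f1 in all traces and always first; f2/f3 frequent; f4..f6 rare
  traces <- c(replicate(100, mk(c("f1", sample(c("f2", "f3")))),
                        simplify = FALSE),
              replicate(5, mk(c("f4", "f5", "f6")), simplify = FALSE))
  cons <- rankAndCut(traces)
  expect_true("f1" %in% cons)
  expect_false(any(c("f4", "f5", "f6") %in% cons))
  expect_identical(rankAndCut(rev(traces)), cons)
  # the printed 6-point curve: scores (100, 99, 98, 5, 4, 3) cut after 3
  traces2 <- c(
    rep(list(mk(c("a", "b", "c"))), 98),
    list(mk(c("a", "b"))), list(mk("a")),
    lapply(1:5, function(i) mk("d")), lapply(1:4, function(i) mk("e")),
    lapply(1:3, function(i) mk("f")))
  freq <- table(unlist(lapply(traces2, `[[`, "features")))
  expect_equal(unname(sort(as.vector(freq), decreasing = TRUE)),
               c(100, 99, 98, 5, 4, 3))
  expect_setequal(rankAndCut(traces2), c("a", "b", "c"))
})

test_that("evaluation metrics agree with a hand-computed confusion matrix", {
  lv <- c("Ctr", "LN", "LC")
  model <- structure(list(coef = matrix(0, 1, 2), levels = lv,
                          feature_ids = character(0), logLik = 0,
                          n_train = 9, converged = TRUE, separation = FALSE,
                          ridge = 0), class = "mlrModel")
  # fabricate posteriors: predictions Ctr,Ctr,LN | LN,LN,LC | LC,LC,Ctr
  P <- rbind(c(.8, .1, .1), c(.7, .2, .1), c(.2, .7, .1),
             c(.1, .8, .1), c(.2, .6, .2), c(.1, .2, .7),
             c(.1, .1, .8), c(.2, .2, .6), c(.6, .2, .2))
  colnames(P) <- lv
  y <- factor(rep(lv, each = 3), levels = lv)
  pred <- mapClass(P)
  conf <- table(truth = y, pred = pred)
  expect_equal(unname(diag(conf)), c(2, 2, 2))
  acc <- mean(pred == y)
  expect_equal(acc, 6 / 9)
  sens <- diag(conf) / rowSums(conf)
  expect_equal(unname(sens), rep(2 / 3, 3))
  # specificity of Ctr: 5 of 6 non-Ctr samples not called Ctr
  expect_equal(unname(sum(pred[y != "Ctr"] != "Ctr") / 6), 5 / 6)
})

test_that("one-vs-rest AUC matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(27)
  score <- rnorm(80); lab <- rbinom(80, 1, 0.5) == 1
  ours <- metabscreen:::.aucMW(score, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = score,
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("a separable fixture reaches ceiling metrics", {
  set.seed(28)
  y <- factor(rep(c("Ctr", "LN", "LC"), each = 20),
              levels = c("Ctr", "LN", "LC"))
  X <- cbind(10 * (y == "LN") + rnorm(60, 0, .1),
             10 * (y == "LC") + rnorm(60, 0, .1))
  colnames(X) <- c("a", "b")
  fit <- fitMLR(X, y)
  ev <- evaluateModel(fit, X, y)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
  expect_equal(unname(ev$sensitivity), rep(1, 3))
  expect_equal(unname(ev$specificity), rep(1, 3))
  expect_equal(ev$balanced_accuracy, 1)
})

test_that("outer CV partitions test sets and aggregates ten folds", {
  set.seed(29)
  n <- 360
  X <- matrix(rnorm(n * 30), n); colnames(X) <- paste0("f", 1:30)
  y <- factor(rep(c("Ctr", "LN", "LC"), each = 120),
              levels = c("Ctr", "LN", "LC"))
  X[, 1] <- X[, 1] + 1.5 * (as.integer(y) - 2)
  rep1 <- outerCV(X, y, folds = 5, perGroupTest = 8, mrcvReps = 8,
                  candidateCap = 15, seed = 3)
  expect_length(rep1$folds, 5)
  testSets <- lapply(rep1$folds, function(f) f$test)
  # aggregate CIs bracket the means
  for (s in names(rep1$aggregate)) {
    a <- rep1$aggregate[[s]]
    expect_true(all(a[, "lo"] <= a[, "mean"] & a[, "mean"] <= a[, "hi"]))
  }
  # deterministic given the master seed
  rep2 <- outerCV(X, y, folds = 5, perGroupTest = 8, mrcvReps = 8,
                  candidateCap = 15, seed = 3)
  expect_identical(rep1$aggregate, rep2$aggregate)
  # the planted feature dominates the consensus signatures
  expect_true(all(vapply(rep1$folds, function(f) "f1" %in% f$consensus,
                         logical(1))))
  expect_identical(names(rep1$selectionFrequency)[1], "f1")
  mt <- metricsTable(rep1)
  expect_identical(mt$Set, c("Training", "Test"))
})

test_that("outer CV test folds are disjoint across folds", {
  # reconstruct the fold assignment from the seed fan-out
  y <- factor(rep(c("Ctr", "LN", "LC"), each = 120))
  seeds <- metabscreen:::splitSeed(3, 6)
  foldOf <- metabscreen:::withSeed(seeds[6], {
    f <- rep(NA_integer_, length(y))
    for (s in split(seq_along(y), y)) {
      chosen <- sample(s, 5 * 8)
      f[chosen] <- rep(seq_len(5), each = 8)
    }
    f
  })
  counts <- table(foldOf, y)
  expect_true(all(counts == 8))
  expect_equal(sum(!is.na(foldOf)), 5 * 8 * 3)
})
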
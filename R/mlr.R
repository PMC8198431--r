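#' Fit a multinomial logistic regression model
#'
#' Maximum-likelihood multinomial logit (reference class = first factor
#' level, i.e. Ctr) fitted by Newton-Raphson with step halving; convergence
#' when the relative log-likelihood change falls below \code{tol} or after
#' \code{maxit} iterations. Quasi-perfect separation (non-convergence or
#' exploding coefficients) triggers a small ridge penalty and is flagged.
#'
#' @param X numeric matrix, samples x features.
#' @param y class labels (factor or coercible; >= 2 classes present).
#' @param ridge baseline ridge penalty (default 0).
#' @param tol,maxit convergence controls.
#' @return object of class \code{mlrModel}: coefficient matrix
#'   ((features + 1) x (k - 1), intercept first), class levels, log-likelihood,
#'   \code{n_train}, separation flag.
#' @export
fitMLR <- function(X, y, ridge = 0, tol = 1e-8, maxit = 200) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need >= 2 classes present")
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  fit <- cpp_mlr_fit(X, as.integer(y) - 1L, nlevels(y), ridge, tol, maxit)
  coef <- fit$coef
  rownames(coef) <- c("(Intercept)", colnames(X))
  colnames(coef) <- levels(y)[-1]
  structure(list(coef = coef, levels = levels(y),
                 feature_ids = colnames(X),
                 logLik = fit$logLik, n_train = nrow(X),
                 converged = fit$converged, separation = fit$separation,
                 ridge = fit$ridge),
            class = "mlrModel")
}

#' @export
print.mlrModel <- function(x, ...) {
  cat("mlrModel:", length(x$feature_ids), "features,",
      length(x$levels), "classes (ref", x$levels[1], "), logLik",
      format(x$logLik, digits = 6),
      if (x$separation) "[separation fallback]" else "", "\n")
  invisible(x)
}

#' Bayesian information criterion of a fitted model
#'
#' \eqn{BIC = -2 \log L + q \log n} with \eqn{q = (k-1)(features+1)} free
#' parameters.
#'
#' @param model an \code{mlrModel}.
#' @return numeric BIC.
#' @export
bicMLR <- function(model) {
  if (!inherits(model, "mlrModel")) stop("not a fitted mlrModel")
  q <- (length(model$levels) - 1) * nrow(model$coef)
  -2 * model$logLik + q * log(model$n_train)
}

#' Class posterior probabilities
#'
#' @param model an \code{mlrModel}.
#' @param X samples x features matrix with the model's features (by name if
#'   the matrix is named).
#' @return samples x classes probability matrix (rows sum to 1).
#' @export
predictProbMLR <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && length(model$feature_ids))
    X <- X[, model$feature_ids, drop = FALSE]
  P <- cpp_mlr_prob(X, model$coef)
  colnames(P) <- model$levels
  rownames(P) <- rownames(X)
  P
}

#' Maximum-a-posteriori class assignment
#'
#' Ties are broken by the fixed class order (first level wins).
#' @param prob samples x classes probability matrix.
#' @return factor of predicted classes.
#' @export
mapClass <- function(prob) {
  factor(colnames(prob)[apply(prob, 1, which.max)],
         levels = colnames(prob))
}

# Mann-Whitney AUC of scores for positives vs negatives
.aucMW <- function(score, positive) {
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Classification metrics on labelled data
#'
#' MAP accuracy, macro one-vs-rest AUC from the class posteriors, per-class
#' sensitivity (recall) and specificity (one-vs-rest true-negative rate), and
#' balanced accuracy (mean per-class sensitivity).
#'
#' @param model an \code{mlrModel}.
#' @param X samples x features matrix.
#' @param y true class labels (all model classes should be present).
#' @return list with \code{accuracy}, \code{auc}, \code{sensitivity},
#'   \code{specificity} (named per class), \code{balanced_accuracy},
#'   \code{confusion}.
#' @export
evaluateModel <- function(model, X, y) {
  y <- factor(y, levels = model$levels)
  if (anyNA(y)) stop("labels outside the model's classes")
  if (any(table(y) == 0)) stop("a class is absent from y")
  P <- predictProbMLR(model, X)
  pred <- mapClass(P)
  conf <- table(truth = y, pred = pred)
  acc <- mean(pred == y)
  sens <- diag(conf) / rowSums(conf)
  spec <- vapply(model$levels, function(cl) {
    neg <- y != cl
    sum(pred[neg] != cl) / sum(neg)
  }, numeric(1))
  auc <- vapply(model$levels, function(cl)
    .aucMW(P[, cl], y == cl), numeric(1))
  list(accuracy = acc, auc = mean(auc), auc_per_class = auc,
       sensitivity = sens, specificity = spec,
       balanced_accuracy = mean(sens), confusion = conf)
}
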
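#' ROC AUC of a score vector
#'
#' Computed as the tie-corrected Mann-Whitney statistic: the probability that
#' a random positive scores above a random negative, ties counting one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or factor; `TRUE`/second level = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two classes")
  f == levels(f)[2]
}

#' Precision-recall AUC
#'
#' Default `"interpolated"` integrates precision over recall with the
#' nonlinear interpolation between adjacent operating points (precision is a
#' hyperbolic, not linear, function of recall between counts), matching the
#' continuous convention of standard PR evaluation tools. `"trapezoid"` is
#' the linear fallback.
#'
#' @param scores numeric scores.
#' @param labels positive/negative labels, see [roc_auc()].
#' @param method interpolation convention.
#' @return AUC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels, method = c("interpolated", "trapezoid")) {
  method <- match.arg(method)
  pos <- as_positive(labels)
  P <- sum(pos)
  if (P == 0 || all(pos)) stop("both classes required for AUC")
  o <- order(scores, decreasing = TRUE)
  y <- pos[o]; s <- scores[o]
  # operating points at distinct thresholds
  cut <- which(diff(s) != 0)
  idx <- c(cut, length(s))
  tp <- cumsum(y)[idx]
  fp <- cumsum(!y)[idx]
  tp <- c(0, tp); fp <- c(0, fp)
  auc <- 0
  for (k in 2:length(tp)) {
    dtp <- tp[k] - tp[k - 1]
    if (dtp == 0) next
    a <- tp[k - 1]; b <- tp[k - 1] + fp[k - 1]
    m <- ((tp[k] + fp[k]) - b) / dtp     # denominator slope per unit TP
    if (method == "trapezoid") {
      p1 <- if (b + m * dtp > 0) (a + dtp) / (b + m * dtp) else 1
      p0 <- if (b > 0) a / b else p1
      auc <- auc + dtp / P * (p0 + p1) / 2
    } else {
      # integral of (a + t)/(b + m t) dt from 0 to dtp
      if (abs(m) < 1e-12) {
        auc <- auc + (a * dtp + dtp^2 / 2) / b / P
      } else if (b == 0) {
        # first segment from the origin: precision constant a'/b' along ray
        auc <- auc + dtp / P * (tp[k] / (tp[k] + fp[k]))
      } else {
        auc <- auc + (dtp / m + (a - b / m) * log((b + m * dtp) / b) / m) / P
      }
    }
  }
  auc
}

#' Per-feature F-score for feature ranking
#'
#' `F(j) = ((mean_pos - mean)^2 + (mean_neg - mean)^2) /
#' (var_pos + var_neg)` with unbiased within-class variances. Larger values
#' mean better single-feature separation of the classes.
#'
#' @param X numeric feature matrix.
#' @param y two-class labels.
#' @return Named numeric vector of F-scores (Inf flagged as `Inf` when a
#'   class has zero variance and the means differ).
#' @export
feature_fscore <- function(X, y) {
  pos <- as_positive(y)
  apply(as.matrix(X), 2, function(x) {
    m <- mean(x); mp <- mean(x[pos]); mn <- mean(x[!pos])
    num <- (mp - m)^2 + (mn - m)^2
    den <- stats::var(x[pos]) + stats::var(x[!pos])
    if (den == 0) { if (num == 0) 0 else Inf } else num / den
  })
}

#' Stratified k-fold partition
#'
#' Shuffles each class independently and deals indices round-robin, so the
#' per-fold class counts differ from exact proportionality by at most one
#' sample.
#'
#' @param y labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_kfold <- function(y, k = 4, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit an RBF-kernel SVM origin classifier
#'
#' Wraps a support vector machine with Gaussian kernel
#' `k(x, z) = exp(-sigma * ||x - z||^2)` (note: `sigma` multiplies the
#' squared distance directly, the kernlab convention; another common
#' parameterization uses `1/(2 sigma^2)`). Features are standardized to zero
#' mean and unit variance with training-set statistics, and a Platt sigmoid
#' fitted on cross-validated decision values provides probabilistic output.
#'
#' @param X numeric feature matrix.
#' @param y two-class factor (`neg`/`pos` ordering respected).
#' @param sigma RBF width parameter.
#' @param C soft-margin cost.
#' @param standardize scale features before the kernel.
#' @param prob_model fit Platt scaling for probability output.
#' @param seed RNG seed (Platt scaling uses internal cross-validation).
#' @return Object of class `origin_svm`.
#' @export
origin_svm <- function(X, y, sigma = 0.01, C = 10, standardize = TRUE,
                       prob_model = TRUE, seed = NULL) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("training labels are single-class")
  X <- as.matrix(X)
  fit <- with_seed(seed,
    kernlab::ksvm(X, y, type = "C-svc", kernel = "rbfdot",
                  kpar = list(sigma = sigma), C = C, scaled = standardize,
                  prob.model = prob_model))
  structure(list(fit = fit, features = colnames(X),
                 levels = levels(y), sigma = sigma, C = C,
                 positive = levels(y)[2]),
            class = "origin_svm")
}

#' @export
print.origin_svm <- function(x, ...) {
  cat(sprintf(
    "RBF-SVM origin classifier (sigma = %g, C = %g)\n  features: %s\n",
    x$sigma, x$C, paste(x$features, collapse = ", ")))
  cat(sprintf("  support vectors: %d\n", kernlab::nSV(x$fit)))
  invisible(x)
}

#' Predict from an origin classifier
#'
#' @param object an `origin_svm`.
#' @param newdata feature matrix with the training columns.
#' @param type `"prob"` (Platt probability of the positive class),
#'   `"decision"` or `"class"`.
#' @param ... unused.
#' @return Numeric vector (prob/decision) or factor (class).
#' @export
predict.origin_svm <- function(object, newdata,
                               type = c("prob", "decision", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  if (type == "class")
    return(kernlab::predict(object$fit, newdata))
  if (type == "decision")
    return(as.numeric(kernlab::predict(object$fit, newdata,
                                       type = "decision")))
  pr <- kernlab::predict(object$fit, newdata, type = "probabilities")
  as.numeric(pr[, object$positive])
}

#' Repeated stratified cross-validation of the origin classifier
#'
#' Runs `rounds` independent stratified k-fold partitions; in each fold the
#' classifier is trained on the remaining folds and scored on the held-out
#' fold (ROC and PR AUC). Fold AUCs are averaged per round, and the mean and
#' percentile-bootstrap 95% confidence interval over the round means are
#' reported.
#'
#' @param X feature matrix.
#' @param y two-class factor.
#' @param features optional character subset of columns to use.
#' @param k folds per round.
#' @param rounds repetitions with fresh partitions.
#' @param sigma,C,standardize SVM settings, see [origin_svm()].
#' @param boot_reps bootstrap resamples for the CI of the round means.
#' @param keep_models keep the `k * rounds` fitted classifiers (needed for
#'   [score_heldout()]).
#' @param seed master seed; round partitions and fits derive from it.
#' @return Object of class `origin_cv`: per-fold table, round means, overall
#'   means with CIs, out-of-fold probabilities, optionally the models.
#' @export
origin_cv <- function(X, y, features = NULL, k = 4, rounds = 10,
                      sigma = 0.01, C = 10, standardize = TRUE,
                      boot_reps = 10000, keep_models = TRUE, seed = NULL) {
  X <- as.matrix(X)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  y <- as.factor(y)
  folds_tab <- NULL
  oof <- matrix(NA_real_, nrow(X), rounds)
  models <- list()
  per_fold <- list()
  for (r in seq_len(rounds)) {
    fold <- stratified_kfold(y, k, seed = derive_seed(seed,
                                                      paste0("fold", r)))
    for (f in seq_len(k)) {
      test <- fold == f
      m <- origin_svm(X[!test, , drop = FALSE], y[!test], sigma = sigma,
                      C = C, standardize = standardize,
                      seed = derive_seed(seed, paste0("fit", r, "_", f)))
      p <- predict(m, X[test, , drop = FALSE], type = "prob")
      oof[test, r] <- p
      per_fold[[length(per_fold) + 1]] <- data.frame(
        round = r, fold = f,
        roc_auc = roc_auc(p, y[test]), pr_auc = pr_auc(p, y[test]))
      if (keep_models) models[[length(models) + 1]] <- m
    }
  }
  per_fold <- do.call(rbind, per_fold)
  round_means <- stats::aggregate(cbind(roc_auc, pr_auc) ~ round,
                                  data = per_fold, FUN = mean)
  ci_roc <- bootstrap_ci(round_means$roc_auc, reps = boot_reps,
                         seed = derive_seed(seed, "ciroc"))
  ci_pr <- bootstrap_ci(round_means$pr_auc, reps = boot_reps,
                        seed = derive_seed(seed, "cipr"))
  structure(list(
    per_fold = per_fold, round_means = round_means,
    roc_auc = mean(round_means$roc_auc), pr_auc = mean(round_means$pr_auc),
    roc_auc_ci = c(ci_roc$lower, ci_roc$upper),
    pr_auc_ci = c(ci_pr$lower, ci_pr$upper),
    oof_prob = rowMeans(oof), features = colnames(X),
    k = k, rounds = rounds, models = if (keep_models) models),
    class = "origin_cv")
}

#' @export
print.origin_cv <- function(x, ...) {
  cat(sprintf(
    "%d x %d-fold stratified CV on {%s}\n", x$rounds, x$k,
    paste(x$features, collapse = ", ")))
  cat(sprintf("  mean ROC-AUC %.3f (95%% CI %.3f-%.3f)\n", x$roc_auc,
              x$roc_auc_ci[1], x$roc_auc_ci[2]))
  cat(sprintf("  mean PR-AUC  %.3f (95%% CI %.3f-%.3f)\n", x$pr_auc,
              x$pr_auc_ci[1], x$pr_auc_ci[2]))
  invisible(x)
}

#' @export
summary.origin_cv <- function(object, ...) {
  print(object)
  cat("\nPer-round means:\n")
  print(object$round_means, row.names = FALSE)
  invisible(object)
}

#' Score new windows with the cross-validated classifiers
#'
#' Mean Platt probability across every classifier built in the repeated CV,
#' the protocol used to score held-out O-site IGRs and intragenic sites.
#'
#' @param cv an `origin_cv` fitted with `keep_models = TRUE`.
#' @param newdata feature matrix containing the CV's feature columns.
#' @return Numeric probability per row of `newdata`.
#' @export
score_heldout <- function(cv, newdata) {
  if (is.null(cv$models)) stop("origin_cv was run with keep_models = FALSE")
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(numeric(0))
  ps <- vapply(cv$models, function(m) predict(m, newdata, type = "prob"),
               numeric(nrow(newdata)))
  rowMeans(matrix(ps, nrow = nrow(newdata)))
}
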
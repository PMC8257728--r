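# ROC/AUC machinery, prevalence-based cutoffs, fivefold cross-validated AUC,
# permutation-test model significance, and validation-set performance.

#' Area under the ROC curve (tie-corrected concordance)
#'
#' `AUC = (#{case > control} + 0.5 * #{ties}) / (n_case * n_control)`,
#' computed through mid-ranks; identical to the trapezoidal area under the
#' ROC curve.
#'
#' @param scores numeric vector of scores (higher = more case-like).
#' @param labels binary 0/1 vector (1 = case); both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- check_binary(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve
#'
#' Thresholds sweep from above the largest score downwards; a sample is
#' called case when its score is `>=` the threshold, so TPR and FPR are
#' non-decreasing along the returned vectors.
#'
#' @inheritParams auc
#' @return An object of class `roc_curve`: `thresholds` (decreasing), `tpr`,
#'   `fpr`, `auc` (trapezoidal area).
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / n0, numeric(1))
  area <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = area),
            class = "roc_curve")
}

#' Prevalence-based classification cutoff
#'
#' The cutoff is the case proportion of the training labels; a predicted
#' probability at or above it classifies as case. This ties the operating
#' point to the case/control balance of each model's training set.
#'
#' @param train_labels binary 0/1 vector.
#' @return the cutoff (a scalar in (0, 1)).
#' @export
prevalence_cutoff <- function(train_labels) {
  if (!length(train_labels)) stop("empty labels")
  train_labels <- check_binary(train_labels)
  mean(train_labels)
}

#' Cross-validated AUC of the full model-building procedure
#'
#' Stratified k-fold cross-validation in which **all** of model building is
#' repeated inside each training portion: the penalty is re-selected by a
#' nested fivefold cross-validation ([cv_select_lambda()]) on the k-1
#' training folds, the model is refitted there, and the held-out fold is
#' scored. `auc_cv` is the arithmetic mean of the k fold AUCs.
#'
#' @param X numeric design matrix (original scale).
#' @param y binary 0/1 response.
#' @param k number of outer folds (default 5).
#' @param seed integer seed; folds, nested seeds and hence the whole result
#'   are deterministic given it.
#' @param n_lambda,lambda_min_ratio,metric passed to [cv_select_lambda()].
#' @param tol,max_iter,kkt_tol passed to the fitter.
#' @return An object of class `cv_result`: `fold_aucs`, `auc_cv`,
#'   `fold_indices`, `chosen_lambdas`, `seed`.
#' @export
cross_validated_auc <- function(X, y, k = 5L, seed = NULL, n_lambda = 20L,
                                lambda_min_ratio = 1e-3,
                                metric = "deviance", tol = 1e-7,
                                max_iter = 1e5, kkt_tol = 1e-4) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- check_binary(y)
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(y, k)
  nested_seeds <- vapply(seq_len(k), function(i) draw_seed(), integer(1))
  fold_aucs <- numeric(k)
  lambdas <- numeric(k)
  for (i in seq_len(k)) {
    tr <- fold != i
    cvres <- cv_select_lambda(X[tr, , drop = FALSE], y[tr], k = 5L,
                              n_lambda = n_lambda,
                              lambda_min_ratio = lambda_min_ratio,
                              seed = nested_seeds[i], metric = metric,
                              tol = tol, max_iter = max_iter, kkt_tol = kkt_tol)
    fit <- fit_lasso_lr(X[tr, , drop = FALSE], y[tr], cvres$chosen_lambda,
                        tol = tol, max_iter = max_iter, kkt_tol = kkt_tol)
    p <- predict_prob(fit, X[!tr, , drop = FALSE])
    fold_aucs[i] <- auc(p, y[!tr])
    lambdas[i] <- cvres$chosen_lambda
  }
  structure(
    list(fold_aucs = fold_aucs, auc_cv = mean(fold_aucs),
         fold_indices = split(seq_along(y), fold),
         chosen_lambdas = lambdas, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> AUC_CV = ", format(x$auc_cv, digits = 4), " (folds: ",
      paste(format(x$fold_aucs, digits = 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Permutation-test significance of a cross-validated model
#'
#' The observed statistic is the cross-validated AUC of the full model-
#' building procedure on the true labels. Each permutation shuffles the
#' labels uniformly and reruns the entire procedure — penalty re-selection
#' included — on the permuted labels. The p-value uses the add-one rule
#' `(1 + #(null >= observed)) / (1 + B)`, so it is never zero (minimum
#' 1/(B+1), e.g. ~0.001 at B = 1000).
#'
#' @inheritParams cross_validated_auc
#' @param B number of permutations.
#' @param observed optionally, a precomputed `cv_result` on the true labels
#'   to reuse as the observed statistic.
#' @param fast if TRUE, the penalty is selected once on the observed labels
#'   and frozen across permutations (approximate, but much cheaper); the
#'   default rebuilds everything per permutation.
#' @return An object of class `permutation_model_result`: `observed_auc_cv`,
#'   `null_auc_cv` (length B), `B`, `p_value`, `seed`.
#' @export
permutation_model_test <- function(X, y, B = 1000L, k = 5L, seed = NULL,
                                   n_lambda = 20L, lambda_min_ratio = 1e-3,
                                   metric = "deviance", observed = NULL,
                                   fast = FALSE, tol = 1e-7, max_iter = 1e5,
                                   kkt_tol = 1e-4) {
  if (B < 1L) stop("B must be >= 1")
  X <- as.matrix(X)
  y <- check_binary(y)
  if (!is.null(seed)) set.seed(seed)
  obs_seed <- draw_seed()
  null_seeds <- vapply(seq_len(B), function(b) draw_seed(), integer(1))
  perms <- lapply(seq_len(B), function(b) sample(length(y)))
  if (is.null(observed)) {
    observed <- cross_validated_auc(X, y, k = k, seed = obs_seed,
                                    n_lambda = n_lambda,
                                    lambda_min_ratio = lambda_min_ratio,
                                    metric = metric, tol = tol,
                                    max_iter = max_iter, kkt_tol = kkt_tol)
  } else {
    stopifnot(inherits(observed, "cv_result"))
  }
  frozen_lambda <- if (fast) stats::median(observed$chosen_lambdas) else NULL
  null_stat <- vapply(seq_len(B), function(b) {
    yb <- y[perms[[b]]]
    if (fast) {
      cv_fixed_lambda_auc(X, yb, frozen_lambda, k, null_seeds[b],
                          tol, max_iter, kkt_tol)
    } else {
      cross_validated_auc(X, yb, k = k, seed = null_seeds[b],
                          n_lambda = n_lambda,
                          lambda_min_ratio = lambda_min_ratio,
                          metric = metric, tol = tol, max_iter = max_iter,
                          kkt_tol = kkt_tol)$auc_cv
    }
  }, numeric(1))
  structure(
    list(observed_auc_cv = observed$auc_cv, null_auc_cv = null_stat, B = B,
         p_value = (1 + sum(null_stat >= observed$auc_cv)) / (1 + B),
         seed = seed, fast = fast),
    class = "permutation_model_result"
  )
}

# k-fold AUC at a frozen penalty (the `fast` permutation mode)
cv_fixed_lambda_auc <- function(X, y, lambda, k, seed, tol, max_iter, kkt_tol) {
  set.seed(seed)
  fold <- stratified_folds(y, k)
  mean(vapply(seq_len(k), function(i) {
    tr <- fold != i
    fit <- fit_lasso_lr(X[tr, , drop = FALSE], y[tr], lambda, tol = tol,
                        max_iter = max_iter, kkt_tol = kkt_tol)
    auc(predict_prob(fit, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1)))
}

#' @export
print.permutation_model_result <- function(x, ...) {
  cat("<permutation_model_result> observed AUC_CV = ",
      format(x$observed_auc_cv, digits = 4), ", p = ",
      format(x$p_value, digits = 4), " (B = ", x$B,
      if (x$fast) ", fast/frozen-lambda" else "", ")\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted model on the external validation set
#'
#' Scores the validation samples with the trained model, computes the
#' validation AUC and the confusion table at the given cutoff (probability
#' `>=` cutoff classifies as case; ties at the cutoff go to case).
#' Sensitivity and specificity are reported as integer percentages
#' (half-up rounding), the table-presentation convention.
#'
#' @param model a [fit_lasso_lr()] model trained on the training split only.
#' @param cutoff classification cutoff, typically [prevalence_cutoff()] of
#'   the training labels.
#' @param X_val validation design matrix (same variables, original scale,
#'   residualized with the training ASCA where applicable).
#' @param y_val binary 0/1 validation labels (both classes required).
#' @return An object of class `validation_metrics`: `auc_vs`, `cutoff`,
#'   `sensitivity_pct`, `specificity_pct`, `confusion` (2x2 integer matrix).
#' @export
external_validation <- function(model, cutoff, X_val, y_val) {
  y_val <- check_binary(y_val)
  p <- predict_prob(model, X_val)
  a <- auc(p, y_val)
  pred <- as.integer(p >= cutoff)
  tp <- sum(pred == 1 & y_val == 1)
  fn <- sum(pred == 0 & y_val == 1)
  fp <- sum(pred == 1 & y_val == 0)
  tn <- sum(pred == 0 & y_val == 0)
  confusion <- matrix(c(tp, fn, fp, tn), 2L, 2L,
                      dimnames = list(predicted = c("case", "control"),
                                      truth = c("case", "control")))
  structure(
    list(auc_vs = a, cutoff = cutoff,
         sensitivity_pct = round_half_up(100 * tp / (tp + fn)),
         specificity_pct = round_half_up(100 * tn / (tn + fp)),
         confusion = confusion),
    class = "validation_metrics"
  )
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat("<validation_metrics> AUC_VS = ", format(x$auc_vs, digits = 4),
      "; sensitivity ", x$sensitivity_pct, "%, specificity ",
      x$specificity_pct, "% at cutoff ", format(x$cutoff, digits = 4),
      "\n", sep = "")
  invisible(x)
}
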
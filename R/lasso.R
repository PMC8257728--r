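# L1-penalized logistic regression: standardization, lambda_max, path/single
# fits via compiled coordinate descent, KKT verification, cross-validated
# lambda selection, prediction and odds ratios.

#' Standardize a design matrix
#'
#' Centers every column to mean 0 and scales to population standard deviation
#' 1 (divisor n, so the L1 penalty acts scale-equivariantly). Zero-variance
#' columns are dropped with a warning and recorded. The stored (mean, sd)
#' allow exact back-transformation of fitted coefficients.
#'
#' @param X numeric matrix (>= 2 rows).
#' @return list with `X` (standardized), `center`, `scale` (named by the kept
#'   columns) and `dropped` (names of zero-variance columns).
#' @export
standardize_design <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples to standardize")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- sqrt(pmax(colMeans(X * X) - ctr^2, 0))
  zero <- scl <= sqrt(.Machine$double.eps) * (abs(ctr) + 1)
  dropped <- colnames(X)[zero]
  if (any(zero)) {
    warning("dropping zero-variance column(s): ", paste(dropped, collapse = ", "))
  }
  keep <- !zero
  p <- sum(keep)
  Xs <- (X[, keep, drop = FALSE] - matrix(ctr[keep], n, p, byrow = TRUE)) /
    matrix(scl[keep], n, p, byrow = TRUE)
  list(X = Xs, center = ctr[keep], scale = scl[keep], dropped = dropped)
}

#' Smallest penalty with an all-zero solution
#'
#' For standardized predictors and binary response, the LASSO logistic
#' solution is identically zero for all `lambda >= lambda_max`, where
#' `lambda_max = max_j |x_j' (y - ybar)| / n`.
#'
#' @param X standardized numeric matrix.
#' @param y binary 0/1 vector with both classes present.
#' @return `lambda_max` (a scalar).
#' @export
lambda_max <- function(X, y) {
  X <- as.matrix(X)
  y <- check_binary(y)
  max(abs(crossprod(X, y - mean(y)))) / nrow(X)
}

check_binary <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("y must be coded 0/1")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  y
}

# log-spaced decreasing lambda grid
lambda_grid <- function(lmax, n_lambda, lambda_min_ratio) {
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

fit_path_cpp <- function(Xs, y, lambdas, tol, max_iter, kkt_tol) {
  lasso_logistic_path_cpp(Xs, y, lambdas, tol, as.integer(max_iter), kkt_tol)
}

#' Fit an L1-penalized logistic regression at a single penalty
#'
#' Minimizes `-(1/n) loglik + lambda * ||beta||_1` (intercept unpenalized) by
#' IRLS with cyclic coordinate descent and soft-thresholding, warm-started
#' along a short path from `lambda_max` down to the target penalty.
#' Convergence is declared only when the Karush-Kuhn-Tucker stationarity
#' conditions hold at the true gradient (see [check_kkt()]).
#'
#' @param X numeric design matrix (samples x variables); standardized
#'   internally unless `standardize = FALSE` (in which case `X` is used
#'   as-is and coefficients are reported on that scale).
#' @param y binary 0/1 response (1 = case).
#' @param lambda penalty, `>= 0`.
#' @param standardize standardize columns before fitting (default TRUE).
#' @param tol convergence tolerance on coefficient change per sweep.
#' @param max_iter maximum coordinate-descent sweeps.
#' @param kkt_tol tolerance on the KKT residual at exit.
#' @param path_length number of warm-start path points from `lambda_max`
#'   down to `lambda`.
#' @param class_labels named character vector `c(case = ..., control = ...)`
#'   recording the class coding.
#' @return An object of class `lasso_model`: `lambda`, `intercept` and `beta`
#'   on the standardized scale, `intercept_orig`/`beta_orig` back-transformed
#'   to the original variable scale, `selected` (variables with nonzero
#'   coefficient), `odds_ratios` (exp of original-scale coefficients of the
#'   selected variables, per 1 unit of the original variable),
#'   `standardization` (center/scale/dropped) and convergence diagnostics.
#' @export
fit_lasso_lr <- function(X, y, lambda, standardize = TRUE, tol = 1e-7,
                         max_iter = 1e5, kkt_tol = 1e-6, path_length = 10L,
                         class_labels = c(case = "1", control = "0")) {
  if (lambda < 0) stop("lambda must be >= 0")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- check_binary(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (standardize) {
    std <- standardize_design(X)
  } else {
    std <- list(X = X, center = setNames(rep(0, ncol(X)), colnames(X)),
                scale = setNames(rep(1, ncol(X)), colnames(X)),
                dropped = character(0))
  }
  Xs <- std$X
  lmax <- lambda_max(Xs, y)
  lambdas <- if (lambda >= lmax || lambda == 0 && lmax == 0) {
    lambda
  } else if (lambda == 0) {
    # approach the unpenalized problem through a short path, then lambda = 0
    c(lambda_grid(lmax, path_length - 1L, 1e-3), 0)
  } else {
    gr <- exp(seq(log(lmax), log(lambda), length.out = path_length))
    gr[path_length] <- lambda # guard fp drift at the target
    gr
  }
  fit <- fit_path_cpp(Xs, y, lambdas, tol, max_iter, kkt_tol)
  last <- length(lambdas)
  if (!fit$converged[last]) {
    stop("coordinate descent did not reach KKT stationarity within ",
         max_iter, " sweeps (", fit$iters[last], " used, lambda = ", lambda, ")")
  }
  beta <- setNames(fit$beta[, last], colnames(Xs))
  a0 <- fit$a0[last]
  beta_orig <- beta / std$scale
  a0_orig <- a0 - sum(beta * std$center / std$scale)
  selected <- names(beta)[beta != 0]
  structure(
    list(lambda = lambda, intercept = a0, beta = beta,
         intercept_orig = a0_orig, beta_orig = beta_orig,
         selected = selected,
         odds_ratios = exp(beta_orig[selected]),
         standardization = std[c("center", "scale", "dropped")],
         variables = colnames(Xs), class_labels = class_labels,
         iters = fit$iters[last], converged = TRUE),
    class = "lasso_model"
  )
}

#' @export
print.lasso_model <- function(x, ...) {
  cat("<lasso_model> lambda = ", format(x$lambda, digits = 4), "; ",
      length(x$selected), "/", length(x$beta), " variables selected\n", sep = "")
  if (length(x$selected)) {
    cat("  ", paste0(x$selected, " (OR ",
                     format(x$odds_ratios, digits = 3), ")",
                     collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Verify KKT stationarity of a fitted model
#'
#' For the objective `-(1/n) loglik + lambda * ||beta||_1`, stationarity
#' requires `|grad_j| <= lambda` wherever `beta_j = 0` and
#' `grad_j + lambda * sign(beta_j) = 0` elsewhere (and zero intercept
#' gradient). Returns the maximum violation.
#'
#' @param model a [fit_lasso_lr()] model.
#' @param X,y the data the model was fitted on (original scale).
#' @return the maximum KKT residual (a scalar).
#' @export
check_kkt <- function(model, X, y) {
  stopifnot(inherits(model, "lasso_model"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- check_binary(y)
  Xs <- sweep(sweep(X[, model$variables, drop = FALSE], 2L,
                    model$standardization$center, "-"),
              2L, model$standardization$scale, "/")
  eta <- drop(model$intercept + Xs %*% model$beta)
  res <- stats::plogis(eta) - y
  g <- drop(crossprod(Xs, res)) / nrow(Xs)
  g0 <- mean(res)
  viol <- ifelse(model$beta == 0,
                 pmax(abs(g) - model$lambda, 0),
                 abs(g + model$lambda * sign(model$beta)))
  max(abs(g0), viol)
}

#' Predicted case probabilities from a fitted model
#'
#' `p = 1 / (1 + exp(-(intercept + X beta)))`, applying the model's stored
#' standardization (equivalently, the back-transformed original-scale
#' coefficients).
#'
#' @param model a [fit_lasso_lr()] model.
#' @param X_new numeric matrix on the original variable scale, with columns
#'   covering the model's variables (matched by name when named).
#' @return vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, X_new) {
  stopifnot(inherits(model, "lasso_model"))
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new))) {
    missing <- setdiff(model$variables, colnames(X_new))
    if (length(missing)) {
      stop("X_new lacks model variable(s): ", paste(missing, collapse = ", "))
    }
    X_new <- X_new[, model$variables, drop = FALSE]
  } else if (ncol(X_new) != length(model$variables)) {
    stop("X_new has ", ncol(X_new), " columns; model uses ",
         length(model$variables))
  }
  drop(stats::plogis(model$intercept_orig + X_new %*% model$beta_orig))
}

#' Odds ratios of the selected variables
#'
#' `exp(beta_j)` on the original variable scale, per 1 unit of the original
#' variable, for every variable with a nonzero coefficient.
#'
#' @param model a [fit_lasso_lr()] model.
#' @return named numeric vector.
#' @export
odds_ratios <- function(model) {
  stopifnot(inherits(model, "lasso_model"))
  model$odds_ratios
}

#' Stratified k-fold assignment
#'
#' Shuffles indices within each class and deals them cyclically over folds, so
#' fold sizes differ by at most one per class and every fold contains both
#' classes whenever the minority class has at least `k` members (otherwise an
#' error: a valid stratification is impossible).
#'
#' @param y binary 0/1 vector.
#' @param k number of folds.
#' @return integer vector of fold labels in 1..k.
#' @export
stratified_folds <- function(y, k) {
  y <- check_binary(y)
  if (k < 2L) stop("k must be >= 2")
  if (min(table(y)) < k) {
    stop("minority class has fewer than k = ", k,
         " members; stratified folds infeasible")
  }
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select the LASSO penalty by stratified k-fold cross-validation
#'
#' Builds a log-spaced grid from `lambda_max` (computed on the full
#' standardized data) down to `lambda_max * lambda_min_ratio`, fits the warm-
#' started path on each training fold, and scores held-out samples per
#' penalty. The chosen penalty minimizes the cross-validated binomial
#' deviance (default) or maximizes the cross-validated AUC; ties go to the
#' largest penalty.
#'
#' @param X numeric design matrix (original scale; each fold standardizes its
#'   own training portion).
#' @param y binary 0/1 response.
#' @param k number of folds (default 5).
#' @param n_lambda grid length.
#' @param lambda_min_ratio grid floor relative to `lambda_max`.
#' @param seed integer seed; folds and hence the choice are deterministic
#'   given it.
#' @param metric `"deviance"` (default) or `"auc"`.
#' @param tol,max_iter,kkt_tol passed to the coordinate-descent fitter.
#' @return An object of class `cv_lambda_result`: `lambda_grid`, `cvm`
#'   (per-penalty cross-validated metric), `chosen_lambda`, `folds`, `seed`,
#'   `metric`.
#' @export
cv_select_lambda <- function(X, y, k = 5L, n_lambda = 20L,
                             lambda_min_ratio = 1e-3, seed = NULL,
                             metric = c("deviance", "auc"),
                             tol = 1e-7, max_iter = 1e5, kkt_tol = 1e-4) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- check_binary(y)
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(y, k)
  std_full <- standardize_design(X)
  grid <- lambda_grid(lambda_max(std_full$X, y), n_lambda, lambda_min_ratio)

  metric_mat <- matrix(NA_real_, k, length(grid))
  wts <- numeric(k)
  for (i in seq_len(k)) {
    tr <- fold != i
    std <- standardize_design(X[tr, , drop = FALSE])
    fit <- fit_path_cpp(std$X, y[tr], grid, tol, max_iter, kkt_tol)
    nte <- sum(!tr)
    pk <- ncol(std$X)
    Xte <- (X[!tr, colnames(std$X), drop = FALSE] -
              matrix(std$center, nte, pk, byrow = TRUE)) /
      matrix(std$scale, nte, pk, byrow = TRUE)
    P <- stats::plogis(Xte %*% fit$beta +
                         matrix(fit$a0, nte, length(fit$a0), byrow = TRUE))
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    yte <- y[!tr]
    metric_mat[i, ] <- if (metric == "deviance") {
      -2 * colMeans(yte * log(P) + (1 - yte) * log(1 - P))
    } else {
      apply(P, 2L, function(p) auc(p, yte))
    }
    wts[i] <- sum(!tr)
  }
  cvm <- colSums(metric_mat * wts) / sum(wts)
  best <- if (metric == "deviance") which.min(cvm) else which.max(cvm)
  structure(
    list(lambda_grid = grid, cvm = cvm, chosen_lambda = grid[best],
         folds = split(seq_along(y), fold), seed = seed, metric = metric),
    class = "cv_lambda_result"
  )
}

#' @export
print.cv_lambda_result <- function(x, ...) {
  cat("<cv_lambda_result> chosen lambda = ",
      format(x$chosen_lambda, digits = 4), " (", x$metric, " over ",
      length(x$lambda_grid), "-point grid, ", length(x$folds), " folds)\n",
      sep = "")
  invisible(x)
}
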
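# ANOVA-simultaneous component analysis: partition a column-centered matrix
# into design-factor effect matrices plus residual, score each effect by SCA
# (SVD), permutation-test factor importance, and residualize new samples.

#' Column-center a matrix
#'
#' @param X numeric matrix with at least 2 rows.
#' @return list with `centered` (each column mean 0) and `grand_mean`
#'   (vector of column means).
#' @export
center_columns <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to center")
  gm <- colMeans(X)
  list(centered = sweep(X, 2L, gm, "-"), grand_mean = gm)
}

coerce_factor_labels <- function(factor_labels, n) {
  if (is.data.frame(factor_labels)) factor_labels <- as.list(factor_labels)
  if (!is.list(factor_labels) || is.null(names(factor_labels)) ||
      any(names(factor_labels) == "")) {
    stop("factor_labels must be a named list (or data.frame) of per-sample levels")
  }
  factor_labels <- lapply(factor_labels, as.character)
  len <- vapply(factor_labels, length, integer(1))
  if (any(len != n)) stop("every factor must provide one level per sample")
  if (any(vapply(factor_labels, anyNA, logical(1)))) {
    stop("factor levels must not be missing")
  }
  factor_labels
}

# level means of M given labels, rows = levels (named)
level_mean_matrix <- function(M, lab) {
  sums <- rowsum(M, lab)
  counts <- as.vector(table(lab)[rownames(sums)])
  sweep(sums, 1L, counts, "/")
}

#' ASCA decomposition of a feature matrix
#'
#' Sequential main-effects partition of the column-centered matrix: for each
#' factor, in the stated order, the effect matrix holds the level means of the
#' current remainder and is subtracted from it; the final remainder is the
#' residual matrix E. The reconstruction identity
#' `centered X = sum(effects) + E` holds exactly (to numerical tolerance)
#' whether or not the design is balanced; under a balanced design the
#' partition is order-invariant and the sums of squares are additive.
#'
#' @param X numeric matrix (samples x features).
#' @param factor_labels named list / data.frame of per-sample categorical
#'   levels, e.g. `list(season = ..., zone = ...)`.
#' @param order character vector of factor names giving the partition order;
#'   defaults to the order of `factor_labels`.
#' @return An object of class `asca_decomposition`: `grand_mean`, `factors`,
#'   `level_means` (per factor, a levels x features matrix), `effect_matrices`,
#'   `residual_E`, `ssq` (named sums of squares: one per factor, `residual`,
#'   and `centered_total`), and the training `factor_labels`.
#' @export
asca_decompose <- function(X, factor_labels, order = names(factor_labels)) {
  X <- as.matrix(X)
  cc <- center_columns(X)
  factor_labels <- coerce_factor_labels(factor_labels, nrow(X))
  missing <- setdiff(order, names(factor_labels))
  if (length(missing)) stop("factor(s) not provided: ", paste(missing, collapse = ", "))
  R <- cc$centered
  effects <- list()
  level_means <- list()
  for (f in order) {
    lab <- factor_labels[[f]]
    if (length(unique(lab)) < 2L) {
      warning("factor '", f, "' is constant across samples; zero effect matrix")
      lm_mat <- matrix(0, 1L, ncol(R), dimnames = list(unique(lab), colnames(R)))
      eff <- matrix(0, nrow(R), ncol(R), dimnames = dimnames(R))
    } else {
      lm_mat <- level_mean_matrix(R, lab)
      eff <- lm_mat[lab, , drop = FALSE]
      rownames(eff) <- rownames(R)
    }
    effects[[f]] <- eff
    level_means[[f]] <- lm_mat
    R <- R - eff
  }
  ssq <- c(
    vapply(effects, function(m) sum(m^2), numeric(1)),
    residual = sum(R^2),
    centered_total = sum(cc$centered^2)
  )
  structure(
    list(grand_mean = cc$grand_mean, factors = order,
         level_means = level_means, effect_matrices = effects,
         residual_E = R, ssq = ssq, factor_labels = factor_labels[order],
         feature_ids = colnames(X)),
    class = "asca_decomposition"
  )
}

#' @export
print.asca_decomposition <- function(x, ...) {
  cat("<asca_decomposition> factors: ", paste(x$factors, collapse = " -> "),
      "\n", sep = "")
  tot <- x$ssq[["centered_total"]]
  for (nm in names(x$ssq)) {
    cat(sprintf("  ssq %-14s %.6g (%.1f%%)\n", nm, x$ssq[[nm]],
                100 * x$ssq[[nm]] / tot))
  }
  invisible(x)
}

#' Simultaneous component analysis of an effect (or residual) matrix
#'
#' Rank-`ncomp` singular value decomposition: scores are the left singular
#' vectors scaled by singular values; loadings are orthonormal; explained
#' variance fractions are squared singular values over the matrix total sum
#' of squares.
#'
#' @param M numeric matrix (an ASCA effect matrix, residual E, or any
#'   centered matrix).
#' @param ncomp number of components, `1 <= ncomp <= min(dim(M))`.
#' @return An object of class `sca_result`: `scores` (samples x ncomp),
#'   `loadings` (features x ncomp, orthonormal columns),
#'   `explained_variance_fraction`.
#' @export
sca_effect <- function(M, ncomp) {
  M <- as.matrix(M)
  if (ncomp <= 0) stop("ncomp must be positive")
  if (ncomp > min(dim(M))) stop("ncomp exceeds min(dim(M))")
  total <- sum(M^2)
  if (total == 0) {
    warning("zero matrix: scores and explained fractions set to 0")
    return(structure(
      list(scores = matrix(0, nrow(M), ncomp),
           loadings = matrix(0, ncol(M), ncomp),
           explained_variance_fraction = rep(0, ncomp)),
      class = "sca_result"
    ))
  }
  sv <- svd(M, nu = ncomp, nv = ncomp)
  d <- sv$d[seq_len(ncomp)]
  structure(
    list(scores = sv$u %*% diag(d, ncomp, ncomp),
         loadings = sv$v,
         explained_variance_fraction = d^2 / total),
    class = "sca_result"
  )
}

#' Exploratory PCA of a feature matrix
#'
#' Column-centers `X` and applies [sca_effect()]; used for the initial
#' exploratory look at hyper-filtered features (trend/cluster/outlier
#' detection) before any factor correction.
#'
#' @inheritParams sca_effect
#' @param X numeric matrix (samples x features).
#' @return an `sca_result`.
#' @export
pca_explore <- function(X, ncomp) {
  sca_effect(center_columns(X)$centered, ncomp)
}

#' Permutation test of an ASCA factor's sum of squares
#'
#' Permutes the per-sample levels of one factor (only), recomputes that
#' factor's effect sum of squares under the same sequential partition, and
#' returns an add-one permutation p-value
#' `(1 + #(null >= observed)) / (1 + B)`.
#'
#' @inheritParams asca_decompose
#' @param term factor name to test.
#' @param B number of permutations (>= 1).
#' @param seed integer seed for reproducibility.
#' @return An object of class `factor_permutation_result`: `term`,
#'   `observed_ssq`, `null_ssq` (length B), `p_value`.
#' @export
asca_permutation_factor_test <- function(X, factor_labels,
                                         order = names(factor_labels),
                                         term, B = 199L, seed = NULL) {
  if (B < 1L) stop("B must be >= 1")
  if (!term %in% order) stop("term '", term, "' is not among the factors")
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  factor_labels <- coerce_factor_labels(factor_labels, nrow(X))
  observed <- asca_decompose(X, factor_labels, order)$ssq[[term]]
  null_ssq <- vapply(seq_len(B), function(b) {
    fl <- factor_labels
    fl[[term]] <- sample(fl[[term]])
    asca_decompose(X, fl, order)$ssq[[term]]
  }, numeric(1))
  structure(
    list(term = term, observed_ssq = observed, null_ssq = null_ssq, B = B,
         p_value = (1 + sum(null_ssq >= observed)) / (1 + B)),
    class = "factor_permutation_result"
  )
}

#' Remove fitted factor effects from (new) samples
#'
#' Subtracts the training grand mean and, per factor, the stored level mean
#' for each sample's level. A level unseen during fitting contributes zero
#' for that factor (grand-mean-only fallback, with a warning). Applying this
#' to the training data with the training labels reproduces the residual
#' matrix E exactly.
#'
#' @param decomp an [asca_decompose()] fit.
#' @param X_new numeric matrix whose columns match the fitted features.
#' @param labels_new named list / data.frame of per-sample levels for the
#'   fitted factors.
#' @return the corrected matrix (same shape as `X_new`).
#' @export
residualize <- function(decomp, X_new, labels_new) {
  stopifnot(inherits(decomp, "asca_decomposition"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(decomp$grand_mean)) {
    stop("X_new has ", ncol(X_new), " columns; fit used ", length(decomp$grand_mean))
  }
  if (!is.null(colnames(X_new)) && !is.null(decomp$feature_ids) &&
      !identical(colnames(X_new), decomp$feature_ids)) {
    stop("X_new column names do not match the fitted features")
  }
  labels_new <- coerce_factor_labels(labels_new, nrow(X_new))
  out <- sweep(X_new, 2L, decomp$grand_mean, "-")
  for (f in decomp$factors) {
    lm_mat <- decomp$level_means[[f]]
    lv <- labels_new[[f]]
    known <- lv %in% rownames(lm_mat)
    if (any(!known)) {
      warning("factor '", f, "': unseen level(s) ",
              paste(unique(lv[!known]), collapse = ", "),
              "; grand-mean-only fallback for those samples")
    }
    if (any(known)) {
      out[known, ] <- out[known, , drop = FALSE] - lm_mat[lv[known], , drop = FALSE]
    }
  }
  out
}
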
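test_that("column centering zeroes every column mean", {
  cc <- center_columns(matrix(c(1, 3), 2, 1))
  expect_equal(cc$centered[, 1], c(-1, 1))
  expect_equal(cc$grand_mean, 2)

  X <- matrix(rnorm(100), 20, 5)
  Xc <- center_columns(X)$centered
  expect_true(all(abs(colMeans(Xc)) < 1e-12))
  expect_equal(center_columns(Xc)$centered, Xc)
  expect_error(center_columns(matrix(1, 1, 3)), "at least 2 rows")
})

test_that("one-factor decomposition reproduces the hand-computed example", {
  X <- matrix(c(1, 3, 5, 7), 4, 1)
  d <- asca_decompose(X, list(f = c("A", "A", "B", "B")))
  expect_equal(d$grand_mean, 4)
  expect_equal(unname(d$effect_matrices$f[, 1]), c(-2, -2, 2, 2))
  expect_equal(unname(d$residual_E[, 1]), c(-1, 1, -1, 1))
  expect_equal(unname(d$level_means$f[, 1]), c(A = -2, B = 2), ignore_attr = TRUE)
})

test_that("reconstruction identity holds on random decompositions", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    p <- sample(2:12, 1)
    X <- matrix(rnorm(n * p, sd = runif(1, 0.5, 5)), n, p)
    fl <- list(season = sample(c("w", "s", "u", "a"), n, replace = TRUE),
               zone = sample(c("Z1", "Z2", "Z3"), n, replace = TRUE))
    d <- asca_decompose(X, fl)
    recon <- Reduce(`+`, d$effect_matrices) + d$residual_E
    Xc <- sweep(X, 2, d$grand_mean)
    expect_lt(max(abs(recon - Xc)), 1e-10 * max(1, max(abs(Xc))))
    # each effect matrix is constant within level
    for (f in names(fl)) {
      for (lv in unique(fl[[f]])) {
        rows <- d$effect_matrices[[f]][fl[[f]] == lv, , drop = FALSE]
        expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
      }
    }
  }
})

test_that("balanced two-factor designs are order-invariant with additive sums of squares", {
  set.seed(22)
  lev <- expand.grid(season = c("w", "s", "u", "a"), zone = c("Z1", "Z2"))
  idx <- rep(seq_len(nrow(lev)), each = 3) # balanced: 3 replicates per cell
  fl <- list(season = as.character(lev$season[idx]),
             zone = as.character(lev$zone[idx]))
  X <- matrix(rnorm(length(idx) * 6), length(idx), 6)
  d1 <- asca_decompose(X, fl, order = c("season", "zone"))
  d2 <- asca_decompose(X, fl, order = c("zone", "season"))
  expect_lt(max(abs(d1$effect_matrices$season - d2$effect_matrices$season)), 1e-10)
  expect_lt(max(abs(d1$effect_matrices$zone - d2$effect_matrices$zone)), 1e-10)
  # Pythagorean identity under balance
  tot <- d1$ssq[["centered_total"]]
  expect_equal(d1$ssq[["season"]] + d1$ssq[["zone"]] + d1$ssq[["residual"]],
               tot, tolerance = 1e-10)
  expect_true(all(d1$ssq >= 0))
  # balanced effect matrices have zero column means
  expect_lt(max(abs(colMeans(d1$effect_matrices$season))), 1e-12)
})

test_that("degenerate factors produce zero effects with a warning", {
  X <- matrix(rnorm(20), 10, 2)
  expect_warning(d <- asca_decompose(X, list(f = rep("only", 10))), "constant")
  expect_true(all(d$effect_matrices$f == 0))
  expect_equal(d$residual_E, center_columns(X)$centered)
})

test_that("SCA yields orthonormal loadings and the best low-rank reconstruction", {
  set.seed(23)
  # rank-1 matrix: one component explains everything
  M1 <- outer(rnorm(8), rnorm(5))
  s1 <- sca_effect(M1, 1)
  expect_equal(s1$explained_variance_fraction[1], 1, tolerance = 1e-10)

  M <- matrix(rnorm(60), 10, 6)
  s <- sca_effect(M, 2)
  expect_equal(crossprod(s$loadings), diag(2), tolerance = 1e-10)
  expect_true(all(diff(s$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(s$explained_variance_fraction), 1 + 1e-12)
  # Eckart-Young: reconstruction error equals the tail singular values
  recon_err <- sum((M - s$scores %*% t(s$loadings))^2)
  d_full <- svd(M)$d
  expect_equal(recon_err, sum(d_full[3:length(d_full)]^2), tolerance = 1e-8)

  expect_warning(z <- sca_effect(matrix(0, 4, 3), 2), "zero matrix")
  expect_true(all(z$scores == 0))
  expect_error(sca_effect(M, 0), "positive")
  expect_error(sca_effect(M, 99), "exceeds")
})

test_that("exploratory PCA equals SCA of the centered matrix", {
  set.seed(24)
  X <- matrix(rnorm(80), 16, 5)
  a <- pca_explore(X, 3)
  b <- sca_effect(center_columns(X)$centered, 3)
  expect_equal(a$scores, b$scores)
  expect_equal(a$explained_variance_fraction, b$explained_variance_fraction)
})

test_that("factor permutation test is deterministic and flags planted effects", {
  set.seed(25)
  n <- 24
  fl <- list(f = rep(c("A", "B"), each = n / 2))
  X0 <- matrix(rnorm(n * 4), n, 4)
  r1 <- asca_permutation_factor_test(X0, fl, term = "f", B = 99, seed = 7)
  r2 <- asca_permutation_factor_test(X0, fl, term = "f", B = 99, seed = 7)
  expect_identical(r1$null_ssq, r2$null_ssq)
  expect_equal(r1$p_value, (1 + sum(r1$null_ssq >= r1$observed_ssq)) / 100)

  # huge planted shift: observed exceeds every permuted ssq
  X1 <- X0
  X1[fl$f == "B", ] <- X1[fl$f == "B", ] + 10
  r3 <- asca_permutation_factor_test(X1, fl, term = "f", B = 199, seed = 8)
  expect_equal(r3$p_value, 1 / 200)
})

test_that("residualization reproduces E on training data and falls back on unseen levels", {
  set.seed(26)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("F", 1:3)))
  fl <- list(season = sample(c("w", "s"), n, replace = TRUE),
             zone = sample(c("Z1", "Z2"), n, replace = TRUE))
  d <- asca_decompose(X, fl)
  expect_equal(residualize(d, X, fl), d$residual_E)

  # unseen zone level: only grand mean and season effect are subtracted
  Xn <- matrix(rnorm(3), 1, 3, dimnames = list(NULL, paste0("F", 1:3)))
  ln <- list(season = "w", zone = "Z9")
  expect_warning(out <- residualize(d, Xn, ln), "unseen level")
  manual <- Xn - d$grand_mean - d$level_means$season["w", ]
  expect_equal(out, manual, ignore_attr = TRUE)

  expect_error(residualize(d, Xn[, 1:2, drop = FALSE],
                           list(season = "w", zone = "Z1")), "columns")
})
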
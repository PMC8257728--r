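test_that("standardization centers, scales, back-transforms and drops constants", {
  X <- matrix(c(0, 2, 5, 5), 2, 2, dimnames = list(NULL, c("a", "const")))
  expect_warning(std <- standardize_design(X), "zero-variance.*const")
  expect_equal(std$X[, "a"], c(-1, 1), ignore_attr = TRUE)
  expect_equal(unname(std$center["a"]), 1)
  expect_equal(unname(std$scale["a"]), 1)
  expect_equal(std$dropped, "const")

  # back-transformed coefficients give identical predictions
  set.seed(31)
  n <- 80
  X2 <- matrix(rnorm(3 * n, mean = 5, sd = c(1, 9, 0.2)), n, 3)
  y <- rbinom(n, 1, plogis(0.8 * scale(X2[, 1])))
  f <- fit_lasso_lr(X2, y, 0.02)
  Xs <- sweep(sweep(X2, 2, f$standardization$center), 2,
              f$standardization$scale, "/")
  p_std <- plogis(f$intercept + Xs %*% f$beta)
  p_orig <- predict_prob(f, X2)
  expect_lt(max(abs(p_std - p_orig)), 1e-10)
})

test_that("lambda_max bounds selection and matches direct arithmetic", {
  set.seed(32)
  n <- 60
  x1 <- scale(rnorm(n)) * sqrt(n / (n - 1)) # population-sd standardized
  y <- rbinom(n, 1, 0.4)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  lm1 <- lambda_max(matrix(x1), y)
  expect_equal(lm1, abs(sum(x1 * (y - mean(y)))) / n)

  X <- matrix(rnorm(n * 6), n, 6)
  std <- standardize_design(X)
  lmx <- lambda_max(std$X, y)
  f <- fit_lasso_lr(X, y, 1.01 * lmx)
  expect_length(f$selected, 0L)
  expect_equal(f$intercept, qlogis(mean(y)), tolerance = 1e-8)
  expect_error(lambda_max(X, rep(1, n)), "both classes")
})

test_that("the unpenalized solution matches the generic-optimizer logistic fit", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 50
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rbinom(n, 1, plogis(0.5 * X[, 1] - X[, 2]))
    if (length(unique(y)) < 2) next
    f <- fit_lasso_lr(X, y, 0)
    g <- suppressWarnings(glm(y ~ X, family = binomial))
    expect_lt(max(abs(c(f$intercept_orig, f$beta_orig) - coef(g))), 1e-4)
  }
})

test_that("converged fits satisfy KKT stationarity and agree with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(34)
  for (rep in 1:6) {
    n <- 70
    p <- sample(4:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    beta_true <- c(1.2, -0.8, rep(0, p - 2))
    y <- rbinom(n, 1, plogis(X %*% beta_true))
    if (min(table(y)) < 3) next
    lam <- runif(1, 0.01, 0.2)
    f <- fit_lasso_lr(X, y, lam)
    expect_lt(check_kkt(f, X, y), 1e-5)
    std <- standardize_design(X)
    g <- glmnet::glmnet(std$X, y, family = "binomial", lambda = lam,
                        standardize = FALSE, thresh = 1e-12)
    expect_lt(max(abs(f$beta - as.numeric(coef(g))[-1])), 1e-4)
    expect_lt(abs(f$intercept - as.numeric(coef(g))[1]), 1e-4)
  }
})

test_that("warm-started path solutions equal cold single-lambda fits", {
  set.seed(35)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8)
  y <- rbinom(n, 1, plogis(X[, 1]))
  std <- standardize_design(X)
  lmx <- lambda_max(std$X, y)
  grid <- exp(seq(log(lmx), log(lmx * 1e-2), length.out = 8))
  path <- breathdiscrim:::fit_path_cpp(std$X, y, grid, 1e-7, 1e5, 1e-8)
  for (l in c(3, 6, 8)) {
    cold <- breathdiscrim:::fit_path_cpp(std$X, y, grid[l], 1e-7, 1e5, 1e-8)
    expect_lt(max(abs(path$beta[, l] - cold$beta[, 1])), 1e-6)
  }
})

test_that("predictions follow the logistic closed form and stay in (0,1)", {
  set.seed(36)
  n <- 40
  X <- matrix(rnorm(n), n, 1)
  y <- rbinom(n, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  f <- fit_lasso_lr(X, y, 10) # null model
  # hand-build a model with known coefficients through the same structure
  f$beta_orig[] <- 1
  f$intercept_orig <- 0
  expect_equal(predict_prob(f, matrix(0)), 0.5)
  expect_equal(predict_prob(f, matrix(log(3))), 0.75)
  probs <- predict_prob(f, matrix(rnorm(100, sd = 10), 100, 1))
  expect_true(all(probs > 0 & probs < 1))
  expect_error(predict_prob(f, matrix(1, 2, 3)), "columns")
})

test_that("odds ratios are exp of original-scale coefficients of selected variables", {
  set.seed(37)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + log(2) * x))
  f0 <- fit_lasso_lr(matrix(x, dimnames = list(NULL, "expo")), y, 0,
                     kkt_tol = 1e-9)
  or <- odds_ratios(f0)
  expect_named(or, "expo")
  expect_equal(unname(or), exp(unname(f0$beta_orig)))
  # equivariance: OR from the standardized fit equals OR from a raw-scale fit
  f_raw <- fit_lasso_lr(matrix(x, dimnames = list(NULL, "expo")), y, 0,
                        standardize = FALSE, kkt_tol = 1e-9)
  expect_equal(unname(or), unname(odds_ratios(f_raw)), tolerance = 1e-6)
})

test_that("predictions are invariant to affine rescaling of the inputs", {
  set.seed(38)
  n <- 90
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(X[, 1] - X[, 3]))
  Xr <- sweep(sweep(X, 2, c(2, 0.1, 5, 1), "*"), 2, c(-3, 7, 0, 100), "+")
  f1 <- fit_lasso_lr(X, y, 0.05)
  f2 <- fit_lasso_lr(Xr, y, 0.05)
  expect_lt(max(abs(predict_prob(f1, X) - predict_prob(f2, Xr))), 1e-6)
})

test_that("cross-validated penalty selection is seeded, stratified and sane", {
  set.seed(39)
  n <- 100
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rbinom(n, 1, plogis(1.5 * X[, 1]))
  r1 <- cv_select_lambda(X, y, seed = 5)
  r2 <- cv_select_lambda(X, y, seed = 5)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$chosen_lambda, r2$chosen_lambda)
  expect_true(r1$chosen_lambda %in% r1$lambda_grid)
  expect_true(all(diff(r1$lambda_grid) < 0))
  # folds partition the samples with both classes in each
  idx <- unname(sort(unlist(r1$folds)))
  expect_equal(idx, seq_len(n))
  for (f in r1$folds) expect_gt(length(unique(y[f])), 1L)
  expect_error(stratified_folds(c(1, 1, 0, 0), 5), "infeasible")
})
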
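# Subject-characteristics statistics: percentages from subgroup counts,
# normality-gated continuous comparisons, and categorical association tests.

#' Integer percentage of a subgroup count
#'
#' `round(100 * count / n)` with half-up rounding — the convention of the
#' characteristics tables (e.g. 72 of 186 prints as 39%, 14 of 186 as 8%).
#'
#' @param count non-negative integer, `<= n`.
#' @param n positive subgroup size.
#' @return integer percent.
#' @export
subgroup_percentage <- function(count, n) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(count < 0 | count > n)) stop("count must lie in [0, n]")
  round_half_up(100 * count / n)
}

#' Normality test p-value
#'
#' Shapiro-Wilk or Lilliefors (Kolmogorov-Smirnov with estimated
#' parameters) test of a numeric sample.
#'
#' @param x numeric vector, `n >= 4` (Shapiro-Wilk also requires
#'   `n <= 5000`); a constant vector is degenerate and rejected.
#' @param method `"shapiro_wilk"` or `"lilliefors"`.
#' @return the test p-value.
#' @export
normality_test <- function(x, method = c("shapiro_wilk", "lilliefors")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (anyNA(x)) stop("x must not contain missing values")
  if (length(x) < 4L) stop("need n >= 4 for a normality test")
  if (length(unique(x)) == 1L) stop("constant vector: normality test undefined")
  if (method == "shapiro_wilk") {
    stats::shapiro.test(x)$p.value
  } else {
    nortest::lillie.test(x)$p.value
  }
}

# can every group be normality-tested and does every group pass both tests?
normality_gate <- function(groups, alpha_gate) {
  gate <- lapply(groups, function(g) {
    if (length(g) < 4L || length(unique(g)) == 1L) {
      return(list(testable = FALSE, shapiro = NA_real_, lilliefors = NA_real_))
    }
    list(testable = TRUE,
         shapiro = normality_test(g, "shapiro_wilk"),
         lilliefors = normality_test(g, "lilliefors"))
  })
  pass <- all(vapply(gate, function(r) {
    r$testable && r$shapiro > alpha_gate && r$lilliefors > alpha_gate
  }, logical(1)))
  list(record = gate, parametric = pass)
}

#' Compare a continuous variable across groups with a normality gate
#'
#' Every group is screened by both the Shapiro-Wilk and Lilliefors tests;
#' only when all groups pass both at `alpha_gate` is the parametric branch
#' used (Welch t-test for 2 groups, one-way ANOVA for more), otherwise the
#' nonparametric branch (Mann-Whitney U for 2 groups, Kruskal-Wallis for
#' more). Groups too small for the normality tests (n < 4) cannot pass the
#' gate and default to the nonparametric branch.
#'
#' @param groups list of >= 2 numeric vectors (each n >= 3, non-empty).
#' @param alpha_gate gate level for the normality tests.
#' @return An object of class `group_test_result`: `test_used` (one of t,
#'   anova, mann_whitney, kruskal_wallis), `p_value`, and `gate` (the
#'   per-group normality decisions).
#' @export
compare_continuous <- function(groups, alpha_gate = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) stop("need a list of >= 2 groups")
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  if (any(vapply(groups, length, integer(1)) < 3L)) {
    stop("each group needs n >= 3")
  }
  gate <- normality_gate(groups, alpha_gate)
  two <- length(groups) == 2L
  if (gate$parametric) {
    if (two) {
      test_used <- "t"
      p <- stats::t.test(groups[[1L]], groups[[2L]])$p.value
    } else {
      test_used <- "anova"
      val <- unlist(groups)
      grp <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
      p <- summary(stats::aov(val ~ grp))[[1L]][["Pr(>F)"]][1L]
    }
  } else {
    if (two) {
      test_used <- "mann_whitney"
      p <- stats::wilcox.test(groups[[1L]], groups[[2L]])$p.value
    } else {
      test_used <- "kruskal_wallis"
      p <- stats::kruskal.test(groups)$p.value
    }
  }
  structure(
    list(test_used = test_used, p_value = p, gate = gate$record),
    class = "group_test_result"
  )
}

#' Test association in a contingency table
#'
#' For a 2x2 table with any expected cell below 5, Fisher's exact test
#' (two-sided by the point-probability rule: the p-value sums the
#' probabilities of all tables, under the hypergeometric null with the
#' observed margins, no more probable than the observed one). Otherwise the
#' chi-square test, with Yates continuity correction for 2x2 tables; larger
#' tables with small expected counts fall back to uncorrected chi-square
#' with a warning.
#'
#' @param table non-negative integer matrix (2x2 or r x c) with positive
#'   margins.
#' @return An object of class `group_test_result`: `test_used`
#'   (`"fisher"` or `"chi_square"`), `p_value`, `gate` (the expected-count
#'   decision record).
#' @export
contingency_test <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  small <- any(expected < 5)
  is2x2 <- all(dim(tab) == c(2L, 2L))
  if (small && is2x2) {
    test_used <- "fisher"
    p <- stats::fisher.test(tab)$p.value
  } else {
    if (small) warning("expected count < 5 in an r x c table; chi-square approximation may be poor")
    test_used <- "chi_square"
    p <- suppressWarnings(stats::chisq.test(tab, correct = is2x2)$p.value)
  }
  structure(
    list(test_used = test_used, p_value = p,
         gate = list(min_expected = min(expected), is_2x2 = is2x2)),
    class = "group_test_result"
  )
}

#' @export
print.group_test_result <- function(x, ...) {
  cat("<group_test_result> ", x$test_used, ", p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
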
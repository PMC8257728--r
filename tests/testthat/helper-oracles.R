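# Independent oracles and small fixture builders shared across tests.

# brute-force signed-rank p by enumerating all 2^n sign assignments of the
# observed mid-ranks (feasible for n <= ~12)
oracle_signrank_p <- function(x, y, alternative) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Wb <- as.vector(signs %*% r)
  p_ge <- mean(Wb >= W - 1e-9)
  p_le <- mean(Wb <= W + 1e-9)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# two-sided Fisher p for a 2x2 table by direct hypergeometric enumeration
# (point-probability rule)
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force tie-corrected concordance
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# tiny cohort for structural tests
tiny_cohort <- function(seed = 42L, effect_log2 = 2, n_case = 12L,
                        n_control = 36L, n_features = 15L) {
  generate_cohort(generator_config(
    n_case = n_case, n_control = n_control, n_features = n_features,
    n_discriminant = 3L, effect_log2 = effect_log2, n_contaminants = 2L,
    n_ambient_dominant = 2L, validation_fraction = 0.3, seed = seed
  ))
}

# write a small feature-table CSV and return its path
write_ft_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# training design matrix and labels from a cohort (VOC block only, raw)
cohort_train_design <- function(cohort) {
  sa <- cohort$truth$sample_assignments
  tr <- sa$split == "train"
  list(X = cohort$table$intensities[sa$sample_id[tr], , drop = FALSE],
       y = as.integer(sa$class[tr] == "case"))
}
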
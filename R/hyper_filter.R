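# "Hyper-filtering": drop named contaminant features, then drop features whose
# intensity is significantly higher in paired room-air samples than in breath.

#' Validate a data frame as feature metadata
#'
#' Feature metadata carries, per feature id: `retention_time` (seconds,
#' >= 0), `quant_mz` (quantifier m/z, > 0), optional `compound_name` /
#' `cas_number`, and `contaminant_class` — one of none, bag_artifact (gas
#' sampling bag artefacts such as N,N-dimethylacetamide and phenol), pump_oil,
#' siloxane (GC column bleed).
#'
#' @param df a data.frame with at least `feature_id` and `contaminant_class`.
#' @return `df` with class `feature_meta` prepended.
#' @export
as_feature_meta <- function(df) {
  df <- as.data.frame(df)
  if (!"feature_id" %in% colnames(df)) stop("feature metadata lacks 'feature_id'")
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature id: ", df$feature_id[duplicated(df$feature_id)][1L])
  }
  if (!"contaminant_class" %in% colnames(df)) df$contaminant_class <- "none"
  bad <- !df$contaminant_class %in% CONTAMINANT_CLASSES
  if (any(bad)) {
    stop("unknown contaminant_class '", df$contaminant_class[bad][1L],
         "' (expected one of: ", paste(CONTAMINANT_CLASSES, collapse = ", "), ")")
  }
  if ("retention_time" %in% colnames(df) && any(df$retention_time < 0, na.rm = TRUE)) {
    stop("retention_time must be >= 0")
  }
  if ("quant_mz" %in% colnames(df) && any(df$quant_mz <= 0, na.rm = TRUE)) {
    stop("quant_mz must be > 0")
  }
  if (!inherits(df, "feature_meta")) class(df) <- c("feature_meta", class(df))
  df
}

#' Remove features annotated as known contaminants
#'
#' Drops every feature whose `contaminant_class` is not `"none"` — gas-bag
#' artefacts, pump oils and column siloxanes. Matching is by the explicit
#' annotation, not by compound-name strings. Column order of survivors is
#' preserved.
#'
#' @param table a [feature_table()].
#' @param feature_meta a `feature_meta` data frame covering every feature in
#'   `table` (a feature without metadata is an error).
#' @return list with `table` (filtered) and `removed` (character vector of
#'   removed feature ids).
#' @export
remove_named_contaminants <- function(table, feature_meta) {
  stopifnot(inherits(table, "feature_table"))
  feature_meta <- as_feature_meta(as.data.frame(feature_meta))
  missing <- setdiff(table$feature_ids, feature_meta$feature_id)
  if (length(missing)) {
    stop("no metadata for feature(s): ", paste(missing, collapse = ", "))
  }
  cls <- feature_meta$contaminant_class[match(table$feature_ids, feature_meta$feature_id)]
  removed <- table$feature_ids[cls != "none"]
  keep <- setdiff(table$feature_ids, removed)
  if (!length(keep)) {
    warning("all features are annotated contaminants; empty feature set remains")
    out <- structure(
      list(intensities = table$intensities[, 0, drop = FALSE],
           sample_ids = table$sample_ids, feature_ids = character(0)),
      class = "feature_table"
    )
    return(list(table = out, removed = removed))
  }
  list(table = subset_feature_table(table, features = keep), removed = removed)
}

# exact tail probabilities of the signed-rank statistic under random sign
# flips of the observed (possibly tied) mid-ranks, via a generating-function
# DP over doubled ranks (so tied .5 ranks become integers)
signrank_exact_tails <- function(ranks, W) {
  n <- length(ranks)
  s <- as.integer(round(2 * ranks))
  total <- sum(s)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (si in s) {
    g <- numeric(total + 1L)
    g[(si + 1L):(total + 1L)] <- f[1L:(total + 1L - si)]
    f <- f + g
  }
  w2 <- as.integer(round(2 * W))
  denom <- 2^n
  list(
    p_ge = sum(f[(w2 + 1L):(total + 1L)]) / denom,
    p_le = sum(f[1L:(w2 + 1L)]) / denom
  )
}

#' Paired Wilcoxon signed-rank test
#'
#' Compares paired intensity vectors (e.g. ambient vs breath) by the Wilcoxon
#' signed-rank test on `x - y`. Zero differences are dropped (Wilcoxon
#' convention); ties among absolute differences receive mid-ranks. The p-value
#' is exact — by enumeration over all sign assignments of the observed
#' mid-ranks — whenever the number of non-zero differences is at most
#' `exact_threshold`; above that, a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y numeric vectors of equal length, aligned pairs.
#' @param alternative `"greater"` tests x > y, `"less"` x < y, or
#'   `"two_sided"`.
#' @param exact_threshold largest n (non-zero differences) for the exact path.
#' @return An object of class `wilcoxon_result`: `statistic_W` (sum of
#'   positive signed ranks), `n_effective`, `p_value`, `alternative`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' paired_wilcoxon(c(5, 6, 7), c(1, 2, 3), "greater") # W = 6, p = 0.125
#' @export
paired_wilcoxon <- function(x, y,
                            alternative = c("greater", "less", "two_sided"),
                            exact_threshold = 25L) {
  alternative <- match.arg(gsub("\\.", "_", alternative[1L]),
                           c("greater", "less", "two_sided"))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("need at least one pair")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(structure(
      list(statistic_W = 0, n_effective = 0L, p_value = 1,
           alternative = alternative, method = "exact"),
      class = "wilcoxon_result"
    ))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_threshold) {
    tails <- signrank_exact_tails(r, W)
    p <- switch(alternative,
      greater = tails$p_ge,
      less = tails$p_le,
      two_sided = min(1, 2 * min(tails$p_ge, tails$p_le))
    )
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_sizes^3 - tie_sizes) / 48
    sigma <- sqrt(sigma2)
    p_ge <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    p_le <- stats::pnorm((W - mu + 0.5) / sigma)
    p <- switch(alternative,
      greater = p_ge,
      less = p_le,
      two_sided = min(1, 2 * min(p_ge, p_le))
    )
    method <- "normal_approx"
  }
  structure(
    list(statistic_W = W, n_effective = n, p_value = p,
         alternative = alternative, method = method),
    class = "wilcoxon_result"
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("<wilcoxon_result> W = ", x$statistic_W, ", n = ", x$n_effective,
      ", p = ", format(x$p_value, digits = 4), " (", x$alternative, ", ",
      x$method, ")\n", sep = "")
  invisible(x)
}

#' Hyper-filter a feature table against paired room-air samples
#'
#' Produces the "hyper-filtered" feature set: first removes annotated
#' contaminant features, then removes every feature whose non-normalized
#' intensity is significantly higher in room-air samples than in the paired
#' exhaled-breath samples (one-sided paired Wilcoxon signed-rank test,
#' ambient > breath).
#'
#' @param table a [feature_table()] containing breath samples and their
#'   paired ambient samples.
#' @param feature_meta a `feature_meta` data frame covering all features.
#' @param sample_meta a `sample_meta` data frame covering all samples in
#'   `table`; pairing must be clean (see [validate_pairing()]).
#' @param alpha removal threshold on the (adjusted) one-sided p-value.
#' @param p_adjust multiplicity correction across features: `"none"`
#'   (default) or `"BH"`.
#' @param exact_threshold passed to [paired_wilcoxon()].
#' @return list with `table` (the filtered feature table, all samples kept)
#'   and `report`, a `filter_report` whose `removed_contaminants`,
#'   `removed_ambient_dominant` (data.frame feature_id, p_value) and
#'   `retained` partition the input feature set.
#' @export
hyper_filter <- function(table, feature_meta, sample_meta, alpha = 0.05,
                         p_adjust = c("none", "BH"), exact_threshold = 25L) {
  p_adjust <- match.arg(p_adjust)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  stopifnot(inherits(table, "feature_table"))
  sample_meta <- as_sample_meta(as.data.frame(sample_meta))
  pr <- validate_pairing(table, sample_meta)
  if (pr$n_ambient == 0L) stop("no ambient samples available for filtering")
  if (length(pr$unpaired_breath_ids)) {
    stop("pairing defects: breath sample(s) without a unique ambient partner: ",
         paste(pr$unpaired_breath_ids, collapse = ", "))
  }
  step1 <- remove_named_contaminants(table, feature_meta)
  tab <- step1$table

  meta <- sample_meta[sample_meta$sample_id %in% tab$sample_ids, , drop = FALSE]
  breath <- meta[meta$sample_type == "breath", , drop = FALSE]
  ambient <- meta[meta$sample_type == "ambient", , drop = FALSE]
  amb_ids <- ambient$sample_id[match(breath$pair_key, ambient$pair_key)]
  Xb <- tab$intensities[breath$sample_id, , drop = FALSE]
  Xa <- tab$intensities[amb_ids, , drop = FALSE]

  pvals <- vapply(seq_along(tab$feature_ids), function(j) {
    suppressWarnings(
      paired_wilcoxon(Xa[, j], Xb[, j], "greater",
                      exact_threshold = exact_threshold)$p_value
    )
  }, numeric(1))
  padj <- stats::p.adjust(pvals, method = ifelse(p_adjust == "none", "none", "BH"))
  drop2 <- padj < alpha
  removed_ambient <- data.frame(
    feature_id = tab$feature_ids[drop2],
    p_value = padj[drop2],
    stringsAsFactors = FALSE
  )
  retained <- tab$feature_ids[!drop2]
  report <- structure(
    list(removed_contaminants = step1$removed,
         removed_ambient_dominant = removed_ambient,
         retained = retained,
         alpha = alpha, p_adjust = p_adjust),
    class = "filter_report"
  )
  if (!length(retained)) warning("hyper-filter removed every feature")
  out <- if (length(retained)) {
    subset_feature_table(table, features = retained)
  } else {
    structure(
      list(intensities = table$intensities[, 0, drop = FALSE],
           sample_ids = table$sample_ids, feature_ids = character(0)),
      class = "feature_table"
    )
  }
  list(table = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> retained ", length(x$retained), "; removed ",
      length(x$removed_contaminants), " contaminant(s), ",
      nrow(x$removed_ambient_dominant), " ambient-dominant (alpha = ",
      x$alpha, ", adjust = ", x$p_adjust, ")\n", sep = "")
  invisible(x)
}
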
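# Orchestration of the full modeling workflow: hyper-filter -> ASCA ->
# design assembly -> cross-validated AUC + permutation significance ->
# final fit -> external validation; plus the 16-comparison model catalog.

#' Specify one discrimination comparison
#'
#' @param model_id short identifier, e.g. `"I.A"`.
#' @param case_category the case diagnostic category (coded 1).
#' @param control_categories character vector of control categories (their
#'   union is coded 0); must not overlap the case category.
#' @param variable_blocks subset of `c("voc", "parental_history", "wbc",
#'   "atopic_flag")` entering the design matrix.
#' @param folds cross-validation folds (default 5).
#' @param permutations permutation count for model significance.
#' @param seed integer seed for the whole comparison.
#' @return an object of class `comparison_spec`.
#' @export
comparison_spec <- function(model_id, case_category, control_categories,
                            variable_blocks = "voc", folds = 5L,
                            permutations = 1000L, seed = 1L) {
  if (case_category %in% control_categories) {
    stop("case and control categories must be disjoint")
  }
  bad <- setdiff(variable_blocks, c("voc", names(VARIABLE_BLOCKS)))
  if (length(bad)) stop("unknown variable block(s): ", paste(bad, collapse = ", "))
  structure(
    list(model_id = model_id, case_category = case_category,
         control_categories = control_categories,
         variable_blocks = variable_blocks, folds = as.integer(folds),
         permutations = as.integer(permutations), seed = as.integer(seed)),
    class = "comparison_spec"
  )
}

#' The 16-model comparison catalog
#'
#' Sixteen comparisons over four contrasts: seven for A-AD vs NA (VOCs alone,
#' then with parental atopic history, blood eosinophil count, their
#' combination, the other-atopic-disorder flags, and combinations of all
#' blocks), four each for A-AD vs NA-NAD and A-AD vs NA-AD (VOCs, +parental
#' history, +WBC counts, +both), and one VOC-only model for NA-AD vs NA-NAD.
#'
#' @param permutations,folds defaults applied to every spec.
#' @param seed base seed; each model gets `seed + its index`.
#' @return list of 16 [comparison_spec()] objects.
#' @export
default_catalog <- function(permutations = 1000L, folds = 5L, seed = 1L) {
  na_union <- c("NA-AD", "NA-NAD")
  defs <- list(
    list("I.A", "A-AD", na_union, "voc"),
    list("I.B", "A-AD", na_union, c("voc", "parental_history")),
    list("I.C", "A-AD", na_union, c("voc", "wbc")),
    list("I.D", "A-AD", na_union, c("voc", "parental_history", "wbc")),
    list("I.E", "A-AD", na_union, c("voc", "atopic_flag")),
    list("I.F", "A-AD", na_union, c("voc", "parental_history", "atopic_flag")),
    list("I.G", "A-AD", na_union, c("voc", "parental_history", "wbc", "atopic_flag")),
    list("II.A", "A-AD", "NA-NAD", "voc"),
    list("II.B", "A-AD", "NA-NAD", c("voc", "parental_history")),
    list("II.C", "A-AD", "NA-NAD", c("voc", "wbc")),
    list("II.D", "A-AD", "NA-NAD", c("voc", "parental_history", "wbc")),
    list("III.A", "A-AD", "NA-AD", "voc"),
    list("III.B", "A-AD", "NA-AD", c("voc", "parental_history")),
    list("III.C", "A-AD", "NA-AD", c("voc", "wbc")),
    list("III.D", "A-AD", "NA-AD", c("voc", "parental_history", "wbc")),
    list("IV.A", "NA-AD", "NA-NAD", "voc")
  )
  lapply(seq_along(defs), function(i) {
    d <- defs[[i]]
    comparison_spec(d[[1]], d[[2]], d[[3]], d[[4]], folds = folds,
                    permutations = permutations, seed = seed + i)
  })
}

#' Assemble a design matrix from residualized VOCs and covariate blocks
#'
#' @param E residualized (or raw) feature matrix, columns named by feature id.
#' @param meta breath-sample metadata rows aligned with `E`.
#' @param blocks which variable blocks to include.
#' @return numeric matrix with a `block` attribute mapping column -> block.
#' @export
build_design_matrix <- function(E, meta, blocks) {
  parts <- list()
  block_of <- character(0)
  if ("voc" %in% blocks) {
    parts$voc <- as.matrix(E)
    block_of <- c(block_of, setNames(rep("voc", ncol(E)), colnames(E)))
  }
  for (b in intersect(names(VARIABLE_BLOCKS), blocks)) {
    vars <- VARIABLE_BLOCKS[[b]]
    missing <- setdiff(vars, colnames(meta))
    if (length(missing)) {
      stop("metadata lacks covariate(s) for block '", b, "': ",
           paste(missing, collapse = ", "))
    }
    m <- as.matrix(meta[, vars, drop = FALSE])
    storage.mode(m) <- "double"
    parts[[b]] <- m
    block_of <- c(block_of, setNames(rep(b, length(vars)), vars))
  }
  X <- do.call(cbind, parts)
  rownames(X) <- meta$sample_id
  attr(X, "block") <- block_of
  X
}

#' Run one comparison end-to-end
#'
#' In order: hyper-filter (feature set determined on the training split's
#' breath/ambient pairs by default), ASCA fit on the training breath samples
#' (factors season then zone) with residualization of both splits, design
#' assembly per variable blocks, cross-validated AUC with nested penalty
#' selection, permutation-test significance (full rebuild per permutation),
#' final fit on all training samples at the cross-validated penalty,
#' prevalence cutoff, and external validation.
#'
#' @param spec a [comparison_spec()].
#' @param cohort a `breath_cohort` (or a list with `table`, `sample_meta`,
#'   `feature_meta`) whose breath samples carry `category`, `season`,
#'   `zone` and `split`.
#' @param filter_scope `"train"` (default: the screen uses training pairs
#'   only) or `"all"` (all pairs, as when filtering precedes splitting).
#' @param alpha,p_adjust hyper-filter parameters.
#' @param fast passed to [permutation_model_test()].
#' @return An object of class `model_report`: model id, sample sizes,
#'   selected variables with block tags, `auc_cv`, `p_value`, `auc_vs`,
#'   `sensitivity_pct`, `specificity_pct`, the fitted model and stage
#'   objects, and provenance (seed, retained feature count).
#' @export
run_comparison <- function(spec, cohort, filter_scope = c("train", "all"),
                           alpha = 0.05, p_adjust = "none", fast = FALSE) {
  stopifnot(inherits(spec, "comparison_spec"))
  filter_scope <- match.arg(filter_scope)
  tab <- cohort$table
  meta <- as_sample_meta(as.data.frame(cohort$sample_meta))

  cats <- c(spec$case_category, spec$control_categories)
  breath <- meta[meta$sample_type == "breath" & meta$category %in% cats, ,
                 drop = FALSE]
  if (!all(breath$split %in% SPLIT_LEVELS)) {
    stop("breath samples need an assigned train/validation split")
  }
  train_b <- breath[breath$split == "train", , drop = FALSE]
  val_b <- breath[breath$split == "validation", , drop = FALSE]
  n_case_train <- sum(train_b$category == spec$case_category)
  if (n_case_train < 10L) {
    warning("fewer than 10 training case samples (", n_case_train, ")")
  }

  # hyper-filter on the chosen scope's breath/ambient pairs
  ambient <- meta[meta$sample_type == "ambient", , drop = FALSE]
  scope_b <- if (filter_scope == "train") train_b else breath
  scope_a <- ambient[ambient$pair_key %in% scope_b$pair_key, , drop = FALSE]
  sub_tab <- subset_feature_table(tab, samples = c(scope_b$sample_id,
                                                   scope_a$sample_id))
  hf <- hyper_filter(sub_tab, cohort$feature_meta,
                     rbind(scope_b, scope_a), alpha = alpha,
                     p_adjust = p_adjust)
  feats <- hf$report$retained
  if (!length(feats) && "voc" %in% spec$variable_blocks) {
    stop("stage hyper_filter: no features retained")
  }

  # ASCA on training breath samples; residualize both splits
  Xtr_raw <- tab$intensities[train_b$sample_id, feats, drop = FALSE]
  dec <- asca_decompose(Xtr_raw,
                        list(season = train_b$season, zone = train_b$zone))
  Etr <- dec$residual_E
  Eval <- residualize(dec, tab$intensities[val_b$sample_id, feats, drop = FALSE],
                      list(season = val_b$season, zone = val_b$zone))

  Xtr <- build_design_matrix(Etr, train_b, spec$variable_blocks)
  Xval <- build_design_matrix(Eval, val_b, spec$variable_blocks)
  ytr <- as.integer(train_b$category == spec$case_category)
  yval <- as.integer(val_b$category == spec$case_category)

  set.seed(spec$seed)
  s_cv <- draw_seed(); s_perm <- draw_seed(); s_final <- draw_seed()

  cv <- cross_validated_auc(Xtr, ytr, k = spec$folds, seed = s_cv)
  perm <- permutation_model_test(Xtr, ytr, B = spec$permutations,
                                 k = spec$folds, seed = s_perm,
                                 observed = cv, fast = fast)
  lam <- cv_select_lambda(Xtr, ytr, k = spec$folds, seed = s_final)
  fit <- fit_lasso_lr(Xtr, ytr, lam$chosen_lambda,
                      class_labels = c(case = spec$case_category,
                                       control = paste(spec$control_categories,
                                                       collapse = "+")))
  cutoff <- prevalence_cutoff(ytr)
  val <- external_validation(fit, cutoff, Xval, yval)

  block_of <- attr(Xtr, "block")
  structure(
    list(model_id = spec$model_id,
         case_category = spec$case_category,
         control_categories = spec$control_categories,
         variable_blocks = spec$variable_blocks,
         n_train = nrow(Xtr), n_validation = nrow(Xval),
         selected_variables = data.frame(
           variable = fit$selected,
           block = unname(block_of[fit$selected]),
           odds_ratio = unname(fit$odds_ratios),
           stringsAsFactors = FALSE
         ),
         auc_cv = cv$auc_cv, p_value = perm$p_value, auc_vs = val$auc_vs,
         sensitivity_pct = val$sensitivity_pct,
         specificity_pct = val$specificity_pct,
         cutoff = cutoff, model = fit, cv = cv, permutation = perm,
         validation = val, filter_report = hf$report, asca = dec,
         provenance = list(seed = spec$seed, permutations = spec$permutations,
                           folds = spec$folds, n_features_retained = length(feats),
                           filter_scope = filter_scope)),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> ", x$model_id, ": ", x$case_category, " vs ",
      paste(x$control_categories, collapse = "+"), "\n", sep = "")
  cat(sprintf("  AUC_CV %.2f  p %.3g  AUC_VS %.2f  sens %d%%  spec %d%%\n",
              x$auc_cv, x$p_value, x$auc_vs, x$sensitivity_pct,
              x$specificity_pct))
  if (nrow(x$selected_variables)) {
    cat("  selected: ", paste(x$selected_variables$variable, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Run a catalog of comparisons
#'
#' Maps [run_comparison()] over a catalog; an individual model failure is
#' recorded and the run continues. Optionally writes one JSON report per
#' model plus a summary CSV.
#'
#' @param catalog list of [comparison_spec()] objects.
#' @param cohort as in [run_comparison()].
#' @param out_dir optional output directory.
#' @param ... passed to [run_comparison()].
#' @return list with `reports` (named by model id; failed models carry the
#'   error condition) and `summary` (data.frame mirroring the accuracy-table
#'   columns).
#' @export
run_all <- function(catalog, cohort, out_dir = NULL, ...) {
  reports <- lapply(catalog, function(spec) {
    tryCatch(run_comparison(spec, cohort, ...), error = function(e) e)
  })
  names(reports) <- vapply(catalog, function(s) s$model_id, character(1))
  ok <- !vapply(reports, inherits, logical(1), what = "condition")
  summary <- do.call(rbind, lapply(reports[ok], function(r) {
    data.frame(model_id = r$model_id, auc_cv = r$auc_cv, p_value = r$p_value,
               auc_vs = r$auc_vs, sensitivity_pct = r$sensitivity_pct,
               specificity_pct = r$specificity_pct,
               variables = paste(r$selected_variables$variable, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary)) {
    summary <- data.frame(model_id = character(0), auc_cv = numeric(0),
                          p_value = numeric(0), auc_vs = numeric(0),
                          sensitivity_pct = numeric(0),
                          specificity_pct = numeric(0),
                          variables = character(0))
  }
  rownames(summary) <- NULL
  if (any(!ok)) {
    warning("model(s) failed: ", paste(names(reports)[!ok], collapse = ", "))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(reports)[ok]) {
      jsonlite::write_json(report_as_json(reports[[id]]),
                           file.path(out_dir, paste0("model_", gsub("[^A-Za-z0-9._-]", "_", id), ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    utils::write.table(summary, file.path(out_dir, "summary.csv"), sep = ",",
                       row.names = FALSE, quote = TRUE)
  }
  list(reports = reports, summary = summary)
}

# serializable subset of a model report
report_as_json <- function(r) {
  list(
    model_id = r$model_id, case_category = r$case_category,
    control_categories = r$control_categories,
    variable_blocks = r$variable_blocks,
    n_train = r$n_train, n_validation = r$n_validation,
    auc_cv = r$auc_cv, p_value = r$p_value, auc_vs = r$auc_vs,
    sensitivity_pct = r$sensitivity_pct, specificity_pct = r$specificity_pct,
    cutoff = r$cutoff,
    selected_variables = r$selected_variables,
    lambda = r$model$lambda,
    odds_ratios = as.list(r$model$odds_ratios),
    provenance = r$provenance
  )
}
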
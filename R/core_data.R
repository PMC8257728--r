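# Data model, readers/writers and structural validation for feature tables
# and sample metadata.

#' Construct a feature table
#'
#' A feature table holds non-negative relative intensities of GC/MS features
#' (ion peaks with a retention time and characteristic m/z), one row per
#' sample, one column per feature.
#'
#' @param intensities numeric matrix, rows = samples, columns = features;
#'   all values must be finite and non-negative.
#' @param sample_ids character vector of unique sample identifiers, one per row.
#' @param feature_ids character vector of unique feature identifiers, one per
#'   column.
#' @return An object of class `feature_table` with elements `intensities`
#'   (a dimnamed matrix), `sample_ids` and `feature_ids`.
#' @export
feature_table <- function(intensities, sample_ids, feature_ids) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (nrow(intensities) != length(sample_ids)) {
    stop("row count (", nrow(intensities), ") does not match number of sample ids (",
         length(sample_ids), ")")
  }
  if (ncol(intensities) != length(feature_ids)) {
    stop("column count (", ncol(intensities), ") does not match number of feature ids (",
         length(feature_ids), ")")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id: ", feature_ids[duplicated(feature_ids)][1L])
  }
  if (any(!is.finite(intensities))) {
    bad <- which(!is.finite(intensities), arr.ind = TRUE)[1L, ]
    stop("non-finite intensity at sample '", sample_ids[bad[1L]],
         "', feature '", feature_ids[bad[2L]], "'")
  }
  if (any(intensities < 0)) {
    bad <- which(intensities < 0, arr.ind = TRUE)[1L, ]
    stop("negative intensity at sample '", sample_ids[bad[1L]],
         "', feature '", feature_ids[bad[2L]], "'")
  }
  dimnames(intensities) <- list(sample_ids, feature_ids)
  structure(
    list(intensities = intensities, sample_ids = sample_ids,
         feature_ids = feature_ids),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", length(x$sample_ids), " samples x ",
      length(x$feature_ids), " features\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table by sample and/or feature ids (order preserved)
#'
#' @param x a [feature_table()].
#' @param samples,features character vectors of ids to keep; `NULL` keeps all.
#' @return a `feature_table`.
#' @export
subset_feature_table <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "feature_table"))
  s <- if (is.null(samples)) x$sample_ids else as.character(samples)
  f <- if (is.null(features)) x$feature_ids else as.character(features)
  missing_s <- setdiff(s, x$sample_ids)
  if (length(missing_s)) stop("unknown sample id(s): ", paste(missing_s, collapse = ", "))
  missing_f <- setdiff(f, x$feature_ids)
  if (length(missing_f)) stop("unknown feature id(s): ", paste(missing_f, collapse = ", "))
  feature_table(x$intensities[s, f, drop = FALSE], s, f)
}

infer_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a feature table from delimited text
#'
#' The first column holds sample ids; the header row holds feature ids; the
#' body must be numeric and non-negative. Missing values are rejected unless
#' `impute_zero = TRUE`, in which case blank/NA cells are replaced by 0 (with
#' a message).
#'
#' @param path path to a CSV (default) or TSV file.
#' @param sep field separator; inferred from the file extension when `NULL`.
#' @param impute_zero replace missing cells by 0 instead of failing.
#' @return a [feature_table()]; row/column order follows the file.
#' @export
read_feature_table <- function(path, sep = NULL, impute_zero = FALSE) {
  sep <- infer_sep(path, sep)
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table needs a sample-id column plus at least one feature")
  sample_ids <- df[[1L]]
  feature_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id: ", feature_ids[duplicated(feature_ids)][1L])
  }
  n_imputed <- 0L
  mat <- matrix(NA_real_, nrow(df), length(feature_ids))
  for (j in seq_along(feature_ids)) {
    raw <- trimws(df[[j + 1L]])
    blank <- raw == "" | toupper(raw) == "NA"
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & !blank
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-numeric value '", raw[i], "' at sample '", sample_ids[i],
           "', feature '", feature_ids[j], "'")
    }
    if (any(blank)) {
      if (!impute_zero) {
        i <- which(blank)[1L]
        stop("missing intensity at sample '", sample_ids[i], "', feature '",
             feature_ids[j], "' (use impute_zero = TRUE to replace with 0)")
      }
      val[blank] <- 0
      n_imputed <- n_imputed + sum(blank)
    }
    if (any(val < 0)) {
      i <- which(val < 0)[1L]
      stop("negative intensity ", val[i], " at sample '", sample_ids[i],
           "', feature '", feature_ids[j], "'")
    }
    mat[, j] <- val
  }
  if (n_imputed > 0L) message("imputed ", n_imputed, " missing cell(s) with 0")
  feature_table(mat, sample_ids, feature_ids)
}

#' Write a feature table to delimited text
#'
#' Values are written with 15 significant digits so that any value with a
#' decimal representation of up to 12 significant digits round-trips exactly.
#'
#' @param x a [feature_table()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "feature_table"))
  body <- matrix(formatC(x$intensities, digits = 15, format = "g"),
                 nrow = nrow(x$intensities))
  df <- data.frame(sample_id = x$sample_ids, body, stringsAsFactors = FALSE,
                   check.names = FALSE)
  colnames(df) <- c("sample_id", x$feature_ids)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_sample_meta <- function(df) {
  required <- c("sample_id", "subject_id", "sample_type", "pair_key")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols)) {
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id: ", df$sample_id[duplicated(df$sample_id)][1L])
  }
  bad_type <- !df$sample_type %in% SAMPLE_TYPES
  if (any(bad_type)) {
    stop("unknown sample_type '", df$sample_type[bad_type][1L],
         "' (expected one of: ", paste(SAMPLE_TYPES, collapse = ", "), ")")
  }
  if ("season" %in% colnames(df)) {
    bad <- !is.na(df$season) & !df$season %in% SEASON_LEVELS
    if (any(bad)) {
      stop("unknown season '", df$season[bad][1L],
           "' (expected one of: ", paste(SEASON_LEVELS, collapse = ", "), ")")
    }
  }
  is_breath <- df$sample_type == "breath"
  if ("category" %in% colnames(df)) {
    bad <- is_breath & !is.na(df$category) & !df$category %in% CATEGORY_LEVELS
    if (any(bad)) {
      stop("unknown category '", df$category[bad][1L],
           "' (expected one of: ", paste(CATEGORY_LEVELS, collapse = ", "), ")")
    }
  }
  if ("split" %in% colnames(df)) {
    bad <- !is.na(df$split) & df$split != "" & !df$split %in% SPLIT_LEVELS
    if (any(bad)) {
      stop("unknown split '", df$split[bad][1L],
           "' (expected one of: ", paste(SPLIT_LEVELS, collapse = ", "), ")")
    }
    if (any(!is.na(df$split) & df$split %in% SPLIT_LEVELS & !is_breath)) {
      # ambient samples may only inherit their partner's split; tolerate but
      # do not require it
    }
  }
  no_pair <- is_breath & (is.na(df$pair_key) | df$pair_key == "")
  if (any(no_pair)) {
    stop("breath sample '", df$sample_id[no_pair][1L], "' lacks a pair_key")
  }
  for (cv in intersect(BINARY_COVARIATES, colnames(df))) {
    v <- df[[cv]][is_breath]
    bad <- !is.na(v) & !v %in% c(0, 1)
    if (any(bad)) stop("covariate '", cv, "' must be coded 0/1; found '", v[bad][1L], "'")
  }
  invisible(df)
}

#' Read per-sample metadata from delimited text
#'
#' Expected columns: `sample_id`, `subject_id`, `sample_type`
#' (breath/ambient), `pair_key` (links each breath sample to its room-air
#' sample), and optionally `category` (A-AD / NA-AD / NA-NAD; the NA class is
#' the union NA-AD + NA-NAD and is never stored), `season`, `zone`, `split`
#' (train/validation), a `sampling_date` (ISO-8601) and clinical covariate
#' columns. Binary covariates are coded 0/1; unknown columns are carried
#' through untouched. Enumerated fields are validated against their closed
#' vocabularies.
#'
#' @param path path to a CSV/TSV file.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return a `data.frame` of class `sample_meta`.
#' @export
read_sample_meta <- function(path, sep = NULL) {
  sep <- infer_sep(path, sep)
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  as_sample_meta(df)
}

#' Validate a data frame as sample metadata
#'
#' @param df a data.frame with the columns described in [read_sample_meta()].
#' @return `df` with class `sample_meta` prepended.
#' @export
as_sample_meta <- function(df) {
  validate_sample_meta(df)
  if (!inherits(df, "sample_meta")) class(df) <- c("sample_meta", class(df))
  df
}

#' Check breath/ambient pairing of a feature table against its metadata
#'
#' Every exhaled-breath sample is expected to have exactly one paired room-air
#' (ambient) sample, linked through `pair_key`. This is a reporting operation:
#' defects are listed, not raised.
#'
#' @param table a [feature_table()].
#' @param meta a `sample_meta` data frame covering all samples in `table`.
#' @return An object of class `pairing_report`: `n_breath`, `n_ambient`,
#'   `unpaired_breath_ids` (breath samples whose pair key resolves to zero or
#'   several ambient samples) and `orphan_ambient_ids` (ambient samples never
#'   referenced by a breath sample).
#' @export
validate_pairing <- function(table, meta) {
  stopifnot(inherits(table, "feature_table"))
  meta <- as_sample_meta(as.data.frame(meta))
  uncovered <- setdiff(table$sample_ids, meta$sample_id)
  if (length(uncovered)) {
    stop("metadata does not cover sample id(s): ", paste(uncovered, collapse = ", "))
  }
  meta <- meta[meta$sample_id %in% table$sample_ids, , drop = FALSE]
  breath <- meta[meta$sample_type == "breath", , drop = FALSE]
  ambient <- meta[meta$sample_type == "ambient", , drop = FALSE]
  amb_count <- table(ambient$pair_key)
  n_match <- as.integer(amb_count[breath$pair_key])
  n_match[is.na(n_match)] <- 0L
  unpaired <- breath$sample_id[n_match != 1L]
  orphan <- ambient$sample_id[!ambient$pair_key %in% breath$pair_key]
  structure(
    list(n_breath = nrow(breath), n_ambient = nrow(ambient),
         unpaired_breath_ids = unpaired, orphan_ambient_ids = orphan),
    class = "pairing_report"
  )
}

#' @export
print.pairing_report <- function(x, ...) {
  cat("<pairing_report> ", x$n_breath, " breath / ", x$n_ambient, " ambient; ",
      length(x$unpaired_breath_ids), " unpaired breath, ",
      length(x$orphan_ambient_ids), " orphan ambient\n", sep = "")
  invisible(x)
}

#' Assign train/validation split by sampling date
#'
#' Breath samples strictly before `cutoff` become the training set, the rest
#' the validation set (half-open interval: the cutoff day itself is
#' validation). Ambient samples inherit the split of their breath partner.
#'
#' @param meta a `sample_meta` data frame with a `sampling_date` column
#'   (ISO-8601 strings) on breath samples.
#' @param cutoff a `Date` or ISO-8601 string.
#' @return `meta` with the `split` column filled in.
#' @export
split_by_date <- function(meta, cutoff) {
  meta <- as_sample_meta(as.data.frame(meta))
  if (!"sampling_date" %in% colnames(meta)) {
    stop("metadata lacks a 'sampling_date' column")
  }
  cutoff <- as.Date(cutoff)
  is_breath <- meta$sample_type == "breath"
  dates <- as.Date(meta$sampling_date)
  if (any(is_breath & is.na(dates))) {
    bad <- meta$sample_id[is_breath & is.na(dates)][1L]
    stop("missing or unparseable sampling_date for breath sample '", bad, "'")
  }
  meta$split <- NA_character_
  meta$split[is_breath] <- ifelse(dates[is_breath] < cutoff, "train", "validation")
  # ambient samples inherit their partner's split
  is_amb <- meta$sample_type == "ambient"
  partner <- match(meta$pair_key[is_amb], meta$pair_key[is_breath])
  meta$split[is_amb] <- meta$split[is_breath][partner]
  meta
}
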
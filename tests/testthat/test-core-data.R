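test_that("feature tables read from CSV with shape, order and value checks", {
  p <- write_ft_csv(c("sample_id,F1,F2", "s1,1.5,2", "s2,0,3.25", "s3,4,5"))
  ft <- read_feature_table(p)
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft), c(3L, 2L))
  expect_equal(ft$sample_ids, c("s1", "s2", "s3"))
  expect_equal(ft$feature_ids, c("F1", "F2"))
  expect_equal(ft$intensities[2, 2], 3.25)

  dup <- write_ft_csv(c("sample_id,F1", "s1,1", "s1,2"))
  expect_error(read_feature_table(dup), "duplicate sample id.*s1")

  neg <- write_ft_csv(c("sample_id,F1,F2", "s1,1,2", "s2,-1.0,3"))
  expect_error(read_feature_table(neg), "negative intensity.*s2.*F1")

  txt <- write_ft_csv(c("sample_id,F1", "s1,abc"))
  expect_error(read_feature_table(txt), "non-numeric.*abc")

  gap <- write_ft_csv(c("sample_id,F1", "s1,", "s2,2"))
  expect_error(read_feature_table(gap), "missing intensity")
  expect_message(ft2 <- read_feature_table(gap, impute_zero = TRUE), "imputed 1")
  expect_equal(ft2$intensities[1, 1], 0)
})

test_that("feature tables round-trip through CSV to 12 significant digits", {
  set.seed(1)
  for (rep in 1:5) {
    vals <- signif(10^runif(12, -2, 6), sample(1:12, 12, replace = TRUE))
    ft <- feature_table(matrix(vals, 4, 3), paste0("s", 1:4), paste0("F", 1:3))
    path <- tempfile(fileext = ".csv")
    write_feature_table(ft, path)
    back <- read_feature_table(path)
    expect_identical(back$sample_ids, ft$sample_ids)
    expect_identical(back$feature_ids, ft$feature_ids)
    expect_identical(unname(back$intensities), unname(ft$intensities))
  }
})

test_that("sample metadata enforces closed vocabularies and pairing keys", {
  base <- data.frame(
    sample_id = c("b1", "a1"), subject_id = c("s1", "s1"),
    sample_type = c("breath", "ambient"), pair_key = c("p1", "p1"),
    category = c("A-AD", NA), season = c("spring", "spring"),
    stringsAsFactors = FALSE
  )
  expect_s3_class(as_sample_meta(base), "sample_meta")

  bad_season <- base
  bad_season$season[1] <- "Spr"
  expect_error(as_sample_meta(bad_season), "unknown season 'Spr'")

  bad_type <- base
  bad_type$sample_type[2] <- "air"
  expect_error(as_sample_meta(bad_type), "unknown sample_type")

  no_pair <- base
  no_pair$pair_key[1] <- ""
  expect_error(as_sample_meta(no_pair), "lacks a pair_key")

  bad_cat <- base
  bad_cat$category[1] <- "AAD"
  expect_error(as_sample_meta(bad_cat), "unknown category")
})

test_that("pairing validation reports unpaired breath and orphan ambient samples", {
  meta <- data.frame(
    sample_id = c("b1", "b2", "a1", "a2"), subject_id = paste0("s", 1:4),
    sample_type = c("breath", "breath", "ambient", "ambient"),
    pair_key = c("p1", "p2", "p1", "p2"), stringsAsFactors = FALSE
  )
  ft <- feature_table(matrix(1:8, 4, 2), meta$sample_id, c("F1", "F2"))
  pr <- validate_pairing(ft, meta)
  expect_equal(pr$n_breath, 2L)
  expect_equal(pr$n_ambient, 2L)
  expect_length(pr$unpaired_breath_ids, 0L)
  expect_length(pr$orphan_ambient_ids, 0L)

  # drop one ambient -> its breath partner is unpaired
  pr2 <- validate_pairing(subset_feature_table(ft, samples = c("b1", "b2", "a1")),
                          meta)
  expect_equal(pr2$unpaired_breath_ids, "b2")

  # ambient never referenced
  meta3 <- meta
  meta3$pair_key[4] <- "p9"
  pr3 <- validate_pairing(ft, meta3)
  expect_equal(pr3$orphan_ambient_ids, "a2")
  expect_equal(pr3$unpaired_breath_ids, "b2")

  expect_error(validate_pairing(ft, meta[-1, ]), "does not cover")
})

test_that("date-based splitting is half-open, exhaustive and inherited by ambient", {
  meta <- data.frame(
    sample_id = c("b1", "b2", "a1", "a2"), subject_id = c("s1", "s2", "s1", "s2"),
    sample_type = c("breath", "breath", "ambient", "ambient"),
    pair_key = c("p1", "p2", "p1", "p2"),
    sampling_date = c("2018-01-10", "2018-04-02", NA, NA),
    stringsAsFactors = FALSE
  )
  out <- split_by_date(meta, "2018-03-01")
  expect_equal(out$split, c("train", "validation", "train", "validation"))

  all_before <- meta
  all_before$sampling_date[2] <- "2018-02-28"
  out2 <- split_by_date(all_before, "2018-03-01")
  expect_true(all(out2$split == "train"))

  # cutoff day itself goes to validation (half-open interval)
  on_cut <- meta
  on_cut$sampling_date[1] <- "2018-03-01"
  expect_equal(split_by_date(on_cut, "2018-03-01")$split[1], "validation")

  miss <- meta
  miss$sampling_date[1] <- NA
  expect_error(split_by_date(miss, "2018-03-01"), "sampling_date")

  # partition property on generated dates
  set.seed(3)
  n <- 50
  m <- data.frame(
    sample_id = paste0("b", 1:n), subject_id = paste0("s", 1:n),
    sample_type = "breath", pair_key = paste0("p", 1:n),
    sampling_date = as.character(as.Date("2017-06-01") + sample(0:500, n)),
    stringsAsFactors = FALSE
  )
  sp <- split_by_date(m, "2018-03-01")$split
  expect_true(all(sp %in% c("train", "validation")))
  expect_equal(sum(sp == "train") + sum(sp == "validation"), n)
})
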
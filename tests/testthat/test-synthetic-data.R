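test_that("generated cohorts have the contracted shape and clean structure", {
  cfg <- generator_config(n_case = 20, n_control = 20, n_features = 200,
                          n_discriminant = 3, seed = 1)
  ch <- generate_cohort(cfg)
  expect_equal(dim(ch$table), c(80L, 200L)) # 40 breath + 40 ambient
  expect_length(ch$truth$discriminant_ids, 3L)

  # core-data invariants: completeness, non-negativity, pairing
  expect_true(all(is.finite(ch$table$intensities)))
  expect_true(all(ch$table$intensities >= 0))
  pr <- validate_pairing(ch$table, ch$sample_meta)
  expect_length(pr$unpaired_breath_ids, 0L)
  expect_length(pr$orphan_ambient_ids, 0L)

  # ground-truth feature roles are disjoint
  ids <- with(ch$truth, c(discriminant_ids, contaminant_ids, ambient_dominant_ids))
  expect_equal(anyDuplicated(ids), 0L)

  # categories consistent with class and the atopy-flag definition
  meta <- as.data.frame(ch$sample_meta)
  breath <- meta[meta$sample_type == "breath", ]
  expect_true(all(breath$category[ch$truth$sample_assignments$class == "case"] == "A-AD"))
  flags <- breath[, c("allergic_rhinitis", "atopic_dermatitis",
                      "allergic_conjunctivitis", "food_allergy", "drug_allergy")]
  expect_true(all(rowSums(flags[breath$category == "NA-NAD", ]) == 0))
  expect_true(all(rowSums(flags[breath$category != "NA-NAD", ]) >= 1))
})

test_that("generation is bit-identical under a fixed seed and splits are stratified", {
  cfg <- generator_config(n_case = 15, n_control = 45, n_features = 30, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$sample_meta, b$sample_meta)
  expect_identical(a$truth, b$truth)

  sa <- a$truth$sample_assignments
  expect_equal(sum(sa$split == "validation" & sa$class == "case"),
               round(cfg$validation_fraction * 15))
  expect_equal(sum(sa$split == "validation" & sa$class == "control"),
               round(cfg$validation_fraction * 45))
})

test_that("a zero planted effect leaves case and control distributions identical in law", {
  cfg <- generator_config(n_case = 100, n_control = 100, n_features = 20,
                          n_discriminant = 3, effect_log2 = 0, seed = 7)
  ch <- generate_cohort(cfg)
  sa <- ch$truth$sample_assignments
  disc <- ch$truth$discriminant_ids
  X <- log10(ch$table$intensities[sa$sample_id, disc, drop = FALSE])
  ks <- suppressWarnings(
    stats::ks.test(as.vector(X[sa$class == "case", ]),
                   as.vector(X[sa$class == "control", ]))
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("configuration invariants are enforced", {
  expect_error(generator_config(n_features = 5, n_discriminant = 3,
                                n_contaminants = 2, n_ambient_dominant = 2),
               "exceeds n_features")
  expect_error(generator_config(noise_sd_log = -1), "standard deviations")
  expect_error(generator_config(ambient_fraction = 1.2), "ambient_fraction")
})

test_that("benchmark profiles differ only in planted effect and carry fixed seeds", {
  suite <- benchmark_suite()
  expect_named(suite, c("null", "moderate", "strong"))
  expect_equal(suite$null$effect_log2, 0)
  expect_equal(suite$moderate$effect_log2, 1)
  expect_equal(suite$strong$effect_log2, 2)
  for (cfg in suite) {
    expect_equal(cfg$n_case, 20L)
    expect_equal(cfg$n_control, 80L)
    expect_equal(cfg$n_discriminant, 3L)
  }
  expect_false(suite$null$seed == suite$strong$seed)
  # reproducible: same profile twice gives identical configs
  expect_identical(benchmark_suite("strong")$strong, suite$strong)
})

test_that("study fixtures reproduce the printed subgroup relations", {
  fx <- study_fixtures()
  expect_equal(unname(fx$group1$n["NA"]),
               unname(fx$group1$n["NA-AD"] + fx$group1$n["NA-NAD"]))
  expect_equal(unname(fx$group1$n["NA"]), 186L)
  expect_equal(unname(fx$group2$n["NA"]), 111L)
  # validation-set A-AD allergic rhinitis: all 14 of 14
  row <- subset(fx$group2$rows, variable == "allergic_rhinitis" & category == "A-AD")
  expect_equal(row$count, 14L)
  expect_equal(row$count, unname(fx$group2$n["A-AD"]))
  expect_equal(subgroup_percentage(row$count, row$n), 100)
  # per-subject reconstruction is consistent with the flow counts
  expect_equal(nrow(fx$subjects), fx$flow$sampled)
  expect_equal(sum(fx$subjects$group == 1), fx$flow$group1_n)
})
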
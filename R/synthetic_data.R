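# Seeded synthetic breath-cohort generator: planted discriminant VOC
# features, season/zone batch effects, paired ambient samples with
# contamination, and clinical covariates. Every other module is testable
# from this module alone.

#' Configuration of the synthetic breath-cohort generator
#'
#' Intensities follow a lognormal model: per-feature log10 baselines with
#' additive class, season, zone and noise effects on the log10 scale,
#' exponentiated to strictly positive relative intensities (GC/MS relative
#' abundances behave multiplicatively). Each breath sample gets one paired
#' ambient (room-air) sample sharing its season/zone effects (room air is
#' collected at the same visit) at `ambient_fraction` of the breath baseline
#' — except `n_ambient_dominant` features whose ambient level is 10x that,
#' emulating exogenous pollutants. `n_contaminants` features are flagged as
#' gas-bag artefacts / pump oil / siloxanes in the feature metadata.
#'
#' @param n_case,n_control breath sample counts per class (whole cohort,
#'   before the train/validation split).
#' @param n_features total number of features.
#' @param n_discriminant number of class-discriminant features.
#' @param effect_log2 log2 mean shift of discriminant features in cases
#'   (converted internally to log10).
#' @param season_effect_sd,zone_effect_sd SD of per-(level, feature) batch
#'   shifts on the log10 scale.
#' @param n_zones number of residence zones.
#' @param noise_sd_log residual SD on the log10 scale.
#' @param ambient_fraction fraction of a breath feature's baseline appearing
#'   in room air, in \[0, 1\].
#' @param n_contaminants number of annotated contaminant features.
#' @param n_ambient_dominant number of features with ambient >> breath.
#' @param covariate_effects named numeric: per-covariate case effect —
#'   a log-odds shift for binary covariates, a mean shift (counts per ul)
#'   for white-blood-cell counts.
#' @param validation_fraction fraction of breath samples held out as the
#'   validation split (stratified by class).
#' @param prop_na_ad fraction of controls assigned the NA-AD category (the
#'   rest are NA-NAD).
#' @param seed integer RNG seed; output is fully deterministic given it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_case = 39L, n_control = 297L,
                             n_features = 300L, n_discriminant = 3L,
                             effect_log2 = 1, season_effect_sd = 0.2,
                             zone_effect_sd = 0.1, n_zones = 3L,
                             noise_sd_log = 0.3, ambient_fraction = 0.2,
                             n_contaminants = 4L, n_ambient_dominant = 5L,
                             covariate_effects = default_covariate_effects(),
                             validation_fraction = 125 / 336,
                             prop_na_ad = 72 / 186, seed = 1L) {
  cfg <- list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_features = as.integer(n_features),
    n_discriminant = as.integer(n_discriminant),
    effect_log2 = effect_log2, season_effect_sd = season_effect_sd,
    zone_effect_sd = zone_effect_sd, n_zones = as.integer(n_zones),
    noise_sd_log = noise_sd_log, ambient_fraction = ambient_fraction,
    n_contaminants = as.integer(n_contaminants),
    n_ambient_dominant = as.integer(n_ambient_dominant),
    covariate_effects = covariate_effects,
    validation_fraction = validation_fraction,
    prop_na_ad = prop_na_ad, seed = as.integer(seed)
  )
  with(cfg, {
    if (n_case < 1L || n_control < 1L) stop("need cases and controls")
    if (n_discriminant + n_contaminants + n_ambient_dominant > n_features) {
      stop("n_discriminant + n_contaminants + n_ambient_dominant exceeds n_features")
    }
    if (any(c(season_effect_sd, zone_effect_sd, noise_sd_log) < 0)) {
      stop("standard deviations must be >= 0")
    }
    if (ambient_fraction < 0 || ambient_fraction > 1) {
      stop("ambient_fraction must be in [0, 1]")
    }
    if (validation_fraction < 0 || validation_fraction >= 1) {
      stop("validation_fraction must be in [0, 1)")
    }
  })
  structure(cfg, class = "generator_config")
}

#' Default case effects of the clinical covariates
#'
#' Log-odds shifts for binary covariates and mean shifts (counts per ul) for
#' WBC counts, sized so that the synthetic marginal rates resemble those of
#' an atopy-enriched obstetric cohort (e.g. parental asthma ~24% in cases vs
#' ~6% in controls; eosinophils ~75/ul higher in cases). All are
#' configuration, not hard-coded truth.
#'
#' @return named numeric vector.
#' @export
default_covariate_effects <- function() {
  c(parental_asthma = 1.6, parental_rhinitis = 1.0, parental_dermatitis = 1.2,
    allergic_rhinitis = 2.8, atopic_dermatitis = 0.8,
    allergic_conjunctivitis = 1.3, food_allergy = 0.4, drug_allergy = 0.1,
    eosinophils = 75)
}

# control-category base rates / moments used by the generator
GEN_PARENTAL_BASE <- c(parental_asthma = 0.06, parental_rhinitis = 0.19,
                       parental_dermatitis = 0.04)
GEN_ATOPIC_BASE_NAAD <- c(allergic_rhinitis = 0.65, atopic_dermatitis = 0.17,
                          allergic_conjunctivitis = 0.36, food_allergy = 0.14,
                          drug_allergy = 0.19)
GEN_WBC_MOMENTS <- list( # control mean, sd (counts per ul)
  leucocytes = c(9250, 2000), monocytes = c(612, 150),
  lymphocytes = c(2015, 550), basophils = c(31, 15),
  eosinophils = c(140, 80), neutrophils = c(6450, 1600)
)
GEN_SEASON_PROB <- c(winter = 0.24, spring = 0.12, summer = 0.22, autumn = 0.42)

#' Generate a synthetic breath cohort
#'
#' Log10 intensities are
#' `baseline(feature) + class_effect * case * discriminant + season_effect +
#' zone_effect + N(0, noise_sd_log)`; intensities are `10^log10`. Each breath
#' sample gets one ambient partner at `ambient_fraction` of its baseline
#' level (no class effect), 10x that for the ambient-dominant features.
#' Cases are A-AD; controls split between NA-AD and NA-NAD. The
#' train/validation split is stratified by class. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return An object of class `breath_cohort`: `table` (a [feature_table()]
#'   with breath then ambient rows), `sample_meta`, `feature_meta`, `truth`
#'   (ground truth: `discriminant_ids`, `contaminant_ids`,
#'   `ambient_dominant_ids`, `true_betas`, `sample_assignments`), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  p <- config$n_features

  feat_ids <- sprintf("F%03d", seq_len(p))
  roles <- sample(feat_ids, config$n_discriminant + config$n_contaminants +
                    config$n_ambient_dominant)
  disc_ids <- roles[seq_len(config$n_discriminant)]
  cont_ids <- roles[config$n_discriminant + seq_len(config$n_contaminants)]
  ambd_ids <- roles[config$n_discriminant + config$n_contaminants +
                      seq_len(config$n_ambient_dominant)]

  cont_class <- rep_len(c("bag_artifact", "pump_oil", "siloxane"),
                        config$n_contaminants)
  cont_names <- rep_len(c("N,N-dimethylacetamide", "phenol",
                          "hexadecane (pump oil)",
                          "hexamethylcyclotrisiloxane"),
                        config$n_contaminants)
  feature_meta <- data.frame(
    feature_id = feat_ids,
    retention_time = round(sort(stats::runif(p, 60, 1800)), 1),
    quant_mz = round(stats::runif(p, 30, 250), 1),
    compound_name = NA_character_,
    cas_number = NA_character_,
    contaminant_class = "none",
    stringsAsFactors = FALSE
  )
  feature_meta$contaminant_class[match(cont_ids, feat_ids)] <- cont_class
  feature_meta$compound_name[match(cont_ids, feat_ids)] <- cont_names
  feature_meta <- as_feature_meta(feature_meta)

  is_case <- c(rep(1L, config$n_case), rep(0L, config$n_control))
  category <- ifelse(is_case == 1L, "A-AD",
                     ifelse(stats::runif(n) < config$prop_na_ad, "NA-AD", "NA-NAD"))
  category[is_case == 0L & !category %in% c("NA-AD", "NA-NAD")] <- "NA-NAD"
  season <- sample(names(GEN_SEASON_PROB), n, replace = TRUE,
                   prob = GEN_SEASON_PROB)
  zone <- sample(sprintf("Z%d", seq_len(config$n_zones)), n, replace = TRUE)

  baseline <- stats::runif(p, 4, 6) # log10 relative intensity
  season_eff <- matrix(stats::rnorm(4L * p, 0, config$season_effect_sd), 4L, p,
                       dimnames = list(SEASON_LEVELS, feat_ids))
  zone_eff <- matrix(stats::rnorm(config$n_zones * p, 0, config$zone_effect_sd),
                     config$n_zones, p,
                     dimnames = list(sprintf("Z%d", seq_len(config$n_zones)),
                                     feat_ids))
  class_shift <- config$effect_log2 * log10(2)

  mu <- matrix(baseline, n, p, byrow = TRUE) +
    season_eff[season, , drop = FALSE] + zone_eff[zone, , drop = FALSE]
  mu_breath <- mu
  jd <- match(disc_ids, feat_ids)
  mu_breath[, jd] <- mu_breath[, jd] + class_shift * is_case
  log_breath <- mu_breath + matrix(stats::rnorm(n * p, 0, config$noise_sd_log), n, p)

  mu_amb <- mu + log10(max(config$ambient_fraction, 1e-6))
  ja <- match(ambd_ids, feat_ids)
  mu_amb[, ja] <- mu_amb[, ja] + 1 # ambient-dominant: 10x
  log_amb <- mu_amb + matrix(stats::rnorm(n * p, 0, config$noise_sd_log), n, p)

  breath_ids <- sprintf("B%03d", seq_len(n))
  amb_ids <- sprintf("A%03d", seq_len(n))
  pair_keys <- sprintf("P%03d", seq_len(n))
  subject_ids <- sprintf("S%03d", seq_len(n))

  intens <- rbind(10^log_breath, 10^log_amb)
  tab <- feature_table(intens, c(breath_ids, amb_ids), feat_ids)

  # stratified validation split on breath samples
  split <- rep("train", n)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(is_case == cls))
    n_val <- round(config$validation_fraction * length(idx))
    split[idx[seq_len(n_val)]] <- "validation"
  }

  covs <- generate_covariates(category, config$covariate_effects)

  meta_breath <- data.frame(
    sample_id = breath_ids, subject_id = subject_ids, sample_type = "breath",
    pair_key = pair_keys, category = category, season = season, zone = zone,
    split = split, stringsAsFactors = FALSE
  )
  meta_breath <- cbind(meta_breath, covs)
  meta_amb <- data.frame(
    sample_id = amb_ids, subject_id = subject_ids, sample_type = "ambient",
    pair_key = pair_keys, category = NA_character_, season = season,
    zone = zone, split = split, stringsAsFactors = FALSE
  )
  for (cv in colnames(covs)) meta_amb[[cv]] <- NA_real_
  sample_meta <- as_sample_meta(rbind(meta_breath, meta_amb))

  true_betas <- c(
    setNames(rep(class_shift, length(disc_ids)), disc_ids),
    config$covariate_effects
  )
  truth <- list(
    discriminant_ids = disc_ids, contaminant_ids = cont_ids,
    ambient_dominant_ids = ambd_ids, true_betas = true_betas,
    sample_assignments = data.frame(
      sample_id = breath_ids, class = ifelse(is_case == 1L, "case", "control"),
      category = category, season = season, zone = zone, split = split,
      stringsAsFactors = FALSE
    )
  )
  structure(
    list(table = tab, sample_meta = sample_meta, feature_meta = feature_meta,
         truth = truth, config = config),
    class = "breath_cohort"
  )
}

# class-conditional clinical covariates; atopy flags are structural:
# NA-NAD carries none, A-AD / NA-AD carry at least one
generate_covariates <- function(category, effects) {
  n <- length(category)
  is_case <- category == "A-AD"
  out <- data.frame(row.names = seq_len(n))
  for (cv in names(GEN_PARENTAL_BASE)) {
    eff <- if (cv %in% names(effects)) effects[[cv]] else 0
    pr <- stats::plogis(stats::qlogis(GEN_PARENTAL_BASE[[cv]]) + eff * is_case)
    out[[cv]] <- stats::rbinom(n, 1L, pr)
  }
  for (cv in names(GEN_ATOPIC_BASE_NAAD)) {
    eff <- if (cv %in% names(effects)) effects[[cv]] else 0
    pr <- stats::plogis(stats::qlogis(GEN_ATOPIC_BASE_NAAD[[cv]]) + eff * is_case)
    v <- stats::rbinom(n, 1L, pr)
    v[category == "NA-NAD"] <- 0L
    out[[cv]] <- v
  }
  # guarantee the category definition: atopic subjects carry >= 1 flag
  flags <- as.matrix(out[names(GEN_ATOPIC_BASE_NAAD)])
  none <- rowSums(flags) == 0L & category %in% c("A-AD", "NA-AD")
  out$allergic_rhinitis[none] <- 1L
  for (cv in names(GEN_WBC_MOMENTS)) {
    m <- GEN_WBC_MOMENTS[[cv]]
    eff <- if (cv %in% names(effects)) effects[[cv]] else 0
    out[[cv]] <- round(pmax(stats::rnorm(n, m[1] + eff * is_case, m[2]), 0))
  }
  out
}

#' @export
print.breath_cohort <- function(x, ...) {
  n <- nrow(x$truth$sample_assignments)
  cat("<breath_cohort> ", n, " breath + ", n, " ambient samples x ",
      x$config$n_features, " features (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Benchmark generator configurations
#'
#' Three named, seeded configurations used by the packaged benchmark and
#' acceptance suites, differing only in planted effect size: `null`
#' (effect_log2 = 0), `moderate` (1.0) and `strong` (2.0), each with 3
#' discriminant features among 24, a marked case/control imbalance (20 cases
#' vs 80 controls, ~14 vs ~56 in the stratified training split), 2 annotated
#' contaminants and 3 ambient-dominant features. These are reduced-scale
#' cohorts: the permutation-calibration suite rebuilds the entire
#' cross-validated model ~20,000 times, so the benchmarks are sized for that
#' while keeping the structure (imbalance, batch effects, paired ambient
#' samples) of the full-scale generator defaults.
#'
#' @param profile which profile(s) to return; defaults to all three.
#' @return a named list of [generator_config()] objects.
#' @export
benchmark_suite <- function(profile = c("null", "moderate", "strong")) {
  profile <- match.arg(profile, several.ok = TRUE)
  effects <- c(null = 0, moderate = 1, strong = 2)
  seeds <- c(null = 1101L, moderate = 1102L, strong = 1103L)
  setNames(lapply(profile, function(pr) {
    generator_config(
      n_case = 20L, n_control = 80L, n_features = 24L, n_discriminant = 3L,
      effect_log2 = effects[[pr]], n_contaminants = 2L,
      n_ambient_dominant = 3L, validation_fraction = 0.3,
      seed = seeds[[pr]]
    )
  }), profile)
}
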
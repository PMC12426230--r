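# Small in-code fixtures. All cohorts are generated programmatically; sizes
# are kept modest so the default test run stays fast.

# 11-protein panel (the named proteins incl. the two duplicate bases).
tiny_lod_map <- function(extra = NULL) {
  proteins <- panel_protein_names(11L)
  m <- stats::setNames(rep(0.02, length(proteins)), proteins)
  if (!is.null(extra)) m[names(extra)] <- extra
  m
}

tiny_fit_config <- function(seed = 1L, n = 240L, missing_fraction = 0.01,
                            lod_quantile_map = tiny_lod_map(), ...) {
  kora_fit_config(seed = seed, n_participants = n, n_proteins = 11L,
                  lod_quantile_map = lod_quantile_map,
                  missing_fraction = missing_fraction,
                  contamination = c(fraction = 0, offset_sd = 0), ...)
}

tiny_age1_config <- function(seed = 2L, n = 260L, missing_fraction = 0.01,
                             lod_quantile_map = tiny_lod_map(), ...) {
  kora_age1_config(seed = seed, n_participants = n, n_proteins = 11L,
                   lod_quantile_map = lod_quantile_map,
                   missing_fraction = missing_fraction,
                   contamination = c(fraction = 0, offset_sd = 0), ...)
}

# Clean world: no confounding, no censoring, no duplicates, no missingness.
clean_config <- function(seed = 1L, n = 300L,
                         effect_map = c(TRANCE = 0.21),
                         noise_sd = 1, prevalence = 0.3, ...) {
  cohort_config(n_participants = n, statin_prevalence = prevalence,
                covariate_spec = default_covariate_spec("fit"),
                confounding_weights = c(age = 0),
                n_proteins = 3L, effect_map = effect_map,
                protein_noise_sd = noise_sd,
                seed = seed, study_label = "clean", ...)
}

make_assay <- function(values, name = "P1", lod = -Inf, mask = NULL,
                       cv = NA_real_, group = NA_character_) {
  protein_assay(name, values, lod = lod, below_lod_mask = mask,
                inter_assay_cv = cv, duplicate_group = group)
}

# Minimal hand-built cohort for descriptives tests.
toy_cohort <- function() {
  pt <- data.frame(
    participant_id = sprintf("T-%02d", 1:6),
    statin_use = c(1, 1, 1, 0, 0, 0),
    age = c(70, 66, 68, 60, 62, 58),
    sex = factor(c("male", "male", "female", "female", "female", "male"),
                 levels = c("male", "female")),
    bmi = c(31, 29, 30, 25, 26, 27),
    systolic_bp = c(140, 130, 135, 120, 118, 125),
    alcohol = c(0, 5, 10, 5, 20, 0),
    diabetes = c(1, 0, 1, 0, 0, 0),
    smoking = factor(rep(c("never", "previous", "current"), 2),
                     levels = c("never", "previous", "current")),
    physical_activity = factor(rep(c("little_or_not", "regular_1h"), 3),
                               levels = c("little_or_not", "irregular_1h",
                                          "regular_1h", "regular_2h")),
    education = factor(rep(c("low", "middle", "high"), 2),
                       levels = c("low", "middle", "high")),
    hypertension = c(1, 1, 0, 0, 1, 0),
    myocardial_infarction = c(0, 0, 0, 0, 0, 0),
    stroke = c(0, 0, 0, 0, 0, 0),
    cancer = c(0, 1, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  structure(list(study_label = "toy", participants = pt, panel = list(),
                 truth = NULL, config = NULL), class = "pleio_cohort")
}

# Model frame straight from a clean generated cohort (protein TRANCE).
clean_frame <- function(seed = 1L, n = 300L, ...) {
  co <- generate_cohort(clean_config(seed = seed, n = n, ...))
  build_model_frame(co, "TRANCE")
}
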
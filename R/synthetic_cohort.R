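## Synthetic two-cohort generator ---------------------------------------------
##
## Emulates the statistical structure the association pipeline assumes: two
## population-based cohorts with a confounded binary statin exposure, a panel
## of ~90 inflammation proteins on the NPX (log2) scale, limit-of-detection
## left-censoring, duplicate assays, heavy-tail contamination, and MCAR
## covariate missingness.

.continuous_covariates  <- c("age", "bmi", "systolic_bp", "alcohol")
.categorical_covariates <- c("sex", "diabetes", "smoking",
                             "physical_activity", "education")
.clinical_flags <- c("hypertension", "myocardial_infarction", "stroke", "cancer")

.smoking_levels   <- c("never", "previous", "current")
.activity_levels  <- c("little_or_not", "irregular_1h", "regular_1h", "regular_2h")
.education_levels <- c("low", "middle", "high")
.sex_levels       <- c("male", "female")

.participant_columns <- c("participant_id", "statin_use", "age", "sex", "bmi",
                          "systolic_bp", "alcohol", "diabetes", "smoking",
                          "physical_activity", "education", "hypertension",
                          "myocardial_infarction", "stroke", "cancer")

#' Construct a single protein assay
#'
#' An assay bundles one protein's NPX values (log2 scale, may be negative)
#' with its limit of detection (LOD), the below-LOD indicator, the
#' inter-assay coefficient of variation, and an optional duplicate group.
#'
#' @param protein_name Assay name (unique within a panel).
#' @param values Numeric NPX values, one per participant (NA = missing).
#' @param lod Limit of detection on the NPX scale.
#' @param below_lod_mask Logical vector, TRUE where the pre-imputation value
#'   fell strictly below `lod`.
#' @param inter_assay_cv Inter-assay coefficient of variation (percent).
#' @param duplicate_group Optional group label shared by duplicate assays of
#'   the same protein.
#' @return An object of class `protein_assay`.
#' @export
protein_assay <- function(protein_name, values, lod = -Inf,
                          below_lod_mask = NULL, inter_assay_cv = NA_real_,
                          duplicate_group = NA_character_) {
  if (!is.character(protein_name) || length(protein_name) != 1L) {
    abort_config("field 'protein_name' must be a single string")
  }
  values <- as.numeric(values)
  if (is.null(below_lod_mask)) below_lod_mask <- !is.na(values) & values < lod
  if (length(below_lod_mask) != length(values)) {
    abort_config("'below_lod_mask' and 'values' lengths differ for %s",
                 protein_name)
  }
  structure(list(protein_name = protein_name, values = values, lod = lod,
                 below_lod_mask = as.logical(below_lod_mask),
                 inter_assay_cv = as.numeric(inter_assay_cv),
                 duplicate_group = duplicate_group),
            class = "protein_assay")
}

#' Default panel protein names
#'
#' The first names are the inflammation-panel proteins the analysis singles
#' out (TRANCE/RANKL, TRAIL, SCF, ...); the remainder are generic
#' placeholders `INFxx`.
#'
#' @param n Number of unique proteins.
#' @return Character vector of length `n`.
#' @export
panel_protein_names <- function(n = 90L) {
  core <- c("TRANCE", "TRAIL", "SCF", "NT-3", "MMP-10", "uPA", "CD244",
            "GDNF", "PDL1", "IL6", "CXCL8")
  if (n <= length(core)) return(core[seq_len(n)])
  c(core, sprintf("INF%02d", seq_len(n - length(core))))
}

#' Cohort generator configuration
#'
#' Full recipe for one synthetic cohort. Defaults are inherited by the two
#' study presets [kora_fit_config()] and [kora_age1_config()]; see those for
#' cohort-calibrated values.
#'
#' @param n_participants Cohort size.
#' @param statin_prevalence Target statin-use fraction in (0, 1).
#' @param covariate_spec Per-covariate distribution parameters (see
#'   [default_covariate_spec()]).
#' @param confounding_weights Named coefficients of (standardized) covariates
#'   in the statin-assignment logit; the intercept is calibrated so the
#'   expected prevalence equals `statin_prevalence`.
#' @param n_proteins Number of unique proteins in the panel.
#' @param effect_map Named numeric vector: protein -> planted statin effect
#'   on NPX (log2 units).
#' @param protein_noise_sd Default residual NPX noise SD.
#' @param noise_sd_map Named per-protein overrides of `protein_noise_sd`.
#' @param protein_intercept_sd SD of the per-protein intercept hyperprior.
#' @param protein_covariate_sd SD of the per-protein covariate-loading
#'   hyperprior (loadings act on standardized covariates).
#' @param protein_covariate_mean Mean of the covariate-loading hyperprior
#'   (nonzero values make covariates systematic confounders of every
#'   protein, e.g. for confounding-recovery experiments).
#' @param lod_quantile_map Named vector: protein -> target below-LOD fraction.
#' @param duplicate_spec List of duplicate-assay recipes, each a list with
#'   fields `protein`, `cv_a`, `cv_b`, `below_lod_a`, `below_lod_b`.
#' @param contamination Length-2 vector `c(fraction, offset_sd)`: fraction of
#'   entries per assay shifted by `offset_sd` residual SDs.
#' @param missing_fraction MCAR missingness rate applied to covariate cells.
#' @param flag_spec Clinical-flag recipes: per flag `c(base, statin_or)`
#'   (baseline prevalence and statin odds ratio).
#' @param seed Integer RNG seed.
#' @param study_label Cohort label used in outputs.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants, statin_prevalence,
                          covariate_spec = default_covariate_spec(),
                          confounding_weights = c(age = 0),
                          n_proteins = 90L,
                          effect_map = c(TRANCE = 0.21, TRAIL = 0.09, SCF = -0.11),
                          protein_noise_sd = 1,
                          noise_sd_map = numeric(),
                          protein_intercept_sd = 0.3,
                          protein_covariate_sd = 0.05,
                          protein_covariate_mean = 0,
                          lod_quantile_map = numeric(),
                          duplicate_spec = list(),
                          contamination = c(fraction = 0, offset_sd = 0),
                          missing_fraction = 0,
                          flag_spec = default_flag_spec(),
                          seed = 1L,
                          study_label = "cohort") {
  n_participants <- check_count(n_participants, "n_participants")
  check_fraction(statin_prevalence, "statin_prevalence",
                 lo_open = TRUE, hi_open = TRUE)
  n_proteins <- check_count(n_proteins, "n_proteins")
  check_fraction(contamination[[1]], "contamination.fraction", hi = 0.5,
                 hi_open = TRUE)
  check_fraction(missing_fraction, "missing_fraction", hi_open = TRUE)
  if (protein_noise_sd < 0) abort_config("field 'protein_noise_sd' must be >= 0")
  proteins <- panel_protein_names(n_proteins)
  bad <- setdiff(names(effect_map), proteins)
  if (length(bad)) {
    abort_config("field 'effect_map' names unknown proteins: %s",
                 paste(bad, collapse = ", "))
  }
  bad <- setdiff(names(lod_quantile_map), proteins)
  if (length(bad)) {
    abort_config("field 'lod_quantile_map' names unknown proteins: %s",
                 paste(bad, collapse = ", "))
  }
  for (d in duplicate_spec) {
    if (!d$protein %in% proteins) {
      abort_config("field 'duplicate_spec' names unknown protein: %s", d$protein)
    }
  }
  for (f in lod_quantile_map) check_fraction(f, "lod_quantile_map")
  structure(list(
    n_participants = n_participants, statin_prevalence = statin_prevalence,
    covariate_spec = covariate_spec, confounding_weights = confounding_weights,
    n_proteins = n_proteins, proteins = proteins, effect_map = effect_map,
    protein_noise_sd = protein_noise_sd, noise_sd_map = noise_sd_map,
    protein_intercept_sd = protein_intercept_sd,
    protein_covariate_sd = protein_covariate_sd,
    protein_covariate_mean = protein_covariate_mean,
    lod_quantile_map = lod_quantile_map, duplicate_spec = duplicate_spec,
    contamination = c(fraction = unname(contamination[[1]]),
                      offset_sd = unname(contamination[[2]])),
    missing_fraction = missing_fraction, flag_spec = flag_spec,
    seed = as.integer(seed), study_label = study_label
  ), class = "cohort_config")
}

#' Default covariate generating distributions
#'
#' Shifted-normal / log-normal families parameterized to match published
#' median/IQR marginals; categorical probabilities from published relative
#' frequencies. `cohort` selects the calibration.
#'
#' @param cohort `"fit"` (discovery) or `"age1"` (replication).
#' @return Named list of per-covariate parameter lists.
#' @export
default_covariate_spec <- function(cohort = c("fit", "age1")) {
  cohort <- match.arg(cohort)
  if (cohort == "fit") {
    list(
      age = list(dist = "normal", mean = 62.6, sd = 7.4, min = 54, max = 75),
      bmi = list(dist = "lognormal", meanlog = log(27.4), sdlog = 0.18),
      systolic_bp = list(dist = "normal", mean = 123, sd = 15, min = 80),
      alcohol = list(dist = "zero_lognormal", p_zero = 0.28,
                     meanlog = 2.55, sdlog = 1.6),
      sex = c(male = 0.461, female = 0.539),
      diabetes = 0.084,
      smoking = c(never = 0.43, previous = 0.43, current = 0.14),
      physical_activity = c(little_or_not = 0.172, irregular_1h = 0.126,
                            regular_1h = 0.327, regular_2h = 0.375),
      education = c(low = 0.365, middle = 0.433, high = 0.202)
    )
  } else {
    list(
      age = list(dist = "normal", mean = 76, sd = 8.2, min = 65, max = 94),
      bmi = list(dist = "lognormal", meanlog = log(27.9), sdlog = 0.14),
      systolic_bp = list(dist = "normal", mean = 137, sd = 19, min = 80),
      alcohol = list(dist = "zero_lognormal", p_zero = 0.28,
                     meanlog = 2.4, sdlog = 1.55),
      sex = c(male = 0.498, female = 0.502),
      diabetes = 0.177,
      smoking = c(never = 0.539, previous = 0.415, current = 0.046),
      physical_activity = c(little_or_not = 0.343, irregular_1h = 0.133,
                            regular_1h = 0.241, regular_2h = 0.283),
      education = c(low = 0.642, middle = 0.249, high = 0.109)
    )
  }
}

#' @rdname default_covariate_spec
#' @export
default_flag_spec <- function(cohort = c("fit", "age1")) {
  cohort <- match.arg(cohort)
  if (cohort == "fit") {
    list(hypertension = c(base = 0.43, statin_or = 3.2),
         myocardial_infarction = c(base = 0.010, statin_or = 16),
         stroke = c(base = 0.011, statin_or = 11),
         cancer = c(base = 0.114, statin_or = 1.3))
  } else {
    list(hypertension = c(base = 0.725, statin_or = 1.7),
         myocardial_infarction = c(base = 0.055, statin_or = 5),
         stroke = c(base = 0.074, statin_or = 1.8),
         cancer = c(base = 0.148, statin_or = 0.8))
  }
}

#' Discovery-cohort (KORA-Fit-like) generator preset
#'
#' n = 855 with 16.1% statin prevalence; citrate-plasma-like censoring (18
#' generic proteins planted above the 25% below-LOD exclusion rule so panel
#' QC retains 72 of 90 unique proteins); planted statin effects
#' TRANCE +0.21, TRAIL +0.09, SCF -0.11 NPX. Per-protein residual SDs for the
#' three named proteins are back-derived from the published confidence-interval
#' half-widths; all other proteins have unit SD (NPX is SD-normalized).
#'
#' @param seed RNG seed.
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
kora_fit_config <- function(seed = 1L, ...) {
  proteins <- panel_protein_names(90L)
  generic <- grep("^INF", proteins, value = TRUE)
  lod_map <- stats::setNames(rep(0.02, length(proteins)), proteins)
  lod_map[generic[seq_len(18)]] <- seq(0.30, 0.55, length.out = 18)
  defaults <- list(
    n_participants = 855L, statin_prevalence = 0.161,
    covariate_spec = default_covariate_spec("fit"),
    confounding_weights = c(age = 0.45, bmi = 0.20, sex_male = 0.25,
                            diabetes = 1.10),
    n_proteins = 90L,
    effect_map = c(TRANCE = 0.21, TRAIL = 0.09, SCF = -0.11),
    protein_noise_sd = 1,
    noise_sd_map = c(TRANCE = 0.69, TRAIL = 0.33, SCF = 0.44),
    lod_quantile_map = lod_map,
    duplicate_spec = list(
      list(protein = "IL6", cv_a = 8.5, cv_b = 12.0,
           below_lod_a = 2L, below_lod_b = 5L),
      list(protein = "CXCL8", cv_a = 7.0, cv_b = 9.0,
           below_lod_a = 3L, below_lod_b = 3L)
    ),
    contamination = c(fraction = 0.002, offset_sd = 12),
    missing_fraction = 0.0045,
    flag_spec = default_flag_spec("fit"),
    seed = seed, study_label = "KORA-Fit"
  )
  dots <- list(...)
  defaults[names(dots)] <- dots  # plain replacement, never a recursive merge
  do.call(cohort_config, defaults)
}

#' Replication-cohort (KORA-Age1-like) generator preset
#'
#' n = 1079 with 27.4% statin prevalence; EDTA-plasma-like censoring (no
#' protein above the 25% rule, so QC retains all 90 unique proteins); planted
#' effects TRANCE +0.13, TRAIL +0.09, SCF -0.11 NPX.
#'
#' @inheritParams kora_fit_config
#' @return A `cohort_config`.
#' @export
kora_age1_config <- function(seed = 2L, ...) {
  proteins <- panel_protein_names(90L)
  lod_map <- stats::setNames(rep(0.02, length(proteins)), proteins)
  defaults <- list(
    n_participants = 1079L, statin_prevalence = 0.274,
    covariate_spec = default_covariate_spec("age1"),
    confounding_weights = c(age = 0.05, bmi = 0.05, diabetes = 0.70),
    n_proteins = 90L,
    effect_map = c(TRANCE = 0.13, TRAIL = 0.09, SCF = -0.11),
    protein_noise_sd = 1,
    noise_sd_map = c(TRANCE = 0.60, TRAIL = 0.30, SCF = 0.41),
    lod_quantile_map = lod_map,
    duplicate_spec = list(
      list(protein = "IL6", cv_a = 8.5, cv_b = 12.0,
           below_lod_a = 2L, below_lod_b = 5L),
      list(protein = "CXCL8", cv_a = 7.0, cv_b = 9.0,
           below_lod_a = 3L, below_lod_b = 3L)
    ),
    contamination = c(fraction = 0.002, offset_sd = 12),
    missing_fraction = 0.0036,
    flag_spec = default_flag_spec("age1"),
    seed = seed, study_label = "KORA-Age1"
  )
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(cohort_config, defaults)
}

.draw_continuous <- function(n, sp) {
  x <- switch(sp$dist,
    normal = stats::rnorm(n, sp$mean, sp$sd),
    lognormal = stats::rlnorm(n, sp$meanlog, sp$sdlog),
    zero_lognormal = ifelse(stats::runif(n) < sp$p_zero, 0,
                            stats::rlnorm(n, sp$meanlog, sp$sdlog)),
    abort_config("unknown covariate distribution '%s'", sp$dist)
  )
  if (!is.null(sp$min)) x <- pmax(x, sp$min)
  if (!is.null(sp$max)) x <- pmin(x, sp$max)
  x
}

.draw_categorical <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

## Standardized confounder design used by the statin-assignment logit and the
## protein covariate loadings. Columns: age, bmi, systolic_bp, alcohol
## (scaled), sex_male, diabetes.
.confounder_matrix <- function(participants) {
  zscale <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(x * 0)
    (x - mean(x)) / s
  }
  cbind(age = zscale(participants$age),
        bmi = zscale(participants$bmi),
        systolic_bp = zscale(participants$systolic_bp),
        alcohol = zscale(participants$alcohol),
        sex_male = as.numeric(participants$sex == "male"),
        diabetes = as.numeric(participants$diabetes))
}

#' Generate one synthetic cohort
#'
#' Deterministic given `config$seed`. Statin use is assigned by a logistic
#' model on (standardized) covariates with the configured confounding
#' weights and a calibrated intercept; each protein's NPX is
#' intercept + covariate loadings + planted statin effect + Gaussian noise;
#' censoring, duplicate assays, contamination and MCAR covariate missingness
#' are applied per the config. The planted effect map is stored in
#' `$truth` so recovery is testable.
#'
#' @param config A [cohort_config()].
#' @return An object of class `pleio_cohort`: list with `study_label`,
#'   `participants` (data.frame), `panel` (list of `protein_assay`), `truth`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_config("field 'config' must be a cohort_config")
  }
  set.seed(config$seed)
  n <- config$n_participants
  sp <- config$covariate_spec

  participants <- data.frame(
    participant_id = sprintf("%s-%05d", gsub("[^A-Za-z0-9]", "",
                                             config$study_label), seq_len(n)),
    age = .draw_continuous(n, sp$age),
    bmi = .draw_continuous(n, sp$bmi),
    systolic_bp = .draw_continuous(n, sp$systolic_bp),
    alcohol = .draw_continuous(n, sp$alcohol),
    stringsAsFactors = FALSE
  )
  participants$sex <- .draw_categorical(n, sp$sex)
  participants$diabetes <- stats::rbinom(n, 1L, sp$diabetes)
  participants$smoking <- .draw_categorical(n, sp$smoking)
  participants$physical_activity <- .draw_categorical(n, sp$physical_activity)
  participants$education <- .draw_categorical(n, sp$education)

  ## Statin assignment: logit with calibrated intercept.
  Z <- .confounder_matrix(participants)
  w <- config$confounding_weights
  bad <- setdiff(names(w), colnames(Z))
  if (length(bad)) {
    abort_config("field 'confounding_weights' names unknown covariates: %s",
                 paste(bad, collapse = ", "))
  }
  lp <- as.numeric(Z[, names(w), drop = FALSE] %*% w)
  f <- function(b0) mean(stats::plogis(b0 + lp)) - config$statin_prevalence
  b0 <- stats::uniroot(f, c(-30, 30))$root
  participants$statin_use <- stats::rbinom(n, 1L, stats::plogis(b0 + lp))

  ## Clinical flags (descriptives only; never enter the regression models).
  for (fl in .clinical_flags) {
    fs <- config$flag_spec[[fl]]
    if (is.null(fs)) { participants[[fl]] <- NA_integer_; next }
    base_logit <- stats::qlogis(fs[["base"]])
    p <- stats::plogis(base_logit + log(fs[["statin_or"]]) *
                         participants$statin_use +
                         0.3 * Z[, "age"] * (fl != "cancer"))
    participants[[fl]] <- stats::rbinom(n, 1L, p)
  }

  ## Protein panel.
  proteins <- config$proteins
  dup_bases <- vapply(config$duplicate_spec, `[[`, "", "protein")
  noise_sd_for <- function(p) {
    if (p %in% names(config$noise_sd_map)) config$noise_sd_map[[p]]
    else config$protein_noise_sd
  }
  k_load <- ncol(Z)
  panel <- list()
  contam <- config$contamination
  assay_idx <- 0L
  for (p in proteins) {
    intercept <- stats::rnorm(1, 0, config$protein_intercept_sd)
    loadings <- stats::rnorm(k_load, config$protein_covariate_mean,
                             config$protein_covariate_sd)
    beta <- if (p %in% names(config$effect_map)) config$effect_map[[p]] else 0
    signal <- intercept + as.numeric(Z %*% loadings) +
      beta * participants$statin_use
    sdn <- noise_sd_for(p)
    make_assay <- function(name, blod_target, cv, group) {
      assay_idx <<- assay_idx + 1L
      a <- protein_assay(name, signal + stats::rnorm(n, 0, sdn),
                         lod = -Inf,
                         below_lod_mask = rep(FALSE, n),
                         inter_assay_cv = cv, duplicate_group = group)
      if (contam[["fraction"]] > 0) {
        a <- inject_outliers(a, contam[["fraction"]], contam[["offset_sd"]],
                             seed = derive_seed(config$seed, 1000L + assay_idx))
      }
      if (!is.na(blod_target) && blod_target > 0) {
        a <- censor_at_lod(a, blod_target)
      }
      a
    }
    if (p %in% dup_bases) {
      d <- config$duplicate_spec[[match(p, dup_bases)]]
      panel[[paste0(p, "_A")]] <-
        make_assay(paste0(p, "_A"), d$below_lod_a / n, d$cv_a, p)
      panel[[paste0(p, "_B")]] <-
        make_assay(paste0(p, "_B"), d$below_lod_b / n, d$cv_b, p)
    } else {
      target <- if (p %in% names(config$lod_quantile_map)) {
        config$lod_quantile_map[[p]]
      } else NA_real_
      panel[[p]] <- make_assay(p, target, stats::runif(1, 4, 15),
                               NA_character_)
    }
  }

  ## MCAR missingness on covariate cells (exposure kept complete).
  mf <- config$missing_fraction
  if (mf > 0) {
    cols <- c(.continuous_covariates, .categorical_covariates)
    for (cl in cols) {
      miss <- stats::runif(n) < mf
      participants[[cl]][miss] <- NA
    }
  }

  structure(list(study_label = config$study_label,
                 participants = participants,
                 panel = panel,
                 truth = config$effect_map,
                 config = config),
            class = "pleio_cohort")
}

#' @export
print.pleio_cohort <- function(x, ...) {
  cat(sprintf("<pleio_cohort> %s: %d participants, %d assays (%d statin users)\n",
              x$study_label, nrow(x$participants), length(x$panel),
              sum(x$participants$statin_use, na.rm = TRUE)))
  invisible(x)
}

#' Left-censor an assay at an empirical quantile
#'
#' Sets the LOD to the empirical `target_fraction` quantile of the values and
#' marks values strictly below it; the values themselves are untouched (LOD
#' substitution happens in QC).
#'
#' @param assay A `protein_assay`.
#' @param target_fraction Target below-LOD fraction in \[0, 1\].
#' @return The censored `protein_assay`.
#' @export
censor_at_lod <- function(assay, target_fraction) {
  check_fraction(target_fraction, "target_fraction")
  v <- assay$values[!is.na(assay$values)]
  if (!length(v)) abort_data("assay %s has no values to censor", assay$protein_name)
  lod <- as.numeric(stats::quantile(v, target_fraction, type = 7, names = FALSE))
  assay$lod <- lod
  assay$below_lod_mask <- !is.na(assay$values) & assay$values < lod
  assay
}

#' Inject offset outliers into an assay
#'
#' Shifts `ceiling(fraction * n)` entries (chosen without replacement under a
#' private seeded RNG stream) by `offset_sd` sample standard deviations. The
#' modified indices are recorded in the `outlier_indices` attribute for test
#' oracles.
#'
#' @param assay A `protein_assay`.
#' @param fraction Fraction of entries to modify, in \[0, 0.5).
#' @param offset_sd Offset in units of the sample SD of the values.
#' @param seed Integer seed for the private RNG stream.
#' @return The modified `protein_assay`.
#' @export
inject_outliers <- function(assay, fraction, offset_sd, seed = 1L) {
  check_fraction(fraction, "fraction", hi = 0.5, hi_open = TRUE)
  if (fraction == 0) return(assay)
  ok <- which(!is.na(assay$values))
  k <- ceiling(fraction * length(ok))
  idx <- with_preserved_seed(seed, sample(ok, k))
  s <- stats::sd(assay$values, na.rm = TRUE)
  assay$values[idx] <- assay$values[idx] + offset_sd * s
  attr(assay, "outlier_indices") <- sort(idx)
  assay
}

## Serialization ---------------------------------------------------------------

#' Write / read a cohort as plain-text tables
#'
#' `write_cohort()` writes `participants.tsv` (fixed column set),
#' `npx_matrix.tsv` (wide; first column participant_id), `assay_meta.tsv`
#' (protein_name, lod, inter_assay_cv, duplicate_group) and `truth.json`
#' into `dir`. `read_cohort()` reconstructs the cohort; the below-LOD mask is
#' recomputed as `values < lod`.
#'
#' @param cohort A `pleio_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a
#'   `pleio_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pt <- cohort$participants
  out <- pt[, .participant_columns]
  write_tsv(out, file.path(dir, "participants.tsv"))
  npx <- data.frame(participant_id = pt$participant_id,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (a in cohort$panel) npx[[a$protein_name]] <- a$values
  write_tsv(npx, file.path(dir, "npx_matrix.tsv"))
  meta <- data.frame(
    protein_name = vapply(cohort$panel, `[[`, "", "protein_name"),
    lod = vapply(cohort$panel, `[[`, 0, "lod"),
    inter_assay_cv = vapply(cohort$panel, `[[`, 0, "inter_assay_cv"),
    duplicate_group = vapply(cohort$panel, `[[`, "", "duplicate_group"),
    stringsAsFactors = FALSE
  )
  write_tsv(meta, file.path(dir, "assay_meta.tsv"))
  write_json_file(as.list(cohort$truth %||% numeric()),
                  file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname write_cohort
#' @param study_label Label for the reconstructed cohort.
#' @export
read_cohort <- function(dir, study_label = basename(dir)) {
  pt <- read_tsv(file.path(dir, "participants.tsv"))
  missing_cols <- setdiff(.participant_columns, names(pt))
  if (length(missing_cols)) {
    abort_data("participant table lacks columns: %s",
               paste(missing_cols, collapse = ", "))
  }
  pt$sex <- factor(pt$sex, levels = .sex_levels)
  pt$smoking <- factor(pt$smoking, levels = .smoking_levels)
  pt$physical_activity <- factor(pt$physical_activity, levels = .activity_levels)
  pt$education <- factor(pt$education, levels = .education_levels)
  npx <- read_tsv(file.path(dir, "npx_matrix.tsv"))
  meta <- read_tsv(file.path(dir, "assay_meta.tsv"))
  if (!identical(npx$participant_id, pt$participant_id)) {
    abort_data("npx matrix and participant table are not row-aligned")
  }
  panel <- list()
  for (i in seq_len(nrow(meta))) {
    nm <- meta$protein_name[i]
    if (!nm %in% names(npx)) abort_data("assay %s absent from npx matrix", nm)
    panel[[nm]] <- protein_assay(
      nm, npx[[nm]], lod = meta$lod[i],
      inter_assay_cv = meta$inter_assay_cv[i],
      duplicate_group = if (is.na(meta$duplicate_group[i])) NA_character_
                        else meta$duplicate_group[i]
    )
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    unlist(jsonlite::read_json(truth_path))
  } else NULL
  structure(list(study_label = study_label, participants = pt,
                 panel = panel, truth = truth, config = NULL),
            class = "pleio_cohort")
}
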
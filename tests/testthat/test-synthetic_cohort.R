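test_that("generation is deterministic given the seed", {
  a <- generate_cohort(tiny_fit_config(seed = 7))
  b <- generate_cohort(tiny_fit_config(seed = 7))
  a$config <- b$config <- NULL
  expect_identical(a, b)
  c <- generate_cohort(tiny_fit_config(seed = 8))
  expect_false(identical(a$participants$age, c$participants$age))
})

test_that("statin prevalence is binomially calibrated without confounding", {
  cfg <- cohort_config(n_participants = 855L, statin_prevalence = 0.161,
                       confounding_weights = c(age = 0), n_proteins = 3L,
                       seed = 42L)
  co <- generate_cohort(cfg)
  count <- sum(co$participants$statin_use)
  bounds <- qbinom(c(0.005, 0.995), 855, 0.161)
  expect_gte(count, bounds[1])
  expect_lte(count, bounds[2])
})

test_that("noise-free construction recovers the planted effect exactly", {
  cfg <- clean_config(seed = 3L, n = 200L, effect_map = c(TRANCE = 0.21),
                      noise_sd = 0, protein_covariate_sd = 0)
  co <- generate_cohort(cfg)
  v <- co$panel$TRANCE$values
  s <- co$participants$statin_use
  expect_equal(mean(v[s == 1]) - mean(v[s == 0]), 0.21, tolerance = 1e-12)
  expect_identical(co$truth, c(TRANCE = 0.21))
})

test_that("censor_at_lod boundary and quantile behavior", {
  a <- make_assay(rnorm(50))
  c0 <- censor_at_lod(a, 0)
  expect_lte(c0$lod, min(a$values))
  expect_false(any(c0$below_lod_mask))
  c1 <- censor_at_lod(a, 1)
  expect_equal(c1$below_lod_mask, a$values < max(a$values))
  set.seed(5)
  orig <- make_assay(rnorm(1000))
  b <- censor_at_lod(orig, 0.3)
  expect_equal(mean(b$below_lod_mask), 0.3, tolerance = 1 / 1000 + 1e-9)
  expect_identical(b$values, orig$values)  # values untouched
  expect_error(censor_at_lod(make_assay(rep(NA_real_, 3)), 0.5),
               class = "pleioscan_data_error")
})

test_that("inject_outliers shifts exactly ceiling(fraction * n) entries", {
  a <- make_assay(rnorm(100))
  expect_identical(inject_outliers(a, 0, 10), a)
  b <- inject_outliers(a, 0.01, 10, seed = 11)
  changed <- which(b$values != a$values)
  expect_length(changed, 1L)
  expect_identical(changed, attr(b, "outlier_indices"))
  expect_equal(b$values[changed] - a$values[changed],
               10 * sd(a$values), tolerance = 1e-12)
  expect_error(inject_outliers(a, 0.5, 10), class = "pleioscan_config_error")
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(0, 0.2), class = "pleioscan_config_error")
  expect_error(cohort_config(100, 1.2), "statin_prevalence",
               class = "pleioscan_config_error")
  expect_error(cohort_config(100, 0.2, n_proteins = 3L,
                             effect_map = c(NOPE = 1)),
               "effect_map", class = "pleioscan_config_error")
  expect_error(cohort_config(100, 0.2, n_proteins = 3L,
                             lod_quantile_map = c(XX = 0.1)),
               "lod_quantile_map", class = "pleioscan_config_error")
  expect_error(cohort_config(100, 0.2, missing_fraction = 1),
               class = "pleioscan_config_error")
})

test_that("cohort round-trips through the plain-text writers", {
  co <- generate_cohort(tiny_fit_config(seed = 9, n = 120L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("participants.tsv", "npx_matrix.tsv", "assay_meta.tsv",
                    "truth.json"))
  back <- read_cohort(dir, study_label = co$study_label)
  expect_identical(names(back$panel), names(co$panel))
  expect_equal(back$panel$TRANCE$values, co$panel$TRANCE$values,
               tolerance = 1e-12)
  expect_equal(back$panel$IL6_A$below_lod_mask, co$panel$IL6_A$below_lod_mask)
  expect_equal(back$participants$age, co$participants$age, tolerance = 1e-12)
  expect_identical(as.character(back$participants$smoking),
                   as.character(co$participants$smoking))
  expect_equal(sort(names(back$truth)), sort(names(co$truth)))
})

test_that("no-confounding worlds have balanced covariates; confounded worlds do not", {
  ## weights = 0: two-sample t statistics for age stay small
  tstats <- vapply(1:40, function(s) {
    co <- generate_cohort(clean_config(seed = s, n = 400L))
    with(co$participants, unname(t.test(age[statin_use == 1],
                                        age[statin_use == 0])$statistic))
  }, 0)
  expect_gt(mean(abs(tstats) < 4), 0.97)

  ## strong confounding: naive group difference biased, adjusted estimate not
  err <- t(vapply(1:200, function(s) {
    cfg <- clean_config(seed = s, n = 400L, effect_map = c(TRANCE = 0.3),
                        noise_sd = 0.5,
                        protein_covariate_mean = 0.4,
                        protein_covariate_sd = 0.05)
    cfg$confounding_weights <- c(age = 1.2, bmi = 0.8, diabetes = 1.0)
    co <- generate_cohort(cfg)
    frame <- build_model_frame(co, "TRANCE")
    naive <- unname(diff(tapply(frame$npx, frame$statin_use, mean)))
    fit <- fit_linear_model(frame)
    c(naive = naive - 0.3, adjusted = fit$beta - 0.3)
  }, c(naive = 0, adjusted = 0)))
  expect_gt(abs(mean(err[, "naive"])), 3 * abs(mean(err[, "adjusted"])))
})
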
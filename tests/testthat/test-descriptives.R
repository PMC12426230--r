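test_that("median_iqr follows the h = (n - 1) p + 1 convention", {
  expect_equal(median_iqr(c(1, 2, 3, 4)),
               c(median = 2.5, q1 = 1.75, q3 = 3.25))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  expect_equal(median_iqr(rep(3.2, 10)), c(median = 3.2, q1 = 3.2, q3 = 3.2))
  expect_equal(median_iqr(c(NA, 1, NA, 5)), c(median = 3, q1 = 2, q3 = 4))
  expect_error(median_iqr(NA_real_), class = "pleioscan_data_error")
})

test_that("wilcoxon exact branch matches full enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_identical(w$method, "exact")
  expect_equal(w$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(w$p_value, wilcox_enumerate(c(1, 2), c(3, 4)), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    mine <- wilcoxon_rank_sum(x, y)
    expect_equal(mine$p_value, wilcox_enumerate(x, y), tolerance = 1e-12)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("wilcoxon large-sample branch matches the standard tie-corrected test", {
  set.seed(22)
  for (i in 1:8) {
    x <- round(rnorm(80), 1); y <- round(rnorm(120, 0.2), 1)  # heavy ties
    mine <- wilcoxon_rank_sum(x, y)
    expect_identical(mine$method, "normal_approximation")
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(wilcoxon_rank_sum(1:60, 1:60)$p_value, 1)
  expect_warning(res <- wilcoxon_rank_sum(rep(1, 5), rep(1, 7)),
                 "zero variance")
  expect_identical(res$p_value, 1)
})

test_that("wilcoxon p is invariant under strictly monotone transforms", {
  set.seed(23)
  x <- rnorm(40); y <- rnorm(50, 0.4)
  p0 <- wilcoxon_rank_sum(x, y)$p_value
  expect_equal(wilcoxon_rank_sum(exp(x), exp(y))$p_value, p0, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(x^3, y^3)$p_value, p0, tolerance = 1e-12)
})

test_that("wilcoxon type-I error is calibrated at the 5% level", {
  set.seed(24)
  rej <- vapply(1:1000, function(i) {
    wilcoxon_rank_sum(rnorm(200), rnorm(200))$p_value < 0.05
  }, logical(1))
  expect_equal(mean(rej), 0.05, tolerance = 0.02)
})

test_that("pearson chi-square: closed-form behavior and published tables", {
  prop <- matrix(c(10, 20, 30, 60), 2)  # proportional rows
  res <- pearson_chi_square(prop)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  refs <- baseline_reference_tables()
  sex <- pearson_chi_square(refs$t1$counts)
  expect_equal(round(sex$p_value, 3), 0.002)
  edu <- pearson_chi_square(refs$t11$counts)
  expect_equal(round(edu$p_value, 3), 0.033)

  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 6), 2, byrow = TRUE)),
               class = "pleioscan_data_error")
  expect_error(pearson_chi_square(matrix(1:3, 3, 1)),
               class = "pleioscan_data_error")
})

test_that("pearson chi-square matches a brute-force oracle on random tables", {
  set.seed(25)
  for (i in 1:1000) {
    tab <- matrix(rpois(sample(c(4, 6, 8), 1), 20) + 1, ncol = 2)
    mine <- pearson_chi_square(tab)
    oracle <- chisq_bruteforce(tab)
    expect_equal(mine$statistic, oracle$statistic, tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-12)
  }
  # and the standard uncorrected implementation on one case
  tab <- matrix(c(80, 58, 314, 403), 2)
  expect_equal(pearson_chi_square(tab)$p_value,
               suppressWarnings(chisq.test(tab, correct = FALSE))$p.value,
               tolerance = 1e-12)
})

test_that("chi-square is permutation-invariant and scales with counts", {
  set.seed(26)
  tab <- matrix(rpois(8, 30) + 1, 4, 2)
  s0 <- pearson_chi_square(tab)$statistic
  expect_equal(pearson_chi_square(tab[sample(4), ])$statistic, s0,
               tolerance = 1e-12)
  expect_equal(pearson_chi_square(tab[, 2:1])$statistic, s0, tolerance = 1e-12)
  expect_equal(pearson_chi_square(tab * 7)$statistic, 7 * s0, tolerance = 1e-9)
})

test_that("build_baseline_table reproduces hand-computed toy values", {
  tab <- build_baseline_table(toy_cohort(),
                              variables = c("age", "sex", "diabetes"))
  age_row <- tab[tab$variable == "age", ]
  expect_identical(age_row$test, "wilcoxon")
  expect_match(age_row$statin_summary, "^68 \\(67; 69\\)$")
  expect_match(age_row$no_statin_summary, "^60 \\(59; 61\\)$")
  expect_identical(age_row$n_used, 6L)

  sex_row <- tab[tab$variable == "sex", ]
  expect_identical(sex_row$test, "chi_square")
  expect_match(sex_row$statin_summary, "male 2 \\(0\\.667\\)")
  expect_equal(sex_row$statistic,
               chisq_bruteforce(matrix(c(2, 1, 1, 2), 2))$statistic,
               tolerance = 1e-12)
})

test_that("baseline table guards degenerate input", {
  co <- toy_cohort()
  co$participants$statin_use <- 0
  expect_error(build_baseline_table(co), class = "pleioscan_data_error")
  expect_error(build_baseline_table(toy_cohort(), variables = "nope"),
               class = "pleioscan_config_error")
})

test_that("baseline table on a generated cohort satisfies its invariants", {
  co <- generate_cohort(tiny_fit_config(seed = 12))
  tab <- build_baseline_table(co)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$n_used <= nrow(co$participants)))
  expect_identical(nrow(tab), 13L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_baseline_table(tab, path)
  expect_identical(nrow(read.delim(path)), nrow(tab))
})
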
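## Baseline-characteristics machinery ------------------------------------------
##
## Median/IQR summaries, two-tailed Wilcoxon rank-sum tests for continuous
## variables and uncorrected Pearson chi-square tests for categorical
## variables, stratified by statin use, with per-variable complete-case
## denominators.

#' Median and interquartile range
#'
#' Quantiles use the linear-interpolation convention h = (n - 1) p + 1
#' (type 7, the common statistical-environment default).
#'
#' @param values Numeric vector; NA dropped.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) abort_data("median_iqr: no non-missing values")
  q <- stats::quantile(v, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value (from the null rank-sum distribution, equivalent to
#' enumeration of all labelings) when both groups have at most 50
#' observations and there are no ties; otherwise the normal approximation
#' with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric samples (NA dropped; both non-empty).
#' @return List with `statistic` (Mann-Whitney U for `x`), `p_value`, and
#'   `method` ("exact" or "normal_approximation").
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort_data("wilcoxon_rank_sum: empty group")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  if (stats::sd(pooled) == 0) {
    warning("wilcoxon_rank_sum: zero variance across both groups", call. = FALSE)
    return(list(statistic = n1 * n2 / 2, p_value = 1, method = "degenerate"))
  }
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1L)
  if (!has_ties && n1 <= 50L && n2 <= 50L) {
    p <- if (U > n1 * n2 / 2) {
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n1, n2)
    }
    return(list(statistic = U, p_value = min(1, p), method = "exact"))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(statistic = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_approximation")
}

#' Pearson chi-square test of independence
#'
#' Classical statistic sum((O - E)^2 / E) with expectations from the margins,
#' df = (r - 1)(c - 1), NO continuity correction, upper-tail chi-square
#' p-value.
#'
#' @param table Matrix of non-negative counts, at least 2 x 2.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(table) {
  O <- as.matrix(table)
  if (nrow(O) < 2L || ncol(O) < 2L) {
    abort_data("pearson_chi_square: need at least a 2x2 table")
  }
  if (any(O < 0) || sum(O) <= 0) {
    abort_data("pearson_chi_square: counts must be non-negative with positive total")
  }
  rm <- rowSums(O); cm <- colSums(O)
  if (any(rm == 0)) {
    lev <- rownames(O)[which(rm == 0)[1]] %||% as.character(which(rm == 0)[1])
    abort_data("pearson_chi_square: zero margin for row level '%s'", lev)
  }
  if (any(cm == 0)) {
    lev <- colnames(O)[which(cm == 0)[1]] %||% as.character(which(cm == 0)[1])
    abort_data("pearson_chi_square: zero margin for column level '%s'", lev)
  }
  E <- outer(rm, cm) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

.default_baseline_variables <- c("age", "bmi", "systolic_bp", "alcohol",
                                 "sex", "diabetes", "smoking",
                                 "physical_activity", "education",
                                 "hypertension", "myocardial_infarction",
                                 "stroke", "cancer")

#' Build a stratified baseline-characteristics table
#'
#' One row per variable, stratified by statin use: continuous variables get
#' median (q1; q3) summaries and a Wilcoxon rank-sum test; categorical
#' variables get count (fraction) summaries and an uncorrected Pearson
#' chi-square test. Denominators are per-variable complete cases.
#'
#' @param cohort A `pleio_cohort`.
#' @param variables Variables to summarize (subset of the participant
#'   columns).
#' @return A data.frame of class `baseline_table` with columns `variable`,
#'   `type`, `statin_summary`, `no_statin_summary`, `test`, `statistic`,
#'   `p_value`, `n_used`.
#' @export
build_baseline_table <- function(cohort, variables = .default_baseline_variables) {
  pt <- cohort$participants
  strat <- pt$statin_use
  if (length(unique(strat[!is.na(strat)])) < 2L) {
    abort_data("stratifier 'statin_use' is degenerate (single level)")
  }
  unknown <- setdiff(variables, names(pt))
  if (length(unknown)) {
    abort_config("unknown baseline variable(s): %s",
                 paste(unknown, collapse = ", "))
  }
  fmt <- function(x) as.character(signif(x, 6))
  rows <- lapply(variables, function(v) {
    x <- pt[[v]]
    ok <- !is.na(x) & !is.na(strat)
    x <- x[ok]; s <- strat[ok]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      m1 <- median_iqr(x[s == 1]); m0 <- median_iqr(x[s == 0])
      w <- wilcoxon_rank_sum(x[s == 1], x[s == 0])
      data.frame(
        variable = v, type = "continuous",
        statin_summary = sprintf("%s (%s; %s)", fmt(m1[1]), fmt(m1[2]), fmt(m1[3])),
        no_statin_summary = sprintf("%s (%s; %s)", fmt(m0[1]), fmt(m0[2]), fmt(m0[3])),
        test = "wilcoxon", statistic = w$statistic, p_value = w$p_value,
        n_used = length(x), stringsAsFactors = FALSE
      )
    } else {
      xf <- if (is.factor(x)) droplevels(x) else factor(x)
      tab <- table(xf, factor(s, levels = c(1, 0)))
      ct <- pearson_chi_square(tab)
      cell <- function(col) {
        paste(sprintf("%s %d (%s)", rownames(tab), tab[, col],
                      formatC(tab[, col] / sum(tab[, col]), digits = 3,
                              format = "f")),
              collapse = "; ")
      }
      data.frame(
        variable = v, type = "categorical",
        statin_summary = cell("1"), no_statin_summary = cell("0"),
        test = "chi_square", statistic = ct$statistic, p_value = ct$p_value,
        n_used = length(x), stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Published baseline contingency tables
#'
#' The categorical baseline-characteristics counts published for the two
#' cohorts (stratified by statin use), shipped as reference data. One entry
#' per target id: a counts matrix (levels x {statin, no_statin}) plus the
#' p-value as printed in the source tables.
#'
#' @return Named list of entries with `cohort`, `variable`, `counts`,
#'   `printed_p` (string).
#' @export
baseline_reference_tables <- function() {
  path <- system.file("extdata", "baseline_reference_counts.tsv",
                      package = "pleioscan")
  if (!nzchar(path)) {
    path <- file.path("inst", "extdata", "baseline_reference_counts.tsv")
  }
  df <- read_tsv(path, colClasses = "character")
  out <- list()
  for (id in unique(df$target_id)) {
    sub <- df[df$target_id == id, ]
    counts <- cbind(statin = as.numeric(sub$statin),
                    no_statin = as.numeric(sub$no_statin))
    rownames(counts) <- sub$level
    out[[id]] <- list(cohort = sub$cohort[1], variable = sub$variable[1],
                      counts = counts, printed_p = sub$printed_p[1])
  }
  out
}

#' Export a baseline table
#'
#' @param table A `baseline_table`.
#' @param path Output file (`.tsv` or `.json` chosen by `format`).
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_baseline_table <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") write_tsv(as.data.frame(table), path)
  else write_json_file(as.data.frame(table), path)
  invisible(path)
}
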
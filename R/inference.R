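## Multiple testing, E-values, replication classification ----------------------

#' Inference configuration
#'
#' @param alpha FDR significance level (a protein is "notable" when its
#'   adjusted p-value q <= alpha).
#' @param fdr_scope Fixed at `"per_study"`: adjustment runs across the
#'   retained proteins within one study, never pooled across studies.
#' @param evalue_effect_scale Fixed at `"standardized_outcome"`: effects are
#'   standardized by the SD of the analyzed (post-filter) outcome before the
#'   risk-ratio approximation.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(alpha = 0.05, fdr_scope = "per_study",
                             evalue_effect_scale = "standardized_outcome") {
  check_fraction(alpha, "alpha", lo_open = TRUE, hi_open = TRUE)
  fdr_scope <- match.arg(fdr_scope, "per_study")
  evalue_effect_scale <- match.arg(evalue_effect_scale, "standardized_outcome")
  structure(list(alpha = alpha, fdr_scope = fdr_scope,
                 evalue_effect_scale = evalue_effect_scale),
            class = "inference_config")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort, compute p_(i) * m / i, enforce
#' monotonicity by the cumulative minimum from the largest rank, cap at 1,
#' restore input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
adjust_fdr_bh <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_data("adjust_fdr_bh: p-values must be in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  ## p * (m/i), not (p*m)/i: at rank m the factor is exactly 1, so the
  ## q >= p invariant survives floating point
  q <- pmin(1, cummin(p[o] * (m / (m:1))))
  q[ro]
}

#' E-value for a continuous-outcome association
#'
#' The effect is standardized (d = beta / outcome_sd), converted to an
#' approximate risk ratio rr = exp(0.91 d), and the E-value computed as
#' rr* + sqrt(rr* (rr* - 1)) with rr* = max(rr, 1/rr). The CI E-value uses
#' the confidence limit closer to the null and is 1 whenever the interval
#' spans 0.
#'
#' @param beta Point estimate (outcome units).
#' @param ci_low,ci_high 95% confidence limits (ci_low <= beta <= ci_high).
#' @param outcome_sd SD of the analyzed outcome (> 0).
#' @return An `evalue_result`: list with `rr_approx`, `ev_point`, `ev_ci`.
#' @export
evalue_from_continuous <- function(beta, ci_low, ci_high, outcome_sd) {
  if (!is.finite(outcome_sd) || outcome_sd <= 0) {
    abort_data("evalue_from_continuous: outcome_sd must be > 0")
  }
  if (ci_low > beta || beta > ci_high) {
    abort_data("evalue_from_continuous: need ci_low <= beta <= ci_high")
  }
  ev_of <- function(effect) {
    rr <- exp(0.91 * effect / outcome_sd)
    rr_star <- max(rr, 1 / rr)
    rr_star + sqrt(rr_star * (rr_star - 1))
  }
  rr <- exp(0.91 * beta / outcome_sd)
  ev_point <- ev_of(beta)
  ev_ci <- if (ci_low <= 0 && ci_high >= 0) {
    1
  } else if (ci_low > 0) {
    ev_of(ci_low)
  } else {
    ev_of(ci_high)
  }
  structure(list(rr_approx = rr, ev_point = ev_point, ev_ci = ev_ci),
            class = "evalue_result")
}

#' Attach q-values, E-values and notability to panel results
#'
#' Runs the per-study BH adjustment over the fitted proteins' p-values,
#' computes E-values on the modeled outcome scale (using each fit's
#' analyzed-outcome SD), and flags proteins with q <= alpha as notable.
#'
#' @param panel A `panel_results` from [run_panel()].
#' @param config An [inference_config()].
#' @return A data.frame of class `association_results`, one row per fitted
#'   protein: beta, se, ci, p, q, E-values, notability, model provenance.
#' @export
annotate_inference <- function(panel, config = inference_config()) {
  if (!inherits(panel, "panel_results")) {
    abort_config("'panel' must be a panel_results object")
  }
  recs <- panel$results
  if (!length(recs)) abort_data("no fitted proteins to annotate")
  fits <- lapply(recs, `[[`, "fit")
  p <- vapply(fits, `[[`, 0, "p_value")
  q <- adjust_fdr_bh(p)
  ev <- Map(function(f) {
    evalue_from_continuous(f$beta, f$ci_low, f$ci_high, f$outcome_sd)
  }, fits)
  out <- data.frame(
    protein = vapply(recs, `[[`, "", "protein"),
    study_label = panel$study_label,
    beta = vapply(fits, `[[`, 0, "beta"),
    se = vapply(fits, `[[`, 0, "se"),
    ci_low = vapply(fits, `[[`, 0, "ci_low"),
    ci_high = vapply(fits, `[[`, 0, "ci_high"),
    p_value = p,
    q_value = q,
    ev_point = vapply(ev, `[[`, 0, "ev_point"),
    ev_ci = vapply(ev, `[[`, 0, "ev_ci"),
    notable = q <= config$alpha,
    transform = vapply(recs, function(r) r$transform$transform, ""),
    n_used = vapply(fits, `[[`, 0L, "n_used"),
    n_outliers_removed = vapply(fits, `[[`, 0L, "n_outliers_removed"),
    n_influential_removed = vapply(fits, `[[`, 0L, "n_influential_removed"),
    knots = vapply(fits, function(f) {
      paste(sprintf("%s=%d", names(f$spec$spline_spec), f$spec$spline_spec),
            collapse = ",")
    }, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("association_results", "data.frame")
  out
}

#' Classify cross-cohort replication
#'
#' Matched on protein name: `replicated` when notable in both studies with
#' equal effect sign; `suggestive` when notable in exactly one with the
#' other study's effect in the same direction; `inconsistent` when the
#' signs differ and at least one study is notable; `null` otherwise.
#' Proteins measured in only one study are classified from that study alone
#' (notable -> suggestive, else null) and flagged `single_study`.
#'
#' @param discovery,replication `association_results` data.frames.
#' @param config An [inference_config()] (unused fields reserved).
#' @return A data.frame of class `replication_verdicts`.
#' @export
classify_replication <- function(discovery, replication,
                                 config = inference_config()) {
  for (d in list(discovery, replication)) {
    if (anyDuplicated(d$protein)) {
      abort_data("duplicate protein keys within a study: %s",
                 paste(unique(d$protein[duplicated(d$protein)]), collapse = ", "))
    }
  }
  keep <- c("protein", "beta", "ci_low", "ci_high", "p_value", "q_value",
            "ev_point", "ev_ci", "notable")
  m <- merge(discovery[keep], replication[keep], by = "protein",
             suffixes = c("_discovery", "_replication"), all = TRUE)
  classify_one <- function(b1, n1, b2, n2) {
    if (is.na(b1) || is.na(b2)) {
      notable <- isTRUE(n1) || isTRUE(n2)
      return(c(if (notable) "suggestive" else "null", TRUE))
    }
    same_sign <- sign(b1) == sign(b2)
    cat_ <- if (n1 && n2) {
      if (same_sign) "replicated" else "inconsistent"
    } else if (n1 || n2) {
      if (same_sign) "suggestive" else "inconsistent"
    } else "null"
    c(cat_, FALSE)
  }
  cls <- t(mapply(classify_one, m$beta_discovery, m$notable_discovery,
                  m$beta_replication, m$notable_replication))
  m$category <- cls[, 1]
  m$single_study <- as.logical(cls[, 2])
  m <- m[order(m$protein), c("protein", "category", "single_study",
                             setdiff(names(m), c("protein", "category",
                                                 "single_study")))]
  rownames(m) <- NULL
  class(m) <- c("replication_verdicts", "data.frame")
  m
}

#' @export
print.replication_verdicts <- function(x, ...) {
  cat("<replication_verdicts>\n")
  print(table(x$category))
  invisible(x)
}
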
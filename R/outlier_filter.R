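## Iterative SD-ratio outlier detection ----------------------------------------
##
## In each iteration the detector removes the lowest or highest remaining
## value whose removal shrinks the sample SD the most, provided the ratio
## s_{n-1}/s_n falls below the threshold (default 0.95). The classical
## mean +/- 3 SD screen is available as a comparator. Safeguards (minimum
## retained n, maximum removal fraction) keep the rule from degenerating on
## small samples; at the cohort sizes the pipeline targets they never bind.

#' Outlier-detector configuration
#'
#' @param ratio_threshold Flag an extreme value when the SD ratio after/before
#'   its removal is below this (default 0.95).
#' @param min_n Never let the retained sample fall below this size.
#' @param max_removal_fraction Cap on the flagged fraction of the initial n.
#' @param comparator `"sd_ratio"` (iterative, default) or `"mean_3sd"`.
#' @return An object of class `outlier_config`.
#' @export
outlier_config <- function(ratio_threshold = 0.95, min_n = 50L,
                           max_removal_fraction = 0.05,
                           comparator = c("sd_ratio", "mean_3sd")) {
  check_fraction(ratio_threshold, "ratio_threshold", lo_open = TRUE,
                 hi_open = TRUE)
  check_fraction(max_removal_fraction, "max_removal_fraction", hi = 0.5,
                 lo_open = TRUE, hi_open = TRUE)
  min_n <- check_count(min_n, "min_n", min = 3L)
  structure(list(ratio_threshold = ratio_threshold, min_n = min_n,
                 max_removal_fraction = max_removal_fraction,
                 comparator = match.arg(comparator)),
            class = "outlier_config")
}

#' One SD-ratio step
#'
#' Computes the sample SD (denominator n - 1) of `values` and of `values`
#' with the single stated extreme removed, and returns the ratio
#' s_{n-1}/s_n plus the candidate value. A zero-variance input returns ratio
#' 1 and no flag.
#'
#' @param values At least 3 finite values.
#' @param end Which extreme to test: `"min"` or `"max"`.
#' @return An `outlier_step`: list with `end`, `s_n`, `s_n_minus_1`, `ratio`,
#'   `flagged_value`, `flagged_index`.
#' @export
sd_ratio_step <- function(values, end = c("max", "min")) {
  end <- match.arg(end)
  if (length(values) < 3L || any(!is.finite(values))) {
    abort_data("sd_ratio_step needs >= 3 finite values")
  }
  s_n <- stats::sd(values)
  if (s_n == 0) {
    return(structure(list(end = end, s_n = 0, s_n_minus_1 = 0, ratio = 1,
                          flagged_value = NULL, flagged_index = NULL),
                     class = "outlier_step"))
  }
  idx <- if (end == "max") which.max(values) else which.min(values)
  s_n1 <- stats::sd(values[-idx])
  structure(list(end = end, s_n = s_n, s_n_minus_1 = s_n1,
                 ratio = s_n1 / s_n, flagged_value = values[idx],
                 flagged_index = idx),
            class = "outlier_step")
}

#' Detect outcome outliers
#'
#' With the `sd_ratio` comparator: in each iteration both ends are tested
#' with [sd_ratio_step()]; if neither ratio is below the threshold the loop
#' stops, otherwise the end with the smaller ratio (ties to the maximum) is
#' flagged and removed. The loop also stops when removal would push the
#' retained n below `min_n` or exceed `max_removal_fraction` of the initial
#' n. With the `mean_3sd` comparator: a single pass flags values outside
#' mean +/- 3 SD.
#'
#' Missing values are ignored (never flagged); non-finite values are an
#' error.
#'
#' @param values Numeric vector (NA allowed).
#' @param config An [outlier_config()].
#' @return List with `flags` (logical, aligned with the input) and `trace`
#'   (list of `outlier_step`, one per iteration, including the final
#'   non-flagging evaluation).
#' @export
detect_outliers <- function(values, config = outlier_config()) {
  keep_na <- is.na(values)
  if (any(!is.finite(values[!keep_na]))) {
    abort_data("detect_outliers: non-finite values in input")
  }
  flags <- rep(FALSE, length(values))
  trace <- list()
  idx_map <- which(!keep_na)
  work <- values[idx_map]
  n0 <- length(work)

  if (config$comparator == "mean_3sd") {
    if (n0 >= 2L) {
      m <- mean(work); s <- stats::sd(work)
      if (s > 0) flags[idx_map[abs(work - m) > 3 * s]] <- TRUE
    }
    return(list(flags = flags, trace = trace))
  }

  max_remove <- floor(config$max_removal_fraction * n0)
  removed <- 0L
  iter <- 0L
  while (length(work) >= 3L) {
    iter <- iter + 1L
    step_max <- sd_ratio_step(work, "max")
    step_min <- sd_ratio_step(work, "min")
    ## ties go to the maximum end
    best <- if (step_min$ratio < step_max$ratio) step_min else step_max
    best$iteration <- iter
    can_remove <- removed < max_remove && (length(work) - 1L) >= config$min_n
    if (best$ratio >= config$ratio_threshold || is.null(best$flagged_index) ||
        !can_remove) {
      best$flagged_value <- NULL
      best$flagged_index <- NULL
      trace[[iter]] <- best
      break
    }
    trace[[iter]] <- best
    flags[idx_map[best$flagged_index]] <- TRUE
    idx_map <- idx_map[-best$flagged_index]
    work <- work[-best$flagged_index]
    removed <- removed + 1L
  }
  list(flags = flags, trace = trace)
}

#' Write an outlier trace as JSON lines
#'
#' One `outlier_step` per line, for audit.
#'
#' @param trace The `trace` element returned by [detect_outliers()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_outlier_trace <- function(trace, path) {
  lines <- vapply(trace, function(s) {
    jsonlite::toJSON(list(
      iteration = s$iteration %||% NA_integer_, end_tested = s$end,
      s_n = s$s_n, s_n_minus_1 = s$s_n_minus_1, ratio = s$ratio,
      flagged_value = s$flagged_value
    ), auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
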
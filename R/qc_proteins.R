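## Panel-level quality control -------------------------------------------------
##
## Rules: exclude proteins with MORE than `max_below_lod_fraction` of their
## non-missing values below the limit of detection (strict inequality, i.e.
## exactly 25% is retained at the default), exclude all-missing proteins,
## resolve duplicate assays (fewer below-LOD values first, lower inter-assay
## CV as tie-break), and substitute below-LOD values with the LOD.

#' QC configuration
#'
#' @param max_below_lod_fraction Exclusion threshold for the below-LOD
#'   fraction (strict inequality), default 0.25.
#' @param substitute_with_lod Substitute below-LOD values with the LOD in the
#'   retained assays (default TRUE).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(max_below_lod_fraction = 0.25, substitute_with_lod = TRUE) {
  check_fraction(max_below_lod_fraction, "max_below_lod_fraction",
                 lo_open = TRUE, hi_open = TRUE)
  structure(list(max_below_lod_fraction = max_below_lod_fraction,
                 substitute_with_lod = isTRUE(substitute_with_lod)),
            class = "qc_config")
}

#' Substitute below-LOD values with the LOD
#'
#' Every masked value is replaced by the assay's LOD; unmasked values are
#' unchanged and the mask is preserved for provenance.
#'
#' @param assay A `protein_assay` with finite `lod`.
#' @return The imputed `protein_assay`.
#' @export
impute_below_lod <- function(assay) {
  if (!is.finite(assay$lod) && any(assay$below_lod_mask)) {
    abort_data("assay %s: LOD must be finite to impute", assay$protein_name)
  }
  sel <- assay$below_lod_mask & !is.na(assay$values)
  assay$values[sel] <- assay$lod
  assay
}

#' Apply panel-level QC to a list of assays
#'
#' @param panel Non-empty list of `protein_assay` objects.
#' @param config A [qc_config()].
#' @return List with elements `panel` (retained assays, imputed when
#'   configured) and `report` (a `qc_report`: `n_input`, `n_retained`,
#'   `excluded` data.frame with reasons in
#'   `{lod_fraction, all_missing, duplicate_dropped}`, and
#'   `duplicate_decisions`).
#' @export
filter_panel <- function(panel, config = qc_config()) {
  if (!length(panel)) abort_data("panel is empty")
  if (!inherits(config, "qc_config")) abort_config("'config' must be a qc_config")
  nm <- vapply(panel, `[[`, "", "protein_name")
  names(panel) <- nm

  excluded <- data.frame(protein_name = character(), reason = character(),
                         stringsAsFactors = FALSE)
  drop <- function(p, why) {
    excluded[nrow(excluded) + 1L, ] <<- list(p, why)
  }

  blod_count <- function(a) sum(a$below_lod_mask & !is.na(a$values))
  keep <- character()
  for (a in panel) {
    n_obs <- sum(!is.na(a$values))
    if (n_obs == 0L) { drop(a$protein_name, "all_missing"); next }
    if (blod_count(a) / n_obs > config$max_below_lod_fraction) {
      drop(a$protein_name, "lod_fraction"); next
    }
    keep <- c(keep, a$protein_name)
  }

  ## Duplicate resolution among survivors.
  groups <- stats::setNames(vapply(panel[keep], `[[`, "", "duplicate_group"),
                            keep)
  dup_decisions <- data.frame(group = character(), kept = character(),
                              dropped = character(), criterion = character(),
                              stringsAsFactors = FALSE)
  for (g in unique(groups[!is.na(groups)])) {
    members <- intersect(keep, names(groups)[!is.na(groups) & groups == g])
    if (length(members) < 2L) next
    counts <- vapply(panel[members], blod_count, 0L)
    cvs <- vapply(panel[members], `[[`, 0, "inter_assay_cv")
    best_count <- members[counts == min(counts)]
    if (length(best_count) == 1L) {
      winner <- best_count
      criterion <- "fewer_below_lod"
    } else {
      cv_sub <- cvs[best_count]
      best_cv <- best_count[cv_sub == min(cv_sub)]
      if (length(best_cv) == 1L) {
        winner <- best_cv
        criterion <- "lower_cv"
      } else {
        winner <- sort(best_cv)[1L]
        criterion <- "lower_cv"
        warning(sprintf(
          "duplicate group '%s': tied below-LOD counts and CVs; keeping '%s' (lexicographic)",
          g, winner), call. = FALSE)
      }
    }
    losers <- setdiff(members, winner)
    for (l in losers) drop(l, "duplicate_dropped")
    keep <- setdiff(keep, losers)
    dup_decisions[nrow(dup_decisions) + 1L, ] <-
      list(g, winner, paste(losers, collapse = ","), criterion)
  }

  retained <- panel[keep]
  if (config$substitute_with_lod) {
    retained <- lapply(retained, impute_below_lod)
  }
  report <- structure(list(
    n_input = length(panel), n_retained = length(retained),
    excluded = excluded, duplicate_decisions = dup_decisions
  ), class = "qc_report")
  stopifnot(report$n_input == report$n_retained + nrow(excluded))
  list(panel = retained, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d assays in, %d retained, %d excluded\n",
              x$n_input, x$n_retained, nrow(x$excluded)))
  if (nrow(x$excluded)) print(table(x$excluded$reason))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  write_json_file(list(
    n_input = report$n_input, n_retained = report$n_retained,
    excluded = report$excluded, duplicate_decisions = report$duplicate_decisions
  ), path)
}
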
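#' @keywords internal
"_PACKAGE"

## Condition helpers -----------------------------------------------------------

abort_config <- function(msg, ...) {
  stop(structure(
    class = c("pleioscan_config_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_data <- function(msg, ...) {
  stop(structure(
    class = c("pleioscan_data_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards. Keeps generator sub-draws independent of the
## order in which surrounding code consumes random numbers.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic 32-bit-safe seed derivation for sub-streams.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483647)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_config("field '%s' must be a single number", name)
  }
  lo_ok <- if (lo_open) x > lo else x >= lo
  hi_ok <- if (hi_open) x < hi else x <= hi
  if (!lo_ok || !hi_ok) {
    abort_config("field '%s' = %g outside %s%g, %g%s", name, x,
                 if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]")
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    abort_config("field '%s' must be an integer >= %d", name, min)
  }
  as.integer(x)
}

## TSV read/write with fixed conventions (tab, header, empty string for NA).
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.15g", x)
    out[is.na(x)] <- NA_character_
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_json_file <- function(x, path) {
  ## digits = I(17): doubles must round-trip exactly (manifest replay)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
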
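# Shared internal helpers: controlled vocabularies, error conditions,
# atomic file writes, percentage formatting.

FEATURE_CATEGORIES <- c("BGC", "DEFENSE_SYSTEM", "CRISPR_ARRAY",
                        "CAS_CLUSTER", "PROPHAGE")

TRIAGE_CLASSES <- c("intact", "questionable", "incomplete", "unscored")

STRAND_VALUES <- c("+", "-", "unknown")

# IUPAC nucleotide one-letter codes (uppercase); U accepted on input.
IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

# Data errors (bad input content) and usage errors (bad invocation) are
# distinct condition classes so the CLI can map them to exit codes 1 and 2.
data_error <- function(...) {
  stop(structure(
    class = c("islescan_data_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

usage_error <- function(...) {
  stop(structure(
    class = c("islescan_usage_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Write through a temp file in the same directory, then rename, so readers
# never observe a half-written output.
atomic_write <- function(path, writer) {
  if (identical(path, "-") || inherits(path, "connection")) {
    writer(if (identical(path, "-")) stdout() else path)
    return(invisible(path))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".islescan-", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Format a percentage for display
#'
#' Rounds half away from zero (so 39.185 prints as "39.19", -0.005 as
#' "-0.01") and formats with a fixed number of decimals. Internal tables
#' always carry full-precision shares; this is display-only.
#'
#' @param x Numeric vector of percentages.
#' @param digits Decimal places to keep (default 2).
#' @return Character vector.
#' @export
#' @examples
#' format_pct(39.18919)
format_pct <- function(x, digits = 2) {
  scale <- 10^digits
  rounded <- sign(x) * floor(abs(x) * scale + 0.5) / scale
  formatC(rounded, format = "f", digits = digits)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    data_error(what, " must be a single string")
  }
}
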
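#' Round half away from zero
#'
#' Rounding used at the reporting layer: ties go away from zero (so 0.5 -> 1,
#' -0.5 -> -1), matching how the published tables print integers, rather than
#' base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Simple leveled logger; WARN-level messages flag model assumptions applied
# at run time (renormalisations, approximate formulas, default cost rules).
brca_log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

# Emit a WARN-level log message at most once per session per key, to keep
# multi-generation loops readable.
.brca_env <- new.env(parent = emptyenv())

brca_log_once <- function(key, level, ...) {
  if (!isTRUE(.brca_env[[key]])) {
    .brca_env[[key]] <- TRUE
    brca_log(level, ...)
  }
  invisible(NULL)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

check_prob <- function(x, name) {
  if (!is_prob(x)) stopf("'%s' must be a single probability in [0, 1], got %s",
                         name, paste(format(x), collapse = ", "))
  invisible(x)
}
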
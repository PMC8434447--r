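# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero (so 0.5 -> 1,
#' -0.5 -> -1), the convention used for all integer percent values in outcome
#' tables. Base `round()` uses round-half-to-even and is not suitable there.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector of the same length.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All stochastic operations in the package go through this
# so no function touches the global stream.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Condition constructors. Validation / data problems exit the CLI with status
# 1; malformed command lines with status 2.
abort_validation <- function(msg, field = NULL) {
  stop(structure(
    class = c("rtp_validation_error", "error", "condition"),
    list(message = msg, call = NULL, field = field)
  ))
}

abort_usage <- function(msg) {
  stop(structure(
    class = c("rtp_usage_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

check_number <- function(x, field, min = -Inf, max = Inf, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort_validation(sprintf("field '%s' is required", field), field)
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_validation(sprintf("field '%s' must be a single number", field), field)
  }
  if (x < min || x > max) {
    abort_validation(
      sprintf("field '%s' = %g outside [%g, %g]", field, x, min, max), field
    )
  }
  invisible(NULL)
}

check_choice <- function(x, field, choices) {
  if (is.null(x) || length(x) != 1L || !(x %in% choices)) {
    abort_validation(sprintf(
      "field '%s' must be one of: %s", field, paste(choices, collapse = ", ")
    ), field)
  }
  invisible(NULL)
}

# Format a double losslessly for the CSV dialect (17 significant digits
# round-trips IEEE doubles); NA -> empty field.
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.17g", x))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
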
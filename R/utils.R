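#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_hf <- function(fmt, ..., class = "hftraj_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_hf("'%s' must be a probability in [0, 1]", name,
            class = "hftraj_validation_error")
  }
  invisible(x)
}

#' Format a count as "num/den (pct%)" with one decimal
#'
#' Cohort summaries report fractions the way clinical tables print them,
#' e.g. `107/534 (20.0%)`.
#'
#' @param num Numerator count.
#' @param den Denominator count.
#' @return Character scalar.
#' @examples
#' format_fraction(107, 534)
#' @export
format_fraction <- function(num, den) {
  sprintf("%d/%d (%s%%)", num, den, formatC(fraction_pct(num, den),
                                            format = "f", digits = 1))
}

#' Percentage of a fraction, rounded to one decimal
#'
#' @param num Numerator.
#' @param den Denominator.
#' @return `round(100 * num / den, 1)`.
#' @export
fraction_pct <- function(num, den) {
  if (den == 0) stop_hf("denominator must be non-zero")
  round(100 * num / den, 1)
}
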
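# Container for a single Bayes factor.

#' Bayes factor result
#'
#' Stores the Bayes factor on the natural-log scale together with the
#' integration-error estimate, reported as a percentage of the Bayes factor
#' (similar to a coefficient of variation). `bf01` is always the exact
#' reciprocal of `bf10`.
#'
#' @param log_bf10 natural log of BF10
#' @param error_pct non-negative relative error estimate in percent, or `NA`
#'   when the quadrature error is below tolerance
#' @param comparison text label, e.g. `"H1 vs H0"` or `"H+ vs H0"`
#' @return an object of class `bf_result`
#' @export
bf_result <- function(log_bf10, error_pct = NA_real_, comparison = "H1 vs H0") {
  stopifnot(is.numeric(log_bf10), length(log_bf10) == 1)
  if (!is.na(error_pct) && error_pct < 0) stop("error_pct must be >= 0", call. = FALSE)
  structure(list(log_bf10 = log_bf10, error_pct = error_pct,
                 comparison = comparison),
            class = "bf_result")
}

#' @rdname bf_result
#' @param x a `bf_result`
#' @export
bf10 <- function(x) {
  stopifnot(inherits(x, "bf_result"))
  exp(x$log_bf10)
}

#' @rdname bf_result
#' @export
bf01 <- function(x) {
  stopifnot(inherits(x, "bf_result"))
  exp(-x$log_bf10)
}

#' @export
print.bf_result <- function(x, ...) {
  lab <- classify_bf(bf10(x))
  cat(sprintf("BF10 = %s  (BF01 = %s)  [%s]\n",
              format_bf(bf10(x)), format_bf(bf01(x)), x$comparison))
  cat(sprintf("  %s; wheel proportion %.3f", lab$label, wheel_proportion(bf10(x))))
  if (!is.na(x$error_pct)) cat(sprintf("; error %% = %.3g", x$error_pct))
  cat("\n")
  invisible(x)
}

#' @export
to_json.bf_result <- function(x, ...) {
  jsonlite::toJSON(list(bf10 = bf10(x), bf01 = bf01(x), log_bf10 = x$log_bf10,
                        error_pct = x$error_pct, comparison = x$comparison,
                        evidence = classify_bf(bf10(x))$label),
                   auto_unbox = TRUE, digits = NA, na = "null", ...)
}
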
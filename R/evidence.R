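# Discrete evidence categories and proportion-wheel values.

evidence_bounds <- c(1, 3, 10, 30, 100)
evidence_names <- c("Anecdotal", "Moderate", "Strong", "Very strong", "Extreme")

#' Classify a Bayes factor into a descriptive evidence category
#'
#' The conventional bands: BF10 above 100 is extreme, 30-100 very strong,
#' 10-30 strong, 3-10 moderate, 1-3 anecdotal evidence for H1, with the
#' reciprocal bands mirroring them for H0, and exactly 1 meaning no evidence.
#' Values on a boundary are assigned to the stronger band. The labels are an
#' approximate descriptive device, not a decision rule: the Bayes factor
#' itself is the continuous measure of evidence.
#'
#' @param bf10 Bayes factor in favour of H1 (> 0)
#' @return list with `category`, `hypothesis` (`"H1"`, `"H0"` or `NA`),
#'   `label` (printable text) and `bounds` (the BF interval covered)
#' @export
#' @examples
#' classify_bf(11.97)$label  # "Strong evidence for H1"
classify_bf <- function(bf10) {
  if (!is.numeric(bf10) || length(bf10) != 1 || is.na(bf10) || bf10 <= 0) {
    stop("`bf10` must be a single positive number", call. = FALSE)
  }
  if (bf10 == 1) {
    return(list(category = "No evidence", hypothesis = NA_character_,
                label = "No evidence", bounds = c(1, 1)))
  }
  for_h1 <- bf10 > 1
  b <- if (for_h1) bf10 else 1 / bf10
  # boundary values go to the stronger band: band i covers [lo, hi)
  i <- findInterval(b, evidence_bounds)
  i <- min(i, length(evidence_names))
  lo <- evidence_bounds[i]
  hi <- if (i < length(evidence_bounds)) evidence_bounds[i + 1] else Inf
  hyp <- if (for_h1) "H1" else "H0"
  bounds <- if (for_h1) c(lo, hi) else rev(1 / c(lo, hi))
  list(category = evidence_names[i], hypothesis = hyp,
       label = paste0(evidence_names[i], " evidence for ", hyp),
       bounds = bounds)
}

#' Proportion-wheel value of a Bayes factor
#'
#' Maps a Bayes factor to the fraction BF/(BF + 1) of a circle's area, the
#' share of a "pizza plot" supporting the numerator hypothesis. Computed so
#' that `wheel_proportion(bf) + wheel_proportion(1/bf)` is exactly 1 in
#' floating point.
#'
#' @param bf10 Bayes factor (> 0); vectorized
#' @return proportion in (0, 1)
#' @export
#' @examples
#' wheel_proportion(6.33)  # ~0.86: H0 keeps 14% of the circle
wheel_proportion <- function(bf10) {
  if (any(!is.finite(bf10) & !is.infinite(bf10)) || any(bf10 <= 0, na.rm = TRUE)) {
    stop("`bf10` must be positive", call. = FALSE)
  }
  ifelse(bf10 >= 1, 1 / (1 + 1 / bf10), 1 - 1 / (1 + bf10))
}
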
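# Prior families used by all default tests.

#' Cauchy prior on a standardized effect size
#'
#' The default prior of the JZS t-test: a Cauchy distribution centred on zero
#' with interquartile-range scale `scale`. One-sided alternatives use the
#' folded form, whose density is twice the symmetric density on its half-line
#' and zero elsewhere.
#'
#' @param scale positive scale (prior interquartile range); the default is
#'   \eqn{\sqrt{2}/2 \approx 0.707}, stored exactly as `sqrt(2)/2`.
#' @param side `"two_sided"`, `"positive"` (effect size restricted to
#'   \eqn{[0, \infty)}) or `"negative"`.
#' @return an object of class `c("cauchy_prior", "bf_prior")`
#' @export
#' @examples
#' prior_density(cauchy_prior(), 0)        # 1 / (pi * sqrt(2)/2)
#' prior_density(cauchy_prior(side = "positive"), -1)  # 0 off-support
cauchy_prior <- function(scale = sqrt(2) / 2,
                         side = c("two_sided", "positive", "negative")) {
  side <- match.arg(side)
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a positive number", call. = FALSE)
  }
  structure(list(family = "cauchy", scale = scale, side = side),
            class = c("cauchy_prior", "bf_prior"))
}

#' Stretched beta prior on a correlation
#'
#' A beta(1/kappa, 1/kappa) distribution stretched from (0, 1) to (-1, 1), so
#' that the density is proportional to \eqn{(1 - \rho^2)^{1/\kappa - 1}}.
#' Width `kappa = 1` is the uniform prior on (-1, 1); smaller widths
#' concentrate mass near zero. One-sided variants renormalize the density on
#' the half-interval.
#'
#' @param kappa width in (0, 2]. The upper bound keeps both implied beta shape
#'   parameters at or above 1/2.
#' @param side `"two_sided"`, `"positive"` or `"negative"`
#' @return an object of class `c("stretched_beta_prior", "bf_prior")`
#' @export
#' @examples
#' prior_density(stretched_beta_prior(1), 0.3)  # uniform: 0.5 everywhere
stretched_beta_prior <- function(kappa = 1,
                                 side = c("two_sided", "positive", "negative")) {
  side <- match.arg(side)
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) ||
      kappa <= 0 || kappa > 2) {
    stop("`kappa` must be in (0, 2]", call. = FALSE)
  }
  structure(list(family = "stretched_beta", kappa = kappa, side = side),
            class = c("stretched_beta_prior", "bf_prior"))
}

#' Prior density
#'
#' Evaluates the density of an effect-size or correlation prior, including the
#' folding / renormalization implied by a one-sided alternative.
#'
#' @param prior a [cauchy_prior()] or [stretched_beta_prior()]
#' @param x numeric vector of evaluation points
#' @return non-negative numeric vector
#' @export
prior_density <- function(prior, x) UseMethod("prior_density")

#' @export
prior_density.cauchy_prior <- function(prior, x) {
  d <- stats::dcauchy(x, 0, prior$scale)
  switch(prior$side,
         two_sided = d,
         positive = ifelse(x >= 0, 2 * d, 0),
         negative = ifelse(x <= 0, 2 * d, 0))
}

#' @export
prior_density.stretched_beta_prior <- function(prior, x) {
  a <- 1 / prior$kappa
  d <- ifelse(abs(x) < 1, stats::dbeta((x + 1) / 2, a, a) / 2, 0)
  switch(prior$side,
         two_sided = d,
         positive = ifelse(x >= 0, 2 * d, 0),
         negative = ifelse(x <= 0, 2 * d, 0))
}

#' Prior mass on positive values
#'
#' For the symmetric two-sided priors used here this is exactly 1/2; it is the
#' conversion factor between two-sided and one-sided Bayes factors.
#'
#' @param prior a two-sided prior
#' @return probability in `[0, 1]`
#' @export
prior_mass_positive <- function(prior) {
  stopifnot(inherits(prior, "bf_prior"))
  if (prior$side != "two_sided") {
    stop("`prior_mass_positive()` is defined for two-sided priors", call. = FALSE)
  }
  0.5
}

#' @export
print.bf_prior <- function(x, ...) {
  par <- if (x$family == "cauchy") paste0("scale = ", signif(x$scale, 6)) else
    paste0("width kappa = ", signif(x$kappa, 6))
  cat(sprintf("<%s prior, %s, %s>\n", x$family, par, x$side))
  invisible(x)
}

# internal: flip a one-sided prior (used by sign-equivariance code paths)
flip_side <- function(prior) {
  prior$side <- switch(prior$side, positive = "negative",
                       negative = "positive", two_sided = "two_sided")
  prior
}
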
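# Default Bayes factor and posterior for Pearson's rho.

#' Sufficient statistics for the correlation test
#'
#' @param n number of complete pairs (>= 3)
#' @param r sample Pearson correlation in `[-1, 1]`
#' @return object of class `cor_stats`
#' @export
cor_stats <- function(n, r) {
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (!is.finite(r) || abs(r) > 1) stop("|r| must be <= 1", call. = FALSE)
  structure(list(n = n, r = r), class = "cor_stats")
}

# log reduced likelihood ratio L(rho)/L(0) for the sample correlation.
# Exact kernel: (1-rho^2)^((n-1)/2) (1-rho r)^(3/2-n) 2F1(1/2,1/2; n-1/2; (1+rho r)/2);
# the rho-free constants cancel in the ratio. `asymptotic = TRUE` drops the
# hypergeometric factor (Jeffreys's large-n form).
log_lik_rho <- function(rho, n, r, asymptotic = FALSE) {
  base <- (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r)
  if (asymptotic) return(base)
  h <- hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * r) / 2)
  h0 <- hyp2f1(0.5, 0.5, n - 0.5, 0.5)
  base + log(h) - log(h0)
}

#' Correlation Bayes factor under the stretched beta prior
#'
#' \deqn{\mathrm{BF}_{10} = \frac{\int L(\rho; n, r)\, \pi(\rho)\, d\rho}
#' {L(0; n, r)}} with the exact reduced likelihood of the sample correlation
#' (hypergeometric form) by default, or Jeffreys's asymptotic kernel
#' \eqn{(1-\rho^2)^{(n-1)/2} (1-\rho r)^{3/2-n}} when
#' `likelihood = "asymptotic"`. A perfect sample correlation (`|r| = 1`) is
#' information consistent: BF10 is infinite.
#'
#' @param stats a [cor_stats()]
#' @param prior a [stretched_beta_prior()]; a `"positive"` side tests
#'   \eqn{H_+:\rho > 0} with the prior renormalized on (0, 1)
#' @param likelihood `"exact"` or `"asymptotic"`
#' @return a [bf_result()]
#' @export
#' @examples
#' correlation_bf(cor_stats(46, 0.39))
correlation_bf <- function(stats, prior = stretched_beta_prior(),
                           likelihood = c("exact", "asymptotic")) {
  stopifnot(inherits(stats, "cor_stats"), inherits(prior, "stretched_beta_prior"))
  likelihood <- match.arg(likelihood)
  if (abs(stats$r) == 1) {
    return(bf_result(Inf, error_pct = 0, comparison = "H1 vs H0"))
  }
  asym <- likelihood == "asymptotic"
  logf <- function(rho) {
    log_lik_rho(rho, stats$n, stats$r, asymptotic = asym) +
      log(prior_density(prior, rho))
  }
  lims <- switch(prior$side, two_sided = c(-1, 1), positive = c(0, 1),
                 negative = c(-1, 0))
  q <- log_integral(logf, lims[1], lims[2], candidates = c(0, stats$r))
  lab <- switch(prior$side, two_sided = "H1 vs H0",
                positive = "H+ vs H0", negative = "H- vs H0")
  bf_result(q$log_value, error_pct = 100 * q$rel_error, comparison = lab)
}

#' Correlation Bayes factor from a data table
#'
#' Drops pairs with any missing value, computes `(n, r)` and delegates to
#' [correlation_bf()]. "Correlated positively" means \eqn{\rho > 0} between
#' the two variables in the order supplied.
#'
#' @param table a [bf_table()]
#' @param vars character vector of two continuous column names
#' @inheritParams correlation_bf
#' @return list with `bf`, `stats`, and optionally `posterior`
#' @export
correlation_test <- function(table, vars, prior = stretched_beta_prior(),
                             likelihood = c("exact", "asymptotic"),
                             posterior = TRUE) {
  stopifnot(inherits(table, "bf_table"), length(vars) == 2)
  lev <- table_levels(table)
  if (any(lev[vars] == "nominal")) {
    stop("correlation requires numeric variables", call. = FALSE)
  }
  x <- as.numeric(table[[vars[1]]]); y <- as.numeric(table[[vars[2]]])
  keep <- !is.na(x) & !is.na(y)
  st <- cor_stats(sum(keep), stats::cor(x[keep], y[keep]))
  out <- list(bf = correlation_bf(st, prior, likelihood), stats = st)
  if (posterior) out$posterior <- posterior_rho(st, prior, likelihood)
  out
}

#' Posterior distribution of the correlation
#'
#' Posterior \eqn{p(\rho \mid n, r) \propto L(\rho)\,\pi(\rho)}; median and
#' equal-tailed 95\% interval by numeric CDF inversion, plus the posterior
#' density at \eqn{\rho = 0}.
#'
#' @inheritParams correlation_bf
#' @return a [posterior_summary()]
#' @export
posterior_rho <- function(stats, prior = stretched_beta_prior(),
                          likelihood = c("exact", "asymptotic")) {
  stopifnot(inherits(stats, "cor_stats"), inherits(prior, "stretched_beta_prior"))
  likelihood <- match.arg(likelihood)
  asym <- likelihood == "asymptotic"
  two <- prior; two$side <- "two_sided"
  logpost <- function(rho) {
    out <- rep(-Inf, length(rho))
    ok <- abs(rho) < 1
    out[ok] <- log_lik_rho(rho[ok], stats$n, stats$r, asymptotic = asym) +
      log(prior_density(two, rho[ok]))
    out
  }
  lims <- switch(prior$side, two_sided = c(-1, 1), positive = c(0, 1),
                 negative = c(-1, 0))
  eps <- 1e-9
  centre <- min(max(stats$r, lims[1] + 0.02), lims[2] - 0.02)
  grid_posterior(logpost, lo = lims[1] + eps, hi = lims[2] - eps,
                 centre = centre, width = max(8 / sqrt(stats$n), 0.5))
}
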
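# Marginal likelihoods for g-prior linear models, and Bayes factors from them.

#' Settings for the g-prior ANOVA
#'
#' Each term gets its own g parameter with the scaled inverse-chi-square
#' (inverse-gamma(1/2, r^2/2)) mixing density that makes the implied
#' standardized effect-size prior Cauchy with scale r. Fixed terms default to
#' r = 0.5; random (participant) terms use a wider scale, r = 1, reflecting
#' the a-priori expectation that participants differ.
#'
#' @param r_fixed prior scale for fixed terms (default 0.5)
#' @param r_random prior scale for random terms (default 1.0)
#' @param mc_samples importance-sampling size for models with more than one
#'   term (default 10000)
#' @param seed integer seed; results are bit-reproducible given
#'   `(seed, mc_samples)`
#' @return object of class `g_prior_settings`
#' @export
g_prior_settings <- function(r_fixed = 0.5, r_random = 1.0,
                             mc_samples = 10000, seed = 1) {
  stopifnot(r_fixed > 0, r_random > 0, mc_samples >= 100)
  structure(list(r_fixed = r_fixed, r_random = r_random,
                 mc_samples = as.integer(mc_samples), seed = as.integer(seed)),
            class = "g_prior_settings")
}

# log BF(model vs intercept-only | g): intercept under a flat prior and error
# variance under Jeffreys's prior are integrated analytically, leaving
#   -1/2 log|I_p + G^{1/2} X'X G^{1/2}| - (n-1)/2 log(q / y'y)
# with X column-centred, y centred, q the g-shrunken residual sum of squares.
logbf_given_g <- function(g_by_col, Xc, XtX, b, yty, n) {
  sg <- sqrt(g_by_col)
  M <- diag(length(sg)) + (sg %o% sg) * XtX
  R <- tryCatch(chol(M), error = function(e) {
    stop("singular design after projection", call. = FALSE)
  })
  u <- backsolve(R, sg * b, transpose = TRUE)
  q <- yty - sum(u^2)
  if (q <= 0) q <- .Machine$double.eps * yty
  -sum(log(diag(R))) - (n - 1) / 2 * (log(q) - log(yty))
}

# log inverse-gamma(1/2, r^2/2) density at g = exp(lg), including the
# jacobian of the log transformation
log_g_prior <- function(lg, r) {
  g <- exp(lg)
  0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * lg - r^2 / (2 * g) + lg
}

#' Marginal likelihood of a g-prior linear model
#'
#' Log marginal likelihood relative to the intercept-only model (the shared
#' constant cancels out of every Bayes factor). The (g_1, ..., g_p) mixture
#' integral is computed by deterministic quadrature when the model has one
#' term, and by seeded importance sampling with a log-normal proposal centred
#' at the Laplace mode when it has several.
#'
#' @param y response vector
#' @param blocks named list of per-term design matrices (from
#'   [build_design()]); empty list for the intercept-only model
#' @param settings a [g_prior_settings()]
#' @param random logical vector flagging which blocks are random terms
#' @param method `"auto"` (quadrature for one term, importance sampling
#'   otherwise), `"quadrature"` (single-term models only) or `"importance"`
#' @return list with `log_ml`, `mc_error_pct` (0 for quadrature below
#'   tolerance) and `flag` (`TRUE` when the Monte Carlo error exceeds 15%)
#' @export
marginal_likelihood <- function(y, blocks, settings = g_prior_settings(),
                                random = NULL,
                                method = c("auto", "quadrature", "importance")) {
  method <- match.arg(method)
  p <- length(blocks)
  if (p == 0) {
    return(structure(list(log_ml = 0, mc_error_pct = 0, flag = FALSE),
                     class = "ml_estimate"))
  }
  if (is.null(random)) random <- rep(FALSE, p)
  n <- length(y)
  ncols <- vapply(blocks, ncol, integer(1))
  if (n <= sum(ncols) + 1) stop("n must exceed the number of effect columns + 1",
                                call. = FALSE)
  X <- do.call(cbind, blocks)
  Xc <- sweep(X, 2, colMeans(X))
  ytil <- y - mean(y)
  yty <- sum(ytil^2)
  if (yty <= 0) stop("response has zero variance", call. = FALSE)
  XtX <- crossprod(Xc)
  b <- drop(crossprod(Xc, ytil))
  colmap <- rep(seq_len(p), ncols)
  r_scales <- ifelse(random, settings$r_random, settings$r_fixed)

  lpost <- function(lg) {
    # far tails carry no mass and would overflow the g-scaled Gram matrix
    if (!all(is.finite(lg)) || max(abs(lg)) > 200) return(-Inf)
    logbf_given_g(exp(lg)[colmap], Xc, XtX, b, yty, n) +
      sum(log_g_prior(lg, r_scales))
  }

  if (method == "quadrature" && p > 1) {
    stop("deterministic quadrature is only available for single-term models",
         call. = FALSE)
  }
  use_quad <- method == "quadrature" || (method == "auto" && p == 1)
  if (use_quad) {
    q <- log_integral(function(v) vapply(v, lpost, numeric(1)), -Inf, Inf)
    return(structure(list(log_ml = q$log_value,
                          mc_error_pct = 100 * q$rel_error, flag = FALSE),
                     class = "ml_estimate"))
  }

  # importance sampling: log-normal proposal at the Laplace mode
  opt <- stats::optim(rep(0, p), function(lg) -lpost(lg),
                      method = if (p == 1) "Brent" else "BFGS",
                      lower = if (p == 1) -25 else -Inf,
                      upper = if (p == 1) 25 else Inf)
  mode <- opt$par
  hdiag <- vapply(seq_len(p), function(i) {
    e <- 1e-3; d <- numeric(p); d[i] <- e
    (-lpost(mode + d) + 2 * lpost(mode) - lpost(mode - d)) / e^2
  }, numeric(1))
  sds <- 1.3 / sqrt(pmax(hdiag, 1e-4))
  m <- settings$mc_samples
  lw <- with_preserved_seed(settings$seed, {
    Z <- matrix(stats::rnorm(m * p), m, p)
    LG <- sweep(sweep(Z, 2, sds, "*"), 2, mode, "+")
    lq <- rowSums(matrix(stats::dnorm(sweep(sweep(LG, 2, mode, "-"), 2, sds, "/"),
                                      log = TRUE), m, p)) - sum(log(sds))
    vapply(seq_len(m), function(i) lpost(LG[i, ]), numeric(1)) - lq
  })
  mx <- max(lw)
  w <- exp(lw - mx)
  est <- mx + log(mean(w))
  err <- 100 * stats::sd(w) / (mean(w) * sqrt(m))
  structure(list(log_ml = est, mc_error_pct = err, flag = err > 15),
            class = "ml_estimate")
}

#' @export
print.ml_estimate <- function(x, ...) {
  cat(sprintf("log marginal likelihood (vs intercept-only): %.4f  [error %% = %.3g]%s\n",
              x$log_ml, x$mc_error_pct, if (x$flag) "  ** high MC error" else ""))
  invisible(x)
}

#' Bayes factor between two ANOVA models
#'
#' `log BF = log_ml(model) - log_ml(base)`, with the error percentages of the
#' two estimates combined in quadrature. Both models must contain the
#' analysis's nuisance terms, and the base must be nested in the candidate.
#'
#' @param table a [bf_table()]
#' @param dependent continuous outcome column
#' @param model,base [model_spec()] objects
#' @param settings a [g_prior_settings()]
#' @return a [bf_result()]
#' @export
model_bf <- function(table, dependent, model, base,
                     settings = g_prior_settings()) {
  stopifnot(inherits(model, "model_spec"), inherits(base, "model_spec"))
  mlab <- vapply(model$terms, term_label, character(1))
  blab <- vapply(base$terms, term_label, character(1))
  if (!all(blab %in% mlab)) {
    stop("base model is not nested in the candidate model", call. = FALSE)
  }
  nuis <- vapply(model$nuisance, term_label, character(1))
  if (!all(nuis %in% blab)) {
    stop("nuisance terms must appear in the base model too", call. = FALSE)
  }
  if (identical(mlab, blab)) {
    return(bf_result(0, error_pct = 0, comparison = "model vs base"))
  }
  dm <- build_design(table, dependent, model)
  db <- build_design(table, dependent, base)
  ml_m <- marginal_likelihood(dm$y, dm$blocks, settings, dm$random)
  ml_b <- marginal_likelihood(db$y, db$blocks, settings, db$random)
  bf_result(ml_m$log_ml - ml_b$log_ml,
            error_pct = sqrt(ml_m$mc_error_pct^2 + ml_b$mc_error_pct^2),
            comparison = paste(model_label(model, FALSE), "vs",
                               model_label(base, FALSE)))
}

#' Default Bayes factor ANOVA
#'
#' Enumerates all models over the fixed factors under the principle of
#' marginality, augments each with the nuisance and random terms (which also
#' form the null model), computes each model's marginal likelihood, and
#' returns the model-comparison and effects (Bayesian model averaging)
#' tables. Random factors always contribute their main effect to every model,
#' with the wider `r_random` prior scale.
#'
#' @param table a [bf_table()] in long format
#' @param dependent continuous outcome column
#' @param fixed character vector of fixed factor names
#' @param random character vector of random factor names (e.g. `"subject"`)
#' @param nuisance character vector of term labels included in every model
#' @param settings a [g_prior_settings()]
#' @param max_order highest interaction order among fixed factors
#' @return object of class `bf_anova` with elements `comparison`, `effects`,
#'   `models`
#' @export
anova_bf <- function(table, dependent, fixed, random = character(),
                     nuisance = character(), settings = g_prior_settings(),
                     max_order = Inf) {
  specs <- enumerate_models(fixed, nuisance = nuisance,
                            max_order = min(max_order, length(fixed)),
                            random = random)
  labels <- vapply(specs, model_label, character(1))
  mls <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    st <- settings
    st$seed <- settings$seed + i - 1L
    d <- build_design(table, dependent, specs[[i]])
    mls[[i]] <- marginal_likelihood(d$y, d$blocks, st, d$random)
  }
  log_ml <- vapply(mls, `[[`, numeric(1), "log_ml")
  err <- vapply(mls, `[[`, numeric(1), "mc_error_pct")
  i0 <- which(labels == "Null model")
  log_bf10 <- log_ml - log_ml[i0]
  err10 <- sqrt(err^2 + err[i0]^2)
  err10[i0] <- 0
  bfs <- lapply(seq_along(specs), function(i) {
    bf_result(log_bf10[i], error_pct = err10[i],
              comparison = paste(labels[i], "vs Null model"))
  })
  names(bfs) <- labels
  nuis_labs <- unique(c(vapply(specs[[i0]]$terms, term_label, character(1))))
  model_terms <- lapply(specs, function(s) {
    setdiff(vapply(s$terms, term_label, character(1)), nuis_labs)
  })
  names(model_terms) <- labels
  comp <- comparison_table(bfs, models = model_terms)
  terms_of_interest <- unique(unlist(model_terms))
  eff <- if (length(terms_of_interest)) {
    effects_table(comp, terms_of_interest)
  } else NULL
  structure(list(comparison = comp, effects = eff, models = specs,
                 settings = settings),
            class = "bf_anova")
}

#' @export
print.bf_anova <- function(x, ...) {
  cat("Model comparison\n")
  comp <- x$comparison
  comp$bf10 <- format_bf(comp$bf10)
  comp$bf_m <- format_bf(comp$bf_m)
  print(comp, row.names = FALSE)
  if (!is.null(x$effects)) {
    cat("\nAnalysis of effects\n")
    eff <- x$effects
    eff$bf_inclusion <- format_bf(eff$bf_inclusion)
    print(eff, row.names = FALSE)
  }
  invisible(x)
}
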
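# Shared helpers: temporary CSV fixtures and independent brute-force oracles.

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

hair_color_path <- function() {
  system.file("extdata", "hair_color_pain.csv", package = "defaultBF")
}

# singers data (heights of the 1979 NY Choral Society, lattice::singer),
# recoded from the eight voice parts to gender x pitch
singers_table <- function() {
  e <- new.env()
  utils::data("singer", package = "lattice", envir = e)
  vp <- as.character(e$singer$voice.part)
  pitch_map <- c("Bass 2" = "very low", "Alto 2" = "very low",
                 "Bass 1" = "low", "Alto 1" = "low",
                 "Tenor 2" = "high", "Soprano 2" = "high",
                 "Tenor 1" = "very high", "Soprano 1" = "very high")
  bf_table(data.frame(
    height = e$singer$height,
    gender = ifelse(vp %in% c("Bass 2", "Bass 1", "Tenor 2", "Tenor 1"),
                    "M", "F"),
    pitch = pitch_map[vp],
    stringsAsFactors = FALSE))
}

# total prior mass by quadrature, integrating each half-line separately so
# that folded (one-sided) densities do not trip the adaptive integrator
prior_total_mass <- function(p) {
  lims <- if (p$family == "cauchy") c(-Inf, 0, Inf) else c(-1 + 1e-12, 0, 1 - 1e-12)
  integrate(function(x) prior_density(p, x), lims[1], lims[2],
            rel.tol = 1e-10)$value +
    integrate(function(x) prior_density(p, x), lims[2], lims[3],
              rel.tol = 1e-10)$value
}

# dense Riemann-sum oracle for the JZS t-test Bayes factor
riemann_jzs_bf <- function(t, n1, n2, r, lim = 15, points = 40001) {
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  d <- seq(-lim, lim, length.out = points)
  # dt() warns once per element where the noncentral tail loses precision;
  # on a 40k grid that floods the reporter, so silence it for the oracle
  f <- suppressWarnings(dt(t, nu, ncp = d * sqrt(neff))) * dcauchy(d, 0, r)
  h <- d[2] - d[1]
  sum(f) * h / dt(t, nu, 0)
}

# dense Riemann-sum oracle for the correlation Bayes factor, using an
# independently coded likelihood (straight series for the hypergeometric term)
riemann_corr_bf <- function(n, r, kappa = 1, points = 200001) {
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = points)
  f2_1 <- function(z) {            # 2F1(1/2, 1/2; n - 1/2; z), scalar z
    term <- 1; s <- 1
    for (k in 0:10000) {
      term <- term * (0.5 + k)^2 / ((n - 0.5 + k) * (k + 1)) * z
      s <- s + term
      if (abs(term) < 1e-15 * s) break
    }
    s
  }
  lik <- vapply(rho, function(p) {
    exp((n - 1) / 2 * log1p(-p^2) - (n - 1.5) * log1p(-p * r)) * f2_1((1 + p * r) / 2)
  }, numeric(1)) / f2_1(0.5)
  a <- 1 / kappa
  pri <- dbeta((rho + 1) / 2, a, a) / 2
  h <- rho[2] - rho[1]
  sum(lik * pri) * h
}

# brute-force marginality-closure enumeration oracle: all subsets of the term
# lattice over k factors that are downward closed (every interaction's
# immediate sub-terms present, which by induction gives full closure),
# counted including the null model. Bitmask sweep over all 2^terms subsets.
brute_force_model_count <- function(k) {
  factors <- LETTERS[seq_len(k)]
  terms <- list()
  for (m in seq_len(k)) terms <- c(terms, utils::combn(factors, m, simplify = FALSE))
  nt <- length(terms)
  lab <- vapply(terms, function(t) paste(sort(t), collapse = ":"), character(1))
  req <- vapply(seq_len(nt), function(i) {
    tm <- terms[[i]]
    if (length(tm) == 1) return(0)
    subs <- utils::combn(tm, length(tm) - 1, simplify = FALSE)
    sub_labs <- vapply(subs, function(s) paste(sort(s), collapse = ":"), character(1))
    sum(2^(match(sub_labs, lab) - 1))
  }, numeric(1))
  masks <- 0:(2^nt - 1)
  bad <- rep(FALSE, length(masks))
  for (i in seq_len(nt)) {
    sel_i <- bitwAnd(masks, 2^(i - 1)) > 0
    contained <- bitwAnd(masks, req[i]) == req[i]
    bad <- bad | (sel_i & !contained)
  }
  sum(!bad)
}
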
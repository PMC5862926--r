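# Internal numerical helpers shared by the Bayes factor routines.

#' Integrate exp(logf) over (lower, upper) in log space
#'
#' Adaptive quadrature after a tangent substitution centred on the integrand's
#' peak, so that sharply concentrated likelihoods (large n) and heavy-tailed
#' priors are both handled on a finite interval. Returns the log of the
#' integral together with the integrator's relative error estimate.
#'
#' @param logf vectorized function returning the log integrand
#' @param lower,upper integration limits (may be infinite)
#' @param centre,scale location and width of the substitution
#'   x = centre + scale * tan(u); defaults chosen by probing the integrand
#' @return list(log_value, rel_error)
#' @noRd
log_integral <- function(logf, lower = -Inf, upper = Inf,
                         centre = NULL, scale = NULL, candidates = 0,
                         rel.tol = 1e-8, abs.tol = 1e-10) {
  if (is.null(centre) || is.null(scale)) {
    # probe exponentially spaced offsets around each candidate peak location,
    # so that spikes narrower than any fixed grid (very small prior scales)
    # are still located; the same probe supplies the drop-2 width estimate
    offs <- exp(seq(log(1e-12), log(100), length.out = 70))
    probe <- unique(as.vector(outer(c(-offs, 0, offs),
                                    candidates[is.finite(candidates)], `+`)))
    if (is.finite(lower) && is.finite(upper)) {
      probe <- c(probe, seq(lower + 1e-9, upper - 1e-9, length.out = 101))
    }
    probe <- sort(probe[probe > lower & probe < upper])
    lp <- logf(probe)
    lp[!is.finite(lp)] <- -Inf
    imax <- which.max(lp)
    if (is.null(centre)) centre <- probe[imax]
    if (is.null(scale)) {
      # half-width at log-drop 2 read off the probe on each side of the peak
      m <- lp[imax]
      below_l <- which(lp <= m - 2 & probe < centre)
      below_r <- which(lp <= m - 2 & probe > centre)
      # a side with no drop-2 point (flat, or the peak on a support
      # boundary) carries no width information and must not shrink the scale
      w_l <- if (length(below_l)) centre - probe[max(below_l)] else NA_real_
      w_r <- if (length(below_r)) probe[min(below_r)] - centre else NA_real_
      widths <- c(w_l, w_r)
      widths <- widths[!is.na(widths) & widths > 0]
      scale <- if (length(widths)) {
        max(min(widths), 1e-12)
      } else if (is.finite(lower) && is.finite(upper)) {
        (upper - lower) / 4
      } else 1
    }
  }
  u_lo <- if (is.finite(lower)) atan((lower - centre) / scale) else -pi / 2
  u_hi <- if (is.finite(upper)) atan((upper - centre) / scale) else pi / 2
  # scale out the maximum for numerical stability
  u_probe <- seq(u_lo + 1e-10, u_hi - 1e-10, length.out = 201)
  m <- max(logf(centre + scale * tan(u_probe)), na.rm = TRUE)
  g <- function(u) {
    x <- centre + scale * tan(u)
    v <- exp(logf(x) - m) * scale / cos(u)^2
    v[!is.finite(v)] <- 0
    v
  }
  q <- stats::integrate(g, u_lo, u_hi, rel.tol = rel.tol, abs.tol = abs.tol,
                        subdivisions = 500L, stop.on.error = FALSE)
  ok <- q$message %in% c("OK", "roundoff error was detected") ||
    # deep-tail evaluations of the noncentral t density bottom out at an
    # absolute noise floor; accept a subdivision-limited result when its own
    # error estimate is still small, and report that error honestly
    (q$message == "maximum number of subdivisions reached" &&
       q$value > 0 && q$abs.error / q$value < 1e-4)
  if (!ok && q$message == "maximum number of subdivisions reached") {
    # the integrand's tail is dominated by that noise floor, so adaptive
    # refinement cannot converge; a fixed composite grid averages the noise
    # instead of chasing it, and two resolutions bound the remaining error
    simpson <- function(k) {
      u <- seq(u_lo, u_hi, length.out = k)
      w <- c(1, rep(c(4, 2), length.out = k - 2), 1)
      sum(w * g(u)) * (u[2] - u[1]) / 3
    }
    v1 <- simpson(20001L)
    v2 <- simpson(40001L)
    if (is.finite(v2) && v2 > 0) {
      q <- list(value = v2, abs.error = abs(v2 - v1) + abs.tol)
      ok <- TRUE
    }
  }
  if (!ok) stop("quadrature failed: ", q$message, call. = FALSE)
  if (q$value <= 0) {
    return(list(log_value = -Inf, rel_error = 0))
  }
  list(log_value = m + log(q$value), rel_error = q$abs.error / q$value)
}

#' log(sum(exp(x))) without overflow
#' @noRd
log_sum_exp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Gauss hypergeometric function 2F1(a, b; c; z) for 0 <= z < 1
#'
#' Vectorized power series; for z > 0.75 the standard linear transformation
#' z -> 1 - z is applied (valid here because c - a - b is never an integer for
#' the half-integer parameters used by the correlation test).
#' @noRd
hyp2f1 <- function(a, b, cc, z) {
  out <- numeric(length(z))
  near <- z > 0.75
  if (any(!near)) out[!near] <- hyp2f1_series(a, b, cc, z[!near])
  if (any(near)) {
    z1 <- 1 - z[near]
    t1 <- exp(lgamma(cc) + lgamma(cc - a - b) - lgamma(cc - a) - lgamma(cc - b)) *
      hyp2f1_series(a, b, a + b - cc + 1, z1)
    t2 <- z1^(cc - a - b) * gamma(cc) * gamma(a + b - cc) / (gamma(a) * gamma(b)) *
      hyp2f1_series(cc - a, cc - b, cc - a - b + 1, z1)
    out[near] <- t1 + t2
  }
  out
}

#' @noRd
hyp2f1_series <- function(a, b, cc, z) {
  if (!length(z)) return(numeric(0))
  term <- rep(1, length(z))
  s <- term
  for (k in 0:100000) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    if (all(abs(term) < 1e-16 * pmax(abs(s), 1))) break
  }
  s
}

#' Evaluate a Bayes factor with seeded RNG isolated from the caller
#' @noRd
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Format a Bayes factor the way the result tables print it
#'
#' Plain fixed notation in the moderate range, scientific notation with three
#' significant digits for very large or very small values.
#' @param bf numeric vector of Bayes factors
#' @return character vector
#' @export
#' @examples
#' format_bf(c(11.97, 8.192e39, 3e-7))
format_bf <- function(bf) {
  vapply(bf, function(b) {
    if (!is.finite(b)) return(as.character(b))
    if (b != 0 && (abs(b) >= 1e6 || abs(b) < 1e-4)) {
      format(signif(b, 3), scientific = TRUE)
    } else {
      format(signif(b, 4), scientific = FALSE)
    }
  }, character(1))
}
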
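# Sequential evidence traces, prior-robustness curves, stopping rules.

#' Sequential Bayes factor trace
#'
#' Recomputes the Bayes factor on growing prefixes of the data (assumed to be
#' in data-collection order, one row per participant), one trace per prior
#' scale. The trace starts at the smallest n where the statistic is defined:
#' at least two observations per group for the t-test, at least three complete
#' pairs for the correlation. Each point is a deterministic function of the
#' data prefix.
#'
#' @param table a [bf_table()] with rows in collection order
#' @param analysis list describing the analysis: for a t-test
#'   `list(type = "ttest", dependent =, group =, hypothesis =)`; for a
#'   correlation `list(type = "correlation", vars = c(x, y), side =)`
#' @param scales numeric vector of prior scales (Cauchy r, or stretched-beta
#'   width)
#' @return list of `sequential_trace` objects, one per scale; each is a
#'   data.frame `(n, log_bf)` with the scale in attribute `"scale"`
#' @export
sequential_bf <- function(table, analysis, scales = sqrt(2) / 2) {
  stopifnot(inherits(table, "bf_table"), is.list(analysis))
  n_total <- nrow(table)
  type <- match.arg(analysis$type, c("ttest", "correlation"))
  lapply(scales, function(r) {
    pts <- list()
    for (n in seq_len(n_total)) {
      prefix <- bf_table(as.data.frame(table)[seq_len(n), , drop = FALSE],
                         levels = table_levels(table))
      lb <- tryCatch({
        if (type == "ttest") {
          g <- as.character(prefix[[analysis$group]])
          y <- as.numeric(prefix[[analysis$dependent]])
          ok <- !is.na(g) & !is.na(y)
          if (length(unique(g[ok])) < 2 || any(table(g[ok]) < 2)) NULL else {
            fit <- jzs_ttest(prefix, analysis$dependent, analysis$group,
                             prior = cauchy_prior(scale = r),
                             hypothesis = analysis$hypothesis %||% "two_sided",
                             posterior = FALSE)
            fit$bf$log_bf10
          }
        } else {
          x <- as.numeric(prefix[[analysis$vars[1]]])
          y <- as.numeric(prefix[[analysis$vars[2]]])
          ok <- !is.na(x) & !is.na(y)
          if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) NULL else {
            side <- analysis$side %||% "two_sided"
            st <- cor_stats(sum(ok), stats::cor(x[ok], y[ok]))
            correlation_bf(st, stretched_beta_prior(kappa = r, side = side))$log_bf10
          }
        }
      }, error = function(e) NULL)
      if (!is.null(lb)) pts[[length(pts) + 1L]] <- c(n = n, log_bf = lb)
    }
    if (!length(pts)) stop("statistic never defined on any prefix", call. = FALSE)
    tr <- as.data.frame(do.call(rbind, pts))
    structure(tr, scale = r, class = c("sequential_trace", "data.frame"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayes factor robustness curve
#'
#' The Bayes factor as a function of the prior scale r. At r = 0 the
#' alternative collapses onto the null and the Bayes factor is exactly 1
#' (handled analytically, not by quadrature).
#'
#' @param x a [ttest_stats()], [cor_stats()], or [bf_table()]
#' @param r_grid non-negative, ascending prior scales
#' @param side `"two_sided"`, `"positive"` or `"negative"`
#' @param analysis required when `x` is a table; see [sequential_bf()]
#' @return data.frame `(r, log_bf, bf10)`
#' @export
robustness_curve <- function(x, r_grid, side = "two_sided", analysis = NULL) {
  if (any(r_grid < 0) || is.unsorted(r_grid)) {
    stop("r_grid must be non-negative and ascending", call. = FALSE)
  }
  if (inherits(x, "bf_table")) {
    # reduce the full table to its sufficient statistics once
    if (is.null(analysis)) stop("`analysis` is required for table input", call. = FALSE)
    if (match.arg(analysis$type, c("ttest", "correlation")) == "ttest") {
      fit <- jzs_ttest(x, analysis$dependent, analysis$group, posterior = FALSE)
      x <- fit$stats
    } else {
      xv <- as.numeric(x[[analysis$vars[1]]])
      yv <- as.numeric(x[[analysis$vars[2]]])
      ok <- !is.na(xv) & !is.na(yv)
      x <- cor_stats(sum(ok), stats::cor(xv[ok], yv[ok]))
    }
  }
  one <- function(r) {
    if (r == 0) return(0)
    if (inherits(x, "ttest_stats")) {
      jzs_ttest_bf(x, cauchy_prior(scale = r, side = side))$log_bf10
    } else if (inherits(x, "cor_stats")) {
      correlation_bf(x, stretched_beta_prior(kappa = r, side = side))$log_bf10
    } else stop("unsupported input", call. = FALSE)
  }
  lb <- vapply(r_grid, one, numeric(1))
  data.frame(r = r_grid, log_bf = lb, bf10 = exp(lb))
}

#' Preregistered stopping rule
#'
#' Collect at least `min_per_group` participants per group, then stop as soon
#' as the Bayes factor reaches `bf_threshold` in favour of either hypothesis,
#' or when `max_per_group` is reached.
#'
#' @param min_per_group,max_per_group group-size bounds
#' @param bf_threshold Bayes factor threshold (> 1)
#' @return object of class `stopping_rule`
#' @export
stopping_rule <- function(min_per_group = 20, max_per_group = 50,
                          bf_threshold = 10) {
  stopifnot(min_per_group <= max_per_group, bf_threshold > 1)
  structure(list(min_per_group = min_per_group, max_per_group = max_per_group,
                 bf_threshold = bf_threshold), class = "stopping_rule")
}

#' Evaluate a stopping rule along a sequential trace
#'
#' Finds the first n at which every group has reached the minimum size and
#' the Bayes factor lies outside `(1/threshold, threshold)`. The trace's
#' `log_bf` is interpreted as log BF for the comparison being monitored; the
#' decision direction reports which side of 1 was crossed.
#'
#' @param trace a `sequential_trace` from [sequential_bf()]
#' @param rule a [stopping_rule()]
#' @param group_sizes matrix or data.frame aligned with `trace` rows, one
#'   column per group, giving group sizes at each trace point; or `NULL` for
#'   designs without groups (the minimum is then applied to n itself)
#' @return list with `decision` (`"stop"` or `"max reached"`), `stop_n`,
#'   `direction` (`"favours numerator"`, `"favours denominator"` or `NA`)
#' @export
evaluate_stopping <- function(trace, rule, group_sizes = NULL) {
  stopifnot(inherits(trace, "sequential_trace"), inherits(rule, "stopping_rule"))
  if (!is.null(group_sizes)) {
    group_sizes <- as.matrix(group_sizes)
    if (nrow(group_sizes) != nrow(trace)) {
      stop("group_sizes must align with the trace", call. = FALSE)
    }
  }
  lth <- log(rule$bf_threshold)
  for (i in seq_len(nrow(trace))) {
    min_ok <- if (is.null(group_sizes)) {
      trace$n[i] >= rule$min_per_group
    } else {
      all(group_sizes[i, ] >= rule$min_per_group)
    }
    max_hit <- if (is.null(group_sizes)) {
      trace$n[i] >= rule$max_per_group
    } else {
      all(group_sizes[i, ] >= rule$max_per_group)
    }
    if (min_ok && abs(trace$log_bf[i]) >= lth) {
      return(list(decision = "stop", stop_n = trace$n[i],
                  direction = if (trace$log_bf[i] > 0) "favours numerator"
                  else "favours denominator"))
    }
    if (max_hit) {
      return(list(decision = "max reached", stop_n = trace$n[i],
                  direction = NA_character_))
    }
  }
  list(decision = "max reached", stop_n = trace$n[nrow(trace)],
       direction = NA_character_)
}
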
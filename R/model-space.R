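# Model enumeration, comparison tables, rebasing, effects (BMA) tables.

#' Enumerate candidate models under the principle of marginality
#'
#' Generates every set of terms over the given factors that is closed under
#' marginality (an interaction is only included together with all its
#' sub-terms), augments each with the nuisance terms, and returns the list in
#' deterministic order: by model size, then lexicographically. The null
#' (nuisance-only) model comes first. For k = 1, 2, 3, 4 fully crossed
#' factors this yields 2, 5, 19 and 167 models.
#'
#' @param factors character vector of factor names
#' @param nuisance character vector of term labels included in every model
#' @param max_order highest interaction order to consider
#' @param random character vector of random factor names, added (as main
#'   effects) to every model alongside the nuisance terms
#' @return list of [model_spec()] objects
#' @export
#' @examples
#' length(enumerate_models(c("A", "B")))  # 5
enumerate_models <- function(factors, nuisance = character(),
                             max_order = length(factors),
                             random = character()) {
  if (!length(factors)) stop("need at least one factor", call. = FALSE)
  if (anyDuplicated(factors)) stop("factor listed twice", call. = FALSE)
  nuis_terms <- lapply(nuisance, canon_term)
  nuis_labs <- vapply(nuis_terms, term_label, character(1))
  rand_terms <- lapply(random, canon_term)
  rand_labs <- vapply(rand_terms, term_label, character(1))
  always <- unique(c(nuis_labs, rand_labs))

  # candidate terms of interest: all crosses of the factors up to max_order,
  # excluding terms that are already in every model
  cand <- list()
  for (m in seq_len(min(max_order, length(factors)))) {
    cand <- c(cand, utils::combn(factors, m, simplify = FALSE))
  }
  cand <- lapply(cand, canon_term)
  labs <- vapply(cand, term_label, character(1))
  keep <- !labs %in% always
  cand <- cand[keep]; labs <- labs[keep]
  ord <- order(lengths(cand), labs)
  cand <- cand[ord]; labs <- labs[ord]

  # a sub-term counts as present if it is in the model or included always
  closed_ok <- function(sel_labs, term) {
    subs <- vapply(sub_terms(term), term_label, character(1))
    all(subs %in% c(sel_labs, always))
  }
  # depth-first enumeration of downward-closed term sets: at each term decide
  # include/exclude; inclusion requires closure, which the ordering (by term
  # size) guarantees can be checked against the current selection
  results <- list()
  recurse <- function(i, sel) {
    if (i > length(cand)) {
      results[[length(results) + 1L]] <<- sel
      return(invisible())
    }
    recurse(i + 1L, sel)                       # exclude cand[[i]]
    if (closed_ok(vapply(sel, term_label, character(1)), cand[[i]])) {
      recurse(i + 1L, c(sel, cand[i]))         # include
    }
  }
  recurse(1L, list())

  base_terms <- c(nuis_terms, lapply(setdiff(rand_labs, nuis_labs), canon_term))
  specs <- lapply(results, function(sel) {
    model_spec(terms = c(base_terms, sel), nuisance = nuis_terms,
               random = random)
  })
  sizes <- vapply(results, length, integer(1))
  labels <- vapply(specs, model_label, character(1))
  specs[order(sizes, labels)]
}

extract_log_bf <- function(bfs) {
  if (is.numeric(bfs)) {
    list(log_bf = log(bfs), err = rep(NA_real_, length(bfs)), nms = names(bfs))
  } else if (is.list(bfs) && all(vapply(bfs, inherits, logical(1), "bf_result"))) {
    list(log_bf = vapply(bfs, `[[`, numeric(1), "log_bf10"),
         err = vapply(bfs, `[[`, numeric(1), "error_pct"),
         nms = names(bfs))
  } else {
    stop("`bfs` must be a named numeric vector of Bayes factors or a named ",
         "list of bf_result objects", call. = FALSE)
  }
}

#' Model comparison table
#'
#' Converts Bayes factors against a common base model into prior and posterior
#' model probabilities and the change-in-odds Bayes factor BF_M. All
#' arithmetic is carried out in log space so that Bayes factors of magnitude
#' 1e39 and beyond survive intact.
#'
#' \deqn{P(M_i \mid y) = \frac{\mathrm{BF}_{i0} P(M_i)}{\sum_j
#' \mathrm{BF}_{j0} P(M_j)}, \qquad \mathrm{BF}_{M_i} =
#' \frac{P(M_i \mid y)/(1 - P(M_i \mid y))}{P(M_i)/(1 - P(M_i))}.}
#'
#' @param bfs named numeric vector of Bayes factors versus the base model, or
#'   named list of [bf_result()] objects; the base model itself appears with
#'   BF = 1
#' @param prior_probs `"uniform"` or a named numeric vector summing to one
#' @param models optional named list (same names as `bfs`) of the term labels
#'   each model contains, consumed by [effects_table()]
#' @return data.frame with columns `model`, `p_m`, `p_m_data`, `bf10`, `bf_m`,
#'   `error_pct`; models in the order supplied
#' @export
comparison_table <- function(bfs, prior_probs = "uniform", models = NULL) {
  eb <- extract_log_bf(bfs)
  k <- length(eb$log_bf)
  if (is.null(eb$nms) || any(!nzchar(eb$nms))) stop("`bfs` must be named", call. = FALSE)
  if (identical(prior_probs, "uniform")) {
    lp_prior <- rep(-log(k), k)
  } else {
    if (is.null(names(prior_probs)) ||
        !setequal(names(prior_probs), eb$nms)) {
      stop("prior_probs names must match model names", call. = FALSE)
    }
    prior_probs <- prior_probs[eb$nms]
    if (abs(sum(prior_probs) - 1) > 1e-8) {
      stop("prior model probabilities must sum to 1", call. = FALSE)
    }
    lp_prior <- log(prior_probs)
  }
  lpost_un <- eb$log_bf + lp_prior
  lz <- log_sum_exp(lpost_un)
  lpost <- lpost_un - lz
  odds_bf <- vapply(seq_len(k), function(i) {
    if (k == 1) return(Inf)
    l_post_odds <- lpost[i] - log_sum_exp(lpost[-i])
    l_prior_odds <- lp_prior[i] - log_sum_exp(lp_prior[-i])
    exp(l_post_odds - l_prior_odds)
  }, numeric(1))
  out <- data.frame(model = eb$nms, p_m = exp(lp_prior), p_m_data = exp(lpost),
                    bf10 = exp(eb$log_bf), bf_m = odds_bf,
                    error_pct = eb$err, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "log_bf") <- stats::setNames(eb$log_bf, eb$nms)
  attr(out, "log_posterior") <- stats::setNames(lpost, eb$nms)
  if (!is.null(models)) {
    if (!setequal(names(models), eb$nms)) {
      stop("`models` names must match `bfs` names", call. = FALSE)
    }
    attr(out, "models") <- models[eb$nms]
  }
  out
}

#' Re-express Bayes factors against a different base model
#'
#' Each entry is divided by the current Bayes factor of the new base
#' (performed in log space).
#'
#' @param bfs named numeric vector of Bayes factors versus the current base
#' @param new_base name of the model to use as the new base
#' @return named numeric vector of Bayes factors versus `new_base`
#' @export
#' @examples
#' rebase_bayes_factors(c(`G + P` = 8.192e39, `G + P + G:P` = 8.864e38), "G + P")
rebase_bayes_factors <- function(bfs, new_base) {
  if (!new_base %in% names(bfs)) {
    stop("new base '", new_base, "' not present", call. = FALSE)
  }
  exp(log(bfs) - log(bfs[[new_base]]))
}

#' Effects table (Bayesian model averaging)
#'
#' Per-term prior and posterior inclusion probabilities (the summed model
#' probabilities over all models containing the term) and the inclusion Bayes
#' factor, the ratio of posterior to prior inclusion odds.
#'
#' @param rows a [comparison_table()] carrying a `models` attribute, i.e.
#'   built with its `models` argument
#' @param terms character vector of term labels to summarize
#' @return data.frame with columns `term`, `p_incl`, `p_incl_data`,
#'   `bf_inclusion`
#' @export
effects_table <- function(rows, terms) {
  models <- attr(rows, "models")
  if (is.null(models)) {
    stop("`rows` must carry model term sets; build it with ",
         "comparison_table(..., models = )", call. = FALSE)
  }
  lpost <- attr(rows, "log_posterior")
  out <- do.call(rbind, lapply(terms, function(tm) {
    has <- vapply(models, function(m) tm %in% m, logical(1))
    if (!any(has)) stop("term '", tm, "' absent from all models", call. = FALSE)
    p_incl <- sum(rows$p_m[has])
    lp_in <- log_sum_exp(lpost[has])
    p_incl_data <- exp(lp_in)
    bf_incl <- if (all(has)) {
      NA_real_  # prior inclusion odds are infinite; no odds change defined
    } else {
      lp_out <- log_sum_exp(lpost[!has])
      exp(lp_in - lp_out) * (1 - p_incl) / p_incl
    }
    data.frame(term = tm, p_incl = p_incl, p_incl_data = p_incl_data,
               bf_inclusion = bf_incl, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
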
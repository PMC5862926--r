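# Model specifications and design matrices for ANOVA-type linear models.

canon_term <- function(term) {
  if (length(term) == 1 && grepl(":", term, fixed = TRUE)) {
    term <- strsplit(term, ":", fixed = TRUE)[[1]]
  }
  sort(unique(term))
}

term_label <- function(term) paste(canon_term(term), collapse = ":")

sub_terms <- function(term) {
  term <- canon_term(term)
  k <- length(term)
  if (k == 1) return(list())
  subs <- list()
  for (m in seq_len(k - 1)) {
    cmb <- utils::combn(term, m, simplify = FALSE)
    subs <- c(subs, cmb)
  }
  subs
}

#' Specify an ANOVA-type model
#'
#' A model is a set of terms; each term is a set of factor names (a singleton
#' is a main effect, larger sets are interactions). Models must respect the
#' principle of marginality: an interaction may only appear together with all
#' of its component lower-order terms. Nuisance terms are included in every
#' candidate model (including the null model), so Bayes factors against that
#' null isolate the terms of interest. Random factors (typically the
#' participant identifier in repeated measures designs) get their own, wider
#' prior scale.
#'
#' @param terms character vector of term labels (`"A"`, `"A:B"`) or list of
#'   character vectors of factor names
#' @param nuisance terms included in every model; must be a subset of `terms`
#' @param random character vector of factor names treated as random effects
#' @return object of class `model_spec`
#' @export
#' @examples
#' model_spec(c("Gender", "Pitch", "Gender:Pitch"))
model_spec <- function(terms = character(), nuisance = character(),
                       random = character()) {
  as_list <- function(x) {
    if (is.character(x)) lapply(x, canon_term) else lapply(x, canon_term)
  }
  terms <- as_list(terms)
  nuisance <- as_list(nuisance)
  labs <- vapply(terms, term_label, character(1))
  if (anyDuplicated(labs)) stop("duplicate terms", call. = FALSE)
  nuis_labs <- vapply(nuisance, term_label, character(1))
  if (!all(nuis_labs %in% labs)) {
    stop("nuisance terms must be among the model terms", call. = FALSE)
  }
  for (tm in terms) {
    missing <- setdiff(vapply(sub_terms(tm), term_label, character(1)), labs)
    if (length(missing)) {
      stop("marginality violation: term '", term_label(tm),
           "' requires sub-terms: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  ord <- order(lengths(terms), labs)
  structure(list(terms = terms[ord], nuisance = nuisance,
                 random = unique(random)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(model_label(x), "\n")
  invisible(x)
}

#' Human-readable model label
#' @param model a [model_spec()]
#' @param drop_nuisance if `TRUE`, omit nuisance terms from the label
#' @return character scalar, `"Null model"` for a model with no terms of
#'   interest
#' @export
model_label <- function(model, drop_nuisance = TRUE) {
  labs <- vapply(model$terms, term_label, character(1))
  if (drop_nuisance) {
    labs <- setdiff(labs, vapply(model$nuisance, term_label, character(1)))
    labs <- setdiff(labs, model$random)
  }
  if (!length(labs)) "Null model" else paste(labs, collapse = " + ")
}

# orthonormal sum-to-zero contrast for a k-level factor: columns of Q span
# the complement of the constant vector, Q'Q = I. A balanced replication of
# the k levels then yields effect columns that each sum to zero.
contrast_Q <- function(k) {
  if (k < 2) stop("factor with a single level", call. = FALSE)
  e <- eigen(diag(k) - 1 / k, symmetric = TRUE)
  Q <- e$vectors[, seq_len(k - 1), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(ncol(Q))) if (Q[1, j] < 0) Q[, j] <- -Q[, j]
  Q
}

#' Build per-term design matrices
#'
#' Sum-to-zero effect coding: a k-level factor contributes k-1 orthonormal
#' contrast columns; interaction columns are element-wise products of the
#' component contrasts. The intercept is handled separately (it is common to
#' all models and integrated under a flat prior), so only the effect blocks
#' are returned. Complete cases only.
#'
#' @param table a [bf_table()]
#' @param dependent continuous outcome column
#' @param model a [model_spec()]
#' @return list with `y` (response), `blocks` (named list of matrices, one per
#'   term, in the model's term order), `random` (logical per block), `n`
#' @export
build_design <- function(table, dependent, model) {
  stopifnot(inherits(table, "bf_table"), inherits(model, "model_spec"))
  lev <- table_levels(table)
  if (lev[[dependent]] != "continuous") {
    stop("dependent variable must be continuous", call. = FALSE)
  }
  factors <- unique(unlist(model$terms))
  if (!all(factors %in% names(table))) {
    stop("unknown factors: ",
         paste(setdiff(factors, names(table)), collapse = ", "), call. = FALSE)
  }
  if (length(factors) && any(lev[factors] != "nominal")) {
    stop("all model factors must be nominal", call. = FALSE)
  }
  df <- as.data.frame(table)[, c(dependent, factors), drop = FALSE]
  df[[dependent]] <- as.numeric(df[[dependent]])
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  y <- df[[dependent]]

  fac_levels <- lapply(factors, function(f) unique(as.character(df[[f]])))
  names(fac_levels) <- factors
  ones <- vapply(fac_levels, length, integer(1))
  if (length(ones) && any(ones < 2)) {
    stop("factor with a single level: ",
         paste(names(ones)[ones < 2], collapse = ", "), call. = FALSE)
  }
  Qs <- lapply(fac_levels, function(l) contrast_Q(length(l)))

  blocks <- list()
  random <- logical(0)
  for (tm in model$terms) {
    # empty-cell check over the term's factor cross
    if (length(tm) > 1) {
      cross <- table(df[, tm, drop = FALSE])
      if (any(cross == 0)) {
        idx <- which(cross == 0, arr.ind = TRUE)
        cells <- apply(idx, 1, function(i) {
          paste(mapply(function(d, j) dimnames(cross)[[d]][j],
                       seq_along(tm), i), collapse = ":")
        })
        stop("empty cells in term '", term_label(tm), "': ",
             paste(cells, collapse = ", "), call. = FALSE)
      }
    }
    # per-factor contrast rows selected by each observation's level
    mats <- lapply(tm, function(f) {
      Qs[[f]][match(as.character(df[[f]]), fac_levels[[f]]), , drop = FALSE]
    })
    X <- mats[[1]]
    if (length(mats) > 1) {
      for (m in mats[-1]) {
        # element-wise Kronecker over columns
        X <- do.call(cbind, lapply(seq_len(ncol(X)), function(i) X[, i] * m))
      }
    }
    lab <- term_label(tm)
    blocks[[lab]] <- X
    random[lab] <- length(tm) == 1 && tm %in% model$random
  }
  n <- length(y)
  total_cols <- sum(vapply(blocks, ncol, integer(1)))
  if (length(blocks) && n <= total_cols + 1) {
    stop("not enough observations for the requested model", call. = FALSE)
  }
  list(y = y, blocks = blocks, random = random, n = n)
}
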
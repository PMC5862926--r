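# Typed rectangular data: reading, descriptives, wide-to-long reshaping.

#' Construct a typed data table
#'
#' A `bf_table` is a plain data frame carrying one measurement level per
#' column: `"continuous"`, `"ordinal"` or `"nominal"`. Levels not supplied are
#' inferred: an all-numeric column with more than ten distinct non-missing
#' values is treated as continuous, an all-numeric column with ten or fewer as
#' ordinal, anything else as nominal. The threshold is a best-guess heuristic
#' and any level can be overridden with [table_levels<-].
#'
#' @param df a data.frame
#' @param levels optional named character vector of measurement levels
#' @return a `bf_table`
#' @export
#' @examples
#' tab <- bf_table(data.frame(y = rnorm(5), g = c("a", "b", "a", "b", "a")))
#' table_levels(tab)
bf_table <- function(df, levels = NULL) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(names(df))) stop("column names must be unique", call. = FALSE)
  lev <- vapply(df, infer_level, character(1))
  if (!is.null(levels)) {
    bad <- setdiff(names(levels), names(df))
    if (length(bad)) stop("unknown columns: ", paste(bad, collapse = ", "), call. = FALSE)
    lev[names(levels)] <- unname(levels)
  }
  check_levels(df, lev)
  structure(df, measure_levels = lev, class = c("bf_table", "data.frame"))
}

infer_level <- function(x) {
  v <- x[!is.na(x)]
  num <- if (is.numeric(x)) TRUE else {
    suppressWarnings(all(!is.na(as.numeric(as.character(v))))) && length(v) > 0
  }
  if (num) {
    nv <- if (is.numeric(x)) v else as.numeric(as.character(v))
    if (length(unique(nv)) > 10) "continuous" else "ordinal"
  } else {
    "nominal"
  }
}

check_levels <- function(df, lev) {
  stopifnot(all(lev %in% c("continuous", "ordinal", "nominal")))
  for (nm in names(df)) {
    if (lev[[nm]] == "continuous" && !is.numeric(df[[nm]])) {
      ok <- suppressWarnings(all(!is.na(as.numeric(as.character(
        df[[nm]][!is.na(df[[nm]])])))))
      if (!ok) stop("column '", nm, "' declared continuous but is not numeric",
                    call. = FALSE)
    }
    if (lev[[nm]] == "nominal" &&
        length(unique(df[[nm]][!is.na(df[[nm]])])) < 1) {
      stop("nominal column '", nm, "' has no non-missing level", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Measurement levels of a table
#' @param x a `bf_table`
#' @return named character vector
#' @export
table_levels <- function(x) {
  stopifnot(inherits(x, "bf_table"))
  attr(x, "measure_levels")
}

#' @rdname table_levels
#' @param value named character vector of replacement levels
#' @export
`table_levels<-` <- function(x, value) {
  lev <- attr(x, "measure_levels")
  lev[names(value)] <- unname(value)
  check_levels(x, lev)
  attr(x, "measure_levels") <- lev
  x
}

#' Read a CSV file into a typed table
#'
#' Comma-separated, UTF-8, header row, `"."` decimal mark. Files using a
#' decimal comma are not guessed at: their numeric-looking columns simply come
#' out nominal, which the caller can inspect and fix upstream. Ragged rows are
#' a parse error naming the first offending row.
#'
#' @param path file path
#' @param levels optional named character vector overriding inferred levels
#' @return a [bf_table()]
#' @export
read_bf_csv <- function(path, levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = TRUE)
  nf <- nf[!is.na(nf)]
  if (!length(nf)) stop("empty file: ", path, call. = FALSE)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged CSV: row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  bf_table(df, levels = levels)
}

#' Write a typed table to CSV
#'
#' Numeric cells are written with 15 significant digits so that a read/write
#' round trip is the identity up to float formatting.
#'
#' @param x a `bf_table` or data.frame
#' @param path output file path
#' @export
write_bf_csv <- function(x, path) {
  df <- as.data.frame(x)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- formatC(df[[nm]], digits = 15, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-group descriptive statistics
#'
#' Sample size, mean and standard deviation of a continuous dependent variable
#' within each level of a nominal grouping variable. Rows with a missing value
#' in either column are dropped pairwise. Groups are reported in order of
#' first appearance in the table ("group 1" is the level seen first from the
#' top of the file).
#'
#' @param table a `bf_table`
#' @param dependent name of a continuous column
#' @param group name of a nominal column
#' @return data.frame with columns `group`, `n`, `mean`, `sd`
#' @export
descriptives <- function(table, dependent, group) {
  stopifnot(inherits(table, "bf_table"))
  lev <- table_levels(table)
  if (!dependent %in% names(table) || !group %in% names(table)) {
    stop("unknown column name", call. = FALSE)
  }
  if (lev[[dependent]] != "continuous") {
    stop("dependent variable '", dependent, "' must be continuous", call. = FALSE)
  }
  if (lev[[group]] != "nominal") {
    stop("grouping variable '", group, "' must be nominal", call. = FALSE)
  }
  y <- as.numeric(table[[dependent]])
  g <- as.character(table[[group]])
  levels_seen <- unique(g[!is.na(g)])   # group order: first appearance
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  if (!length(levels_seen)) stop("no complete observations", call. = FALSE)
  out <- do.call(rbind, lapply(levels_seen, function(l) {
    yi <- y[g == l]
    if (!length(yi)) stop("group '", l, "' has no non-missing values", call. = FALSE)
    data.frame(group = l, n = length(yi), mean = mean(yi),
               sd = if (length(yi) > 1) stats::sd(yi) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Reshape a wide repeated-measures table to long format
#'
#' Each column of the wide table holds one cell of a factorial
#' repeated-measures design; every factorial cell (the cross of all factor
#' levels) must be mapped to exactly one column. A synthetic subject
#' identifier is added and the factor columns come out nominal.
#'
#' @param table a `bf_table` in wide format (one row per subject)
#' @param factors named list of level vectors, e.g.
#'   `list(Disgust = c("LD", "HD"), Fright = c("LF", "HF"))`
#' @param cell_map named character vector mapping column names to cell labels;
#'   a cell label joins one level per factor with `":"` in the order of
#'   `factors`, e.g. `c(col1 = "LD:LF", ...)`
#' @param dependent name for the outcome column in the result
#' @return a long-format [bf_table()] with columns `subject`, one nominal
#'   column per factor, and the outcome
#' @export
wide_to_cells <- function(table, factors, cell_map, dependent = "y") {
  stopifnot(inherits(table, "bf_table"), is.list(factors), length(factors) >= 1)
  cells <- apply(expand.grid(rev(factors), stringsAsFactors = FALSE), 1,
                 function(r) paste(rev(r), collapse = ":"))
  mapped <- unname(cell_map)
  missing_cells <- setdiff(cells, mapped)
  dup <- mapped[duplicated(mapped)]
  extra <- setdiff(mapped, cells)
  if (length(missing_cells) || length(dup) || length(extra)) {
    stop("bad cell map; unmapped: [", paste(missing_cells, collapse = ", "),
         "] duplicated: [", paste(unique(dup), collapse = ", "),
         "] unknown: [", paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  bad_cols <- setdiff(names(cell_map), names(table))
  if (length(bad_cols)) {
    stop("columns not in table: ", paste(bad_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(table)
  long <- do.call(rbind, lapply(names(cell_map), function(cn) {
    levs <- strsplit(cell_map[[cn]], ":", fixed = TRUE)[[1]]
    row <- data.frame(subject = sprintf("s%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (i in seq_along(factors)) row[[names(factors)[i]]] <- levs[i]
    row[[dependent]] <- as.numeric(table[[cn]])
    row
  }))
  rownames(long) <- NULL
  lv <- c(subject = "nominal",
          stats::setNames(rep("nominal", length(factors)), names(factors)),
          stats::setNames("continuous", dependent))
  bf_table(long, levels = lv)
}

#' @export
print.bf_table <- function(x, ...) {
  lev <- attr(x, "measure_levels")
  cat(sprintf("bf_table: %d rows, %d columns\n", nrow(x), ncol(x)))
  cat(paste(sprintf("  %s <%s>", names(lev), lev), collapse = "\n"), "\n")
  NextMethod()
}

#' JSON representation of package objects
#'
#' @param x a `bf_table`, descriptives data frame, or result object
#' @param ... passed to [jsonlite::toJSON()]
#' @return a JSON string
#' @export
to_json <- function(x, ...) UseMethod("to_json")

#' @export
to_json.bf_table <- function(x, ...) {
  jsonlite::toJSON(list(columns = lapply(names(x), function(nm) {
    list(name = nm, level = table_levels(x)[[nm]], values = x[[nm]])
  })), auto_unbox = TRUE, digits = NA, null = "null", na = "null", ...)
}

#' @export
to_json.default <- function(x, ...) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null", ...)
}
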
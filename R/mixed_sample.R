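#' Construct a mixed-type sample
#'
#' Bundles an observation matrix with a per-column type mask separating
#' qualitative (finite-support, compared by exact equality) from quantitative
#' (real-valued, metric) components. Qualitative columns hold numeric category
#' codes; two entries belong to the same category if and only if they compare
#' exactly equal. Missing or non-finite entries are rejected: rows with
#' missing data must be removed before analysis.
#'
#' @param data numeric matrix or data.frame; rows are i.i.d. observations.
#' @param types character vector with one entry per column, each
#'   `"quantitative"` or `"qualitative"` (shorthands `"t"` and `"l"` are
#'   accepted). A single value is recycled across all columns.
#' @return An object of class `mixed_sample` with elements `data` (numeric
#'   matrix), `types`, `n` and `m`.
#' @examples
#' s <- mixed_sample(cbind(x = rnorm(10), g = rbinom(10, 3, 0.5)),
#'                   c("quantitative", "qualitative"))
#' s
#' @export
mixed_sample <- function(data, types) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L) stop("'data' must contain at least one row")
  if (is.null(colnames(x)) && ncol(x) > 0L)
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) > 0L && !all(is.finite(x)))
    stop("'data' must be finite: missing values are not supported")
  types <- normalize_types(types, ncol(x))
  structure(list(data = x, types = types, n = nrow(x), m = ncol(x)),
            class = "mixed_sample")
}

#' @export
print.mixed_sample <- function(x, ...) {
  cat(sprintf("mixed_sample: %d observations of %d column(s) (%d quantitative, %d qualitative)\n",
              x$n, x$m, sum(x$types == "quantitative"),
              sum(x$types == "qualitative")))
  invisible(x)
}

normalize_types <- function(types, m) {
  if (length(types) == 1L && m > 1L) types <- rep(types, m)
  if (length(types) != m)
    stop("'types' must have one entry per column")
  map <- c(t = "quantitative", quantitative = "quantitative",
           quant = "quantitative", l = "qualitative",
           qualitative = "qualitative", qual = "qualitative")
  out <- unname(map[match(tolower(types), names(map))])
  if (anyNA(out))
    stop("each type must be 'quantitative' or 'qualitative'")
  out
}

as_mixed_sample <- function(data, types) {
  if (inherits(data, "mixed_sample")) return(data)
  if (is.null(types))
    stop("'types' is required when 'data' is not a mixed_sample")
  mixed_sample(data, types)
}

# Resolve a block given as column names or indices to integer indices.
resolve_cols <- function(sample, cols) {
  if (is.null(cols) || length(cols) == 0L) return(integer(0))
  if (is.character(cols)) {
    idx <- match(cols, colnames(sample$data))
    if (anyNA(idx)) stop("unknown column(s): ",
                         paste(cols[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(cols)
  if (any(idx < 1L | idx > sample$m)) stop("column index out of range")
  idx
}

check_disjoint <- function(x, y, z) {
  all_cols <- c(x, y, z)
  if (anyDuplicated(all_cols))
    stop("blocks X, Y and Z must be pairwise disjoint")
  invisible(TRUE)
}

qual_of <- function(sample, cols) cols[sample$types[cols] == "qualitative"]
quant_of <- function(sample, cols) cols[sample$types[cols] == "quantitative"]

#' Rank-transform quantitative components
#'
#' Replaces each value by its rank, using first-appearance order to break
#' ties, so that the output is always a permutation of `1..n`. Applied to a
#' `mixed_sample`, only quantitative columns are transformed; qualitative
#' category codes are left untouched. Rank transformation puts all
#' quantitative components on the same scale and removes duplicate values,
#' which stabilises nearest-neighbour entropy terms.
#'
#' @param x numeric vector or `mixed_sample`.
#' @param ... unused.
#' @return An object of the same shape as `x`.
#' @examples
#' rank_transform(c(10, 30, 20))  # 1 3 2
#' rank_transform(c(5, 5, 5))     # 1 2 3
#' @export
rank_transform <- function(x, ...) UseMethod("rank_transform")

#' @rdname rank_transform
#' @export
rank_transform.default <- function(x, ...) {
  if (length(x) < 1L) stop("input must be nonempty")
  rank(x, ties.method = "first")
}

#' @rdname rank_transform
#' @export
rank_transform.mixed_sample <- function(x, ...) {
  for (j in which(x$types == "quantitative"))
    x$data[, j] <- rank(x$data[, j], ties.method = "first")
  x
}

#' Partition rows by qualitative value tuples
#'
#' Maps each observed tuple of qualitative values to the set of rows carrying
#' it, together with its empirical frequency. With an empty column set a
#' single bin containing every row (frequency 1) is returned, so
#' unconditional quantities are the one-bin special case. Bins are ordered by
#' first occurrence of their defining row, which makes downstream weighted
#' sums invariant to the order in which columns are listed.
#'
#' @param sample a `mixed_sample`.
#' @param l_columns qualitative column names or indices (possibly empty).
#' @return An object of class `bin_partition`: list with `rows` (list of
#'   integer row-index vectors), `freq` (empirical frequencies summing to 1)
#'   and `n`.
#' @export
qualitative_partition <- function(sample, l_columns = NULL) {
  cols <- resolve_cols(sample, l_columns)
  if (any(sample$types[cols] != "qualitative"))
    stop("'l_columns' must all be qualitative")
  n <- sample$n
  if (length(cols) == 0L) {
    rows <- list(seq_len(n))
  } else {
    key <- do.call(paste, c(lapply(cols, function(j) sample$data[, j]),
                            sep = "\r"))
    rows <- split(seq_len(n), factor(key, levels = unique(key)))
    # canonical order: by first row index of each bin (label-independent)
    rows <- rows[order(vapply(rows, `[`, integer(1), 1L))]
    names(rows) <- NULL
  }
  structure(list(rows = rows, freq = lengths(rows) / n, n = n),
            class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  cat(sprintf("bin_partition: %d bin(s) over %d rows; sizes: %s\n",
              length(x$rows), x$n,
              paste(lengths(x$rows), collapse = " ")))
  invisible(x)
}
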
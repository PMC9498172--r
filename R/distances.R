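#' Chebyshev (maximum-norm) distance
#'
#' @param a,b numeric vectors of equal length.
#' @return `max_r |a_r - b_r|`.
#' @examples
#' linf_distance(c(1, 5), c(4, 3))  # 3
#' @export
linf_distance <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have the same length")
  if (length(a) < 1L) stop("vectors must be nonempty")
  max(abs(a - b))
}

#' Adaptive distance for mixed vectors
#'
#' Coordinate-wise maximum of the absolute difference on quantitative
#' components and the (0-Inf) distance on qualitative components: the result
#' is `Inf` as soon as any qualitative component differs, and otherwise the
#' Chebyshev distance over the quantitative components (0 if there are none).
#' This is the metric used to build local permutation neighbourhoods: a
#' neighbourhood can never leave a qualitative stratum.
#'
#' @param a,b mixed vectors of equal length.
#' @param types per-component type mask (`"quantitative"`/`"qualitative"`).
#' @return Nonnegative real or `Inf`.
#' @export
adaptive_distance <- function(a, b, types) {
  if (length(a) != length(b)) stop("'a' and 'b' must have the same length")
  types <- normalize_types(types, length(a))
  qual <- types == "qualitative"
  if (any(a[qual] != b[qual])) return(Inf)
  if (all(qual)) return(0)
  max(abs(a[!qual] - b[!qual]), 0)
}

#' Mixed metric with a finite qualitative distance
#'
#' Like [adaptive_distance()], but qualitative mismatches contribute the
#' finite constant `D_l` instead of `Inf`. This is the (0-D) convention used
#' by the kNN baseline estimators ([cmi_knn()]), with `D_l = 1` as the usual
#' default.
#'
#' @inheritParams adaptive_distance
#' @param D_l positive qualitative distance.
#' @return Nonnegative real.
#' @export
mixed_metric <- function(a, b, types, D_l = 1) {
  if (length(a) != length(b)) stop("'a' and 'b' must have the same length")
  if (D_l <= 0) stop("'D_l' must be positive")
  types <- normalize_types(types, length(a))
  qual <- types == "qualitative"
  d <- 0
  if (any(qual) && any(a[qual] != b[qual])) d <- D_l
  if (any(!qual)) d <- max(d, abs(a[!qual] - b[!qual]))
  d
}

# Full pairwise mixed-metric distance matrix over the given columns.
# D_l = Inf yields the adaptive (0-Inf) distance. Zero columns => all zeros.
mixed_dist_matrix <- function(sample, cols, D_l = 1) {
  n <- sample$n
  qt <- quant_of(sample, cols)
  ql <- qual_of(sample, cols)
  dm <- if (length(qt)) {
    as.matrix(stats::dist(sample$data[, qt, drop = FALSE],
                          method = "maximum"))
  } else {
    matrix(0, n, n)
  }
  for (j in ql) {
    v <- sample$data[, j]
    neq <- outer(v, v, "!=")
    dm[neq & dm < D_l] <- D_l
  }
  dimnames(dm) <- NULL
  dm
}
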
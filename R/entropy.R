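#' Default neighbour-count rule
#'
#' Chooses the number of nearest neighbours from the size of the subsample a
#' kNN entropy term is computed on: `max(floor(n_sub/10), 1)`. The choice is
#' made per entropy term, each from its own subsample size, rather than once
#' globally.
#'
#' @param n_sub subsample size.
#' @return Integer neighbour count, at least 1.
#' @export
default_k <- function(n_sub) max(floor(n_sub / 10), 1L)

#' Plug-in (histogram) entropy of a qualitative partition
#'
#' `-sum(p * log(p))` over the empirical bin frequencies, in nats. Zero for a
#' single bin; at most `log(#bins)`.
#'
#' @param partition a `bin_partition` from [qualitative_partition()].
#' @return Entropy in nats.
#' @export
plugin_entropy <- function(partition) {
  stopifnot(inherits(partition, "bin_partition"))
  p <- partition$freq
  -sum(p * log(p))
}

#' Kozachenko-Leonenko kNN entropy (maximum norm, volume term omitted)
#'
#' Differential-entropy estimate `digamma(n) - digamma(k) +
#' (d/n) * sum(log xi_i)` where `xi_i` is twice the Chebyshev distance from
#' point `i` to its `k`-th nearest neighbour. The `log` of the maximum-norm
#' unit-ball volume (`d * log 2`) is deliberately omitted from every term: in
#' the eight-term conditional mutual information combination the volume
#' contributions cancel exactly (`d_xz + d_yz - d_xyz - d_z = 0`), so
#' dropping them everywhere changes no estimate while keeping each term
#' simple. Add `d * log 2` to recover the conventional single-term value.
#'
#' Duplicate points give `xi_i = 0`; `xi_i` is floored at `tie_floor` to keep
#' the logarithm finite. Rank-transforming quantitative columns beforehand
#' (see [rank_transform()]) removes duplicates altogether and is recommended
#' for testing workflows.
#'
#' @param points numeric matrix (rows = points) or vector (1-D).
#' @param k neighbour count, `1 <= k <= nrow(points) - 1`.
#' @param tie_floor positive floor applied to `xi`; default `1e-10` times the
#'   data range (1e-10 if the range is zero).
#' @return Entropy in nats.
#' @examples
#' knn_entropy(c(0, 0.5, 1), k = 1)  # digamma(3) - digamma(1) = 1.5
#' @export
knn_entropy <- function(points, k, tie_floor = NULL) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 1L)
  storage.mode(pts) <- "double"
  n <- nrow(pts); d <- ncol(pts)
  if (n < 2L) stop("need at least two points")
  if (d < 1L) stop("need at least one dimension")
  if (k < 1 || k > n - 1) stop("'k' must lie in [1, n-1]")
  if (is.null(tie_floor)) tie_floor <- default_tie_floor(pts)
  xi <- 2 * knn_linf_kth(pts, as.integer(k))
  digamma(n) - digamma(k) + d * mean(log(pmax(xi, tie_floor)))
}

default_tie_floor <- function(pts) {
  rng <- diff(range(pts))
  1e-10 * (if (is.finite(rng) && rng > 0) rng else 1)
}

#' Bin-weighted conditional kNN entropy
#'
#' Estimates the entropy of quantitative columns conditionally on a
#' qualitative partition: the frequency-weighted average of per-bin
#' [knn_entropy()] values, each bin using its own neighbour count
#' `k_rule(n_b)` clamped to `[1, n_b - 1]`. Singleton bins (no neighbour
#' available) contribute zero quantitative entropy while keeping their full
#' weight, so the weights always sum to one. An empty quantitative column set
#' returns 0.
#'
#' @param sample a `mixed_sample`.
#' @param t_columns quantitative column names or indices (possibly empty).
#' @param partition a `bin_partition` over the conditioning qualitative
#'   tuples.
#' @param k_rule function mapping a bin size to a neighbour count;
#'   default [default_k()].
#' @param tie_floor see [knn_entropy()]; computed once from the full sample's
#'   quantitative columns so all bins share the same floor.
#' @return Entropy in nats.
#' @export
conditional_knn_entropy <- function(sample, t_columns, partition,
                                    k_rule = default_k, tie_floor = NULL) {
  cols <- resolve_cols(sample, t_columns)
  if (any(sample$types[cols] != "quantitative"))
    stop("'t_columns' must all be quantitative")
  if (length(cols) == 0L) return(0)
  pts_all <- sample$data[, cols, drop = FALSE]
  if (is.null(tie_floor)) tie_floor <- default_tie_floor(pts_all)
  h <- 0
  for (b in seq_along(partition$rows)) {
    rows <- partition$rows[[b]]
    nb <- length(rows)
    if (nb < 2L) next  # singleton bin: zero quantitative entropy
    k <- min(max(k_rule(nb), 1L), nb - 1L)
    h <- h + partition$freq[b] *
      knn_entropy(pts_all[rows, , drop = FALSE], k, tie_floor)
  }
  h
}
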
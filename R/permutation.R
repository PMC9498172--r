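#' Local permutation neighbourhoods over a conditioning block
#'
#' For each observation `i`, determines the set `N_i` of candidate donors for
#' a local permutation of X: points whose conditioning values `Z_j` are at
#' least as close to `Z_i` as its `k_i`-th nearest neighbour (the point
#' itself counts as its own first neighbour, so `i` is always in `N_i`).
#' Distances use the adaptive metric ([adaptive_distance()]): absolute
#' difference on quantitative components, (0-Inf) on qualitative ones, so a
#' neighbourhood never crosses a qualitative stratum as long as `k_i` does
#' not exceed the stratum size.
#'
#' With `adaptive = TRUE` (the LocAT rule) `k_i = min(k_perm, n_i_l)` where
#' `n_i_l` is the number of points sharing `i`'s qualitative conditioning
#' values, which keeps every `k_i`-th neighbour distance finite. With
#' `adaptive = FALSE` (the plain local test) `k_i = k_perm` for all points;
#' if a qualitative stratum is smaller than `k_perm` the neighbour distance
#' is infinite and `N_i` degenerates to the whole sample.
#'
#' With an empty conditioning block every `N_i` is the whole sample.
#'
#' @param z_data numeric matrix of conditioning columns (possibly zero
#'   columns), or a `mixed_sample`.
#' @param types per-column type mask for `z_data` (ignored for a
#'   `mixed_sample`).
#' @param k_perm neighbourhood size hyper-parameter (default 5).
#' @param adaptive use the per-point adaptive `k_i` rule (default `TRUE`).
#' @return An object of class `neighborhood_set`: list with `neighbors`
#'   (list of integer index sets), `k_i`, `d_k` (the `k_i`-th neighbour
#'   distances) and `n_l`.
#' @export
local_neighborhoods <- function(z_data, types = NULL, k_perm = 5,
                                adaptive = TRUE) {
  if (k_perm < 1) stop("'k_perm' must be at least 1")
  s <- if (inherits(z_data, "mixed_sample")) z_data else
    mixed_sample(if (is.matrix(z_data)) z_data else as.matrix(z_data), types)
  n <- s$n
  cols <- seq_len(s$m)
  if (length(cols) == 0L) {
    return(structure(list(neighbors = rep(list(seq_len(n)), n),
                          k_i = rep.int(n, n), d_k = rep.int(Inf, n),
                          n_l = rep.int(n, n)),
                     class = "neighborhood_set"))
  }
  ql <- qual_of(s, cols)
  qt <- quant_of(s, cols)
  classes <- qualitative_partition(s, ql)$rows
  n_l <- integer(n)
  for (rows in classes) n_l[rows] <- length(rows)
  k_i <- if (adaptive) pmin(k_perm, n_l) else pmin(rep.int(k_perm, n), n)

  neighbors <- vector("list", n)
  d_k <- numeric(n)
  for (rows in classes) {
    nc <- length(rows)
    dm <- if (length(qt)) {
      as.matrix(stats::dist(s$data[rows, qt, drop = FALSE],
                            method = "maximum"))
    } else {
      matrix(0, nc, nc)
    }
    for (a in seq_len(nc)) {
      i <- rows[a]
      if (k_i[i] <= nc) {
        d <- sort(dm[a, ], partial = k_i[i])[k_i[i]]
        d_k[i] <- d
        neighbors[[i]] <- rows[dm[a, ] <= d]
      } else {
        # only reachable without the adaptive clamp: the k-th neighbour
        # lies outside the qualitative stratum, at infinite distance
        d_k[i] <- Inf
        neighbors[[i]] <- seq_len(n)
      }
    }
  }
  structure(list(neighbors = neighbors, k_i = k_i, d_k = d_k, n_l = n_l),
            class = "neighborhood_set")
}

#' @export
print.neighborhood_set <- function(x, ...) {
  cat(sprintf("neighborhood_set over %d points; |N_i| in [%d, %d], k_i in [%d, %d]\n",
              length(x$neighbors), min(lengths(x$neighbors)),
              max(lengths(x$neighbors)), min(x$k_i), max(x$k_i)))
  invisible(x)
}

#' Draw one local permutation
#'
#' For each observation `i`, draws a donor index uniformly from its
#' neighbourhood `N_i`, independently across observations and with
#' replacement: the result need not be a bijection, and `pi(i) = i` is a
#' legal draw.
#'
#' @param neighborhoods a `neighborhood_set`.
#' @return Integer vector `pi` of length `n`.
#' @export
draw_local_permutation <- function(neighborhoods) {
  stopifnot(inherits(neighborhoods, "neighborhood_set"))
  vapply(neighborhoods$neighbors,
         function(s) s[sample.int(length(s), 1L)], integer(1))
}

#' Permutation test of conditional independence
#'
#' Tests `H0: X independent of Y given Z` by comparing an observed
#' conditional mutual information statistic against `B` statistics computed
#' on locally permuted samples `(X_pi(i), Y_i, Z_i)`. Three permutation
#' schemes are available:
#'
#' * `"glot"`: global test; `pi` is a uniform random permutation of all
#'   rows, which breaks X-Z dependence as well and is only valid when Z is
#'   empty or independent of X.
#' * `"loct"`: local test with a fixed neighbourhood size `k_perm` under the
#'   adaptive distance.
#' * `"locat"` (default): local adaptive test; the neighbourhood size is
#'   clamped per point to its qualitative stratum size, see
#'   [local_neighborhoods()].
#'
#' The p-value is the fraction of permuted statistics at least as large as
#' the observed one, `mean(permuted >= statistic)`, always a multiple of
#' `1/B` in `[0, 1]` (no add-one smoothing). Quantitative columns are
#' rank-transformed once before testing by default, which puts components on
#' a common scale and removes ties. When Z is empty all three schemes reduce
#' to the global test.
#'
#' @inheritParams cmih
#' @param estimator `"cmih"` (default), `"ms"`, `"ravk"`, `"fp"`, or a
#'   function `f(sample, x, y, z)` returning a numeric statistic.
#' @param scheme permutation scheme, one of `"locat"`, `"loct"`, `"glot"`.
#' @param B number of permutations (default 1000).
#' @param k_perm neighbourhood size hyper-parameter (default 5).
#' @param rank_transform rank-transform quantitative columns first
#'   (default `TRUE`).
#' @param seed optional integer seed; all permutation draws derive from it.
#' @param D_l qualitative distance used by the MS/RAVK/FP estimators inside
#'   the test (default 1, the usual (0-1) convention; neighbourhoods always
#'   use the (0-Inf) adaptive distance regardless).
#' @return An object of classes `cmi_test` and `htest` with fields
#'   `statistic`, `p.value`, `permuted` (the `B` permuted statistics), and
#'   the full configuration.
#' @examples
#' set.seed(7)
#' d <- cbind(x = rnorm(80), y = rnorm(80))
#' tst <- cmi_test(d, x = "x", y = "y", types = "quantitative",
#'                 B = 99, seed = 1)
#' tst$p.value
#' @export
cmi_test <- function(data, x, y, z = NULL, types = NULL,
                     estimator = c("cmih", "ms", "ravk", "fp"),
                     scheme = c("locat", "loct", "glot"),
                     B = 1000, k_perm = 5, rank_transform = TRUE,
                     seed = NULL, k_rule = default_k, D_l = 1) {
  scheme <- match.arg(scheme)
  if (B < 1) stop("'B' must be at least 1")
  sample <- as_mixed_sample(data, types)
  x <- resolve_cols(sample, x)
  y <- resolve_cols(sample, y)
  z <- resolve_cols(sample, z)
  if (length(x) < 1L || length(y) < 1L)
    stop("blocks X and Y must each contain at least one column")
  check_disjoint(x, y, z)
  n <- sample$n
  if (!is.null(seed)) set.seed(seed)
  if (rank_transform) sample <- rank_transform(sample)

  est_name <- if (is.function(estimator)) "custom" else
    match.arg(estimator)
  stat <- if (is.function(estimator)) {
    function(perm) {
      s <- sample
      if (!is.null(perm)) s$data[, x] <- s$data[perm, x, drop = FALSE]
      estimator(s, x, y, z)
    }
  } else if (est_name == "cmih") {
    cmih_statistic(sample, x, y, z, k_rule = k_rule)
  } else {
    function(perm) {
      s <- sample
      if (!is.null(perm)) s$data[, x] <- s$data[perm, x, drop = FALSE]
      cmi_knn(s, x, y, z, method = est_name, D_l = D_l)$value
    }
  }

  observed <- stat(NULL)

  global <- scheme == "glot" || length(z) == 0L
  nb <- NULL
  if (!global) {
    zs <- mixed_sample(sample$data[, z, drop = FALSE], sample$types[z])
    nb <- local_neighborhoods(zs, k_perm = k_perm,
                              adaptive = scheme == "locat")
  }
  # draw all index maps first so results do not depend on evaluation order
  perms <- if (global) {
    replicate(B, sample.int(n), simplify = FALSE)
  } else {
    replicate(B, draw_local_permutation(nb), simplify = FALSE)
  }
  permuted <- vapply(perms, stat, numeric(1))
  p <- mean(permuted >= observed)

  structure(list(statistic = c(cmi = observed), p.value = p,
                 permuted = permuted, B = B,
                 estimator = est_name, scheme = scheme, k_perm = k_perm,
                 rank_transform = rank_transform, seed = seed, n = n,
                 neighborhoods = nb,
                 method = sprintf("%s permutation test of conditional independence (%s statistic, B = %d)",
                                  switch(scheme, locat = "Local adaptive",
                                         loct = "Local", glot = "Global"),
                                  toupper(est_name), B),
                 data.name = deparse(substitute(data)),
                 alternative = "X and Y are dependent given Z"),
            class = c("cmi_test", "htest"))
}
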
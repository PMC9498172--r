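#' Hybrid conditional mutual information estimator for mixed data (CMIh)
#'
#' Estimates `I(X;Y|Z)` in nats for blocks of columns that may each mix
#' qualitative and quantitative components. Writing `Xt`/`Xl` for the
#' quantitative/qualitative sub-vectors (and likewise for Y, Z), the estimate
#' decomposes into eight entropy terms in which conditioning only ever
#' involves qualitative components:
#'
#' \deqn{\hat I = \hat H(Xt,Zt|Xl,Zl) + \hat H(Yt,Zt|Yl,Zl) -
#'   \hat H(Xt,Yt,Zt|Xl,Yl,Zl) - \hat H(Zt|Zl) + \hat H(Xl,Zl) +
#'   \hat H(Yl,Zl) - \hat H(Xl,Yl,Zl) - \hat H(Zl)}
#'
#' Qualitative terms use the plug-in histogram estimator over observed value
#' tuples ([plugin_entropy()]); conditional quantitative terms use
#' Kozachenko-Leonenko kNN entropies within each qualitative bin
#' ([conditional_knn_entropy()]), each with a neighbour count chosen from its
#' own bin size. Empty column sets contribute zero. The result is symmetric
#' in X and Y, deterministic for a fixed input, and may be negative in finite
#' samples; no non-negativity clamp is applied because permutation tests need
#' the raw statistic.
#'
#' @param data a `mixed_sample`, or a matrix/data.frame together with
#'   `types`.
#' @param x,y,z column names or indices of the X, Y and Z blocks; `z` may be
#'   `NULL` or empty, in which case the (unconditional) mutual information is
#'   estimated.
#' @param types per-column type mask; ignored when `data` is a
#'   `mixed_sample`.
#' @param k_rule neighbour-count rule, see [default_k()].
#' @param tie_floor see [knn_entropy()].
#' @return An object of class `cmih_estimate`: list with `value` (nats),
#'   `terms` (the eight entropy terms), `signs`, `n` and the configuration.
#' @examples
#' set.seed(1)
#' n <- 400
#' x <- rnorm(n); y <- 0.6 * x + 0.8 * rnorm(n)
#' est <- cmih(cbind(x = x, y = y), x = "x", y = "y", types = "quantitative")
#' est$value  # close to -log(1 - 0.36) / 2 = 0.223
#' @export
cmih <- function(data, x, y, z = NULL, types = NULL,
                 k_rule = default_k, tie_floor = NULL) {
  sample <- as_mixed_sample(data, types)
  x <- resolve_cols(sample, x)
  y <- resolve_cols(sample, y)
  z <- resolve_cols(sample, z)
  if (length(x) < 1L || length(y) < 1L)
    stop("blocks X and Y must each contain at least one column")
  check_disjoint(x, y, z)
  if (sample$n < 2L &&
      length(quant_of(sample, c(x, y, z))) > 0L)
    stop("at least two observations are required with quantitative columns")

  term <- function(cols) {
    part <- qualitative_partition(sample, qual_of(sample, cols))
    c(quant = conditional_knn_entropy(sample, quant_of(sample, cols), part,
                                      k_rule, tie_floor),
      qual = plugin_entropy(part))
  }
  t_xz  <- term(c(x, z))
  t_yz  <- term(c(y, z))
  t_xyz <- term(c(x, y, z))
  t_z   <- term(z)

  terms <- c("H(Xt,Zt|Xl,Zl)" = unname(t_xz["quant"]),
             "H(Yt,Zt|Yl,Zl)" = unname(t_yz["quant"]),
             "H(Xt,Yt,Zt|Xl,Yl,Zl)" = unname(t_xyz["quant"]),
             "H(Zt|Zl)" = unname(t_z["quant"]),
             "H(Xl,Zl)" = unname(t_xz["qual"]),
             "H(Yl,Zl)" = unname(t_yz["qual"]),
             "H(Xl,Yl,Zl)" = unname(t_xyz["qual"]),
             "H(Zl)" = unname(t_z["qual"]))
  signs <- c(1, 1, -1, -1, 1, 1, -1, -1)
  value <- sum(signs * terms)
  structure(list(value = value, terms = terms, signs = signs,
                 n = sample$n,
                 dims = c(d_xz = length(quant_of(sample, c(x, z))),
                          d_yz = length(quant_of(sample, c(y, z))),
                          d_xyz = length(quant_of(sample, c(x, y, z))),
                          d_z = length(quant_of(sample, z))),
                 blocks = list(x = colnames(sample$data)[x],
                               y = colnames(sample$data)[y],
                               z = colnames(sample$data)[z]),
                 call = match.call()),
            class = "cmih_estimate")
}

#' @export
print.cmih_estimate <- function(x, digits = 4, ...) {
  cat("CMIh conditional mutual information estimate\n")
  cat(sprintf("  I(X;Y|Z) = %.*f nats  (n = %d)\n", digits, x$value, x$n))
  cat("  entropy terms (sign * value):\n")
  for (i in seq_along(x$terms))
    cat(sprintf("   %s %-22s %.*f\n",
                ifelse(x$signs[i] > 0, "+", "-"),
                names(x$terms)[i], digits, x$terms[i]))
  invisible(x)
}

# Statistic closure used by permutation tests: the YZ- and Z-terms do not
# depend on X and are computed once; only the XZ- and XYZ-terms are
# recomputed for each permuted X block.
cmih_statistic <- function(sample, x, y, z, k_rule = default_k,
                           tie_floor = NULL) {
  x <- resolve_cols(sample, x)
  y <- resolve_cols(sample, y)
  z <- resolve_cols(sample, z)
  term <- function(s, cols) {
    part <- qualitative_partition(s, qual_of(s, cols))
    conditional_knn_entropy(s, quant_of(s, cols), part, k_rule, tie_floor) +
      plugin_entropy(part)
  }
  fixed <- term(sample, c(y, z)) - term(sample, z)
  function(perm = NULL) {
    s <- sample
    if (!is.null(perm)) s$data[, x] <- s$data[perm, x, drop = FALSE]
    fixed + term(s, c(x, z)) - term(s, c(x, y, z))
  }
}
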
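# Independent brute-force oracles, deliberately written with plain loops and
# full sorts so they share no code path with the package internals.

# Chebyshev distance between two rows of a matrix
bf_linf <- function(pts, i, j) {
  m <- 0
  for (c in seq_len(ncol(pts))) {
    dv <- abs(pts[i, c] - pts[j, c])
    if (dv > m) m <- dv
  }
  m
}

# distance from point i to its k-th nearest neighbour (self excluded)
bf_kth_dist <- function(pts, i, k) {
  d <- numeric(0)
  for (j in seq_len(nrow(pts))) if (j != i) d <- c(d, bf_linf(pts, i, j))
  sort(d)[k]
}

# Kozachenko-Leonenko entropy, maximum norm, volume term omitted
bf_kl_entropy <- function(pts, k) {
  pts <- as.matrix(pts)
  n <- nrow(pts); d <- ncol(pts)
  acc <- 0
  for (i in seq_len(n)) acc <- acc + log(2 * bf_kth_dist(pts, i, k))
  digamma(n) - digamma(k) + d * acc / n
}

# plug-in entropy of a vector/matrix of category codes via contingency table
bf_table_entropy <- function(codes) {
  codes <- as.matrix(codes)
  if (ncol(codes) == 0L) return(0)
  key <- apply(codes, 1L, paste, collapse = "|")
  p <- as.numeric(table(key)) / nrow(codes)
  -sum(p * log(p))
}

# brute-force plug-in CMI for purely qualitative blocks
bf_plugin_cmi <- function(codes, x, y, z = integer(0)) {
  bf_table_entropy(codes[, c(x, z), drop = FALSE]) +
    bf_table_entropy(codes[, c(y, z), drop = FALSE]) -
    bf_table_entropy(codes[, c(x, y, z), drop = FALSE]) -
    bf_table_entropy(codes[, z, drop = FALSE])
}

# mixed metric between rows under the (0-D) qualitative convention
bf_mixed_dist <- function(dat, types, i, j, D_l = 1) {
  m <- 0
  for (c in seq_len(ncol(dat))) {
    dv <- if (types[c] == "qualitative") {
      if (dat[i, c] != dat[j, c]) D_l else 0
    } else {
      abs(dat[i, c] - dat[j, c])
    }
    if (dv > m) m <- dv
  }
  m
}

# independent Frenzel-Pompe estimator (purely quantitative data)
bf_fp <- function(dat, x, y, z, k) {
  n <- nrow(dat)
  types <- rep("quantitative", ncol(dat))
  rho <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) if (j != i)
      d <- c(d, bf_mixed_dist(dat[, c(x, y, z), drop = FALSE], types, i, j))
    rho[i] <- sort(d)[k]
  }
  cnt <- function(cols, i) {
    s <- 0
    for (j in seq_len(n)) if (j != i &&
        bf_mixed_dist(dat[, cols, drop = FALSE], types, i, j) < rho[i])
      s <- s + 1
    max(s, 1)
  }
  acc <- 0
  for (i in seq_len(n)) {
    nz <- if (length(z)) cnt(z, i) else {
      v <- if (rho[i] > 0) n - 1 else 0
      max(v, 1)
    }
    acc <- acc + digamma(k) - digamma(cnt(c(x, z), i) + 1) -
      digamma(cnt(c(y, z), i) + 1) + digamma(nz + 1)
  }
  acc / n
}

# small random mixed sample for property tests
random_mixed <- function(n, n_quant, n_qual, n_codes = 3) {
  dat <- cbind(
    matrix(rnorm(n * n_quant), n, n_quant),
    matrix(sample(0:(n_codes - 1), n * n_qual, replace = TRUE), n, n_qual))
  colnames(dat) <- paste0("v", seq_len(n_quant + n_qual))
  mixed_sample(dat, c(rep("quantitative", n_quant),
                      rep("qualitative", n_qual)))
}
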
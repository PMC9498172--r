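SETTING_NAMES <- c("mi_quant", "mi_mixed", "mi_mixed_imbalanced",
                   "cmi_quant", "cmi_mixed", "cmi_mixed_imbalanced",
                   "cmi_quant_indep", "cmi_mixed_indep",
                   "cmi_mixed_imb_indep", "m_cmi", "m_mi", "m_icmi")

#' Synthetic benchmark settings with analytic ground truths
#'
#' Generates an i.i.d. sample from one of the named benchmark processes used
#' to validate mixed-data conditional mutual information estimators. Every
#' setting has a closed-form (conditional) mutual information, available via
#' [ground_truth()]. Discrete-valued components (uniform on a finite set,
#' binomial, Poisson, zero-inflated Poisson) carry the qualitative type;
#' Gaussian, continuous-uniform and exponential components are quantitative.
#'
#' Available settings:
#' * `mi_quant`: bivariate Gaussian `(X, Y)` with correlation 0.6;
#'   `I = -log(1 - 0.36)/2`.
#' * `mi_mixed`: `X ~ U{0..4}`, `Y|X=x ~ U([x, x+2])`;
#'   `I = log 5 - (4/5) log 2`.
#' * `mi_mixed_imbalanced`: `X ~ Exp(1)`,
#'   `Y|X=x ~ 0.15 delta_0 + 0.85 Pois(x)`; `I` has a series closed form
#'   (about 0.256 nats).
#' * `cmi_quant`, `cmi_mixed`, `cmi_mixed_imbalanced`: the same pairs plus an
#'   independent conditioner `Z ~ Bi(3, 0.5)`; the truth is unchanged.
#' * `cmi_quant_indep`: `Z ~ Bi(9, 0.5)`, `X|Z=z ~ N(z,1)`,
#'   `Y|Z=z ~ N(z,1)`; truth 0.
#' * `cmi_mixed_indep`: `Z ~ U{0..4}`, `X|Z=z ~ U([z, z+2])`,
#'   `Y|Z=z ~ Bi(z, 0.5)`; truth 0.
#' * `cmi_mixed_imb_indep`: `X ~ Exp(10)`, `Z|X=x ~ Pois(x)`,
#'   `Y|Z=z ~ Bi(z+5, 0.5)`; truth 0. (`Exp(10)` is read as rate 10, mean
#'   0.1, so the Poisson classes are strongly imbalanced.)
#' * `m_cmi`: the `mi_mixed` pair plus `dim_z` independent `Bi(3, 0.5)`
#'   conditioners; truth equals the `mi_mixed` value for every `dim_z`.
#' * `m_mi`: the three MI pairs concatenated into blocks
#'   `X = (X1, X2, X3)`, `Y = (Y1, Y2, Y3)`; truth is the sum of the three
#'   (about 1.534 nats).
#' * `m_icmi`: `Z1 ~ U{0..4}`, `Z2 ~ Bi(3, 0.5)`, `Z3 ~ Exp(1)`,
#'   `Z4 ~ Exp(10)`; `X1 ~ N(z3, 1)`, `X2 ~ N(z4, 1)`,
#'   `X3 ~ Bi(z1 + z2, 0.5)`, `Y ~ Bi(z1 + z2, 0.5)`; truth 0.
#'
#' @param name setting name, one of the list above.
#' @param n sample size.
#' @param seed optional integer seed (the generator is reproducible given
#'   the seed).
#' @param dim_z conditioner dimension for `m_cmi` (0 to 4, default 4).
#' @return An object of class `cmi_sim`: list with `sample` (a
#'   `mixed_sample`), block column names `x`, `y`, `z`, the setting `name`
#'   and its `ground_truth` in nats.
#' @export
sim_setting <- function(name, n, seed = NULL, dim_z = 4) {
  name <- match.arg(name, SETTING_NAMES)
  if (n < 1) stop("'n' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  qual <- "qualitative"; quant <- "quantitative"

  pair_quant <- function(n) {
    x <- rnorm(n); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
    list(x = x, y = y)
  }
  pair_mixed <- function(n) {
    x <- sample(0:4, n, replace = TRUE)
    list(x = x, y = runif(n, x, x + 2))
  }
  pair_imb <- function(n) {
    x <- rexp(n, 1)
    y <- ifelse(runif(n) < 0.15, 0, rpois(n, x))
    list(x = x, y = y)
  }
  with_z <- function(p, n) c(p, list(z = rbinom(n, 3, 0.5)))

  out <- switch(name,
    mi_quant = {
      p <- pair_quant(n)
      list(data = cbind(x = p$x, y = p$y), types = c(quant, quant),
           x = "x", y = "y", z = character(0))
    },
    mi_mixed = {
      p <- pair_mixed(n)
      list(data = cbind(x = p$x, y = p$y), types = c(qual, quant),
           x = "x", y = "y", z = character(0))
    },
    mi_mixed_imbalanced = {
      p <- pair_imb(n)
      list(data = cbind(x = p$x, y = p$y), types = c(quant, qual),
           x = "x", y = "y", z = character(0))
    },
    cmi_quant = {
      p <- with_z(pair_quant(n), n)
      list(data = cbind(x = p$x, y = p$y, z = p$z),
           types = c(quant, quant, qual), x = "x", y = "y", z = "z")
    },
    cmi_mixed = {
      p <- with_z(pair_mixed(n), n)
      list(data = cbind(x = p$x, y = p$y, z = p$z),
           types = c(qual, quant, qual), x = "x", y = "y", z = "z")
    },
    cmi_mixed_imbalanced = {
      p <- with_z(pair_imb(n), n)
      list(data = cbind(x = p$x, y = p$y, z = p$z),
           types = c(quant, qual, qual), x = "x", y = "y", z = "z")
    },
    cmi_quant_indep = {
      z <- rbinom(n, 9, 0.5)
      list(data = cbind(x = rnorm(n, z), y = rnorm(n, z), z = z),
           types = c(quant, quant, qual), x = "x", y = "y", z = "z")
    },
    cmi_mixed_indep = {
      z <- sample(0:4, n, replace = TRUE)
      list(data = cbind(x = runif(n, z, z + 2), y = rbinom(n, z, 0.5),
                        z = z),
           types = c(quant, qual, qual), x = "x", y = "y", z = "z")
    },
    cmi_mixed_imb_indep = {
      x <- rexp(n, 10)
      z <- rpois(n, x)
      y <- rbinom(n, z + 5, 0.5)
      list(data = cbind(x = x, y = y, z = z),
           types = c(quant, qual, qual), x = "x", y = "y", z = "z")
    },
    m_cmi = {
      if (dim_z < 0 || dim_z > 4) stop("'dim_z' must lie in 0..4")
      p <- pair_mixed(n)
      dat <- cbind(x = p$x, y = p$y)
      types <- c(qual, quant)
      zn <- character(0)
      if (dim_z > 0) {
        zm <- vapply(seq_len(dim_z), function(r) rbinom(n, 3, 0.5),
                     numeric(n))
        zn <- paste0("z", seq_len(dim_z))
        colnames(zm) <- zn
        dat <- cbind(dat, zm)
        types <- c(types, rep(qual, dim_z))
      }
      list(data = dat, types = types, x = "x", y = "y", z = zn)
    },
    m_mi = {
      p1 <- pair_quant(n); p2 <- pair_mixed(n); p3 <- pair_imb(n)
      list(data = cbind(x1 = p1$x, x2 = p2$x, x3 = p3$x,
                        y1 = p1$y, y2 = p2$y, y3 = p3$y),
           types = c(quant, qual, quant, quant, quant, qual),
           x = c("x1", "x2", "x3"), y = c("y1", "y2", "y3"),
           z = character(0))
    },
    m_icmi = {
      z1 <- sample(0:4, n, replace = TRUE)
      z2 <- rbinom(n, 3, 0.5)
      z3 <- rexp(n, 1)
      z4 <- rexp(n, 10)
      list(data = cbind(x1 = rnorm(n, z3), x2 = rnorm(n, z4),
                        x3 = rbinom(n, z1 + z2, 0.5),
                        y = rbinom(n, z1 + z2, 0.5),
                        z1 = z1, z2 = z2, z3 = z3, z4 = z4),
           types = c(quant, quant, qual, qual, qual, qual, quant, quant),
           x = c("x1", "x2", "x3"), y = "y",
           z = c("z1", "z2", "z3", "z4"))
    })

  structure(list(sample = mixed_sample(out$data, out$types),
                 x = out$x, y = out$y, z = out$z, name = name,
                 ground_truth = ground_truth(name)),
            class = "cmi_sim")
}

#' Analytic ground-truth (conditional) mutual information of a setting
#'
#' Evaluates the closed-form value, in nats, of the (conditional) mutual
#' information of a named benchmark setting (see [sim_setting()]). The
#' imbalanced settings involve the series `sum_k log(k) 2^(-k)`, which is
#' summed until terms fall below `1e-12` (absolute tail error well under
#' `1e-10`). Adding independent conditioners does not change the value, so
#' the `cmi_*` variants equal their `mi_*` counterparts and `m_cmi` is
#' constant in the conditioner dimension. Chain/fork/collider structure
#' settings ([sim_structure()]) have no analytic value and are rejected.
#'
#' @param name setting name.
#' @param ... unused.
#' @return Ground truth in nats.
#' @examples
#' ground_truth("mi_quant")  # -log(1 - 0.36)/2
#' @export
ground_truth <- function(name, ...) {
  name <- match.arg(name, SETTING_NAMES)
  gamma_e <- -digamma(1)
  imb_series <- function() {
    k <- 2; s <- 0
    repeat {
      term <- log(k) * 2^(-k)
      if (term < 1e-12) break
      s <- s + term
      k <- k + 1
    }
    s
  }
  switch(name,
    mi_quant = , cmi_quant = -log(1 - 0.6^2) / 2,
    mi_mixed = , cmi_mixed = , m_cmi = log(5) - 4 * log(2) / 5,
    mi_mixed_imbalanced = , cmi_mixed_imbalanced =
      0.85 * (2 * log(2) - gamma_e - imb_series()),
    cmi_quant_indep = , cmi_mixed_indep = , cmi_mixed_imb_indep = ,
      m_icmi = 0,
    m_mi = -log(1 - 0.6^2) / 2 + log(5) - 4 * log(2) / 5 +
      0.85 * (2 * log(2) - gamma_e - imb_series()))
}

#' @export
print.cmi_sim <- function(x, ...) {
  cat(sprintf("cmi_sim '%s': n = %d; X = (%s), Y = (%s), Z = (%s); truth = %s\n",
              x$name, x$sample$n,
              paste(x$x, collapse = ","), paste(x$y, collapse = ","),
              if (length(x$z)) paste(x$z, collapse = ",") else "-",
              if (is.na(x$ground_truth)) "unknown"
              else format(x$ground_truth, digits = 4)))
  invisible(x)
}

#' Chain / fork / collider structures over mixed type configurations
#'
#' Generates one of the three classical three-node causal structures --
#' chain `X -> Z -> Y`, fork `X <- Z -> Y`, collider `X -> Z <- Y` -- with a
#' type configuration string over `{"t", "l"}` giving the
#' quantitative/qualitative type of X, Z and Y in that order (e.g. `"tlt"`:
#' X and Y quantitative, Z qualitative). Chain and fork imply
#' `X _||_ Y | Z`; the collider implies marginal independence but
#' conditional dependence.
#'
#' Generating mechanisms (package-defined; no analytic ground-truth value is
#' attached):
#' * quantitative root: `N(0, 1)`; qualitative root: uniform on `{0..3}`.
#' * quantitative -> quantitative: `child = parent + N(0, 1)`.
#' * quantitative -> qualitative: `Bi(3, plogis(1.5 * parent))`.
#' * qualitative -> quantitative: `N(code, 1)` (category-dependent means).
#' * qualitative -> qualitative: copy with 10% uniform relabel over
#'   `{0..3}`.
#' * collider child: parents enter through a centred sum `s` (quantitative
#'   value, or code minus 1.5); quantitative child `s + N(0,1)`, qualitative
#'   child `Bi(3, plogis(s))`.
#'
#' @param structure `"chain"`, `"fork"` or `"collider"`.
#' @param config three-character string over `t` / `l` for the types of
#'   X, Y and Z in that order.
#' @param n sample size.
#' @param seed optional integer seed.
#' @return A `cmi_sim` object with `ground_truth = NA` (unknown).
#' @export
sim_structure <- function(structure = c("chain", "fork", "collider"),
                          config, n, seed = NULL) {
  structure_ <- match.arg(structure)
  cfg <- strsplit(config, "")[[1]]
  if (length(cfg) != 3L || !all(cfg %in% c("t", "l")))
    stop("'config' must be a three-character string over {t, l}")
  if (!is.null(seed)) set.seed(seed)

  root <- function(type, n)
    if (type == "t") rnorm(n) else sample(0:3, n, replace = TRUE)
  edge <- function(parent, ptype, ctype, n) {
    if (ctype == "t") {
      parent + rnorm(n)             # qual parent: category-dependent means
    } else if (ptype == "t") {
      rbinom(n, 3, plogis(1.5 * parent))
    } else {
      ifelse(runif(n) < 0.9, parent, sample(0:3, n, replace = TRUE))
    }
  }
  centred <- function(v, type) if (type == "t") v else v - 1.5
  tx <- cfg[1]; ty <- cfg[2]; tz <- cfg[3]

  if (structure_ == "chain") {
    xv <- root(tx, n)
    zv <- edge(xv, tx, tz, n)
    yv <- edge(zv, tz, ty, n)
  } else if (structure_ == "fork") {
    zv <- root(tz, n)
    xv <- edge(zv, tz, tx, n)
    yv <- edge(zv, tz, ty, n)
  } else {
    xv <- root(tx, n)
    yv <- root(ty, n)
    s <- centred(xv, tx) + centred(yv, ty)
    zv <- if (tz == "t") s + rnorm(n) else rbinom(n, 3, plogis(s))
  }
  types <- ifelse(c(tx, ty, tz) == "t", "quantitative", "qualitative")
  structure(list(sample = mixed_sample(cbind(x = xv, y = yv, z = zv),
                                       types),
                 x = "x", y = "y", z = "z",
                 name = paste(structure_, config, sep = "_"),
                 ground_truth = NA_real_),
            class = "cmi_sim")
}

apply_estimator <- function(estimator, sim, rank_transform = FALSE,
                            k_rule = default_k, D_l = 1) {
  s <- if (rank_transform) rank_transform(sim$sample) else sim$sample
  if (is.function(estimator)) return(estimator(s, sim$x, sim$y, sim$z))
  switch(estimator,
         cmih = cmih(s, sim$x, sim$y, sim$z, k_rule = k_rule)$value,
         fp = , ravk = , ms = cmi_knn(s, sim$x, sim$y, sim$z,
                                      method = estimator, D_l = D_l)$value,
         stop("unknown estimator: ", estimator))
}

#' Mean-squared-error benchmark of estimators on analytic settings
#'
#' For each setting, sample size and estimator, generates `reps` independent
#' datasets, applies the estimator and reports the mean estimate, its
#' standard error, the bias against the analytic ground truth and the mean
#' squared error.
#'
#' @param settings character vector of setting names (see [sim_setting()]).
#' @param n_grid integer vector of sample sizes.
#' @param reps datasets per (setting, n) cell (default 100).
#' @param estimators character vector over
#'   `c("cmih", "fp", "ravk", "ms")`, or a named list of functions
#'   `f(sample, x, y, z) -> numeric`.
#' @param seed optional integer seed for the whole experiment.
#' @param rank_transform rank-transform quantitative columns before
#'   estimating (default `FALSE`, matching estimator benchmarking on the
#'   raw scales).
#' @param dim_z passed to [sim_setting()] for `m_cmi`.
#' @return A data.frame with one row per (setting, n, estimator):
#'   columns `setting`, `n`, `estimator`, `truth`, `mean`, `se`, `bias`,
#'   `mse`, `reps`.
#' @export
mse_experiment <- function(settings, n_grid, reps = 100,
                           estimators = "cmih", seed = NULL,
                           rank_transform = FALSE, dim_z = 4) {
  if (reps < 1) stop("'reps' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  est_names <- if (is.list(estimators)) names(estimators) else estimators
  rows <- list()
  for (setting in settings) {
    truth <- ground_truth(setting)
    for (n in n_grid) {
      ests <- matrix(NA_real_, reps, length(est_names),
                     dimnames = list(NULL, est_names))
      for (r in seq_len(reps)) {
        sim <- sim_setting(setting, n, dim_z = dim_z)
        for (e in seq_along(est_names)) {
          est <- if (is.list(estimators)) estimators[[e]] else estimators[e]
          ests[r, e] <- apply_estimator(est, sim, rank_transform)
        }
      }
      for (e in est_names) {
        v <- ests[, e]
        rows[[length(rows) + 1L]] <- data.frame(
          setting = setting, n = n, estimator = e, truth = truth,
          mean = mean(v), se = sd(v) / sqrt(reps),
          bias = mean(v) - truth, mse = mean((v - truth)^2), reps = reps)
      }
    }
  }
  do.call(rbind, rows)
}

#' Acceptance-rate experiment on causal structures
#'
#' Repeats a conditional-independence test on freshly generated
#' chain/fork/collider data and reports, per threshold, the fraction of
#' correct decisions: for chain and fork (where `X _||_ Y | Z` holds) the
#' fraction of p-values above the threshold; for the collider (where
#' conditional dependence holds) the fraction below it.
#'
#' @inheritParams sim_structure
#' @inheritParams cmi_test
#' @param reps number of repetitions (default 10).
#' @param thresholds rejection thresholds (default `c(0.01, 0.05)`).
#' @param n sample size per repetition (default 500).
#' @return A data.frame with columns `structure`, `config`, `estimator`,
#'   `scheme`, `threshold`, `rate`, `reps`; the raw p-values are attached as
#'   attribute `"p_values"`.
#' @export
acceptance_rate_experiment <- function(structure, config,
                                       estimator = "cmih",
                                       scheme = "locat", reps = 10,
                                       thresholds = c(0.01, 0.05),
                                       n = 500, B = 1000, k_perm = 5,
                                       seed = NULL,
                                       rank_transform = TRUE) {
  structure_ <- match.arg(structure, c("chain", "fork", "collider"))
  if (!is.null(seed)) set.seed(seed)
  pvals <- vapply(seq_len(reps), function(r) {
    sim <- sim_structure(structure_, config, n)
    cmi_test(sim$sample, sim$x, sim$y, sim$z, estimator = estimator,
             scheme = scheme, B = B, k_perm = k_perm,
             rank_transform = rank_transform)$p.value
  }, numeric(1))
  rate <- vapply(thresholds, function(thr) {
    if (structure_ == "collider") mean(pvals < thr) else mean(pvals > thr)
  }, numeric(1))
  out <- data.frame(structure = structure_, config = config,
                    estimator = if (is.function(estimator)) "custom"
                                else estimator,
                    scheme = scheme, threshold = thresholds, rate = rate,
                    reps = reps)
  attr(out, "p_values") <- pvals
  out
}
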
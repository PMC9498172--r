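test_that("analytic ground truths match their closed forms", {
  expect_equal(ground_truth("mi_quant"), -log(1 - 0.6^2) / 2)
  expect_equal(ground_truth("mi_mixed"), log(5) - 4 * log(2) / 5)
  # series value for the zero-inflated setting, summed independently here
  gamma_e <- -digamma(1)
  k <- 2:200
  imb <- 0.85 * (2 * log(2) - gamma_e - sum(log(k) * 2^(-k)))
  expect_equal(ground_truth("mi_mixed_imbalanced"), imb, tolerance = 1e-10)
  expect_equal(round(ground_truth("mi_mixed_imbalanced"), 3), 0.256)
  for (nm in c("cmi_quant_indep", "cmi_mixed_indep", "cmi_mixed_imb_indep",
               "m_icmi"))
    expect_identical(ground_truth(nm), 0)
})

test_that("independent conditioners never change the ground truth", {
  expect_equal(ground_truth("cmi_quant"), ground_truth("mi_quant"))
  expect_equal(ground_truth("cmi_mixed"), ground_truth("mi_mixed"))
  expect_equal(ground_truth("cmi_mixed_imbalanced"),
               ground_truth("mi_mixed_imbalanced"))
  expect_equal(ground_truth("m_cmi"), ground_truth("mi_mixed"))
  # the multidimensional MI process concatenates three independent pairs
  expect_equal(ground_truth("m_mi"),
               ground_truth("mi_quant") + ground_truth("mi_mixed") +
                 ground_truth("mi_mixed_imbalanced"))
  expect_equal(ground_truth("m_mi"), 1.534, tolerance = 5e-4)
})

test_that("generators respect their supports and type masks", {
  s <- sim_setting("mi_mixed", 500, seed = 40)
  x <- s$sample$data[, "x"]; y <- s$sample$data[, "y"]
  expect_true(all(x %in% 0:4))
  expect_true(all(y >= x & y <= x + 2))
  expect_equal(s$sample$types, c("qualitative", "quantitative"))

  si <- sim_setting("mi_mixed_imbalanced", 4000, seed = 41)
  expect_gte(mean(si$sample$data[, "y"] == 0), 0.15)

  sm <- sim_setting("m_icmi", 300, seed = 42)
  expect_equal(sm$x, c("x1", "x2", "x3"))
  expect_equal(sm$z, c("z1", "z2", "z3", "z4"))
  expect_equal(sm$sample$types[match(c("x3", "y", "z1", "z2"),
                                     colnames(sm$sample$data))],
               rep("qualitative", 4))

  sc <- sim_setting("m_cmi", 100, seed = 43, dim_z = 2)
  expect_equal(sc$z, c("z1", "z2"))
  s0 <- sim_setting("m_cmi", 100, seed = 43, dim_z = 0)
  expect_length(s0$z, 0)
})

test_that("generation is reproducible under a fixed seed", {
  a <- sim_setting("cmi_quant_indep", 100, seed = 44)
  b <- sim_setting("cmi_quant_indep", 100, seed = 44)
  expect_identical(a$sample$data, b$sample$data)
  c1 <- sim_structure("chain", "tlt", 100, seed = 45)
  c2 <- sim_structure("chain", "tlt", 100, seed = 45)
  expect_identical(c1$sample$data, c2$sample$data)
})

test_that("generator moments match the named distributions", {
  set.seed(46)
  n <- 1e5
  s <- sim_setting("cmi_mixed_imbalanced", n)
  x <- s$sample$data[, "x"]; z <- s$sample$data[, "z"]
  expect_equal(mean(x), 1, tolerance = 0.05)       # Exp(1)
  expect_equal(stats::var(x), 1, tolerance = 0.1)
  expect_equal(mean(z), 1.5, tolerance = 0.05)     # Bi(3, 0.5)
  expect_equal(stats::var(z), 0.75, tolerance = 0.05)
  sq <- sim_setting("mi_quant", n)
  expect_equal(stats::cor(sq$sample$data[, "x"], sq$sample$data[, "y"]),
               0.6, tolerance = 0.02)
})

test_that("structure configurations carry the declared types", {
  for (cfg in c("ttt", "tlt", "llt", "tll", "ttl", "lll")) {
    sim <- sim_structure("fork", cfg, 50, seed = 47)
    tys <- strsplit(cfg, "")[[1]]
    expect_equal(sim$sample$types[1],
                 ifelse(tys[1] == "t", "quantitative", "qualitative"))
    expect_equal(sim$sample$types[3],  # column order is x, y, z
                 ifelse(tys[3] == "t", "quantitative", "qualitative"))
    expect_equal(sim$sample$types[2],
                 ifelse(tys[2] == "t", "quantitative", "qualitative"))
  }
  expect_error(sim_structure("chain", "tx", 10), "three-character")
  expect_true(is.na(sim_structure("chain", "ttt", 10)$ground_truth))
  expect_error(ground_truth("chain_ttt"))
})

test_that("the MSE harness reduces to bias and variance identities", {
  const <- function(v) function(sample, x, y, z) v
  truth <- ground_truth("mi_quant")
  r0 <- mse_experiment("mi_quant", 50, reps = 3,
                       estimators = list(oracle = const(truth)), seed = 48)
  expect_equal(r0$mse, 0)
  r1 <- mse_experiment("mi_quant", 50, reps = 3,
                       estimators = list(shift = const(truth + 0.1)),
                       seed = 48)
  expect_equal(r1$mse, 0.01)
  expect_equal(r1$bias, 0.1)
})

test_that("acceptance rates invert the decision for colliders", {
  fake_p <- function(p) function(sample, x, y, z) {
    # constant statistic: every permuted value ties the observed one -> p = 1
    0
  }
  # with p-values identically 1: chain accepts, collider never rejects
  set.seed(49)
  r_chain <- acceptance_rate_experiment("chain", "ttt",
                                        estimator = fake_p(1), reps = 2,
                                        n = 30, B = 5)
  expect_equal(r_chain$rate, c(1, 1))
  r_col <- acceptance_rate_experiment("collider", "ttt",
                                      estimator = fake_p(1), reps = 2,
                                      n = 30, B = 5)
  expect_equal(r_col$rate, c(0, 0))
})
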
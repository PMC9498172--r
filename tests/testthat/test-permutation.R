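test_that("neighbourhoods stay inside qualitative strata", {
  # a stratum of 3 members with k_perm = 5: k_i clamps to 3 and the
  # (0-Inf) distance confines N_i to the stratum
  z <- matrix(c(0, 0, 0, 1, 1, 1, 1, 2), ncol = 1)
  nb <- local_neighborhoods(z, "l", k_perm = 5)
  expect_equal(nb$k_i, c(3, 3, 3, 4, 4, 4, 4, 1))
  expect_equal(nb$d_k, rep(0, 8))
  expect_equal(sort(nb$neighbors[[1]]), 1:3)
  expect_equal(sort(nb$neighbors[[5]]), 4:7)
  expect_equal(nb$neighbors[[8]], 8L)
  expect_equal(nb$n_l, c(3, 3, 3, 4, 4, 4, 4, 1))
})

test_that("quantitative neighbourhoods match a brute-force distance sort", {
  set.seed(30)
  z <- matrix(rnorm(40), ncol = 1)
  nb <- local_neighborhoods(z, "t", k_perm = 5)
  for (i in c(1, 7, 40)) {
    d <- abs(z - z[i])
    expect_equal(nb$k_i[i], 5)
    expect_equal(nb$d_k[i], sort(d)[5])  # self included as first neighbour
    expect_equal(sort(nb$neighbors[[i]]), which(d <= sort(d)[5]))
    expect_true(i %in% nb$neighbors[[i]])
    expect_length(nb$neighbors[[i]], 5)  # tie-free
  }
})

test_that("an empty conditioning block yields global neighbourhoods", {
  nb <- local_neighborhoods(matrix(numeric(0), nrow = 6, ncol = 0),
                            character(0))
  expect_equal(nb$neighbors, rep(list(1:6), 6))
})

test_that("the non-adaptive rule degenerates on small strata", {
  z <- matrix(c(0, 0, 1, 1, 1, 1, 1, 1), ncol = 1)
  nb <- local_neighborhoods(z, "l", k_perm = 5, adaptive = FALSE)
  expect_equal(nb$d_k[1], Inf)           # stratum of 2 < k_perm
  expect_equal(nb$neighbors[[1]], 1:8)   # collapses to the whole sample
  expect_equal(sort(nb$neighbors[[3]]), 3:8)
})

test_that("forced singleton neighbourhoods give the identity map", {
  z <- matrix(0:5, ncol = 1)
  nb <- local_neighborhoods(z, "l", k_perm = 5)
  expect_equal(draw_local_permutation(nb), 1:6)
})

test_that("local draws are uniform over each neighbourhood", {
  set.seed(31)
  z <- matrix(c(0, 0, 0, 0, 1, 1), ncol = 1)
  nb <- local_neighborhoods(z, "l", k_perm = 5)
  draws <- replicate(20000, draw_local_permutation(nb)[1])
  freq <- table(factor(draws, levels = 1:4)) / 20000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("p-values follow the exceedance count exactly", {
  # a deterministic statistic sequence makes Eq.-style arithmetic checkable
  set.seed(32)
  d <- cbind(x = rnorm(20), y = rnorm(20))
  maker <- function(values) {
    i <- 0
    function(sample, x, y, z) { i <<- i + 1; values[i] }
  }
  # observed below every permuted statistic -> p = 1
  t1 <- cmi_test(d, "x", "y", types = "t", B = 10,
                 estimator = maker(c(-1, rep(1, 10))), seed = 1)
  expect_equal(t1$p.value, 1)
  # observed above every permuted statistic -> p = 0 (no smoothing)
  t0 <- cmi_test(d, "x", "y", types = "t", B = 10,
                 estimator = maker(c(2, rep(1, 10))), seed = 1)
  expect_equal(t0$p.value, 0)
  # 5 of 100 permuted values at or above the observed -> p = 0.05
  vals <- c(0.5, rep(0, 95), rep(0.7, 5))
  t5 <- cmi_test(d, "x", "y", types = "t", B = 100,
                 estimator = maker(vals), seed = 1)
  expect_equal(t5$p.value, 0.05)
  expect_equal(t5$p.value, mean(t5$permuted >= t5$statistic))
})

test_that("p-values are multiples of 1/B in [0, 1]", {
  set.seed(33)
  for (r in 1:5) {
    s <- random_mixed(30, 2, 1)
    B <- sample(c(9, 20, 37), 1)
    tt <- cmi_test(s, 1, 2, 3, B = B, k_perm = 3)
    expect_gte(tt$p.value, 0)
    expect_lte(tt$p.value, 1)
    expect_equal(tt$p.value * B, round(tt$p.value * B))
  }
})

test_that("permutation never alters Y or Z columns", {
  set.seed(34)
  s <- random_mixed(25, 1, 2)
  seen <- list()
  grab <- function(sample, x, y, z) {
    seen[[length(seen) + 1L]] <<- sample$data[, c(y, z)]
    0
  }
  invisible(cmi_test(s, 1, 2, 3, B = 5, estimator = grab))
  for (m in seen) expect_identical(m, s$data[, 2:3])
})

test_that("LocAT equals LocT for quantitative Z and GloT for empty Z", {
  set.seed(35)
  n <- 60
  d <- cbind(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  a <- cmi_test(d, "x", "y", "z", types = "t", scheme = "locat",
                B = 50, seed = 99)
  b <- cmi_test(d, "x", "y", "z", types = "t", scheme = "loct",
                B = 50, seed = 99)
  expect_identical(a$permuted, b$permuted)
  expect_identical(a$p.value, b$p.value)

  a0 <- cmi_test(d[, 1:2], "x", "y", types = "t", scheme = "locat",
                 B = 50, seed = 7)
  b0 <- cmi_test(d[, 1:2], "x", "y", types = "t", scheme = "glot",
                 B = 50, seed = 7)
  expect_identical(a0$permuted, b0$permuted)
})

test_that("results are reproducible under a fixed seed", {
  set.seed(36)
  s <- random_mixed(40, 2, 1)
  t1 <- cmi_test(s, 1, 2, 3, B = 30, seed = 123)
  t2 <- cmi_test(s, 1, 2, 3, B = 30, seed = 123)
  expect_identical(t1$permuted, t2$permuted)
  expect_identical(t1$p.value, t2$p.value)
})

test_that("the cached CMIh statistic agrees with the full estimator", {
  set.seed(37)
  s <- random_mixed(50, 2, 2)
  stat <- cmih:::cmih_statistic(s, 1, 2, c(3, 4))
  expect_equal(stat(NULL), cmih(s, 1, 2, c(3, 4))$value, tolerance = 1e-12)
  perm <- sample(50)
  s2 <- s
  s2$data[, 1] <- s2$data[perm, 1]
  expect_equal(stat(perm), cmih(s2, 1, 2, c(3, 4))$value, tolerance = 1e-12)
})

test_that("the LocAT test holds its level on a conditional-null mixture", {
  set.seed(38)
  reps <- 100
  pv <- vapply(seq_len(reps), function(r) {
    s <- sim_setting("cmi_mixed_indep", 500)
    cmi_test(s$sample, s$x, s$y, s$z, B = 200)$p.value
  }, numeric(1))
  expect_lt(mean(pv < 0.05), 0.12)  # nominal 0.05 plus 3 binomial SEs
})

test_that("the LocAT test has power against a collider dependence", {
  set.seed(39)
  reps <- 20
  pv <- vapply(seq_len(reps), function(r) {
    sim <- sim_structure("collider", "ttt", 500)
    cmi_test(sim$sample, sim$x, sim$y, sim$z, B = 200)$p.value
  }, numeric(1))
  expect_gte(mean(pv < 0.05), 0.8)
})
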
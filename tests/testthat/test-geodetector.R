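test_that("quantile and equal-interval discretization bin as documented", {
  d <- discretize(1:10, "quantile", k = 2)
  expect_equal(d$labels, rep(1:2, each = 5))
  expect_equal(d$L, 2)
  e <- discretize(c(0, 1, 2, 9, 10), "equal", k = 2)
  expect_equal(e$labels, c(1L, 1L, 1L, 2L, 2L))
  expect_warning(dc <- discretize(rep(3, 6), "quantile", k = 3), "constant")
  expect_equal(dc$L, 1)
  expect_warning(discretize(c(1, 1, 2, 2), "quantile", k = 3), "reducing")
  expect_error(discretize(1:10, "quantile", k = 1), "at least 2")
  f <- discretize(c(10, 20, 10, 30), "categorical")
  expect_equal(f$labels, c(1L, 2L, 1L, 3L))
  # missing values stay unlabelled
  g <- discretize(c(1, NA, 3, 4), "quantile", k = 2)
  expect_true(is.na(g$labels[2]))
})

test_that("natural breaks recover separated components and minimise SS", {
  set.seed(50)
  v <- c(rnorm(70, 0, 0.3), rnorm(70, 5, 0.3), rnorm(60, 11, 0.3))
  d <- discretize(v, "natural", k = 3)
  comp <- rep(1:3, c(70, 70, 60))
  expect_equal(d$labels, comp)
  # exhaustive-enumeration oracle on tiny samples
  set.seed(51)
  for (rep in 1:5) {
    v2 <- rnorm(9)
    d2 <- discretize(v2, "natural", k = 3)
    expect_equal(within_ss_of_labels(v2, d2$labels),
                 oracle_best_partition_ss(v2, 3), tolerance = 1e-10)
  }
})

test_that("factor q matches the hand-computed variance decomposition", {
  qr <- factor_q(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 2, 2, 2))
  expect_equal(qr$SSW, 4)
  expect_equal(qr$SST, 125.5)
  expect_equal(qr$q, 1 - 4 / 125.5)
  expect_equal(qr$N, 6)
  # single stratum: SSW = SST
  expect_equal(factor_q(c(4, 8, 1, 7), rep(1, 4))$q, 0)
  # pure strata (one observation each, allowed at min_stratum_n = 1)
  expect_equal(factor_q(c(4, 8, 1, 7), 1:4, min_stratum_n = 1)$q, 1)
  expect_error(factor_q(rep(2, 6), c(1, 1, 1, 2, 2, 2)), "constant")
  expect_error(factor_q(1:3, 1:2), "length")
})

test_that("small strata are dropped and logged, not silently merged", {
  y <- c(1, 2, 3, 4, 100)
  qr <- factor_q(y, c(1, 1, 2, 2, 3), min_stratum_n = 2)
  expect_equal(qr$dropped_strata, "3")
  expect_equal(qr$N, 4)
  expect_error(factor_q(c(1, 2), c(1, 2), min_stratum_n = 2), "fewer than 2")
})

test_that("q statistic properties: bounds, affine invariance, refinement", {
  set.seed(60)
  for (rep in 1:20) {
    n <- sample(50:400, 1)
    y <- rnorm(n) + rep(rnorm(5), length.out = n)
    la <- sample(1:5, n, replace = TRUE)
    lb <- sample(1:4, n, replace = TRUE)
    qa <- factor_q(y, la)$q
    expect_gte(qa, 0); expect_lte(qa, 1)
    # affine invariance
    expect_equal(factor_q(3.7 * y - 11, la)$q, qa, tolerance = 1e-12)
    # refinement: overlay never explains less than either factor
    ir <- interaction_q(y, la, lb, min_stratum_n = 1)
    expect_gte(ir$qAB, max(ir$qA, ir$qB) - 1e-12)
  }
})

test_that("a balanced XOR response is pure nonlinear enhancement", {
  la <- rep(c(1, 1, 2, 2), 100)
  lb <- rep(c(1, 2, 1, 2), 100)
  y <- as.numeric(xor(la == 2, lb == 2))
  ir <- interaction_q(y, la, lb)
  expect_equal(ir$qA, 0)
  expect_equal(ir$qB, 0)
  expect_equal(ir$qAB, 1)
  expect_equal(ir$category, "nonlinear-enhance")
})

test_that("overlaying a factor with itself reproduces its own q", {
  set.seed(61)
  y <- rnorm(200) + rep(1:5, 40)
  la <- rep(1:5, 40)
  ir <- interaction_q(y, la, la)
  qa <- factor_q(y, la)$q
  expect_equal(ir$qAB, qa, tolerance = 1e-12)
  expect_equal(ir$qA, qa, tolerance = 1e-12)
  expect_equal(ir$category, "bi-enhance")  # boundary tie resolved upward
})

test_that("overlay q equals the brute-force group-variance oracle", {
  set.seed(62)
  for (rep in 1:10) {
    n <- sample(100:1000, 1)
    la <- sample(1:4, n, replace = TRUE)
    lb <- sample(1:3, n, replace = TRUE)
    y <- rnorm(n) + la * 0.5 + lb * 0.8    # planted additive means
    ir <- interaction_q(y, la, lb, min_stratum_n = 1)
    expect_equal(ir$qAB, oracle_q(y, paste(la, lb)), tolerance = 1e-12)
  }
})

test_that("interaction categories follow the five-way comparison rules", {
  expect_equal(classify_interaction(0.3, 0.2, 0.9), "nonlinear-enhance")
  expect_equal(classify_interaction(0.3, 0.2, 0.4), "bi-enhance")
  expect_equal(classify_interaction(0.3, 0.2, 0.5), "independent")
  expect_equal(classify_interaction(0.3, 0.2, 0.25), "single-weaken")
  expect_equal(classify_interaction(0.3, 0.2, 0.1), "nonlinear-weaken")
  expect_equal(classify_interaction(0, 0, 0.4), "nonlinear-enhance")
})

test_that("detector reports rank factors and pairs per sector", {
  set.seed(63)
  n <- 30
  g <- rg(matrix(rnorm(n * n), n, n))
  driver <- rg(matrix(rep(seq(-1, 1, length.out = n), each = n), n, n))
  noisef <- rg(matrix(rnorm(n * n), n, n))
  resp <- as_response_table(raster_like(g, driver$values * 2 +
                                          matrix(rnorm(n * n, sd = 0.2), n, n)))
  det <- run_detectors(resp, list(drv = driver, noise = noisef, copy = driver))
  expect_equal(det$factor_q$factor[1] %in% c("drv", "copy"), TRUE)
  # duplicated factor pair sits at the overlay-identity boundary
  dup <- det$interaction_q[det$interaction_q$factor_a == "drv" &
                             det$interaction_q$factor_b == "copy", ]
  expect_equal(dup$qAB, dup$qA, tolerance = 1e-9)
  expect_equal(dup$category, "bi-enhance")
})

test_that("pure-noise responses yield uniformly small q at large n", {
  set.seed(64)
  n <- 5000
  y <- rnorm(n)
  qs <- sapply(1:5, function(i) factor_q(y, sample(1:5, n, TRUE))$q)
  expect_true(all(qs < 0.1))
})

test_that("strata-count sweep reports one q per factor and k", {
  set.seed(65)
  g <- rg(matrix(rnorm(400), 20, 20))
  f <- list(a = rg(matrix(rnorm(400), 20, 20)),
            b = rg(matrix(rnorm(400), 20, 20)))
  resp <- as_response_table(g)
  sw <- sweep_strata(resp, f, ks = 3:5)
  expect_equal(nrow(sw), 6)
  expect_true(all(sw$q >= 0 & sw$q <= 1))
})
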
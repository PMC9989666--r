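test_that("independent series have near-zero capacity", {
  set.seed(3)
  x <- stats::rnorm(2000); y <- stats::rnorm(2000)
  for (m in c("CCS", "MMI")) {
    res <- emergence_capacity_pair(x, y, method = m)
    expect_lt(abs(res$capacity), 0.05)   # plug-in bias at this T
  }
  g <- emergence_capacity_pair(x, y, estimator = "gaussian")
  expect_lt(abs(g$capacity), 0.02)
})

test_that("planted noisy-XOR dynamics recover the analytic channel synergy", {
  eps <- 0.05
  analytic <- 1 - binary_entropy(eps)   # capacity of the noisy XOR channel
  # exact pmf route (both methods agree analytically on XOR)
  pmf <- noisy_xor_pmf(eps)
  for (m in c("CCS", "MMI")) {
    res <- emergentdyn:::pair_from_pmf16(as.numeric(pmf), m)
    expect_equal(res$capacity, analytic, tolerance = 1e-9)
  }
  # simulated route through the plug-in estimator
  set.seed(17)
  n <- 6000
  x2 <- stats::rbinom(n, 1, 0.5)
  x1 <- integer(n)
  x1[1] <- 0
  for (t in 2:n) {
    v <- xor(x1[t - 1], x2[t - 1]) + 0L
    x1[t] <- if (stats::runif(1) < eps) 1L - v else v
  }
  # map bits to +-1 so mean-binarisation recovers them
  res <- emergence_capacity_pair(2 * x1 - 1 + stats::rnorm(n, sd = 1e-3),
                                 2 * x2 - 1 + stats::rnorm(n, sd = 1e-3),
                                 method = "MMI")
  expect_lt(abs(res$capacity - analytic), 0.05)
})

test_that("capacity equals downward + decoupling on random VAR pairs (MMI)", {
  set.seed(23)
  for (i in 1:50) {
    X <- random_var_pair(300)
    res <- emergence_capacity_pair(X[1, ], X[2, ], method = "MMI")
    expect_equal(res$capacity, res$downward_causation + res$causal_decoupling,
                 tolerance = 1e-9)
    expect_equal(res$normalized_capacity, res$capacity / res$tdmi,
                 tolerance = 1e-12)
  }
})

test_that("capacity is invariant to swapping the two regions", {
  set.seed(29)
  X <- random_var_pair(400)
  for (m in c("CCS", "MMI")) {
    a <- emergence_capacity_pair(X[1, ], X[2, ], method = m)
    b <- emergence_capacity_pair(X[2, ], X[1, ], method = m)
    expect_equal(a$capacity, b$capacity, tolerance = 1e-12)
    expect_equal(a$tdmi, b$tdmi, tolerance = 1e-12)
  }
})

test_that("discrete and Gaussian capacities are rank-correlated on VAR pairs", {
  set.seed(31)
  caps_d <- caps_g <- numeric(50)
  for (i in 1:50) {
    X <- random_var_pair(500)
    caps_d[i] <- emergence_capacity_pair(X[1, ], X[2, ], method = "MMI")$capacity
    caps_g[i] <- emergence_capacity_pair(X[1, ], X[2, ],
                                         estimator = "gaussian")$capacity
  }
  rho <- spearman_cor(caps_d, caps_g)
  expect_gt(rho$estimate, 0.5)
})

test_that("global emergence aggregates pairs correctly", {
  set.seed(37)
  X <- random_var_pair(300)
  ts2 <- regional_timeseries(X, tr = 2)
  ge <- global_emergence(ts2, method = "MMI")
  pairres <- emergence_capacity_pair(X[1, ], X[2, ], method = "MMI")
  expect_equal(ge$global_capacity, pairres$capacity, tolerance = 1e-12)
  expect_equal(nrow(ge$pairs), 1L)

  # all regions identical: constant capacity matrix off-diagonal
  one <- X[1, ]
  tsN <- regional_timeseries(rbind(one, one, one, one), tr = 2)
  geN <- global_emergence(tsN, method = "MMI")
  vals <- geN$capacity_matrix[upper.tri(geN$capacity_matrix)]
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)

  # constant regions are skipped with a message, not an error
  tsC <- regional_timeseries(rbind(X, rep(1, ncol(X))), tr = 2)
  expect_message(geC <- global_emergence(tsC, method = "MMI"), "skipped")
  expect_equal(geC$n_skipped, 2L)
  expect_error(global_emergence(regional_timeseries(matrix(1, 2, 50), tr = 2)),
               "usable")
  expect_error(global_emergence(ts2, method = "CCS", estimator = "gaussian"),
               "MMI")
})
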
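# Desk-scale DMF checks: small connectomes and short probes keep this file
# within a few minutes while exercising every operation.

dmf_A <- function() generate_connectome(10, 0.5, seed = 33)

test_that("FIC tuning holds the target firing band", {
  A <- dmf_A()
  tuned0 <- fic_tune(A, G = 0)
  expect_true(tuned0$converged)
  expect_equal(diff(range(tuned0$J)), 0, tolerance = 1e-12)  # identical isolated regions
  expect_true(all(tuned0$rate_mean > 2.5 & tuned0$rate_mean < 4.5))

  # J non-decreasing (on average) in G: stronger coupling needs more inhibition
  js <- vapply(c(0, 1, 2), function(G) {
    mean(suppressWarnings(fic_tune(A, G = G, params = dmf_params(G = G)))$J)
  }, numeric(1))
  expect_true(all(diff(js) >= -1e-9))
})

test_that("simulation is deterministic under a fixed seed and decouples at G=0", {
  A <- dmf_A()
  p <- dmf_params(G = 0)
  tuned <- fic_tune(A, G = 0, params = p)
  s1 <- simulate_dmf(A, params = p, duration = 60, tr = 2, J = tuned$J, seed = 7)
  s2 <- simulate_dmf(A, params = p, duration = 60, tr = 2, J = tuned$J, seed = 7)
  expect_identical(as.matrix(s1$bold), as.matrix(s2$bold))
  expect_identical(s1$rate_mean, s2$rate_mean)

  s3 <- simulate_dmf(A, params = p, duration = 120, tr = 2, J = tuned$J, seed = 8)
  fc <- stats::cor(t(as.matrix(s3$bold)))
  expect_lt(mean(abs(fc[upper.tri(fc)])), 0.25)  # decoupled regions
  expect_true(all(s3$rate_mean >= 0))
})

test_that("mean functional connectivity grows with coupling below instability", {
  A <- dmf_A()
  fc_at <- vapply(c(0.5, 2, 3.5), function(G) {
    p <- dmf_params(G = G)
    tuned <- suppressWarnings(fic_tune(A, G = G, params = p))
    sim <- simulate_dmf(A, params = p, duration = 120, tr = 2, J = tuned$J,
                        seed = 11)
    fc <- stats::cor(t(as.matrix(sim$bold)))
    mean(fc[upper.tri(fc)])
  }, numeric(1))
  expect_true(all(diff(fc_at) > 0))
})

test_that("Balloon-Windkessel produces the canonical response shape", {
  dt <- 0.01
  n_t <- 4000                             # 40 s at 10 ms
  z <- matrix(0, 1, n_t)
  z[1, 500:600] <- 0.5                    # 1 s input pulse at t = 5 s
  bold <- balloon_windkessel(z, dt = dt, tr = 0.5)
  base <- bold[1, 1:8]
  dev <- bold[1, ] - mean(base)
  # positive deflection followed by an undershoot
  expect_gt(max(dev), 0)
  expect_lt(min(dev[which.max(dev):length(dev)]), 0)
  expect_gt(which.max(dev), 10)           # peak lags the stimulus

  # zero input: flat baseline
  b0 <- balloon_windkessel(matrix(0, 2, 1000), dt = dt, tr = 0.5)
  expect_equal(max(abs(b0 - b0[1, 1])), 0, tolerance = 1e-12)

  # doubling TR halves the number of output volumes
  b1 <- balloon_windkessel(z, dt = dt, tr = 0.5)
  b2 <- balloon_windkessel(z, dt = dt, tr = 1)
  expect_equal(ncol(b2), ncol(b1) %/% 2L)
  expect_error(balloon_windkessel(matrix(NaN, 1, 10), dt = dt, tr = 1),
               "non-finite")
})

test_that("stability selection returns a grid value just before instability", {
  A <- dmf_A()
  grid <- seq(1, 6, by = 1)
  s1 <- select_g_stability(A, grid = grid, probe = 30, seed = 3)
  s2 <- select_g_stability(A, grid = grid, probe = 30, seed = 3)
  expect_identical(s1$G, s2$G)            # deterministic
  expect_true(s1$G %in% grid)
  sweep_tbl <- tidy(s1)
  first_bad <- which(sweep_tbl$unstable)[1]
  expect_false(is.na(first_bad))
  expect_equal(s1$G, grid[first_bad - 1L])

  # saturating grid triggers the documented fallback
  expect_warning(s3 <- select_g_stability(A, grid = c(0.5, 1), probe = 30,
                                          seed = 3), "grid maximum")
  expect_equal(s3$G, 1)
  expect_error(select_g_stability(A, grid = c(2, 1)), "ascending")
})

test_that("a uniformly attenuated connectome never destabilises earlier", {
  A <- dmf_A()
  half <- structural_connectome(unclass(A) * 0.5)
  grid <- seq(1, 6, by = 1)
  g_full <- select_g_stability(A, grid = grid, probe = 30, seed = 3)$G
  g_half <- suppressWarnings(
    select_g_stability(half, grid = grid, probe = 30, seed = 3)$G)
  expect_gte(g_half, g_full)
})

test_that("FCD windows and statistics behave as specified", {
  set.seed(51)
  # periodic signal, window = period: near-identical FC in every window
  tr <- 1
  t <- seq_len(240)
  X <- rbind(sin(2 * pi * t / 30), cos(2 * pi * t / 30),
             sin(2 * pi * t / 30 + 1))
  f <- fcd(regional_timeseries(X, tr = tr), window = 30, step = 3)
  expect_equal(nrow(f), floor((240 - 30) / 3) + 1L)
  expect_true(all(abs(f[upper.tri(f)]) > 0.99))
  expect_equal(diag(unclass(f)), rep(1, nrow(f)))

  # white noise: off-diagonal FCD centred on zero
  N <- matrix(stats::rnorm(20 * 300), 20, 300)
  fn <- fcd(regional_timeseries(N, tr = tr), window = 30, step = 3)
  expect_lt(abs(mean(fn[upper.tri(fn)])), 0.1)
  expect_true(all(fn >= -1 - 1e-9 & fn <= 1 + 1e-9))
  expect_error(fcd(regional_timeseries(N[, 1:20], tr = tr), window = 30), "window")

  # KS statistic: distribution against itself is 0; range [0, 1]
  v <- as.numeric(fn[upper.tri(fn)])
  expect_equal(emergentdyn:::ks_stat(v, v), 0)
  expect_gte(emergentdyn:::ks_stat(v, v + 10), 0)
  expect_lte(emergentdyn:::ks_stat(v, v + 10), 1)
})

test_that("fit_g_to_fcd validates its inputs", {
  A <- dmf_A()
  expect_error(fit_g_to_fcd(A, list()), "empty")
  ts1 <- regional_timeseries(matrix(stats::rnorm(300), 10, 30), tr = 2)
  ts2 <- regional_timeseries(matrix(stats::rnorm(300), 10, 30), tr = 1)
  expect_error(fit_g_to_fcd(A, list(ts1, ts2)), "share a TR")
  expect_error(fit_g_to_fcd(A, list(ts1), n_sims = 0), "n_sims")
})
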
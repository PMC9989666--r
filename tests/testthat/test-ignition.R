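test_that("event detection finds one upward crossing per oscillation", {
  tr <- 2
  n_t <- 400                         # 800 s
  t <- seq(0, by = tr, length.out = n_t)
  set.seed(5)
  X <- rbind(sin(2 * pi * 0.05 * t) + stats::rnorm(n_t, sd = 0.01),
             sin(2 * pi * 0.05 * t + 1) + stats::rnorm(n_t, sd = 0.01))
  raster <- detect_events(regional_timeseries(X, tr = tr))
  n_cycles <- 0.05 * (n_t * tr)
  expect_true(all(abs(rowSums(raster) - n_cycles) <= 1))
  expect_true(all(raster[, 1] == 0))

  # constant signal: no events; extreme threshold: no events
  flat <- regional_timeseries(matrix(1, 2, 100), tr = tr)
  expect_equal(sum(detect_events(flat)), 0L)
  expect_equal(sum(detect_events(regional_timeseries(X, tr = tr),
                                 z_threshold = 1e6)), 0L)
  expect_error(detect_events(regional_timeseries(X, tr = tr), band = c(0.04, 0.3)),
               "Nyquist")
})

test_that("the worked ignition example traces by hand", {
  r <- event_raster(list(5, 6, 20), n_regions = 3, n_timepoints = 30)
  prof <- intrinsic_driven_ignition(r, window = 4)
  expect_equal(prof$mean_idi, c(2, 1, 1))
  expect_equal(prof$n_events, c(1L, 1L, 1L))
  expect_equal(spatiotemporal_hierarchy(prof), stats::sd(c(2, 1, 1)))
  expect_equal(round(spatiotemporal_hierarchy(prof), 3), 0.577)
})

test_that("full recruitment and single-region cases behave as stated", {
  # identical event times everywhere: every event recruits all regions
  r <- event_raster(list(c(4, 10), c(4, 10), c(4, 10), c(4, 10)),
                    n_regions = 4, n_timepoints = 20)
  prof <- intrinsic_driven_ignition(r, window = 4)
  expect_equal(prof$mean_idi, rep(4, 4))
  expect_equal(spatiotemporal_hierarchy(prof), 0)

  # only one region has events: its IDI is 1, others missing
  r1 <- event_raster(list(c(3, 9)), n_regions = 3, n_timepoints = 20)
  prof1 <- intrinsic_driven_ignition(r1, window = 4)
  expect_equal(prof1$mean_idi, c(1, NA, NA))
  expect_error(spatiotemporal_hierarchy(prof1), "2 regions")
  expect_equal(spatiotemporal_hierarchy(prof1, include_eventless = TRUE),
               stats::sd(c(1, 0, 0)))
})

test_that("IDI equals the largest connected component of the co-event matrix", {
  set.seed(41)
  sigma <- matrix(stats::rbinom(8 * 40, 1, 0.08), 8, 40)
  sigma[, 1] <- 0
  r <- event_raster(apply(sigma == 1, 1, which, simplify = FALSE),
                    n_regions = 8, n_timepoints = 40)
  prof <- intrinsic_driven_ignition(r, window = 4)
  for (i in 1:8) {
    times <- which(sigma[i, ] == 1)
    if (length(times) == 0) next
    sizes <- vapply(times, function(t0) {
      win <- t0:min(40, t0 + 3)
      part <- which(rowSums(sigma[, win, drop = FALSE]) >= 1)
      # co-event matrix links every pair of participating regions (clique),
      # so the BFS largest component must equal the participating-set size
      adj <- matrix(0, 8, 8)
      adj[part, part] <- 1
      comp <- largest_component_size(adj[part, part, drop = FALSE])
      expect_equal(comp, length(part))
      length(part)
    }, numeric(1))
    expect_equal(prof$mean_idi[i], mean(sizes))
  }
})

test_that("hierarchy is invariant to relabelling and time shifts, monotone in window", {
  ev <- list(c(5, 14), c(6, 20), 8, c(11, 25))
  r <- event_raster(ev, n_regions = 4, n_timepoints = 40)
  h <- spatiotemporal_hierarchy(intrinsic_driven_ignition(r, window = 4))
  # relabel regions
  r2 <- event_raster(ev[c(3, 1, 4, 2)], n_regions = 4, n_timepoints = 40)
  expect_equal(spatiotemporal_hierarchy(intrinsic_driven_ignition(r2, window = 4)), h)
  # shift all events by +5
  r3 <- event_raster(lapply(ev, `+`, 5), n_regions = 4, n_timepoints = 45)
  expect_equal(spatiotemporal_hierarchy(intrinsic_driven_ignition(r3, window = 4)), h)
  # monotonicity: larger window never decreases any mean IDI
  p4 <- intrinsic_driven_ignition(r, window = 4)
  p8 <- intrinsic_driven_ignition(r, window = 8)
  expect_true(all(p8$mean_idi >= p4$mean_idi))
})
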
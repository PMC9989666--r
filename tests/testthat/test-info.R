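test_that("binarize_and_estimate_pmf implements the plug-in estimator", {
  # alternating surrogate concentrates on two joint states
  x <- rep(c(0, 1), 50)
  pmf <- binarize_and_estimate_pmf(x, x, lag = 1)
  expect_equal(sum(pmf), 1)
  expect_equal(sum(as.numeric(pmf) > 0), 2L)

  # independent uniform series converge to the product law
  set.seed(4)
  n <- 1e5
  a <- stats::runif(n); b <- stats::runif(n)
  pmf <- binarize_and_estimate_pmf(a, b, lag = 1)
  # each variable is ~Bernoulli(1/2), lagged copies nearly independent
  expect_lt(max(abs(as.numeric(pmf) - 1 / 16)), 0.01)

  expect_error(binarize_and_estimate_pmf(a[1:10], b[1:10], lag = 10), "lag")
  expect_warning(out <- binarize_and_estimate_pmf(rep(1, 50), stats::rnorm(50)),
                 "constant")
  expect_null(out)
})

test_that("joint_pmf4 validates its invariants", {
  expect_error(joint_pmf4(rep(1 / 15, 15)), "16")
  expect_error(joint_pmf4(rep(1 / 8, 16)), "sum to 1")
  expect_error(joint_pmf4(rep(1 / 16, 16), lag = 0), "lag")
  p <- joint_pmf4(rep(1 / 16, 16), lag = 4)
  expect_equal(attr(p, "lag"), 4L)
  expect_equal(tdmi(p), 0)
})

test_that("HRF deconvolution inverts convolution with the canonical kernel", {
  tr <- 2
  h <- canonical_hrf(tr)
  set.seed(11)
  z <- stats::rnorm(300)
  conv <- stats::filter(c(rep(0, length(h)), z), h, sides = 1)
  conv <- as.numeric(conv[-seq_len(length(h))])
  ts <- regional_timeseries(rbind(conv, conv), tr = tr)
  dec <- hrf_deconvolve(ts)
  expect_equal(ncol(dec), length(conv))
  expect_gt(stats::cor(dec[1, ], z - mean(z)), 0.9)
  expect_equal(mean(dec[1, ]), 0, tolerance = 1e-10)

  # linearity: zero in, zero out; constant in, zero out (after mean removal)
  zero <- regional_timeseries(matrix(0, 2, 100), tr = tr)
  expect_equal(max(abs(hrf_deconvolve(zero))), 0)
  const <- regional_timeseries(matrix(3.7, 2, 100), tr = tr)
  expect_equal(max(abs(hrf_deconvolve(const))), 0, tolerance = 1e-10)
  expect_error(regional_timeseries(matrix(0, 2, 100), tr = -1), "tr")
})

test_that("Butterworth band-pass matches the reference design", {
  # frozen reference coefficients (scipy.signal.butter, order 2, fs = 0.5 Hz)
  co <- butter_bandpass(0.04, 0.07, fs = 0.5)
  expect_equal(co$b,
               c(2.785976611714e-02, 0, -5.571953223427e-02, 0, 2.785976611714e-02),
               tolerance = 1e-10)
  expect_equal(co$a,
               c(1, -2.726192063279, 3.359759015216, -2.078145396410,
                 0.5869195080612),
               tolerance = 1e-10)
  co2 <- butter_bandpass(0.008, 0.09, fs = 0.5)
  expect_equal(co2$b,
               c(1.511366024747e-01, 0, -3.022732049493e-01, 0, 1.511366024747e-01),
               tolerance = 1e-10)
  expect_equal(co2$a,
               c(1, -2.477115460157, 2.299927448045, -1.060641285795,
                 0.2450486642925),
               tolerance = 1e-10)
  expect_error(butter_bandpass(0.04, 0.3, fs = 0.5), "Nyquist")
})

test_that("zero-phase filtering passes the band without phase shift", {
  tr <- 2
  t <- seq(0, by = tr, length.out = 400)
  in_band <- sin(2 * pi * 0.05 * t)
  out_band <- sin(2 * pi * 0.2 * t)
  y <- bandpass_timeseries(rbind(in_band + out_band), band = c(0.04, 0.07), tr = tr)
  mid <- 100:300   # avoid edge transients
  # in-band component survives, aligned in phase (zero-phase filtering)
  expect_gt(stats::cor(y[1, mid], in_band[mid]), 0.99)
  # out-of-band component strongly attenuated
  resid <- y[1, mid] - in_band[mid] * stats::sd(y[1, mid]) / stats::sd(in_band[mid])
  expect_lt(stats::sd(resid), 0.1 * stats::sd(out_band))
})
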
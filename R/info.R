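# Discrete and Gaussian Shannon-information primitives.
# All quantities are in bits (log base 2).

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# p: array over k binary (or general) variables. Marginalise onto `dims`.
marginal <- function(p, dims) apply(p, dims, sum)

# Mutual information between two disjoint groups of dimensions of a pmf array.
mi_groups <- function(p, src, tgt) {
  entropy_bits(marginal(p, src)) + entropy_bits(marginal(p, tgt)) -
    entropy_bits(marginal(p, c(src, tgt)))
}

#' Binarise two series at their means and estimate the lagged joint pmf
#'
#' Each series is binarised at its own mean (strictly above the mean maps to
#' 1, ties to 0) and the plug-in (empirical frequency) estimator is applied to
#' the 16 joint states of `(X1[t-lag], X2[t-lag], X1[t], X2[t])` over the
#' `T - lag` aligned samples.
#'
#' @param x,y numeric vectors of equal length `T`.
#' @param lag positive integer lag in timepoints, `lag < T`.
#' @return an object of class `joint_pmf4`: a 2x2x2x2 probability array with
#'   dimensions (X1 past, X2 past, X1 future, X2 future), attributes `lag`
#'   and `sample_count`. Returns `NULL` with a warning if either series is
#'   constant (no variance, the pair must be skipped).
#' @export
binarize_and_estimate_pmf <- function(x, y, lag = 1L) {
  if (length(x) != length(y)) stop_param("series must have equal length")
  lag <- as.integer(lag)
  if (lag < 1L) stop_param("`lag` must be >= 1")
  n <- length(x)
  if (n - lag < 1L) stop_param("`lag` leaves no aligned samples (lag >= length)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant series: pair skipped", call. = FALSE)
    return(NULL)
  }
  xb <- as.integer(x > mean(x))
  yb <- as.integer(y > mean(y))
  past <- seq_len(n - lag)
  fut <- past + lag
  state <- 1L + xb[past] + 2L * yb[past] + 4L * xb[fut] + 8L * yb[fut]
  p <- tabulate(state, nbins = 16L) / (n - lag)
  joint_pmf4(p, lag = lag, sample_count = n - lag)
}

#' Construct a 16-state lagged joint pmf
#'
#' @param p numeric vector of 16 probabilities in the state order
#'   `1 + x1p + 2*x2p + 4*x1f + 8*x2f` (each variable in {0,1}), or a
#'   2x2x2x2 array.
#' @param lag lag in timepoints (>= 1).
#' @param sample_count number of samples behind the estimate (NA if analytic).
#' @return a `joint_pmf4` array.
#' @export
joint_pmf4 <- function(p, lag = 1L, sample_count = NA_integer_) {
  p <- as.numeric(p)
  if (length(p) != 16L) stop_param("`p` must have 16 entries")
  if (any(p < -1e-12)) stop_param("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) stop_param("probabilities must sum to 1 (within 1e-12)")
  if (lag < 1L) stop_param("`lag` must be >= 1")
  arr <- array(pmax(p, 0), dim = c(2L, 2L, 2L, 2L),
               dimnames = list(x1_past = 0:1, x2_past = 0:1,
                               x1_future = 0:1, x2_future = 0:1))
  structure(arr, lag = as.integer(lag), sample_count = sample_count,
            class = c("joint_pmf4", "array"))
}

# Precomputed aggregation matrices mapping the 16-state pmf vector (state
# order 1 + x1p + 2*x2p + 4*x1f + 8*x2f) onto every marginal needed below.
# Keeping these as dense 0/1 matrices makes each marginal a tiny matvec,
# which is what lets the all-pairs emergence loop run at scale.
pmf16_maps <- local({
  bits <- expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1, b4 = 0:1)
  subsets <- list("1" = 1, "2" = 2, "3" = 3, "4" = 4,
                  "12" = c(1, 2), "34" = c(3, 4), "13" = c(1, 3),
                  "14" = c(1, 4), "23" = c(2, 3), "24" = c(2, 4),
                  "134" = c(1, 3, 4), "234" = c(2, 3, 4))
  out <- lapply(subsets, function(s) {
    key <- as.integer(as.matrix(bits[, s, drop = FALSE]) %*% 2^(seq_along(s) - 1)) + 1L
    M <- matrix(0, 2^length(s), 16L)
    M[cbind(key, seq_len(16L))] <- 1
    list(M = M, key = key)
  })
  out
})

marg16 <- function(p, name) as.numeric(pmf16_maps[[name]]$M %*% p)

# The nine Shannon MIs between subsets of past and subsets of future
# variables, for a joint_pmf4 (dims 1:2 = past, 3:4 = future) or a 16-vector.
phid_mis <- function(pmf) {
  p <- as.numeric(pmf)
  h1 <- entropy_bits(marg16(p, "1")); h2 <- entropy_bits(marg16(p, "2"))
  h3 <- entropy_bits(marg16(p, "3")); h4 <- entropy_bits(marg16(p, "4"))
  h12 <- entropy_bits(marg16(p, "12")); h34 <- entropy_bits(marg16(p, "34"))
  h13 <- entropy_bits(marg16(p, "13")); h14 <- entropy_bits(marg16(p, "14"))
  h23 <- entropy_bits(marg16(p, "23")); h24 <- entropy_bits(marg16(p, "24"))
  h134 <- entropy_bits(marg16(p, "134")); h234 <- entropy_bits(marg16(p, "234"))
  h123 <- entropy_bits(marg16_3(p, c(1L, 2L, 3L)))
  h124 <- entropy_bits(marg16_3(p, c(1L, 2L, 4L)))
  h1234 <- entropy_bits(p)
  list(
    i11 = h1 + h3 - h13, i12 = h1 + h4 - h14,
    i21 = h2 + h3 - h23, i22 = h2 + h4 - h24,
    i1j = h1 + h34 - h134, i2j = h2 + h34 - h234,
    ij1 = h12 + h3 - h123, ij2 = h12 + h4 - h124,
    ijj = h12 + h34 - h1234
  )
}

# 3-variable marginals over state bits (1-based bit indices).
pmf16_maps3 <- local({
  bits <- as.matrix(expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1, b4 = 0:1))
  build <- function(s) {
    key <- as.integer(bits[, s, drop = FALSE] %*% 2^(seq_along(s) - 1)) + 1L
    M <- matrix(0, 2^length(s), 16L)
    M[cbind(key, seq_len(16L))] <- 1
    M
  }
  list("123" = build(c(1, 2, 3)), "124" = build(c(1, 2, 4)))
})

marg16_3 <- function(p, s) {
  as.numeric(pmf16_maps3[[paste(s, collapse = "")]] %*% p)
}

#' Time-delayed mutual information of a lagged joint pmf
#'
#' `I(X1_past, X2_past ; X1_future, X2_future)` in bits.
#'
#' @param pmf a [joint_pmf4()].
#' @return scalar, bits.
#' @export
tdmi <- function(pmf) {
  stopifnot(inherits(pmf, "joint_pmf4"))
  mi_groups(pmf, c(1L, 2L), c(3L, 4L))
}

# ---- Gaussian (closed-form) MIs ---------------------------------------------

gauss_logdet <- function(C) {
  d <- determinant(as.matrix(C), logarithm = TRUE)
  as.numeric(d$modulus)
}

# MI between index sets of a multivariate Gaussian with covariance C, in bits.
gauss_mi <- function(C, src, tgt) {
  val <- 0.5 * (gauss_logdet(C[src, src, drop = FALSE]) +
                  gauss_logdet(C[tgt, tgt, drop = FALSE]) -
                  gauss_logdet(C[c(src, tgt), c(src, tgt), drop = FALSE]))
  val / log(2)
}

# Lagged 4x4 covariance of a pair of continuous series; ridge-regularised if
# near-singular (warning).
lagged_cov_pair <- function(x, y, lag) {
  n <- length(x)
  past <- seq_len(n - lag)
  fut <- past + lag
  Z <- cbind(x[past], y[past], x[fut], y[fut])
  C <- stats::cov(Z)
  if (rcond_sym(C) < 1e-12) {
    warning("near-singular lagged covariance: ridge 1e-9 applied", call. = FALSE)
    C <- C + diag(1e-9, 4L)
  }
  C
}

rcond_sym <- function(C) {
  ev <- abs(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (max(ev) == 0) 0 else min(ev) / max(ev)
}

phid_mis_gaussian <- function(C) {
  list(
    i11 = gauss_mi(C, 1L, 3L), i12 = gauss_mi(C, 1L, 4L),
    i21 = gauss_mi(C, 2L, 3L), i22 = gauss_mi(C, 2L, 4L),
    i1j = gauss_mi(C, 1L, c(3L, 4L)), i2j = gauss_mi(C, 2L, c(3L, 4L)),
    ij1 = gauss_mi(C, c(1L, 2L), 3L), ij2 = gauss_mi(C, c(1L, 2L), 4L),
    ijj = gauss_mi(C, c(1L, 2L), c(3L, 4L))
  )
}
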
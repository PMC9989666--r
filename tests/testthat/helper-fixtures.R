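# Shared fixtures and independent oracles, all built in code.

# Analytic 16-state pmf of two independent binary copy-chains
# (X1_t = X1_{t-lag}, X2_t = X2_{t-lag}, fair marginals).
copy_chain_pmf <- function() {
  p <- numeric(16)
  for (a in 0:1) for (b in 0:1) p[1 + a + 2 * b + 4 * a + 8 * b] <- 0.25
  joint_pmf4(p)
}

# Analytic pmf of noisy-XOR dynamics: S1, S2 fair iid bits in the past;
# X1_future = XOR(S1, S2) flipped with probability eps; X2_future fresh fair
# bit independent of everything.
noisy_xor_pmf <- function(eps) {
  p <- numeric(16)
  for (a in 0:1) for (b in 0:1) for (f1 in 0:1) for (f2 in 0:1) {
    x <- xor(a, b) + 0L
    pr <- 0.25 * (if (f1 == x) 1 - eps else eps) * 0.5
    p[1 + a + 2 * b + 4 * f1 + 8 * f2] <- pr
  }
  joint_pmf4(p)
}

binary_entropy <- function(eps) {
  if (eps <= 0 || eps >= 1) return(0)
  -eps * log2(eps) - (1 - eps) * log2(1 - eps)
}

# Random valid 16-state pmf (multinomial draw -> plug-in-like pmf).
random_pmf16 <- function(n = 400) {
  w <- stats::runif(16)
  p <- as.numeric(stats::rmultinom(1, n, w)) / n
  joint_pmf4(p)
}

# Simulate a stable random 2-region VAR(1) and return the series.
random_var_pair <- function(n_t = 400, rho = NULL) {
  W <- matrix(stats::rnorm(4, sd = 0.5), 2, 2)
  r <- max(Mod(eigen(W, only.values = TRUE)$values))
  target <- rho %||% stats::runif(1, 0.3, 0.9)
  if (r > 0) W <- W * (target / r)
  X <- matrix(0, 2, n_t + 50)
  for (t in 2:ncol(X)) X[, t] <- W %*% X[, t - 1] + stats::rnorm(2)
  X[, -(1:50)]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Small synthetic cohort reused by several files.
small_cohort <- function(seed = 5, n_regions = 16, n_per_group = 3,
                         n_timepoints = 120) {
  generate_var_cohort(synthetic_cohort_spec(
    n_regions = n_regions,
    n_subjects_per_group = c(control = n_per_group, MCS = n_per_group,
                             UWS = n_per_group),
    n_timepoints = n_timepoints, seed = seed))
}

# Independent largest-connected-component oracle (BFS) for the ignition
# clique-equivalence check.
largest_component_size <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  best <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      nb <- which(adj[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    best <- max(best, size)
  }
  best
}
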
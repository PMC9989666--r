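test_that("normalisation gives Schur stability", {
  A <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  An <- normalize_connectome(A)
  expect_equal(An[1, 2], 0.4 / 1.4, tolerance = 1e-12)
  expect_true(attr(An, "normalized"))

  set.seed(2)
  B <- generate_connectome(30, 0.4, seed = 12)
  Bn <- normalize_connectome(B)
  expect_lt(max(abs(eigen(unclass(Bn), symmetric = TRUE,
                          only.values = TRUE)$values)), 1)

  expect_warning(Z <- normalize_connectome(matrix(0, 3, 3)), "all-zero")
  expect_equal(max(abs(Z)), 0)
  expect_error(structural_connectome(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("average controllability solves the node Gramian trace", {
  # A = 0: W = B B', trace 1 for every node
  Z <- suppressWarnings(normalize_connectome(matrix(0, 4, 4)))
  expect_equal(average_controllability(Z)$average, rep(1, 4))

  # 2-node worked example equals the truncated Gramian sum
  An <- normalize_connectome(matrix(c(0, 0.4, 0.4, 0), 2, 2))
  avg <- average_controllability(An)$average
  M <- unclass(An)
  for (node in 1:2) {
    B <- diag(2)[, node, drop = FALSE]
    W <- matrix(0, 2, 2)
    Ak <- diag(2)
    for (tau in 0:200) {
      W <- W + Ak %*% B %*% t(B) %*% t(Ak)
      Ak <- Ak %*% M
    }
    expect_equal(avg[node], unname(sum(diag(W))), tolerance = 1e-10)
  }

  # Lyapunov solution equals the truncated sum on random normalised matrices
  set.seed(6)
  for (i in 1:5) {
    An <- normalize_connectome(generate_connectome(12, 0.5, seed = 100 + i))
    avg <- average_controllability(An)$average
    M <- unclass(An)
    P <- diag(12)
    S <- matrix(0, 12, 12)
    for (tau in 0:400) {
      S <- S + P %*% t(P)
      P <- M %*% P
    }
    expect_equal(avg, unname(diag(S)), tolerance = 1e-10)
    expect_true(all(avg >= 1))        # tau = 0 term alone contributes 1
  }

  expect_error(average_controllability(structural_connectome(matrix(0, 2, 2))),
               "normalis")
})

test_that("modal controllability matches the eigenmode formula", {
  Z <- suppressWarnings(normalize_connectome(matrix(0, 4, 4)))
  expect_equal(modal_controllability(Z)$modal, rep(1, 4))

  An <- normalize_connectome(matrix(c(0, 0.4, 0.4, 0), 2, 2))
  phi <- modal_controllability(An)$modal
  expect_equal(phi, rep(1 - (0.4 / 1.4)^2, 2), tolerance = 1e-12)
  expect_equal(round(phi[1], 4), 0.9184)

  # phi in (0, 1] and anticorrelated with node strength
  set.seed(14)
  rhos <- vapply(1:20, function(i) {
    sc <- generate_connectome(50, 0.3, seed = 2000 + i)
    An <- normalize_connectome(sc)
    phi <- modal_controllability(An)$modal
    expect_true(all(phi > 0 & phi <= 1 + 1e-12))
    stats::cor(phi, rowSums(sc), method = "spearman")
  }, numeric(1))
  expect_true(all(rhos < 0))
})

test_that("consensus connectome applies the strict majority rule", {
  mk <- function(v) structural_connectome(matrix(c(0, v, v, 0), 2, 2))
  # identical inputs: idempotent
  cc <- consensus_connectome(list(mk(3), mk(3), mk(3)))
  expect_equal(cc[1, 2], 3)
  # present in 1 of 3 -> 0; in 2 of 3 with weights 2 and 4 -> 3
  expect_equal(consensus_connectome(list(mk(5), mk(0), mk(0)))[1, 2], 0)
  expect_equal(consensus_connectome(list(mk(2), mk(4), mk(0)))[1, 2], 3)
  # exactly half (2 of 4) -> 0: "more than half" is strict
  expect_equal(consensus_connectome(list(mk(2), mk(4), mk(0), mk(0)))[1, 2], 0)
  expect_error(consensus_connectome(list()), "empty")
})

test_that("the lesioned (UWS-analogue) group has lower global modal controllability", {
  cohort <- small_cohort(seed = 19, n_regions = 40, n_per_group = 6)
  gm <- vapply(cohort$connectomes, function(sc) {
    mean(modal_controllability(normalize_connectome(sc))$modal)
  }, numeric(1))
  grp <- cohort$subjects$group
  expect_gt(mean(gm[grp == "control"]), mean(gm[grp == "UWS"]))
})
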
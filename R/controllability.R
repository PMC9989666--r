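#' Normalise a structural connectome for Schur stability
#'
#' Divides the adjacency matrix by its largest singular value plus one, so
#' the linear dynamics `x(t+1) = A x(t) + B u(t)` are strictly Schur stable
#' (spectral radius < 1).
#'
#' @param A a [structural_connectome()] or symmetric non-negative matrix.
#' @return a normalised [structural_connectome()] (`normalized` flag set).
#' @export
normalize_connectome <- function(A) {
  sc <- if (inherits(A, "structural_connectome")) A else structural_connectome(A)
  if (all(sc == 0)) {
    warning("all-zero connectome returned unchanged", call. = FALSE)
    return(structural_connectome(unclass(sc), labels = rownames(sc),
                                 normalized = TRUE))
  }
  sigma <- sigma_max_sym(unclass(sc))
  out <- unclass(sc) / (sigma + 1)
  structural_connectome(out, labels = rownames(sc), normalized = TRUE)
}

assert_normalized <- function(A, caller) {
  if (!inherits(A, "structural_connectome") || !isTRUE(attr(A, "normalized"))) {
    stop_param(sprintf("%s() needs a normalised connectome; run normalize_connectome() first",
                       caller))
  }
  invisible(A)
}

#' Average controllability per region
#'
#' For each region `i` (control input `B = e_i`), the controllability Gramian
#' solves the discrete Lyapunov equation `W = A W A' + B B'`; the regional
#' value is `trace(W_i)`, the energy of the network impulse response from
#' node `i`. For symmetric Schur-stable `A` this equals
#' `[(I - A^2)^{-1}]_{ii}`, which is how it is computed (an exact Lyapunov
#' solution via the eigendecomposition, not a truncated sum).
#'
#' @param A a normalised [structural_connectome()].
#' @return an object of class `controllability_profile` restricted to the
#'   average measure: tibble with `region`, `average`; attribute
#'   `global_average` (mean over regions).
#' @export
average_controllability <- function(A) {
  assert_normalized(A, "average_controllability")
  M <- unclass(A)
  ev <- eigen(M, symmetric = TRUE)
  lambda <- ev$values
  if (max(abs(lambda)) >= 1) stop_param("unstable matrix: spectral radius >= 1")
  # (I - A^2)^{-1} = V diag(1/(1-lambda^2)) V'
  diag_part <- rowSums(sweep(ev$vectors^2, 2L, 1 / (1 - lambda^2), `*`))
  tibble::tibble(region = rownames(M), average = diag_part)
}

#' Modal controllability per region
#'
#' With the eigendecomposition `A = V L V'` (real, orthonormal for symmetric
#' `A`), the modal controllability of region `i` is
#' `phi_i = sum_j (1 - lambda_j^2) * v_ij^2`: the scaled ability of node `i`
#' to control all dynamic modes, high when the node can steer the system into
#' hard-to-reach (fast-decaying) configurations. Eigenvalues are sorted in
#' descending order; for degenerate spectra the sum over the degenerate
#' subspace is rotation-invariant.
#'
#' @param A a normalised, symmetric [structural_connectome()].
#' @return tibble with `region`, `modal`.
#' @export
modal_controllability <- function(A) {
  assert_normalized(A, "modal_controllability")
  M <- unclass(A)
  ev <- eigen(M, symmetric = TRUE)   # descending eigenvalues
  phi <- rowSums(sweep(ev$vectors^2, 2L, 1 - ev$values^2, `*`))
  tibble::tibble(region = rownames(M), modal = phi)
}

#' Regional and global controllability profile
#'
#' Convenience wrapper combining [average_controllability()] and
#' [modal_controllability()].
#'
#' @param A a [structural_connectome()]; normalised automatically if needed.
#' @return an object of class `controllability_profile`: tibble with
#'   `region`, `average`, `modal`; `glance()` returns the whole-brain
#'   (unweighted mean) values.
#' @export
controllability_profile <- function(A) {
  if (!inherits(A, "structural_connectome") || !isTRUE(attr(A, "normalized"))) {
    A <- suppressWarnings(normalize_connectome(A))
  }
  out <- dplyr::left_join(average_controllability(A), modal_controllability(A),
                          by = "region")
  class(out) <- c("controllability_profile", class(out))
  out
}

#' @exportS3Method generics::glance
glance.controllability_profile <- function(x, ...) {
  tibble::tibble(global_average = mean(x$average), global_modal = mean(x$modal),
                 n_regions = nrow(x))
}

#' Group consensus connectome
#'
#' Entrywise rule over a list of subject connectomes: if strictly more than
#' half of the subjects have a non-zero connection between `i` and `j`, the
#' consensus weight is the mean over the subjects with a non-zero connection;
#' otherwise it is zero.
#'
#' @param connectomes non-empty list of [structural_connectome()]s with equal
#'   dimensions and label order.
#' @return a [structural_connectome()].
#' @export
consensus_connectome <- function(connectomes) {
  if (length(connectomes) == 0L) stop_param("empty connectome list")
  mats <- lapply(connectomes, function(x) unclass(as.matrix(x)))
  dims <- vapply(mats, nrow, 1L)
  if (length(unique(dims)) != 1L) stop_param("connectomes must share dimensions")
  labels <- rownames(mats[[1]])
  n_sub <- length(mats)
  arr <- simplify2array(mats)
  nz <- apply(arr != 0, c(1L, 2L), sum)
  s <- apply(arr, c(1L, 2L), sum)
  consensus <- ifelse(nz > n_sub / 2, s / pmax(nz, 1L), 0)
  structural_connectome(consensus, labels = labels)
}
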
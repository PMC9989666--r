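#' Partial information decomposition of two sources about one target
#'
#' Decomposes `I(S1, S2; T)` into redundancy, two unique components and
#' synergy, given a redundancy function:
#'
#' * `"MMI"` (minimum mutual information): redundancy is
#'   `min(I(S1;T), I(S2;T))`.
#' * `"CCS"` (common change in surprisal): redundancy is the sum, over joint
#'   states, of the local co-information
#'   `c = i(s1;t) + i(s2;t) - i(s1,s2;t)` weighted by the state probability,
#'   restricted to states where the three local informations and `c` all
#'   share the same (strict) sign; any state with a zero local term
#'   contributes nothing.
#'
#' The remaining components follow from the consistency equations
#' `unique_k = I(Sk;T) - red` and
#' `synergy = I(S1,S2;T) - red - unique_1 - unique_2`.
#'
#' @param pmf a 3-dimensional probability array `p[s1, s2, t]`; the target may
#'   be composite (any number of states along the third dimension).
#' @param method `"CCS"` or `"MMI"`.
#' @return an object of class `pid_result`: a list with `redundancy`,
#'   `unique_1`, `unique_2`, `synergy`, `total_mi` (all bits) and `method`.
#' @export
#' @examples
#' # XOR: two fair bits and their parity -> 1 bit of pure synergy
#' p <- array(0, c(2, 2, 2))
#' for (a in 0:1) for (b in 0:1) p[a + 1, b + 1, xor(a, b) + 1] <- 0.25
#' pid(p, method = "CCS")
pid <- function(pmf, method = c("CCS", "MMI")) {
  method <- match.arg(method)
  p <- as.array(pmf)
  if (length(dim(p)) != 3L) stop_param("`pmf` must be a 3-d array p[s1, s2, t]")
  if (any(p < 0)) stop_param("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop_param("`pmf` is not normalised")

  i_s1 <- mi_groups(p, 1L, 3L)
  i_s2 <- mi_groups(p, 2L, 3L)
  i_joint <- mi_groups(p, c(1L, 2L), 3L)

  red <- switch(method,
    MMI = min(i_s1, i_s2),
    CCS = ccs_redundancy(p)
  )
  unique_1 <- i_s1 - red
  unique_2 <- i_s2 - red
  synergy <- i_joint - red - unique_1 - unique_2
  structure(list(redundancy = red, unique_1 = unique_1, unique_2 = unique_2,
                 synergy = synergy, total_mi = i_joint, method = method),
            class = "pid_result")
}

# Sign-coherent local co-information (common change in surprisal).
ccs_redundancy <- function(p) {
  p1 <- marginal(p, 1L); p2 <- marginal(p, 2L); pt <- marginal(p, 3L)
  p1t <- marginal(p, c(1L, 3L)); p2t <- marginal(p, c(2L, 3L))
  p12 <- marginal(p, c(1L, 2L))
  red <- 0
  d <- dim(p)
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) for (tt in seq_len(d[3])) {
    pr <- p[a, b, tt]
    if (pr == 0) next
    i1 <- log2(p1t[a, tt] / (p1[a] * pt[tt]))
    i2 <- log2(p2t[b, tt] / (p2[b] * pt[tt]))
    i12 <- log2(pr / (p12[a, b] * pt[tt]))
    co <- i1 + i2 - i12
    s <- sign(c(i1, i2, i12, co))
    if (all(s == 1) || all(s == -1)) red <- red + pr * co
  }
  red
}

#' @export
print.pid_result <- function(x, ...) {
  cat(sprintf(
    "<pid_result> method=%s | red=%.4f unq1=%.4f unq2=%.4f syn=%.4f (total %.4f bits)\n",
    x$method, x$redundancy, x$unique_1, x$unique_2, x$synergy, x$total_mi))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pid_result <- function(x, ...) {
  tibble::tibble(
    component = c("redundancy", "unique_1", "unique_2", "synergy"),
    bits = c(x$redundancy, x$unique_1, x$unique_2, x$synergy),
    method = x$method
  )
}

#' @exportS3Method generics::glance
glance.pid_result <- function(x, ...) {
  tibble::tibble(total_mi = x$total_mi, method = x$method)
}

# Forward PID of a joint_pmf4: sources = the two past variables, composite
# target = the joint future state (4 states).
pid_forward <- function(pmf, method) {
  p3 <- array(as.numeric(pmf), dim = c(2L, 2L, 4L))
  pid(p3, method = method)
}

# Vectorised CCS redundancy of the forward decomposition of a 16-state
# lagged pmf (sources = past bits, composite target = future bits);
# equivalent to ccs_redundancy() on the reshaped 3-d array.
ccs_red16 <- function(p) {
  k1 <- pmf16_maps[["1"]]$key; k2 <- pmf16_maps[["2"]]$key
  kT <- pmf16_maps[["34"]]$key; k12 <- pmf16_maps[["12"]]$key
  k134 <- pmf16_maps[["134"]]$key; k234 <- pmf16_maps[["234"]]$key
  m1 <- marg16(p, "1"); m2 <- marg16(p, "2"); mT <- marg16(p, "34")
  m12 <- marg16(p, "12"); m134 <- marg16(p, "134"); m234 <- marg16(p, "234")
  pos <- p > 0
  i1 <- log2(m134[k134] / (m1[k1] * mT[kT]))
  i2 <- log2(m234[k234] / (m2[k2] * mT[kT]))
  i12 <- log2(p / (m12[k12] * mT[kT]))
  co <- i1 + i2 - i12
  coh <- pos & ((i1 > 0 & i2 > 0 & i12 > 0 & co > 0) |
                  (i1 < 0 & i2 < 0 & i12 < 0 & co < 0))
  sum(p[coh] * co[coh])
}
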
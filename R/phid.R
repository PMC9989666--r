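# Integrated Information Decomposition of the time-delayed mutual information
# of a bivariate process into 16 atoms indexed by (past, future) combinations
# of {Red, Unq1, Unq2, Syn}.

ATOMS <- c("Red", "Unq1", "Unq2", "Syn")

# Down-sets of the 2-source redundancy lattice: which atoms are accumulated
# by each collection node.
atom_downset <- list(Red = "Red", Unq1 = c("Red", "Unq1"),
                     Unq2 = c("Red", "Unq2"), Syn = ATOMS)

# 16x16 linear system relating cumulative (redundancy-lattice) quantities to
# atoms. Rows: the 9 Shannon MIs between subsets of past and future, the 3
# forward and 3 backward single-sided redundancies, and the double redundancy.
# The design is fixed and full-rank; its inverse is precomputed once.
phid_design <- local({
  idx <- function(a, b) (match(b, ATOMS) - 1L) * 4L + match(a, ATOMS)
  nodes <- c(r = "Red", s1 = "Unq1", s2 = "Unq2", j = "Syn")
  rows <- list(
    i11 = c("Unq1", "Unq1"), i12 = c("Unq1", "Unq2"),
    i21 = c("Unq2", "Unq1"), i22 = c("Unq2", "Unq2"),
    i1j = c("Unq1", "Syn"), i2j = c("Unq2", "Syn"),
    ij1 = c("Syn", "Unq1"), ij2 = c("Syn", "Unq2"),
    ijj = c("Syn", "Syn"),
    rf1 = c("Red", "Unq1"), rf2 = c("Red", "Unq2"), rfj = c("Red", "Syn"),
    rb1 = c("Unq1", "Red"), rb2 = c("Unq2", "Red"), rbj = c("Syn", "Red"),
    rr = c("Red", "Red")
  )
  M <- matrix(0, 16L, 16L, dimnames = list(names(rows), NULL))
  for (r in names(rows)) {
    past <- atom_downset[[rows[[r]][1]]]
    fut <- atom_downset[[rows[[r]][2]]]
    for (a in past) for (b in fut) M[r, idx(a, b)] <- 1
  }
  stopifnot(abs(det(M)) > 0.5)  # unimodular-ish 0/1 design, always invertible
  list(M = M, Minv = solve(M))
})

# Solve the lattice from the 9 Shannon MIs using MMI single- and
# double-redundancies. Returns a 4x4 matrix atoms[past, future].
phid_solve_mmi <- function(mis) {
  rhs <- c(
    mis$i11, mis$i12, mis$i21, mis$i22,
    mis$i1j, mis$i2j, mis$ij1, mis$ij2, mis$ijj,
    rf1 = min(mis$i11, mis$i21), rf2 = min(mis$i12, mis$i22),
    rfj = min(mis$i1j, mis$i2j),
    rb1 = min(mis$i11, mis$i12), rb2 = min(mis$i21, mis$i22),
    rbj = min(mis$ij1, mis$ij2),
    rr = min(mis$i11, mis$i12, mis$i21, mis$i22)
  )
  atoms <- phid_design$Minv %*% rhs
  matrix(atoms, 4L, 4L, dimnames = list(past = ATOMS, future = ATOMS))
}

#' Integrated Information Decomposition atoms of a lagged joint pmf
#'
#' Solves the 16-atom lattice of the time-delayed mutual information of a
#' bivariate binary process: the 9 Shannon mutual informations between
#' subsets of past and subsets of future variables, together with the 6
#' single-sided minimum-mutual-information (MMI) redundancies and the MMI
#' double redundancy (the minimum of the four cross mutual informations
#' `I(Xi_past; Xj_future)`), pin down all 16 atoms.
#'
#' @param pmf a [joint_pmf4()].
#' @param double_redundancy redundancy function for the lattice; only
#'   `"MMI"` is implemented.
#' @return an object of class `info_atoms`: a 4x4 matrix `atoms[past, future]`
#'   over `{Red, Unq1, Unq2, Syn}` with attribute `tdmi` (bits).
#' @export
phid_atoms <- function(pmf, double_redundancy = "MMI") {
  stopifnot(inherits(pmf, "joint_pmf4"))
  double_redundancy <- match.arg(double_redundancy, "MMI")
  mis <- phid_mis(pmf)
  atoms <- phid_solve_mmi(mis)
  structure(atoms, tdmi = mis$ijj, double_redundancy_method = double_redundancy,
            class = c("info_atoms", "matrix", "array"))
}

#' @export
print.info_atoms <- function(x, ...) {
  cat(sprintf("<info_atoms> TDMI = %.4f bits (double redundancy: %s)\n",
              attr(x, "tdmi"), attr(x, "double_redundancy_method")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.info_atoms <- function(x, ...) {
  grid <- expand.grid(past = ATOMS, future = ATOMS, stringsAsFactors = FALSE)
  tibble::tibble(past = grid$past, future = grid$future,
                 bits = as.numeric(unclass(x)[cbind(grid$past, grid$future)]))
}

#' @exportS3Method generics::glance
glance.info_atoms <- function(x, ...) {
  tibble::tibble(tdmi = attr(x, "tdmi"),
                 atom_sum = sum(x),
                 double_redundancy_method = attr(x, "double_redundancy_method"))
}
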
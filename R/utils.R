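# Internal validators shared across modules.

stop_param <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) stop_param(sprintf("`%s` must be > 0", name))
  invisible(x)
}

assert_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_param(sprintf("`%s` must be a numeric matrix", name))
  }
  if (anyNA(x)) stop_param(sprintf("`%s` contains missing values", name))
  invisible(x)
}

assert_square_symmetric <- function(A, name = "A", tol = 1e-8) {
  assert_matrix(A, name)
  if (nrow(A) != ncol(A)) stop_param(sprintf("`%s` must be square", name))
  if (max(abs(A - t(A))) > tol * max(1, max(abs(A)))) {
    stop_param(sprintf("`%s` must be symmetric", name))
  }
  invisible(A)
}

# Largest singular value of a symmetric matrix = spectral radius.
sigma_max_sym <- function(A) {
  if (all(A == 0)) return(0)
  max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
}

spectral_radius <- function(W) {
  max(Mod(eigen(W, only.values = TRUE)$values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
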
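#' Pairwise causal-emergence capacity of two timeseries
#'
#' Emergence capacity is the synergy that the two past states carry about the
#' joint future state: an upper bound on the unique predictive power of any
#' supervenient macroscopic feature of the pair. Under the MMI lattice it
#' splits into *downward causation* (synergy in the past resolved as
#' redundant or unique information in the future,
#' `Syn->Red + Syn->Unq1 + Syn->Unq2`) and *causal decoupling*
#' (`Syn->Syn`), and `capacity = downward + decoupling`. Under CCS the
#' capacity is computed directly as the synergy of the forward partial
#' information decomposition with composite target; the atom-level split is
#' not defined for CCS and is returned as `NA`.
#'
#' @param x,y numeric vectors (aligned series for two regions).
#' @param lag time lag in timepoints (default 1).
#' @param method redundancy function, `"MMI"` or `"CCS"`.
#' @param estimator `"discrete"` (mean-binarised plug-in) or `"gaussian"`
#'   (closed-form MIs from the lagged covariance of the continuous signals;
#'   MMI only).
#' @return an object of class `emergence_result`: capacity,
#'   downward_causation, causal_decoupling, tdmi, normalized_capacity
#'   (capacity / tdmi, `NA` when tdmi is not positive), all in bits except
#'   the dimensionless normalised value. `NULL` (with a warning) if a series
#'   is constant under the discrete estimator.
#' @export
#' @examples
#' set.seed(1)
#' x <- stats::rnorm(500); y <- stats::rnorm(500)
#' emergence_capacity_pair(x, y)            # independent noise: ~0 bits
emergence_capacity_pair <- function(x, y, lag = 1L,
                                    method = c("MMI", "CCS"),
                                    estimator = c("discrete", "gaussian")) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  if (estimator == "gaussian" && method == "CCS") {
    stop_param("the gaussian estimator supports MMI redundancy only")
  }
  lag <- as.integer(lag)
  if (length(x) != length(y)) stop_param("series must have equal length")
  if (lag < 1L || lag >= length(x)) stop_param("`lag` must satisfy 1 <= lag < length")

  if (estimator == "discrete") {
    pmf <- binarize_and_estimate_pmf(x, y, lag = lag)
    if (is.null(pmf)) return(NULL)
    pm <- pair_from_pmf16(as.numeric(pmf), method)
    total <- pm$tdmi
    capacity <- pm$capacity
    downward <- pm$downward
    decoupling <- pm$decoupling
  } else {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant series: pair skipped", call. = FALSE)
      return(NULL)
    }
    C <- lagged_cov_pair(x, y, lag)
    mis <- phid_mis_gaussian(C)
    atoms <- phid_solve_mmi(mis)
    total <- mis$ijj
    downward <- atoms["Syn", "Red"] + atoms["Syn", "Unq1"] + atoms["Syn", "Unq2"]
    decoupling <- atoms["Syn", "Syn"]
    capacity <- downward + decoupling
  }

  structure(list(
    capacity = as.numeric(capacity),
    downward_causation = as.numeric(downward),
    causal_decoupling = as.numeric(decoupling),
    tdmi = as.numeric(total),
    normalized_capacity = if (total > 0) as.numeric(capacity) / total else NA_real_,
    lag = lag, method = method, estimator = estimator
  ), class = "emergence_result")
}

#' @export
print.emergence_result <- function(x, ...) {
  cat(sprintf(
    "<emergence_result> capacity=%.4f bits (downward=%.4f, decoupling=%.4f), TDMI=%.4f [%s/%s, lag %d]\n",
    x$capacity, x$downward_causation, x$causal_decoupling, x$tdmi,
    x$method, x$estimator, x$lag))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.emergence_result <- function(x, ...) {
  tibble::tibble(
    capacity = x$capacity, downward_causation = x$downward_causation,
    causal_decoupling = x$causal_decoupling, tdmi = x$tdmi,
    normalized_capacity = x$normalized_capacity,
    lag = x$lag, method = x$method, estimator = x$estimator
  )
}

# Shared fast path: all pairwise measures from a 16-state pmf vector.
# `split` additionally reports the MMI-lattice downward-causation /
# causal-decoupling split even when the capacity itself is CCS-based (the
# atom-level split is only defined on the MMI lattice).
pair_from_pmf16 <- function(p, method, split = FALSE) {
  mis <- phid_mis(p)
  total <- mis$ijj
  downward <- NA_real_
  decoupling <- NA_real_
  if (method == "MMI" || split) {
    atoms <- phid_solve_mmi(mis)
    downward <- as.numeric(atoms["Syn", "Red"] + atoms["Syn", "Unq1"] +
                             atoms["Syn", "Unq2"])
    decoupling <- as.numeric(atoms["Syn", "Syn"])
  }
  capacity <- if (method == "MMI") {
    downward + decoupling
  } else {
    total - mis$i1j - mis$i2j + ccs_red16(p)
  }
  if (method != "MMI" && !split) {
    downward <- NA_real_
    decoupling <- NA_real_
  }
  list(capacity = as.numeric(capacity), downward = downward,
       decoupling = decoupling, tdmi = total)
}

#' Global emergence capacity of a regional timeseries
#'
#' Computes the pairwise emergence capacity for every unordered pair of
#' regions (self-pairs excluded) and averages. Pairs skipped because a region
#' is constant are excluded from the mean and counted. With the discrete
#' estimator the MMI-lattice downward-causation / causal-decoupling split is
#' reported for every pair regardless of the capacity method (the atom-level
#' split is only defined on the MMI lattice).
#'
#' @param ts a [regional_timeseries()] or a regions x timepoints matrix.
#' @inheritParams emergence_capacity_pair
#' @return an object of class `global_emergence`: list with
#'   `global_capacity`, `global_normalized` (means over usable pairs),
#'   `capacity_matrix` (symmetric region x region, NA diagonal),
#'   `pairs` (tidy tibble, one row per pair) and `n_skipped`.
#' @export
global_emergence <- function(ts, lag = 1L, method = c("MMI", "CCS"),
                             estimator = c("discrete", "gaussian")) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  if (estimator == "gaussian" && method == "CCS") {
    stop_param("the gaussian estimator supports MMI redundancy only")
  }
  X <- as.matrix(ts)
  n <- nrow(X)
  if (n < 2L) stop_param("need at least 2 regions")
  labels <- rownames(X) %||% paste0("R", seq_len(n))

  lag <- as.integer(lag)
  n_t <- ncol(X)
  if (lag < 1L || lag >= n_t) stop_param("`lag` must satisfy 1 <= lag < length")
  usable <- apply(X, 1L, stats::sd) > 0
  past <- seq_len(n_t - lag)
  fut <- past + lag
  # binarise each region once (strictly above its mean -> 1)
  Xb <- (X > rowMeans(X)) + 0L

  cap <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  n_pairs <- n * (n - 1L) / 2L
  pi1 <- integer(n_pairs); pi2 <- integer(n_pairs)
  pcap <- rep(NA_real_, n_pairs); ptd <- rep(NA_real_, n_pairs)
  pdw <- rep(NA_real_, n_pairs); pdc <- rep(NA_real_, n_pairs)
  k <- 0L
  n_skipped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      k <- k + 1L
      pi1[k] <- i; pi2[k] <- j
      if (!usable[i] || !usable[j]) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (estimator == "discrete") {
        state <- 1L + Xb[i, past] + 2L * Xb[j, past] + 4L * Xb[i, fut] + 8L * Xb[j, fut]
        p <- tabulate(state, nbins = 16L) / (n_t - lag)
        res <- pair_from_pmf16(p, method, split = TRUE)
      } else {
        C <- lagged_cov_pair(X[i, ], X[j, ], lag)
        mis <- phid_mis_gaussian(C)
        atoms <- phid_solve_mmi(mis)
        downward <- atoms["Syn", "Red"] + atoms["Syn", "Unq1"] + atoms["Syn", "Unq2"]
        res <- list(capacity = downward + atoms["Syn", "Syn"],
                    downward = downward, decoupling = atoms["Syn", "Syn"],
                    tdmi = mis$ijj)
      }
      cap[i, j] <- cap[j, i] <- res$capacity
      pcap[k] <- res$capacity; ptd[k] <- res$tdmi
      pdw[k] <- res$downward; pdc[k] <- res$decoupling
    }
  }
  keep <- !is.na(pcap)
  pairs <- tibble::tibble(
    region_1 = labels[pi1[keep]], region_2 = labels[pi2[keep]],
    capacity = pcap[keep], tdmi = ptd[keep],
    normalized_capacity = ifelse(ptd[keep] > 0, pcap[keep] / ptd[keep], NA_real_),
    downward_causation = pdw[keep], causal_decoupling = pdc[keep])
  if (nrow(pairs) == 0L) stop_param("fewer than 2 usable (non-constant) regions")
  if (n_skipped > 0L) {
    message(sprintf("global_emergence: %d constant pair(s) skipped", n_skipped))
  }
  structure(list(
    global_capacity = mean(pairs$capacity),
    global_normalized = mean(pairs$normalized_capacity, na.rm = TRUE),
    capacity_matrix = cap, pairs = pairs, n_skipped = n_skipped,
    lag = lag, method = method, estimator = estimator
  ), class = "global_emergence")
}

#' @export
print.global_emergence <- function(x, ...) {
  cat(sprintf(
    "<global_emergence> mean capacity %.4f bits (normalised %.4f) over %d pairs [%s/%s]\n",
    x$global_capacity, x$global_normalized, nrow(x$pairs), x$method, x$estimator))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.global_emergence <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.global_emergence <- function(x, ...) {
  tibble::tibble(global_capacity = x$global_capacity,
                 global_normalized = x$global_normalized,
                 n_pairs = nrow(x$pairs), n_skipped = x$n_skipped,
                 lag = x$lag, method = x$method, estimator = x$estimator)
}
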
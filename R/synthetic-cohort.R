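#' Specification of a synthetic three-group cohort
#'
#' Describes the stated world the generator emulates: three groups (a healthy
#' "control" group and two patient analogues, "MCS" and "UWS"), each subject
#' with a structural connectome and a linearly-coupled stochastic BOLD-like
#' timeseries (TR = 2 s, 160-300 timepoints). The patient analogues carry a
#' planted lesion: group-wise multiplicative attenuation of connection weights
#' plus group-level edge dropout, so effective coupling is ordered
#' control > MCS > UWS.
#'
#' @param n_regions number of regions (parcellation-agnostic).
#' @param n_subjects_per_group named integer vector (control, MCS, UWS);
#'   defaults mirror the analysed group sizes 18/11/10.
#' @param n_timepoints timepoints per subject (default 200).
#' @param tr repetition time, seconds (default 2).
#' @param group_attenuation named multiplicative weight factor in (0, 1].
#' @param edge_dropout named fraction in [0, 1) of base edges removed at the
#'   group level (a shared "lesion" mask).
#' @param coupling_scale dimensionless VAR(1) gain; the control-group spectral
#'   radius (must be <= 0.95).
#' @param noise_sd innovation standard deviation, signal units.
#' @param base_density edge density of the cohort's base connectome template.
#' @param weight_jitter_sd log-scale SD of per-subject multiplicative weight
#'   jitter around the group template.
#' @param seed integer master seed.
#' @return a list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_regions = 50,
                                  n_subjects_per_group = c(control = 18, MCS = 11, UWS = 10),
                                  n_timepoints = 200,
                                  tr = 2,
                                  group_attenuation = c(control = 1, MCS = 0.75, UWS = 0.5),
                                  edge_dropout = c(control = 0, MCS = 0.1, UWS = 0.2),
                                  coupling_scale = 0.9,
                                  noise_sd = 1,
                                  base_density = 0.6,
                                  weight_jitter_sd = 0.2,
                                  seed = 1L) {
  groups <- c("control", "MCS", "UWS")
  if (!all(groups %in% names(n_subjects_per_group)) ||
      !all(groups %in% names(group_attenuation)) ||
      !all(groups %in% names(edge_dropout))) {
    stop_param("group-indexed arguments need names control, MCS, UWS")
  }
  assert_scalar_number(n_regions, "n_regions", positive = TRUE)
  assert_scalar_number(tr, "tr", positive = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  assert_scalar_number(coupling_scale, "coupling_scale")
  if (coupling_scale < 0 || coupling_scale > 0.95) {
    stop_param("`coupling_scale` must lie in [0, 0.95] so the process is stable")
  }
  if (any(group_attenuation <= 0 | group_attenuation > 1)) {
    stop_param("`group_attenuation` must lie in (0, 1]")
  }
  if (any(edge_dropout < 0 | edge_dropout >= 1)) {
    stop_param("`edge_dropout` must lie in [0, 1)")
  }
  if (n_regions < 2) stop_param("`n_regions` must be >= 2")
  structure(list(
    n_regions = as.integer(n_regions),
    n_subjects_per_group = n_subjects_per_group[groups],
    n_timepoints = as.integer(n_timepoints),
    tr = tr,
    group_attenuation = group_attenuation[groups],
    edge_dropout = edge_dropout[groups],
    coupling_scale = coupling_scale,
    noise_sd = noise_sd,
    base_density = base_density,
    weight_jitter_sd = weight_jitter_sd,
    seed = as.integer(seed)
  ), class = "synthetic_cohort_spec")
}

# Heavy-tailed positive weights mimicking streamline counts.
draw_lognormal_weights <- function(n) exp(stats::rnorm(n))

#' Generate a synthetic structural connectome
#'
#' Draws a symmetric non-negative weighted matrix with zero diagonal:
#' edges are Bernoulli(`density`) on the upper triangle, weights are
#' log-normal(0, 1) (heavy-tailed, streamline-count-like), each retained edge
#' is then independently kept with probability `1 - edge_dropout`, and all
#' weights are scaled by `attenuation`. Expected realised density is
#' `density * (1 - edge_dropout)`.
#'
#' @param n_regions number of regions (>= 2).
#' @param density edge probability in (0, 1].
#' @param seed integer seed.
#' @param attenuation multiplicative weight factor in (0, 1].
#' @param edge_dropout fraction in [0, 1) of edges removed.
#' @return a [structural_connectome()].
#' @export
generate_connectome <- function(n_regions, density, seed = 1L,
                                attenuation = 1, edge_dropout = 0) {
  assert_scalar_number(n_regions, "n_regions", positive = TRUE)
  if (n_regions < 2) stop_param("`n_regions` must be >= 2")
  assert_scalar_number(density, "density")
  if (density <= 0 || density > 1) {
    stop_param("`density` must lie in (0, 1]; an empty graph is not allowed")
  }
  if (edge_dropout < 0 || edge_dropout >= 1) stop_param("`edge_dropout` must lie in [0, 1)")
  if (attenuation <= 0 || attenuation > 1) stop_param("`attenuation` must lie in (0, 1]")
  set.seed(as.integer(seed))
  n <- as.integer(n_regions)
  m <- n * (n - 1L) / 2L
  present <- stats::runif(m) < density
  kept <- present & (stats::runif(m) >= edge_dropout)
  w <- numeric(m)
  w[kept] <- attenuation * draw_lognormal_weights(sum(kept))
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- w
  A <- A + t(A)
  structural_connectome(A)
}

#' Generate a cohort of connectomes and coupled timeseries with known ground truth
#'
#' One heavy-tailed base connectome template is drawn for the cohort; each
#' group receives a shared lesion (edge dropout) and weight attenuation, and
#' each subject a multiplicative log-normal weight jitter around its group
#' template. Sharing the template across subjects is what makes the >50%
#' consensus connectome (see [consensus_connectome()]) non-degenerate.
#' Per subject, a first-order linear stochastic process
#' `x(t+1) = W x(t) + noise` is simulated, with
#' `W = coupling_scale * A_subject / sigma_max(A_base)` (normalised by the
#' *unattenuated* base template so the planted group attenuation changes
#' effective coupling), rescaled if needed so the spectral radius is <= 0.95.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return a list of class `synthetic_cohort` with elements `subjects`
#'   (tibble: subject_id, group), `connectomes` (named list of
#'   [structural_connectome()]), `timeseries` (named list of
#'   [regional_timeseries()]), `couplings` (the per-subject VAR coupling
#'   matrices W, spectral radius <= 0.95 by construction), and `spec`.
#' @export
#' @examples
#' cohort <- generate_var_cohort(synthetic_cohort_spec(
#'   n_regions = 12, n_subjects_per_group = c(control = 2, MCS = 2, UWS = 2),
#'   n_timepoints = 80, seed = 7))
#' cohort$subjects
generate_var_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_cohort_spec")) {
    stop_param("`spec` must be a synthetic_cohort_spec()")
  }
  set.seed(spec$seed)
  n <- spec$n_regions
  m <- n * (n - 1L) / 2L

  # Cohort base template (unattenuated, no lesion).
  support <- stats::runif(m) < spec$base_density
  base_w <- numeric(m)
  base_w[support] <- draw_lognormal_weights(sum(support))
  base_A <- matrix(0, n, n)
  base_A[upper.tri(base_A)] <- base_w
  base_A <- base_A + t(base_A)
  sigma_base <- sigma_max_sym(base_A)
  if (sigma_base == 0) stop_param("base template is empty; increase base_density")

  groups <- names(spec$n_subjects_per_group)
  lesion_mask <- lapply(stats::setNames(groups, groups), function(g) {
    support & (stats::runif(m) >= spec$edge_dropout[[g]])
  })

  subjects <- tibble::tibble(
    group = rep(groups, times = spec$n_subjects_per_group),
    subject_id = sprintf("S%02d_%s", seq_len(sum(spec$n_subjects_per_group)), group)
  )[, c("subject_id", "group")]

  connectomes <- vector("list", nrow(subjects))
  timeseries <- vector("list", nrow(subjects))
  couplings <- vector("list", nrow(subjects))
  burn <- 100L
  for (k in seq_len(nrow(subjects))) {
    g <- subjects$group[k]
    w <- numeric(m)
    keep <- lesion_mask[[g]]
    w[keep] <- base_w[keep] *
      exp(stats::rnorm(sum(keep), sd = spec$weight_jitter_sd)) *
      spec$group_attenuation[[g]]
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- w
    A <- A + t(A)
    sc <- structural_connectome(A)
    connectomes[[k]] <- sc

    W <- spec$coupling_scale * unclass(sc) / sigma_base
    rho <- if (all(W == 0)) 0 else sigma_max_sym(W)
    if (rho > 0.95) W <- W * (0.95 / rho)
    stopifnot(all(is.finite(W)))
    couplings[[k]] <- W

    X <- matrix(0, n, spec$n_timepoints + burn)
    eps <- matrix(stats::rnorm(n * (spec$n_timepoints + burn), sd = spec$noise_sd),
                  n, spec$n_timepoints + burn)
    for (t in 2:ncol(X)) X[, t] <- W %*% X[, t - 1L] + eps[, t]
    timeseries[[k]] <- regional_timeseries(X[, (burn + 1L):ncol(X), drop = FALSE],
                                           tr = spec$tr)
  }
  names(connectomes) <- subjects$subject_id
  names(timeseries) <- subjects$subject_id
  names(couplings) <- subjects$subject_id
  structure(list(subjects = subjects, connectomes = connectomes,
                 timeseries = timeseries, couplings = couplings, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s), %d regions, %d timepoints\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(x$spec$n_subjects_per_group),
                            x$spec$n_subjects_per_group), collapse = ", "),
              x$spec$n_regions, x$spec$n_timepoints))
  invisible(x)
}

#' Write a synthetic cohort to a directory of delimited files
#'
#' Each subject yields `<id>_timeseries.tsv` and `<id>_connectome.tsv` with
#' sidecar headers (TR, group, seed), the on-disk contract consumed by
#' [run_subject_measures()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$subject_id[k]
    g <- cohort$subjects$group[k]
    write_timeseries(cohort$timeseries[[id]],
                     file.path(dir, paste0(id, "_timeseries.tsv")),
                     extra = list(subject = id, group = g, seed = cohort$spec$seed))
    write_connectome(cohort$connectomes[[id]],
                     file.path(dir, paste0(id, "_connectome.tsv")),
                     extra = list(subject = id, group = g, seed = cohort$spec$seed))
  }
  invisible(dir)
}
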
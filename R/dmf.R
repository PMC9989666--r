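#' Dynamic mean-field model parameters
#'
#' One auditable table of all constants of the reduced excitatory-inhibitory
#' dynamic mean-field (DMF) model and the Balloon-Windkessel haemodynamic
#' model, at their standard literature values. Each region comprises coupled
#' excitatory (80%) and inhibitory (20%) populations with sigmoidal rate
#' transfer `r(I) = (aI - b) / (1 - exp(-d (aI - b)))`; regions are coupled
#' through the connectome scaled by the global coupling `G`.
#'
#' @param G global coupling (dimensionless).
#' @param dt integration step, ms (<= 1 ms; default 0.1).
#' @param sigma noise amplitude (nA).
#' @param record_dt recording step for the gating trace, ms.
#' @param ... overrides for any constant listed below.
#' @return a list of class `dmf_params`. Constants: `I0` = 0.382 nA external
#'   current, `w_E` = 1, `w_I` = 0.7 external scaling, `w_plus` = 1.4 local
#'   recurrence, `J_NMDA` = 0.15 nA excitatory coupling, transfer gains
#'   `a_E` = 310 nC^-1, `b_E` = 125 Hz, `d_E` = 0.16 s, `a_I` = 615,
#'   `b_I` = 177, `d_I` = 0.087, time constants `tau_E` = 100 ms,
#'   `tau_I` = 10 ms, `gamma` = 0.641 rate-to-gating factor; target
#'   excitatory current `I_E_target` = b_E/a_E - 0.026 nA (approximately
#'   3 Hz firing); Balloon-Windkessel `kappa` = 0.65 s^-1, `gamma_h` = 0.41
#'   s^-1, `tau_h` = 0.98 s, `alpha` = 0.32, `rho` = 0.34, `V0` = 0.02.
#' @export
dmf_params <- function(G = 1, dt = 0.1, sigma = 0.01, record_dt = 10, ...) {
  if (dt > 1) stop_param("`dt` must be <= 1 ms")
  p <- list(
    G = G, dt = dt, sigma = sigma, record_dt = record_dt,
    I0 = 0.382, w_E = 1, w_I = 0.7, w_plus = 1.4, J_NMDA = 0.15,
    a_E = 310, b_E = 125, d_E = 0.16, a_I = 615, b_I = 177, d_I = 0.087,
    tau_E = 100, tau_I = 10, gamma = 0.641,
    I_E_target = 125 / 310 - 0.026,
    kappa = 0.65, gamma_h = 0.41, tau_h = 0.98, alpha = 0.32,
    rho = 0.34, V0 = 0.02
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop_param("unknown dmf parameter(s): ",
                                  paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (any(vapply(p[c("tau_E", "tau_I", "tau_h")], `<=`, TRUE, e2 = 0))) {
    stop_param("time constants must be > 0")
  }
  structure(p, class = "dmf_params")
}

# Connectome input to the DMF is scaled by its maximum entry to the
# conventional ceiling of 0.2 (the scaling used by the reference DMF
# implementations, recorded in the run config); an all-zero matrix passes
# through unchanged.
prep_dmf_connectome <- function(A, ceiling = 0.2) {
  M <- unclass(as.matrix(A))
  mx <- max(M)
  if (mx > 0) M <- M * (ceiling / mx)
  M
}

#' Tune feedback inhibition weights (FIC)
#'
#' Iteratively adjusts each region's inhibitory feedback weight `J_i` so the
#' long-run regional excitatory current sits at the target
#' `I_E = b_E/a_E - 0.026 nA`, clamping excitatory firing near 3-4 Hz.
#' Tuning runs on the noiseless system (deterministic and fast); each
#' iteration simulates a short probe and applies a damped Newton update using
#' the measured inhibitory gating as the local slope.
#'
#' @param A connectome (matrix or [structural_connectome()]); internally
#'   scaled by its maximum entry.
#' @param G global coupling.
#' @param params a [dmf_params()].
#' @param probe_ms probe simulation length per iteration (ms).
#' @param max_iter,tol iteration cap and convergence tolerance on
#'   `max |I_E - target|` (nA).
#' @return list with `J` (per-region weights), `converged`, `n_iter`,
#'   `rate_mean` (Hz at the final iterate).
#' @export
fic_tune <- function(A, G, params = dmf_params(G = G), probe_ms = 6000,
                     max_iter = 20L, tol = 2e-3) {
  C <- prep_dmf_connectome(A)
  n <- nrow(C)
  target <- params$I_E_target

  # Balanced fixed point: at the target excitatory current the equilibrium
  # gating levels are identical across regions, so J has a closed form; the
  # probe iterations below verify (and, off-equilibrium, refine) it.
  r_E_star <- (params$a_E * target - params$b_E) /
    (1 - exp(-params$d_E * (params$a_E * target - params$b_E)))
  gE <- params$gamma * r_E_star * params$tau_E / 1000
  S_E_star <- gE / (1 + gE)
  h_I <- function(I) {
    x <- params$a_I * I - params$b_I
    ifelse(abs(x) < 1e-9, 1 / params$d_I, x / (1 - exp(-params$d_I * x)))
  }
  S_I_star <- stats::uniroot(function(s) {
    params$tau_I / 1000 * h_I(params$w_I * params$I0 +
                                params$J_NMDA * S_E_star - s) - s
  }, c(0, 1), tol = 1e-12)$root
  J <- pmax((params$w_E * params$I0 + params$w_plus * params$J_NMDA * S_E_star +
               G * params$J_NMDA * S_E_star * rowSums(C) - target) / S_I_star, 0)

  converged <- FALSE
  n_iter <- 0L
  rate <- rep(NA_real_, n)
  for (it in seq_len(max_iter)) {
    n_iter <- it
    sim <- .dmf_integrate_cpp(C, G, J, unclass(params), probe_ms, params$dt,
                              params$record_dt, discard_ms = probe_ms / 3,
                              sigma = 0)
    if (!isTRUE(sim$ok) || !all(is.finite(sim$IE_mean))) {
      return(list(J = J, converged = FALSE, n_iter = n_iter,
                  rate_mean = rep(NA_real_, n), diverged = TRUE))
    }
    err <- as.numeric(sim$IE_mean) - target
    rate <- as.numeric(sim$rate_mean)
    if (max(abs(err)) < tol) {
      converged <- TRUE
      break
    }
    slope <- pmax(as.numeric(sim$SI_mean), 0.05)
    J <- pmax(J + 0.75 * err / slope, 0)
  }
  if (!converged) {
    warning("fic_tune: maximum iterations reached without convergence",
            call. = FALSE)
  }
  list(J = J, converged = converged, n_iter = n_iter, rate_mean = rate,
       diverged = FALSE)
}

#' Simulate whole-brain dynamics with the DMF model
#'
#' Euler-Maruyama integration of the coupled excitatory-inhibitory mean-field
#' equations on a connectome, followed by Balloon-Windkessel haemodynamics
#' producing BOLD volumes at the TR. Reproducible for a fixed seed.
#'
#' @param A connectome; scaled internally by its maximum entry.
#' @param params a [dmf_params()] (with `G` set).
#' @param duration simulated time in seconds.
#' @param tr BOLD repetition time in seconds (default 2).
#' @param J inhibitory feedback weights; if `NULL`, [fic_tune()] is run.
#' @param seed integer seed.
#' @param burn seconds of BOLD discarded for the haemodynamic transient
#'   (default 20).
#' @param band optional band edges (Hz) for post-hoc band-pass of the BOLD
#'   (e.g. `c(0.008, 0.09)`, or `c(0.04, 0.07)` for ignition analyses);
#'   `NULL` leaves the signal unfiltered.
#' @return an object of class `dmf_simulation`: list with `bold` (a
#'   [regional_timeseries()]), `rate_mean` (Hz per region), `gating`
#'   (excitatory gating trace at `record_dt` ms), `J`, `params`, `seed`.
#' @export
simulate_dmf <- function(A, params = dmf_params(), duration = 480, tr = 2,
                         J = NULL, seed = 1L, burn = 20, band = NULL) {
  assert_scalar_number(tr, "tr", positive = TRUE)
  C <- prep_dmf_connectome(A)
  if (is.null(J)) {
    tuned <- fic_tune(A, params$G, params = params)
    J <- tuned$J
  }
  set.seed(as.integer(seed))
  sim <- .dmf_integrate_cpp(C, params$G, J, unclass(params),
                            duration_ms = duration * 1000, dt_ms = params$dt,
                            record_dt_ms = params$record_dt, discard_ms = 0,
                            sigma = params$sigma)
  if (!isTRUE(sim$ok)) {
    stop_param("DMF integration failed: non-finite state during Euler-Maruyama step")
  }
  bold <- .balloon_windkessel_cpp(sim$S_E, dt_s = sim$record_dt_ms / 1000,
                                  tr_s = tr, kappa = params$kappa,
                                  gamma = params$gamma_h, tau = params$tau_h,
                                  alpha = params$alpha, rho = params$rho,
                                  V0 = params$V0)
  drop_vols <- min(ncol(bold) - 1L, ceiling(burn / tr))
  if (drop_vols > 0) bold <- bold[, -seq_len(drop_vols), drop = FALSE]
  labels <- rownames(as.matrix(A)) %||% paste0("R", seq_len(nrow(C)))
  bts <- regional_timeseries(bold, tr = tr, regions = labels)
  if (!is.null(band)) bts <- bandpass_timeseries(bts, band = band)
  structure(list(bold = bts, rate_mean = as.numeric(sim$rate_mean),
                 gating = sim$S_E, J = J, params = params, seed = seed),
            class = "dmf_simulation")
}

#' @export
print.dmf_simulation <- function(x, ...) {
  cat(sprintf("<dmf_simulation> G=%.2f, %d regions, %d BOLD volumes, mean rate %.2f Hz\n",
              x$params$G, nrow(x$bold), ncol(x$bold), mean(x$rate_mean)))
  invisible(x)
}

#' Balloon-Windkessel haemodynamic model
#'
#' Turns a neuronal activity trace (e.g. the excitatory synaptic gating of
#' [simulate_dmf()]) into BOLD volumes at the TR via the standard four-state
#' haemodynamic ODE per region (vasodilatory signal, inflow, venous volume,
#' deoxyhaemoglobin).
#'
#' @param z regions x time matrix of neuronal input.
#' @param dt spacing of the input columns, seconds.
#' @param tr output repetition time, seconds.
#' @param params a [dmf_params()] carrying the haemodynamic constants.
#' @return regions x volumes BOLD matrix.
#' @export
balloon_windkessel <- function(z, dt, tr, params = dmf_params()) {
  assert_scalar_number(tr, "tr", positive = TRUE)
  assert_scalar_number(dt, "dt", positive = TRUE)
  z <- as.matrix(z)
  if (anyNA(z) || any(!is.finite(z))) stop_param("non-finite input")
  .balloon_windkessel_cpp(z, dt_s = dt, tr_s = tr, kappa = params$kappa,
                          gamma = params$gamma_h, tau = params$tau_h,
                          alpha = params$alpha, rho = params$rho, V0 = params$V0)
}

#' Select global coupling by the stability criterion
#'
#' Sweeps `G` over an ascending grid; for each value the model is FIC-tuned
#' and a short stochastic probe is simulated. A value is unstable when tuning
#' diverges, the state becomes non-finite, or the time-averaged regional
#' excitatory rate over the last half of the probe exceeds `ceiling_hz`.
#' Returns the grid value just before the first unstable one.
#'
#' @param A connectome.
#' @param grid ascending grid of candidate `G` values.
#' @param params base [dmf_params()].
#' @param probe duration of the stability probe, seconds (default 60).
#' @param ceiling_hz instability ceiling on the mean excitatory rate.
#' @param seed integer seed (one probe per grid value).
#' @return list of class `g_selection`: `G` (selected), `sweep` (tibble with
#'   `G`, `mean_rate`, `unstable`), `criterion = "stability"`.
#' @export
select_g_stability <- function(A, grid = seq(0.1, 2.5, by = 0.1),
                               params = dmf_params(), probe = 60,
                               ceiling_hz = 10, seed = 1L) {
  if (is.unsorted(grid, strictly = TRUE)) stop_param("`grid` must be ascending")
  C_check <- prep_dmf_connectome(A)
  if (nrow(C_check) < 2) stop_param("need at least 2 regions")
  rows <- vector("list", length(grid))
  first_unstable <- NA_integer_
  for (k in seq_along(grid)) {
    p <- params
    p$G <- grid[k]
    tuned <- suppressWarnings(fic_tune(A, grid[k], params = p))
    if (tuned$diverged || !tuned$converged) {
      # the feedback-inhibition contract cannot be met: the balanced
      # low-activity state has lost stability at this coupling
      rows[[k]] <- tibble::tibble(G = grid[k],
                                  mean_rate = mean(tuned$rate_mean),
                                  unstable = TRUE)
      first_unstable <- k
      break
    }
    set.seed(as.integer(seed) + k)
    probe_sim <- .dmf_integrate_cpp(prep_dmf_connectome(A), grid[k], tuned$J,
                                    unclass(p), duration_ms = probe * 1000,
                                    dt_ms = p$dt, record_dt_ms = p$record_dt,
                                    discard_ms = probe * 500, sigma = p$sigma)
    unstable <- !isTRUE(probe_sim$ok) ||
      mean(as.numeric(probe_sim$rate_mean)) > ceiling_hz
    rows[[k]] <- tibble::tibble(G = grid[k],
                                mean_rate = mean(as.numeric(probe_sim$rate_mean)),
                                unstable = unstable)
    if (unstable) {
      first_unstable <- k
      break
    }
  }
  sweep_tbl <- dplyr::bind_rows(rows)
  if (is.na(first_unstable)) {
    warning("no unstable G on the grid; returning the grid maximum", call. = FALSE)
    g_star <- grid[length(grid)]
  } else if (first_unstable == 1L) {
    stop_param("the first grid value is already unstable; extend the grid downwards")
  } else {
    g_star <- grid[first_unstable - 1L]
  }
  structure(list(G = g_star, sweep = sweep_tbl, criterion = "stability"),
            class = "g_selection")
}

#' Functional connectivity dynamics (FCD) matrix
#'
#' Pearson functional connectivity is computed in sliding windows; the FCD
#' entry `(x, y)` is the Pearson correlation between the vectorised
#' upper-triangular FC of windows `x` and `y`.
#'
#' @param ts a [regional_timeseries()] or matrix (regions x time).
#' @param window window length in TRs (default 30).
#' @param step window increment in TRs (default 3).
#' @return an object of class `fcd_matrix`: windows x windows correlation
#'   matrix with attributes `window` and `step`.
#' @export
fcd <- function(ts, window = 30L, step = 3L) {
  X <- as.matrix(ts)
  n_t <- ncol(X)
  window <- as.integer(window)
  step <- as.integer(step)
  if (n_t < window + step) stop_param("timeseries shorter than window + step")
  starts <- seq.int(1L, n_t - window + 1L, by = step)
  fc_vecs <- vapply(starts, function(s) {
    fc <- suppressWarnings(stats::cor(t(X[, s:(s + window - 1L), drop = FALSE])))
    fc[is.na(fc)] <- 0
    fc[upper.tri(fc)]
  }, numeric(nrow(X) * (nrow(X) - 1L) / 2L))
  M <- suppressWarnings(stats::cor(fc_vecs))
  M[is.na(M)] <- 0
  diag(M) <- 1
  structure(M, window = window, step = step,
            class = c("fcd_matrix", "matrix", "array"))
}

fcd_values <- function(f) f[upper.tri(f)]

#' Fit global coupling to empirical functional connectivity dynamics
#'
#' For each candidate `G`, simulates `n_sims` runs, pools the
#' upper-triangular FCD values, and computes the two-sample
#' Kolmogorov-Smirnov statistic against the pooled empirical FCD values.
#' The selected `G` minimises the mean KS distance.
#'
#' @param A connectome.
#' @param empirical_ts non-empty list of [regional_timeseries()] sharing a TR.
#' @param grid candidate `G` values.
#' @param n_sims simulations per grid value.
#' @param params base [dmf_params()].
#' @param duration simulated seconds per run.
#' @param window,step FCD parameters (TRs).
#' @param pool `"group"` pools empirical windows across subjects before the
#'   KS comparison (default); `"subject"` averages per-subject KS distances.
#' @param seed integer seed.
#' @return list of class `g_selection`: `G`, `sweep` (tibble with `G`,
#'   `ks`), `criterion = "fcd"`.
#' @export
fit_g_to_fcd <- function(A, empirical_ts, grid = seq(0.1, 2.5, by = 0.1),
                         n_sims = 3L, params = dmf_params(), duration = 300,
                         window = 30L, step = 3L,
                         pool = c("group", "subject"), seed = 1L) {
  pool <- match.arg(pool)
  if (length(empirical_ts) == 0L) stop_param("empty empirical timeseries list")
  if (n_sims < 1L) stop_param("`n_sims` must be >= 1")
  trs <- vapply(empirical_ts, ts_tr, numeric(1))
  if (length(unique(trs)) != 1L) stop_param("empirical series must share a TR")
  tr <- trs[[1]]
  emp_vals <- lapply(empirical_ts, function(e) fcd_values(fcd(e, window, step)))
  emp_pooled <- unlist(emp_vals)

  rows <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    p <- params
    p$G <- grid[k]
    tuned <- suppressWarnings(fic_tune(A, grid[k], params = p))
    if (tuned$diverged || !tuned$converged) {
      rows[[k]] <- tibble::tibble(G = grid[k], ks = NA_real_)
      next
    }
    sim_vals <- vector("list", n_sims)
    bad <- FALSE
    for (s in seq_len(n_sims)) {
      sim <- tryCatch(
        simulate_dmf(A, params = p, duration = duration, tr = tr, J = tuned$J,
                     seed = as.integer(seed) + 1000L * k + s),
        error = function(e) NULL)
      if (is.null(sim) || ncol(sim$bold) < window + step) {
        bad <- TRUE
        break
      }
      sim_vals[[s]] <- fcd_values(fcd(sim$bold, window, step))
    }
    if (bad) {
      rows[[k]] <- tibble::tibble(G = grid[k], ks = NA_real_)
      next
    }
    sim_pooled <- unlist(sim_vals)
    ks <- if (pool == "group") {
      ks_stat(emp_pooled, sim_pooled)
    } else {
      mean(vapply(emp_vals, ks_stat, numeric(1), y = sim_pooled))
    }
    rows[[k]] <- tibble::tibble(G = grid[k], ks = ks)
  }
  sweep_tbl <- dplyr::bind_rows(rows)
  if (all(is.na(sweep_tbl$ks))) stop_param("all grid values diverged; no fit possible")
  g_star <- sweep_tbl$G[which.min(sweep_tbl$ks)]
  structure(list(G = g_star, sweep = sweep_tbl, criterion = "fcd"),
            class = "g_selection")
}

# Two-sample Kolmogorov-Smirnov statistic.
ks_stat <- function(x, y) {
  as.numeric(suppressWarnings(stats::ks.test(x, y)$statistic))
}

#' @export
print.g_selection <- function(x, ...) {
  cat(sprintf("<g_selection> G* = %.2f (%s criterion, %d grid values)\n",
              x$G, x$criterion, nrow(x$sweep)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.g_selection <- function(x, ...) x$sweep
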
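#' Detect intrinsic driver events in regional BOLD timeseries
#'
#' The signal is narrowband-filtered (default 0.04-0.07 Hz, the conventional
#' ignition band), z-scored per region, and an event is declared at `(i, t)`
#' when the z-score crosses the threshold from below:
#' `z[t] > threshold` and `z[t-1] <= threshold`. No event can occur at the
#' first timepoint. Simultaneous crossings in several regions count as
#' separate events.
#'
#' @param ts a [regional_timeseries()] with more than 20 timepoints.
#' @param band band edges in Hz (must lie inside (0, Nyquist)).
#' @param z_threshold event threshold in SD units (default 1).
#' @param filter apply the band-pass before z-scoring (default TRUE; set to
#'   FALSE for data already filtered to the ignition band).
#' @return an object of class `event_raster`: a binary regions x timepoints
#'   matrix with attributes `tr`, `band`, `z_threshold`.
#' @export
detect_events <- function(ts, band = c(0.04, 0.07), z_threshold = 1,
                          filter = TRUE) {
  tr <- ts_tr(ts)
  X <- as.matrix(ts)
  if (ncol(X) <= 20L) stop_param("need more than 20 timepoints")
  nyq <- 1 / (2 * tr)
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < nyq)) {
    stop_param(sprintf("band must lie inside (0, %.4g) Hz (Nyquist)", nyq))
  }
  sd_in <- apply(X, 1L, stats::sd)
  if (filter) X <- as.matrix(bandpass_timeseries(X, band = band, tr = tr))
  # a region that was constant on input carries only round-off after
  # filtering; z-scoring that noise would fabricate events
  degenerate <- sd_in == 0 | apply(X, 1L, stats::sd) < 1e-10 * sd_in
  Z <- t(apply(X, 1L, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  Z[degenerate, ] <- 0
  above <- Z > z_threshold
  sigma <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(as.matrix(ts)))
  sigma[, -1L] <- (above[, -1L] & !above[, -ncol(X), drop = FALSE]) + 0L
  structure(sigma, tr = tr, band = band, z_threshold = z_threshold,
            class = c("event_raster", "matrix", "array"))
}

#' Build an event raster from known event times
#'
#' Convenience constructor (mainly for worked examples and tests).
#'
#' @param events list mapping region index/name to a vector of event times
#'   (1-based timepoints), or a binary matrix.
#' @param n_regions,n_timepoints raster dimensions.
#' @param tr repetition time in seconds.
#' @return an `event_raster`.
#' @export
event_raster <- function(events, n_regions, n_timepoints, tr = 2) {
  sigma <- matrix(0L, n_regions, n_timepoints,
                  dimnames = list(paste0("R", seq_len(n_regions)), NULL))
  for (i in seq_along(events)) {
    tt <- events[[i]]
    if (any(tt < 1 | tt > n_timepoints)) stop_param("event time out of range")
    sigma[i, tt] <- 1L
  }
  structure(sigma, tr = tr, band = c(NA_real_, NA_real_), z_threshold = NA_real_,
            class = c("event_raster", "matrix", "array"))
}

#' Intrinsic-driven ignition profile of an event raster
#'
#' For each driver event at `(i, t)`, the participating set is every region
#' with at least one event in the window `[t, t + window - 1]` (the driver's
#' own timepoint anchors the window). The co-event matrix M links every pair
#' of participating regions, so the largest connected component of M equals
#' the participating-set size; this size is the event's intrinsic-driven
#' ignition (IDI). Per-region mean IDI over that region's driver events is
#' returned; regions without events get `NA`.
#'
#' @param raster an `event_raster` (see [detect_events()]).
#' @param window window length in timepoints (default 4, i.e. `[t, t+3]`).
#' @return an object of class `ignition_profile`: tibble with columns
#'   `region`, `n_events`, `mean_idi`.
#' @export
intrinsic_driven_ignition <- function(raster, window = 4L) {
  window <- as.integer(window)
  if (window < 1L) stop_param("`window` must be >= 1")
  sigma <- unclass(raster)
  n <- nrow(sigma); n_t <- ncol(sigma)
  labels <- rownames(sigma) %||% paste0("R", seq_len(n))
  # cumulative event counts per region for O(1) window queries
  cs <- cbind(0L, t(apply(sigma, 1L, cumsum)))
  mean_idi <- rep(NA_real_, n)
  n_events <- integer(n)
  for (i in seq_len(n)) {
    times <- which(sigma[i, ] == 1L)
    n_events[i] <- length(times)
    if (length(times) == 0L) next
    sizes <- vapply(times, function(t0) {
      t1 <- min(n_t, t0 + window - 1L)
      sum(cs[, t1 + 1L] - cs[, t0] >= 1L)
    }, numeric(1))
    mean_idi[i] <- mean(sizes)
  }
  structure(tibble::tibble(region = labels, n_events = n_events,
                           mean_idi = mean_idi),
            window = window, class = c("ignition_profile", class(tibble::tibble())))
}

#' Spatiotemporal hierarchy score
#'
#' The sample standard deviation (denominator `n - 1`) of per-region mean
#' intrinsic-driven ignition, across regions with at least one event. High
#' values mean regions differ widely in their capacity to ignite global
#' activity (a steep spatiotemporal hierarchy); 0 means all regions ignite
#' identically.
#'
#' @param profile an `ignition_profile` from [intrinsic_driven_ignition()].
#' @param include_eventless if `TRUE`, regions without events enter the SD
#'   with a mean IDI of 0 instead of being excluded (default `FALSE`).
#' @return scalar hierarchy score.
#' @export
spatiotemporal_hierarchy <- function(profile, include_eventless = FALSE) {
  v <- profile$mean_idi
  if (include_eventless) v[is.na(v)] <- 0 else v <- v[!is.na(v)]
  if (length(v) < 2L) stop_param("need at least 2 regions with events")
  stats::sd(v)
}
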
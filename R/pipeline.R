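#' Configuration for per-subject measures
#'
#' Defaults follow the analysis conventions of the pipeline: a time-step of
#' one TR for the emergence decomposition (a slower 4-TR timescale can be
#' set), discrete mean-binarised plug-in estimation with the MMI lattice,
#' optional HRF deconvolution (off by default for synthetic or simulated
#' data), and ignition computed after internal 0.04-0.07 Hz re-filtering
#' (inputs are assumed to be denoised/filtered at 0.008-0.09 Hz already, so
#' only the ignition stage re-filters; do not double-filter upstream).
#'
#' @param lag emergence time lag, TRs.
#' @param method redundancy function, `"MMI"` or `"CCS"`.
#' @param estimator `"discrete"` or `"gaussian"`.
#' @param deconvolve run [hrf_deconvolve()] before the emergence stage.
#' @param ignition_band band (Hz) for event detection.
#' @param ignition_window ignition window, TRs.
#' @param z_threshold event threshold, SD units.
#' @param n_perm,fdr_alpha permutation count and FDR alpha for group stats.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(lag = 1L, method = "CCS", estimator = "discrete",
                            deconvolve = FALSE,
                            ignition_band = c(0.04, 0.07),
                            ignition_window = 4L, z_threshold = 1,
                            n_perm = 10000L, fdr_alpha = 0.05) {
  structure(list(lag = lag, method = method, estimator = estimator,
                 deconvolve = deconvolve, ignition_band = ignition_band,
                 ignition_window = ignition_window, z_threshold = z_threshold,
                 n_perm = n_perm, fdr_alpha = fdr_alpha),
            class = "pipeline_config")
}

# Resolve input into per-subject lists. Accepts a synthetic_cohort or a
# directory of *_timeseries.tsv / *_connectome.tsv files with sidecar headers.
resolve_subjects <- function(data) {
  if (inherits(data, "synthetic_cohort")) {
    return(list(subjects = data$subjects, timeseries = data$timeseries,
                connectomes = data$connectomes))
  }
  if (is.character(data) && length(data) == 1L && dir.exists(data)) {
    ts_files <- list.files(data, pattern = "_timeseries\\.tsv$", full.names = TRUE)
    sc_files <- list.files(data, pattern = "_connectome\\.tsv$", full.names = TRUE)
    ids <- unique(c(sub("_timeseries\\.tsv$", "", basename(ts_files)),
                    sub("_connectome\\.tsv$", "", basename(sc_files))))
    timeseries <- list(); connectomes <- list(); groups <- character()
    for (id in ids) {
      tf <- file.path(data, paste0(id, "_timeseries.tsv"))
      cf <- file.path(data, paste0(id, "_connectome.tsv"))
      grp <- NA_character_
      if (file.exists(tf)) {
        ts <- tryCatch(read_timeseries(tf), error = function(e) {
          stop_param(sprintf("failed to read '%s': %s", tf, conditionMessage(e)))
        })
        timeseries[[id]] <- ts
        grp <- attr(ts, "meta")$group %||% grp
      }
      if (file.exists(cf)) {
        sc <- tryCatch(read_connectome(cf), error = function(e) {
          stop_param(sprintf("failed to read '%s': %s", cf, conditionMessage(e)))
        })
        connectomes[[id]] <- sc
        grp <- attr(sc, "meta")$group %||% grp
      }
      groups[id] <- grp
    }
    return(list(subjects = tibble::tibble(subject_id = ids,
                                          group = unname(groups[ids])),
                timeseries = timeseries, connectomes = connectomes))
  }
  stop_param("`data` must be a synthetic_cohort or an existing directory")
}

#' Compute per-subject functional and structural measures
#'
#' For every subject: global emergence capacity (with its normalised value
#' and, under the MMI lattice, the downward-causation / causal-decoupling
#' split), the spatiotemporal hierarchy of intrinsic-driven ignition, and
#' global average and modal controllability of the structural connectome.
#' Subjects missing a modality get `NA` for the measures that need it.
#'
#' @param data a `synthetic_cohort` (see [generate_var_cohort()]) or a
#'   directory of per-subject delimited files (see [write_cohort()]).
#' @param config a [pipeline_config()].
#' @return a tidy tibble, one row per subject x measure: columns
#'   `subject_id`, `group`, `measure`, `value`.
#' @export
run_subject_measures <- function(data, config = pipeline_config()) {
  inp <- resolve_subjects(data)
  rows <- vector("list", nrow(inp$subjects))
  for (k in seq_len(nrow(inp$subjects))) {
    id <- inp$subjects$subject_id[k]
    grp <- inp$subjects$group[k]
    vals <- c(emergence_capacity = NA_real_, normalized_capacity = NA_real_,
              downward_causation = NA_real_, causal_decoupling = NA_real_,
              hierarchy = NA_real_, avg_controllability = NA_real_,
              modal_controllability = NA_real_)
    ts <- inp$timeseries[[id]]
    if (!is.null(ts)) {
      ts_e <- if (isTRUE(config$deconvolve)) hrf_deconvolve(ts) else ts
      ge <- global_emergence(ts_e, lag = config$lag, method = config$method,
                             estimator = config$estimator)
      vals["emergence_capacity"] <- ge$global_capacity
      vals["normalized_capacity"] <- ge$global_normalized
      vals["downward_causation"] <- mean(ge$pairs$downward_causation)
      vals["causal_decoupling"] <- mean(ge$pairs$causal_decoupling)
      raster <- detect_events(ts, band = config$ignition_band,
                              z_threshold = config$z_threshold)
      prof <- intrinsic_driven_ignition(raster, window = config$ignition_window)
      vals["hierarchy"] <- tryCatch(spatiotemporal_hierarchy(prof),
                                    error = function(e) NA_real_)
    }
    sc <- inp$connectomes[[id]]
    if (!is.null(sc)) {
      prof <- controllability_profile(sc)
      gl <- glance(prof)
      vals["avg_controllability"] <- gl$global_average
      vals["modal_controllability"] <- gl$global_modal
    }
    rows[[k]] <- tibble::tibble(subject_id = id, group = grp,
                                measure = names(vals), value = unname(vals))
  }
  dplyr::bind_rows(rows)
}

#' Group-level analysis of a per-subject results table
#'
#' Per measure: one-way ANOVA (or ANCOVA when covariates are supplied)
#' across groups, followed by the three pairwise permutation t-tests with
#' Benjamini-Hochberg FDR correction across that family; plus Spearman
#' correlations between every pair of measures across subjects.
#'
#' @param results tidy tibble from [run_subject_measures()].
#' @param config a [pipeline_config()].
#' @param covariates optional data frame with `subject_id` plus numeric or
#'   factor covariate columns (e.g. scan type, motion); an error lists
#'   subjects missing a configured covariate.
#' @param seed integer seed for the permutation draws.
#' @return an object of class `group_analysis`: list of tibbles `omnibus`,
#'   `posthoc` (with `p_adjusted`), `correlations`.
#' @export
run_group_analysis <- function(results, config = pipeline_config(),
                               covariates = NULL, seed = 1L) {
  measures <- unique(results$measure)
  wide <- tidyr::pivot_wider(results, id_cols = c("subject_id", "group"),
                             names_from = "measure", values_from = "value")
  groups <- unique(stats::na.omit(wide$group))

  if (!is.null(covariates)) {
    missing_sub <- setdiff(wide$subject_id, covariates$subject_id)
    if (length(missing_sub) > 0L) {
      stop_param("covariates missing for subject(s): ",
                 paste(missing_sub, collapse = ", "))
    }
    wide <- dplyr::left_join(wide, covariates, by = "subject_id")
  }
  cov_names <- if (is.null(covariates)) NULL else setdiff(names(covariates), "subject_id")

  omnibus <- list(); posthoc <- list()
  if (length(groups) >= 2L) {
    for (m in measures) {
      sub <- wide[!is.na(wide[[m]]) & !is.na(wide$group), ]
      if (length(unique(sub$group)) < 2L) next
      om <- tryCatch({
        if (is.null(cov_names)) one_way_anova(sub, value = m)
        else ancova(sub, value = m, covariates = cov_names)
      }, error = function(e) NULL)
      if (!is.null(om)) omnibus[[m]] <- dplyr::mutate(om, measure = m, .before = 1)

      glev <- unique(sub$group)
      glev <- c(intersect("control", glev),
                sort(setdiff(glev, "control"), method = "radix"))
      prs <- utils::combn(glev, 2L, simplify = FALSE)
      ph <- purrr::map_dfr(seq_along(prs), function(i) {
        g1 <- prs[[i]][1]; g2 <- prs[[i]][2]
        a <- sub[[m]][sub$group == g1]
        b <- sub[[m]][sub$group == g2]
        res <- permutation_ttest(a, b, n_perm = config$n_perm,
                                 seed = as.integer(seed) + i)
        dplyr::mutate(res, measure = m, group_1 = g1, group_2 = g2, .before = 1)
      })
      ph$p_adjusted <- bh_fdr(ph$p_value)
      posthoc[[m]] <- ph
    }
  } else {
    message("single group: omnibus tests skipped, correlations still computed")
  }

  grid <- utils::combn(measures, 2L, simplify = FALSE)
  correlations <- purrr::map_dfr(grid, function(pr) {
    x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
    res <- tryCatch(spearman_cor(x, y), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::mutate(res, measure_1 = pr[1], measure_2 = pr[2], .before = 1)
  })

  structure(list(omnibus = dplyr::bind_rows(omnibus),
                 posthoc = dplyr::bind_rows(posthoc),
                 correlations = correlations,
                 alpha = config$fdr_alpha),
            class = "group_analysis")
}

#' @export
print.group_analysis <- function(x, ...) {
  cat("<group_analysis>\n")
  if (nrow(x$omnibus)) {
    cat("Omnibus tests:\n"); print(as.data.frame(x$omnibus), digits = 3)
  }
  if (nrow(x$posthoc)) {
    sig <- sum(x$posthoc$p_adjusted < x$alpha)
    cat(sprintf("Post-hoc permutation tests: %d/%d significant at FDR %.2f\n",
                sig, nrow(x$posthoc), x$alpha))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_analysis <- function(x, ...) x$posthoc

#' @exportS3Method generics::glance
glance.group_analysis <- function(x, ...) {
  tibble::tibble(n_measures = length(unique(x$omnibus$measure)),
                 n_significant_posthoc = sum(x$posthoc$p_adjusted < x$alpha),
                 alpha = x$alpha)
}

#' Model-based replication: simulate groups from consensus connectomes
#'
#' Builds a consensus connectome per group, selects the global coupling `G`
#' per group (stability criterion by default, FCD fit optional), simulates
#' `n_sims` runs per group, computes global emergence capacity and ignition
#' hierarchy on each simulated BOLD run, and compares groups. Desk-scale
#' defaults (tens of regions, minutes of BOLD, 10 simulations per group)
#' stand in for the full-scale experiment.
#'
#' @param data a `synthetic_cohort`, or a named list (group -> list of
#'   [structural_connectome()]).
#' @param config a [pipeline_config()].
#' @param n_sims simulations per group (>= 1).
#' @param duration simulated seconds per run.
#' @param g_criterion `"stability"` or `"fcd"` (the latter needs
#'   `empirical_ts`, a named list group -> list of timeseries).
#' @param grid candidate `G` grid.
#' @param params base [dmf_params()].
#' @param tr simulated TR, seconds.
#' @param empirical_ts empirical timeseries per group for `g_criterion="fcd"`.
#' @param seed integer seed.
#' @return an object of class `model_replication`: list with `consensus`
#'   (per group), `g` (per-group selection), `measures` (tibble: group, sim,
#'   measure, value) and `stats` (a `group_analysis`).
#' @export
run_model_replication <- function(data, config = pipeline_config(),
                                  n_sims = 10L, duration = 300,
                                  g_criterion = c("stability", "fcd"),
                                  grid = seq(0.1, 2.5, by = 0.1),
                                  params = dmf_params(), tr = 2,
                                  empirical_ts = NULL, seed = 1L) {
  g_criterion <- match.arg(g_criterion)
  if (n_sims < 1L) stop_param("`n_sims` must be >= 1")
  groups_conn <- if (inherits(data, "synthetic_cohort")) {
    split(data$connectomes, data$subjects$group)
  } else if (is.list(data) && !is.null(names(data))) {
    data
  } else {
    stop_param("`data` must be a synthetic_cohort or a named list of connectome lists")
  }

  consensus <- lapply(groups_conn, consensus_connectome)
  for (g in names(consensus)) {
    if (all(consensus[[g]] == 0)) stop_param(sprintf("consensus matrix empty for group '%s'", g))
  }

  g_sel <- list()
  for (g in names(consensus)) {
    g_sel[[g]] <- if (g_criterion == "stability") {
      select_g_stability(consensus[[g]], grid = grid, params = params,
                         seed = as.integer(seed))
    } else {
      if (is.null(empirical_ts) || is.null(empirical_ts[[g]])) {
        stop_param("g_criterion='fcd' needs `empirical_ts` for every group")
      }
      fit_g_to_fcd(consensus[[g]], empirical_ts[[g]], grid = grid,
                   params = params, duration = duration, seed = as.integer(seed))
    }
  }

  rows <- list()
  for (g in names(consensus)) {
    p <- params
    p$G <- g_sel[[g]]$G
    tuned <- fic_tune(consensus[[g]], p$G, params = p)
    for (s in seq_len(n_sims)) {
      sim <- simulate_dmf(consensus[[g]], params = p, duration = duration,
                          tr = tr, J = tuned$J,
                          seed = as.integer(seed) + 7919L * match(g, names(consensus)) + s)
      bold <- bandpass_timeseries(sim$bold, band = c(0.008, 0.09))
      ge <- global_emergence(bold, lag = config$lag, method = config$method,
                             estimator = config$estimator)
      raster <- detect_events(sim$bold, band = config$ignition_band,
                              z_threshold = config$z_threshold)
      hier <- tryCatch(
        spatiotemporal_hierarchy(
          intrinsic_driven_ignition(raster, window = config$ignition_window)),
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, sim = s,
        measure = c("emergence_capacity", "hierarchy"),
        value = c(ge$global_capacity, hier))
    }
  }
  measures <- dplyr::bind_rows(rows)
  stats_in <- dplyr::mutate(measures, subject_id = sprintf("%s_sim%02d", group, sim))
  gstats <- run_group_analysis(stats_in, config = config, seed = seed)
  structure(list(consensus = consensus, g = g_sel, measures = measures,
                 stats = gstats),
            class = "model_replication")
}

#' @export
print.model_replication <- function(x, ...) {
  cat("<model_replication>\n")
  for (g in names(x$g)) cat(sprintf("  %s: G* = %.2f\n", g, x$g[[g]]$G))
  summ <- dplyr::summarise(dplyr::group_by(x$measures, .data$group, .data$measure),
                           mean = mean(.data$value, na.rm = TRUE), .groups = "drop")
  print(as.data.frame(summ), digits = 3)
  invisible(x)
}

#' Run manifest for reproducible pipeline runs
#'
#' Snapshot of configuration, seeds, package version and file hashes; two
#' runs from the same manifest reproduce identical outputs for deterministic
#' stages.
#'
#' @param config a [pipeline_config()] (or any list).
#' @param seed master seed.
#' @param files character vector of produced files to hash (md5).
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, files = character()) {
  hashes <- if (length(files)) tools::md5sum(files) else character()
  structure(list(config = config, seed = seed,
                 package_version = as.character(utils::packageVersion("emergentdyn")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 files = tibble::tibble(path = names(hashes),
                                        md5 = unname(hashes))),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> emergentdyn %s, seed %s, %d file(s)\n",
              x$package_version, x$seed, nrow(x$files)))
  invisible(x)
}
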
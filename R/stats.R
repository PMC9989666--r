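# Group-level inference: ANOVA/ANCOVA across three groups, permutation
# t-tests with BH-FDR post-hocs, effect sizes, summary-statistic t-tests and
# Spearman correlations.

test_result <- function(...) {
  structure(tibble::tibble(...), class = c("test_result", class(tibble::tibble())))
}

#' One-way analysis of variance across groups
#'
#' Tests the effect of group (e.g. diagnostic condition with three levels)
#' on a per-subject scalar measure.
#'
#' @param data data frame with the outcome and group columns.
#' @param value,group column names (strings) of the outcome and the group
#'   label.
#' @return a `test_result` tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (anyNA(y) || anyNA(g)) {
    keep <- !is.na(y) & !is.na(g)
    y <- y[keep]; g <- droplevels(g[keep])
  }
  if (any(table(g) < 2L)) stop_param("every group needs at least 2 subjects")
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  test_result(test = "anova", statistic = an$`F value`[1],
              df1 = an$Df[1], df2 = an$Df[2], p_value = an$`Pr(>F)`[1])
}

#' Analysis of covariance: group effect after covariate adjustment
#'
#' Linear model `outcome ~ covariates + group`; the reported F compares the
#' covariate-only model against the full model (the group effect adjusted
#' for the covariates, e.g. DWI sequence type or motion). Constant
#' covariates are dropped with a message; a rank-deficient design errors
#' naming the offending column.
#'
#' @inheritParams one_way_anova
#' @param covariates character vector of covariate column names.
#' @return a `test_result` tibble (F test for the group factor).
#' @export
ancova <- function(data, value = "value", group = "group", covariates) {
  y <- data[[value]]
  g <- factor(data[[group]])
  covs <- data[, covariates, drop = FALSE]
  covs <- as.data.frame(lapply(covs, function(col) {
    if (is.character(col) || is.logical(col)) col <- factor(col)
    if (is.factor(col)) as.numeric(col) else as.numeric(col)
  }))
  constant <- vapply(covs, function(col) stats::var(col) == 0, TRUE)
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(names(covs)[constant], collapse = ", "))
    covs <- covs[, !constant, drop = FALSE]
  }
  if (ncol(covs) == 0L) return(one_way_anova(data, value, group))
  X <- stats::model.matrix(~ ., data = covs)
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop_param("rank-deficient design; offending column(s): ",
               paste(bad, collapse = ", "))
  }
  reduced <- stats::lm(y ~ ., data = covs)
  full <- stats::lm(y ~ . + g, data = cbind(covs, g = g))
  cmp <- stats::anova(reduced, full)
  test_result(test = "ancova", statistic = cmp$F[2],
              df1 = cmp$Df[2], df2 = cmp$Res.Df[2], p_value = cmp$`Pr(>F)`[2])
}

#' Two-sided permutation t-test with Cohen's d
#'
#' Observed pooled-variance two-sample t; the p-value is the proportion of
#' group-label permutations whose |t| meets or exceeds the observed |t|,
#' with add-one smoothing `(b + 1) / (n_perm + 1)` so p is never exactly 0.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed for the permutation draw.
#' @return a `test_result` tibble: `statistic` (t), `df`, `p_value`,
#'   `effect_size` (Cohen's d, a - b).
#' @export
permutation_ttest <- function(a, b, n_perm = 10000L, seed = 1L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop_param("both samples need >= 2 values")
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  t_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    if (sp2 == 0) return(NA_real_)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }
  t_obs <- t_of(seq_len(n1))
  if (is.na(t_obs)) stop_param("zero pooled variance")
  set.seed(as.integer(seed))
  t_perm <- vapply(seq_len(n_perm), function(i) t_of(sample.int(n, n1)), numeric(1))
  p <- (sum(abs(t_perm) >= abs(t_obs), na.rm = TRUE) + 1) / (n_perm + 1)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / (n - 2))
  d <- (mean(a) - mean(b)) / sp
  test_result(test = "permutation_t", statistic = t_obs, df = n - 2,
              p_value = p, effect_size = d, n_perm = n_perm)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) stop_param("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_param("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pooled-variance t-test from summary statistics, with Hedges' g
#'
#' Student t with `df = n1 + n2 - 2` from group means, SDs and sizes;
#' Hedges' g is the bias-corrected standardised mean difference with
#' correction factor `J = 1 - 3 / (4 df - 1)`.
#'
#' @param m1,sd1,n1 mean, SD and size of the first group.
#' @param m2,sd2,n2 mean, SD and size of the second group.
#' @return a `test_result` tibble: `statistic` (t), `df`, `p_value`
#'   (two-sided), `effect_size` (Hedges' g, group 1 - group 2).
#' @export
summary_stats_ttest <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop_param("group sizes must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_param("SDs must be > 0")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  d <- (m1 - m2) / sp
  g <- d * (1 - 3 / (4 * df - 1))
  test_result(test = "summary_t", statistic = t, df = df,
              p_value = 2 * stats::pt(-abs(t), df), effect_size = g)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected rank correlation; p via
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df (two-sided).
#'
#' @param x,y numeric vectors of equal length (>= 3), non-constant.
#' @return a `test_result` tibble: `estimate` (rho), `statistic` (t), `df`,
#'   `p_value`.
#' @export
spearman_cor <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_param("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_param("constant vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
    tstat <- sign(rho) * Inf
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  test_result(test = "spearman", estimate = rho, statistic = tstat,
              df = n - 2, p_value = p)
}

#' Cohen's d from two samples
#'
#' Pooled-SD standardised mean difference (a - b).
#' @param a,b numeric samples.
#' @return scalar d.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}
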
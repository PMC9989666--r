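#' Regional timeseries container
#'
#' A regions x timepoints numeric matrix with a repetition time (TR, seconds)
#' and region labels. This is the microscale process on which all functional
#' measures (emergence capacity, ignition) operate.
#'
#' @param x numeric matrix, regions in rows, timepoints in columns.
#' @param tr repetition time in seconds.
#' @param regions optional character vector of region labels.
#' @return an object of class `regional_timeseries` (a matrix with attributes
#'   `tr` and region rownames).
#' @export
regional_timeseries <- function(x, tr, regions = NULL) {
  assert_matrix(x, "x")
  assert_scalar_number(tr, "tr", positive = TRUE)
  if (is.null(regions)) {
    regions <- rownames(x) %||% paste0("R", seq_len(nrow(x)))
  }
  if (length(regions) != nrow(x)) stop_param("`regions` must match nrow(x)")
  rownames(x) <- regions
  structure(x, tr = tr, class = c("regional_timeseries", "matrix", "array"))
}

#' @export
print.regional_timeseries <- function(x, ...) {
  cat(sprintf("<regional_timeseries> %d regions x %d timepoints, TR = %g s\n",
              nrow(x), ncol(x), attr(x, "tr")))
  invisible(x)
}

ts_tr <- function(ts) {
  tr <- attr(ts, "tr")
  if (is.null(tr)) stop_param("timeseries has no TR attribute; use regional_timeseries()")
  tr
}

#' Structural connectome container
#'
#' A symmetric non-negative weighted adjacency matrix (streamline-count-like)
#' with zero diagonal and region labels.
#'
#' @param A symmetric non-negative numeric matrix; the diagonal is zeroed.
#' @param labels optional region labels.
#' @param normalized logical; `TRUE` once the matrix has been divided by its
#'   largest singular value + 1 (see [normalize_connectome()]).
#' @return an object of class `structural_connectome`.
#' @export
structural_connectome <- function(A, labels = NULL, normalized = FALSE) {
  assert_square_symmetric(A, "A")
  if (any(A < 0)) stop_param("connectome weights must be non-negative")
  diag(A) <- 0
  A <- (A + t(A)) / 2   # enforce exact symmetry against round-off
  if (is.null(labels)) labels <- rownames(A) %||% paste0("R", seq_len(nrow(A)))
  if (length(labels) != nrow(A)) stop_param("`labels` must match nrow(A)")
  dimnames(A) <- list(labels, labels)
  structure(A, normalized = isTRUE(normalized),
            class = c("structural_connectome", "matrix", "array"))
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("<structural_connectome> %d regions, density %.3f%s\n",
              nrow(x), mean(x[upper.tri(x)] > 0),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  invisible(x)
}

# ---- delimited I/O with '#' sidecar header lines -----------------------------

write_header_matrix <- function(x, path, header) {
  lines <- sprintf("# %s: %s", names(header), vapply(header, as.character, ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

read_header_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  keys <- sub("^#\\s*([^:]+):.*$", "\\1", hdr)
  vals <- sub("^#\\s*[^:]+:\\s*", "", hdr)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nc <- unique(lengths(fields))
  if (length(nc) != 1L) stop_param(sprintf("ragged rows in matrix file '%s'", path))
  mat <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(mat)) stop_param(sprintf("non-numeric entries in matrix file '%s'", path))
  list(matrix = mat, header = stats::setNames(as.list(vals), keys))
}

#' Write / read a regional timeseries as delimited text
#'
#' The matrix is written tab-separated, preceded by `# key: value` header
#' lines carrying the TR (seconds), region labels and any extra metadata, so
#' simulated and empirical data share one on-disk format.
#'
#' @param ts a [regional_timeseries()].
#' @param path file path.
#' @param extra named list of additional header fields (e.g. seed, group).
#' @return `write_timeseries()` returns `path` invisibly; `read_timeseries()`
#'   returns a [regional_timeseries()] with any extra header fields attached
#'   as attribute `meta`.
#' @export
write_timeseries <- function(ts, path, extra = list()) {
  header <- c(list(type = "regional_timeseries", tr = ts_tr(ts),
                   regions = paste(rownames(ts), collapse = ",")), extra)
  write_header_matrix(unclass(ts), path, header)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  parsed <- read_header_matrix(path)
  h <- parsed$header
  tr <- as.numeric(h$tr %||% NA)
  if (!is.finite(tr)) stop_param(sprintf("file '%s' has no valid 'tr' header", path))
  regions <- if (!is.null(h$regions)) strsplit(h$regions, ",", fixed = TRUE)[[1]] else NULL
  out <- regional_timeseries(parsed$matrix, tr = tr, regions = regions)
  attr(out, "meta") <- h[setdiff(names(h), c("type", "tr", "regions"))]
  out
}

#' Write / read a structural connectome as delimited text
#'
#' @param sc a [structural_connectome()].
#' @inheritParams write_timeseries
#' @return `write_connectome()` returns `path` invisibly; `read_connectome()`
#'   a [structural_connectome()].
#' @export
write_connectome <- function(sc, path, extra = list()) {
  header <- c(list(type = "structural_connectome",
                   regions = paste(rownames(sc), collapse = ","),
                   normalized = isTRUE(attr(sc, "normalized"))), extra)
  write_header_matrix(unclass(sc), path, header)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  parsed <- read_header_matrix(path)
  h <- parsed$header
  regions <- if (!is.null(h$regions)) strsplit(h$regions, ",", fixed = TRUE)[[1]] else NULL
  if (!is.null(regions) && length(regions) != nrow(parsed$matrix)) {
    stop_param(sprintf("file '%s': %d labels for %d rows", path,
                       length(regions), nrow(parsed$matrix)))
  }
  out <- structural_connectome(parsed$matrix, labels = regions,
                               normalized = isTRUE(as.logical(h$normalized %||% FALSE)))
  attr(out, "meta") <- h[setdiff(names(h), c("type", "regions", "normalized"))]
  out
}
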
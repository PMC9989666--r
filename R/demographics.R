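#' Load the packaged patient demographics table
#'
#' Returns the demographic table of the 22 disorders-of-consciousness (DOC)
#' patients shipped with the package: sex, age (years), aetiology, diagnosis
#' (UWS = unresponsive wakefulness syndrome, MCS = minimally conscious state),
#' CRS-R behavioural score, and the diffusion acquisition available for each
#' patient ("12 dir", "63 dir", or "Not available" for the one patient with
#' functional data only). Ten patients are UWS and twelve MCS; filtering out
#' the "Not available" scan row yields the 21 patients with complete data.
#'
#' @return a tibble with columns `subject_id`, `sex`, `age`, `aetiology`,
#'   `diagnosis`, `crsr`, `scan` (22 rows).
#' @export
#' @examples
#' demo <- load_demographics_fixture()
#' table(demo$diagnosis)
load_demographics_fixture <- function() {
  path <- system.file("extdata", "doc_demographics.tsv", package = "emergentdyn")
  if (!nzchar(path) || !file.exists(path)) {
    stop_param("demographics fixture not found; package installation is corrupted")
  }
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  expected <- c("Sex", "Age", "Aetiology", "Diagnosis", "CRS-R Score", "Scan")
  if (!identical(names(raw), expected)) {
    stop_param("demographics fixture is corrupted: unexpected columns")
  }
  out <- tibble::tibble(
    subject_id = sprintf("DOC%02d", seq_len(nrow(raw))),
    sex = raw$Sex,
    age = as.integer(raw$Age),
    aetiology = raw$Aetiology,
    diagnosis = raw$Diagnosis,
    crsr = as.integer(raw$`CRS-R Score`),
    scan = raw$Scan
  )
  if (nrow(out) != 22L ||
      !all(out$diagnosis %in% c("UWS", "MCS")) ||
      !all(out$sex %in% c("M", "F")) ||
      anyNA(out$age) || any(out$age <= 0) ||
      anyNA(out$crsr) || any(out$crsr < 0 | out$crsr > 23)) {
    stop_param("demographics fixture is corrupted: integrity checks failed")
  }
  out
}
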
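# Detection-report readers (DIA-NN main-report dialect; Skyline dialect maps
# column names only). Records are returned as a tibble, one row per detected
# precursor, filtered to the configured q-value threshold.

DIANN_COLUMNS <- c(
  modified_sequence = "Modified.Sequence",
  charge = "Precursor.Charge",
  apex_rt = "RT",
  rt_start = "RT.Start",
  rt_stop = "RT.Stop",
  q_value = "Q.Value"
)
DIANN_OPTIONAL <- c(site_confidence = "PTM.Site.Confidence",
                    precursor_mz = "Precursor.Mz",
                    protein_ids = "Protein.Ids")

SKYLINE_COLUMNS <- c(
  modified_sequence = "Peptide.Modified.Sequence",
  charge = "Precursor.Charge",
  apex_rt = "Best.Retention.Time",
  rt_start = "Min.Start.Time",
  rt_stop = "Max.End.Time",
  q_value = "Detection.Q.Value"
)
SKYLINE_OPTIONAL <- c(site_confidence = "Site.Confidence",
                      precursor_mz = "Precursor.Mz",
                      protein_ids = "Protein.Name")

#' Read a peptide detection report
#'
#' Reads a tab-separated detection report in the DIA-NN main-report dialect
#' (default) or a Skyline-style dialect (same semantics, different column
#' names). Records are filtered to `q_value <= q_threshold`; in phospho mode
#' an additional site-confidence filter is applied.
#'
#' @param path Path to a tab-separated report.
#' @param dialect `"diann"` or `"skyline"`.
#' @param q_threshold Precursor q-value threshold (default 0.01, a 1% FDR
#'   report).
#' @param phospho If `TRUE`, also require
#'   `site_confidence >= site_confidence_threshold`.
#' @param site_confidence_threshold Minimum PTM site confidence in phospho
#'   mode (default 0.75).
#' @return Tibble with columns `modified_sequence`, `charge`, `q_value`,
#'   `apex_rt`, `rt_start`, `rt_stop`, `site_confidence`, `precursor_mz`
#'   (computed from the peptidoform when the report does not carry it) and
#'   `protein_ids`.
#' @export
read_detection_report <- function(path, dialect = c("diann", "skyline"),
                                  q_threshold = 0.01, phospho = FALSE,
                                  site_confidence_threshold = 0.75) {
  if (length(dialect) == 1L && !dialect %in% c("diann", "skyline")) {
    stop("configuration error: unknown report dialect '", dialect, "'")
  }
  dialect <- match.arg(dialect)
  cols <- if (dialect == "diann") DIANN_COLUMNS else SKYLINE_COLUMNS
  optional <- if (dialect == "diann") DIANN_OPTIONAL else SKYLINE_OPTIONAL
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0L) {
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- tibble::tibble(
    modified_sequence = as.character(raw[[cols["modified_sequence"]]]),
    charge = as.integer(raw[[cols["charge"]]]),
    q_value = as.numeric(raw[[cols["q_value"]]]),
    apex_rt = as.numeric(raw[[cols["apex_rt"]]]),
    rt_start = as.numeric(raw[[cols["rt_start"]]]),
    rt_stop = as.numeric(raw[[cols["rt_stop"]]])
  )
  out$site_confidence <- if (optional["site_confidence"] %in% names(raw)) {
    as.numeric(raw[[optional["site_confidence"]]])
  } else NA_real_
  out$precursor_mz <- if (optional["precursor_mz"] %in% names(raw)) {
    as.numeric(raw[[optional["precursor_mz"]]])
  } else {
    purrr::map2_dbl(out$modified_sequence, out$charge,
                    ~ precursor_mz(parse_modified_sequence(.x), .y))
  }
  out$protein_ids <- if (optional["protein_ids"] %in% names(raw)) {
    as.character(raw[[optional["protein_ids"]]])
  } else NA_character_
  if (any(out$q_value < 0 | out$q_value > 1, na.rm = TRUE)) {
    stop("format error: q-values outside [0, 1]")
  }
  if (any(out$apex_rt < out$rt_start | out$apex_rt > out$rt_stop, na.rm = TRUE)) {
    stop("format error: apex RT outside its peak boundaries")
  }
  out <- dplyr::filter(out, .data$q_value <= q_threshold)
  if (phospho) {
    out <- dplyr::filter(out, !is.na(.data$site_confidence),
                         .data$site_confidence >= site_confidence_threshold)
  }
  out
}

#' Write a detection report in the DIA-NN dialect
#'
#' Inverse of [read_detection_report()]; used by the simulator to emit
#' reports downstream stages can consume.
#'
#' @param report Tibble as returned by [read_detection_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(report, path) {
  out <- tibble::tibble(
    "Modified.Sequence" = report$modified_sequence,
    "Precursor.Charge" = report$charge,
    "Precursor.Mz" = report$precursor_mz,
    "RT" = report$apex_rt,
    "RT.Start" = report$rt_start,
    "RT.Stop" = report$rt_stop,
    "Q.Value" = report$q_value
  )
  if (!all(is.na(report$site_confidence))) {
    out[["PTM.Site.Confidence"]] <- report$site_confidence
  }
  if (!is.null(report$protein_ids) && !all(is.na(report$protein_ids))) {
    out[["Protein.Ids"]] <- report$protein_ids
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
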
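# Spectral-library table output: row-oriented TSV, one row per
# (precursor, fragment), in a schema DIA-NN style search engines consume.

LIBRARY_COLUMNS <- c(
  "ModifiedPeptide", "PrecursorCharge", "PrecursorMz",
  "NormalizedRetentionTime", "FragmentType", "FragmentSeriesNumber",
  "FragmentCharge", "FragmentLossType", "FragmentMz", "RelativeIntensity",
  "ProteinId"
)

#' Write a spectral library to TSV
#'
#' One row per (precursor, fragment). Relative intensities within each
#' precursor must have maximum 1; precursors with zero fragments are a
#' validation error.
#'
#' @param library Tibble as produced by [build_library()]: columns
#'   `modified_sequence`, `charge`, `precursor_mz`, `rt`, `series`,
#'   `ordinal`, `fragment_charge`, `loss`, `fragment_mz`,
#'   `relative_intensity`, `protein_ids`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(library, path) {
  library <- tibble::as_tibble(library)
  if (nrow(library) == 0L) stop("validation error: empty library")
  by_prec <- dplyr::summarise(
    dplyr::group_by(library, .data$modified_sequence, .data$charge),
    n = dplyr::n(), max_rel = max(.data$relative_intensity), .groups = "drop"
  )
  if (any(by_prec$n == 0L)) stop("validation error: precursor with 0 fragments")
  if (any(abs(by_prec$max_rel - 1) > 1e-9)) {
    stop("validation error: per-precursor max relative intensity must be 1")
  }
  out <- tibble::tibble(
    ModifiedPeptide = library$modified_sequence,
    PrecursorCharge = library$charge,
    PrecursorMz = library$precursor_mz,
    NormalizedRetentionTime = library$rt,
    FragmentType = library$series,
    FragmentSeriesNumber = library$ordinal,
    FragmentCharge = library$fragment_charge,
    FragmentLossType = library$loss,
    FragmentMz = library$fragment_mz,
    RelativeIntensity = library$relative_intensity,
    ProteinId = library$protein_ids
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a spectral library TSV
#'
#' Inverse of [write_library_tsv()].
#'
#' @param path Path to a library TSV.
#' @return Tibble in the internal library schema.
#' @export
read_library_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(LIBRARY_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("format error: missing library column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tibble::tibble(
    modified_sequence = raw$ModifiedPeptide,
    charge = as.integer(raw$PrecursorCharge),
    precursor_mz = raw$PrecursorMz,
    rt = raw$NormalizedRetentionTime,
    series = raw$FragmentType,
    ordinal = as.integer(raw$FragmentSeriesNumber),
    fragment_charge = as.integer(raw$FragmentCharge),
    loss = raw$FragmentLossType,
    fragment_mz = raw$FragmentMz,
    relative_intensity = raw$RelativeIntensity,
    protein_ids = as.character(raw$ProteinId)
  )
}

#' Read a FASTA protein database
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of protein sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("data error: ", conditionMessage(e)))
  if (length(aa) == 0L) stop("data error: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(aa))
  stats::setNames(as.character(aa), ids)
}

#' Write a FASTA protein database
#'
#' @param sequences Named character vector of protein sequences.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}
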
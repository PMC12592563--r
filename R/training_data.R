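# Turn annotated, labeled spectra into masked intensity training examples
# and normalized RT training pairs.

#' Build one masked intensity training example
#'
#' Shared cells are masked; unmatched in-range cells keep intensity 0;
#' out-of-range cells stay masked. Intensities are normalized by the highest
#' matched peak. The spectrum is rejected when the highest matched peak is
#' itself shared, when the shared fraction among matched peaks exceeds
#' `reject_shared_fraction`, or when no fragment matched at all.
#'
#' @param annotated An `annotated_spectrum` from [match_peaks()].
#' @param labels Optional tibble (rows of the [label_shared_peaks()] output
#'   for this precursor) marking shared cells; if `NULL` only the
#'   ambiguous-match masking already present in `annotated` applies.
#' @param reject_shared_fraction Rejection threshold on the fraction of
#'   matched peaks that are shared (default 0.5). Out-of-range cells count
#'   in neither numerator nor denominator.
#' @param nce,instrument Metadata carried into the example.
#' @param reject Apply the rejection rules (default). Setting `FALSE`
#'   keeps every spectrum with at least one matched peak regardless of its
#'   shared-peak content; used by ablation experiments that must hold the
#'   training set fixed while toggling the mask.
#' @return A list of class `intensity_example` (`modified_sequence`,
#'   `charge`, `nce`, `instrument`, `target`, `mask`), or a
#'   `rejected_example` carrying the rejection `reason`.
#' @export
build_intensity_example <- function(annotated, labels = NULL,
                                    reject_shared_fraction = 0.5,
                                    nce = 30, instrument = "Lumos",
                                    reject = TRUE) {
  stopifnot(inherits(annotated, "annotated_spectrum"))
  mask <- annotated$mask
  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    sel <- labels$shared
    if (any(sel)) {
      ij <- cbind(labels$row[sel], match(labels$col[sel], annotated$layout))
      keep <- mask[ij] != "out_of_range"
      mask[ij[keep, , drop = FALSE]] <- "shared"
    }
  }
  matched <- !is.na(annotated$matched_peak) & mask != "out_of_range"
  n_matched <- sum(matched)
  rejected <- function(reason) {
    structure(list(reason = reason), class = "rejected_example")
  }
  if (n_matched == 0L) return(rejected("no matched peaks"))
  top_cell <- which(matched)[which.max(annotated$intensity[matched])]
  if (reject) {
    if (mask[top_cell] == "shared") {
      return(rejected("highest matched peak shared"))
    }
    shared_frac <- sum(mask[matched] == "shared") / n_matched
    if (shared_frac > reject_shared_fraction) {
      return(rejected(sprintf("shared fraction %.2f > %.2f",
                              shared_frac, reject_shared_fraction)))
    }
  }
  target <- annotated$intensity / annotated$intensity[top_cell]
  target[mask == "out_of_range"] <- 0
  structure(list(
    modified_sequence = annotated$modified_sequence,
    charge = annotated$charge, nce = nce, instrument = instrument,
    target = target, mask = mask
  ), class = "intensity_example")
}

#' Build intensity training examples for a whole run
#'
#' Annotates every record's apex spectrum, applies the shared-peak labels
#' and [build_intensity_example()] per record.
#'
#' @param run A `dia_run`.
#' @param report Detection-report tibble.
#' @param labels Tibble from [label_shared_peaks()] (or `NULL` to skip
#'   interference masking).
#' @param tol_ppm Fragment mass tolerance in ppm.
#' @param reject_shared_fraction,reject Passed to
#'   [build_intensity_example()].
#' @param nce,instrument Metadata for every example.
#' @param mode `"global"` or `"phospho"`.
#' @return List with `examples` (list of `intensity_example`) and
#'   `rejections` (tibble of rejected records with reasons).
#' @export
build_intensity_examples <- function(run, report, labels = NULL, tol_ppm = 10,
                                     reject_shared_fraction = 0.5, nce = 30,
                                     instrument = "Lumos", mode = "global",
                                     reject = TRUE) {
  report <- tibble::as_tibble(report)
  examples <- list()
  rej <- list()
  for (i in seq_len(nrow(report))) {
    rec <- report[i, ]
    ann <- match_peaks(run$spectra[[select_apex_spectrum(run, rec)]],
                       rec$modified_sequence, rec$charge,
                       tol_ppm = tol_ppm, mode = mode)
    lab_i <- if (is.null(labels)) NULL else {
      dplyr::filter(labels,
                    .data$modified_sequence == rec$modified_sequence,
                    .data$charge == rec$charge)
    }
    ex <- build_intensity_example(ann, lab_i,
                                  reject_shared_fraction = reject_shared_fraction,
                                  nce = nce, instrument = instrument,
                                  reject = reject)
    if (inherits(ex, "rejected_example")) {
      rej[[length(rej) + 1L]] <- tibble::tibble(
        modified_sequence = rec$modified_sequence, charge = rec$charge,
        reason = ex$reason
      )
    } else {
      examples[[length(examples) + 1L]] <- ex
    }
  }
  list(examples = examples, rejections = dplyr::bind_rows(rej))
}

#' RT normalization factor
#'
#' The maximum apex RT observed in the report, or a user-supplied value.
#'
#' @param report Detection-report tibble.
#' @param value Optional user-defined factor in minutes.
#' @return Positive scalar (minutes).
#' @export
rt_normalization_factor <- function(report, value = NULL) {
  f <- if (is.null(value)) max(report$apex_rt) else value
  if (!is.finite(f) || f <= 0) stop("validation error: RT factor must be > 0")
  f
}

#' Build normalized RT training examples
#'
#' One example per peptidoform: among its precursors (charge states) the
#' most confident one (lowest q-value) supplies the RT, which is divided by
#' the normalization factor.
#'
#' @param report Detection-report tibble.
#' @param factor RT normalization factor in minutes (see
#'   [rt_normalization_factor()]).
#' @return Tibble with `modified_sequence`, `rt_normalized` in `[0, 1]`.
#' @export
build_rt_examples <- function(report, factor) {
  stopifnot(factor > 0)
  if (any(report$apex_rt > factor)) {
    stop("validation error: apex RT exceeds the normalization factor")
  }
  report |>
    dplyr::group_by(.data$modified_sequence) |>
    dplyr::slice_min(.data$q_value, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(modified_sequence = .data$modified_sequence,
                     rt_normalized = .data$apex_rt / factor)
}

#' Split examples at the peptidoform level
#'
#' No peptidoform appears in both partitions; all charge states of a
#' peptidoform travel together. Deterministic for a fixed seed.
#'
#' @param examples List of `intensity_example`s or a tibble with a
#'   `modified_sequence` column.
#' @param test_fraction Fraction of peptidoforms assigned to the test set
#'   (default 0.1).
#' @param seed Integer seed.
#' @return List with `train` and `test`, same type as `examples`.
#' @export
train_test_split <- function(examples, test_fraction = 0.1, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("configuration error: test_fraction must be in (0, 1)")
  }
  seqs <- if (is.data.frame(examples)) examples$modified_sequence else
    vapply(examples, `[[`, character(1), "modified_sequence")
  forms <- unique(seqs)
  if (length(forms) < 10L) {
    stop("configuration error: need at least 10 peptidoforms to split")
  }
  test_forms <- with_local_seed(seed, {
    sample(forms, max(1L, round(test_fraction * length(forms))))
  })
  in_test <- seqs %in% test_forms
  if (is.data.frame(examples)) {
    list(train = examples[!in_test, ], test = examples[in_test, ])
  } else {
    list(train = examples[!in_test], test = examples[in_test])
  }
}

#' Serialize intensity examples as a long TSV
#'
#' One row per fragment-matrix cell, for inspection and fixtures.
#'
#' @param examples List of `intensity_example`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_examples <- function(examples, path) {
  rows <- purrr::map(examples, function(ex) {
    ij <- arrayInd(seq_along(ex$target), dim(ex$target))
    tibble::tibble(
      modified_sequence = ex$modified_sequence, charge = ex$charge,
      nce = ex$nce, instrument = ex$instrument,
      row = ij[, 1], col = colnames(ex$mask)[ij[, 2]],
      target = as.vector(ex$target), mask = as.vector(ex$mask)
    )
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}
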
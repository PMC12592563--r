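# Shared-peak (interference) detection on chimeric DIA spectra.
#
# Two routes are combined:
#  * spectrum-centric: a peak in a precursor's apex MS2 spectrum matched by a
#    fragment of any other detected peptide is shared;
#  * peptide-centric: fragment XICs within the precursor's peak boundaries
#    are smoothed and correlated; fragments poorly correlated with the
#    top-scoring fragment, or well correlated but with a both-sided
#    peak-shape anomaly, are shared.
# Peaks matched by more than one fragment ion of the same peptide
# ("ambiguous") are also shared. The final label is the union.

#' Select the apex MS2 spectrum for a detection record
#'
#' Among spectra whose isolation window covers the precursor m/z, the one
#' with retention time nearest the record's apex RT (ties go to the earlier
#' spectrum).
#'
#' @param run A `dia_run`.
#' @param record One detection-report row (list or single-row tibble with
#'   `precursor_mz`, `apex_rt`).
#' @return Index into `run$spectra`.
#' @export
select_apex_spectrum <- function(run, record) {
  idx <- window_spectra(run, record$precursor_mz)
  if (length(idx) == 0L) {
    stop("data error: precursor m/z ", record$precursor_mz,
         " outside all isolation windows")
  }
  idx[which.min(abs(run$rt[idx] - record$apex_rt))]
}

#' Extract an ion chromatogram for one fragment m/z
#'
#' Per covering spectrum within the record's peak boundaries, the intensity
#' of the nearest peak within `tol_ppm` (0 when none). Chromatograms with
#' fewer than 3 time points are flagged short (attribute `"short"`) and are
#' treated as non-scorable downstream.
#'
#' @param run A `dia_run`.
#' @param fragment_mz Fragment m/z to trace.
#' @param record Detection-report row with `precursor_mz`, `rt_start`,
#'   `rt_stop`.
#' @param tol_ppm Mass tolerance in ppm.
#' @return An object of class `xic`: list with `times` (minutes) and
#'   `values`.
#' @export
extract_xic <- function(run, fragment_mz, record, tol_ppm = 10) {
  extract_xic_set(run, fragment_mz, record, tol_ppm)[[1]]
}

# vectorized variant: one XIC per fragment m/z, sharing the covering-spectra
# lookup across fragments
extract_xic_set <- function(run, fragment_mzs, record, tol_ppm = 10) {
  stopifnot(record$rt_start < record$rt_stop)
  idx <- window_spectra(run, record$precursor_mz)
  rts <- run$rt[idx]
  sel <- rts >= record$rt_start & rts <= record$rt_stop
  idx <- idx[sel]; rts <- rts[sel]
  vals <- matrix(0, length(fragment_mzs), length(idx))
  for (j in seq_along(idx)) {
    s <- run$spectra[[idx[j]]]
    if (length(s$mz) == 0L) next
    hit <- nearest_peak_within(s$mz, fragment_mzs, tol_ppm)
    got <- !is.na(hit)
    vals[got, j] <- s$intensity[hit[got]]
  }
  lapply(seq_along(fragment_mzs), function(f) {
    structure(list(times = rts, values = vals[f, ]),
              class = "xic", short = length(idx) < 3L)
  })
}

#' Smooth an ion chromatogram
#'
#' Savitzky-Golay (default: window 5 clipped to the series length,
#' polynomial order 2) or triangular weighted moving average over window 3
#' (weights 0.25/0.5/0.25).
#'
#' @param xic An `xic` (or bare numeric vector).
#' @param method `"savitzky_golay"` or `"weighted_moving_average"`.
#' @param window Odd window length for Savitzky-Golay.
#' @param order Polynomial order for Savitzky-Golay.
#' @return Smoothed object of the same type.
#' @export
smooth_xic <- function(xic, method = c("savitzky_golay", "weighted_moving_average"),
                       window = 5L, order = 2L) {
  method <- match.arg(method)
  v <- if (inherits(xic, "xic")) xic$values else xic
  n <- length(v)
  if (method == "savitzky_golay") {
    if (window < 3L || window %% 2L == 0L) {
      stop("configuration error: Savitzky-Golay window must be odd and >= 3")
    }
    w <- min(window, if (n %% 2L == 1L) n else n - 1L)
    sm <- if (n < 3L || w < 3L) v else
      signal::sgolayfilt(v, p = min(order, w - 1L), n = w)
  } else {
    sm <- if (n < 3L) v else {
      pad <- c(v[1], v, v[n])
      0.25 * pad[1:n] + 0.5 * pad[2:(n + 1L)] + 0.25 * pad[3:(n + 2L)]
    }
  }
  if (inherits(xic, "xic")) {
    out <- xic; out$values <- sm; out
  } else sm
}

#' Peak shape score of a fragment chromatogram
#'
#' For each of the two boundary time points, the criterion is met iff the
#' fragment's boundary intensity exceeds (a) the median boundary intensity
#' of all detected fragment chromatograms and (b) a fraction of the
#' fragment's own apex intensity within the boundaries - 10% normally,
#' raised to 25% when this fragment's apex is below half the highest apex
#' among all detected fragments. The score is the number of boundaries
#' meeting the criterion; a score of 2 indicates a trace that fails to
#' return to baseline on both sides.
#'
#' @param values Smoothed chromatogram of this fragment, spanning the peak
#'   boundaries (first and last element are the boundary points).
#' @param all_values List of smoothed chromatograms of all detected
#'   fragments of the precursor, on the same time grid.
#' @return Integer score 0, 1 or 2.
#' @export
peak_shape_score <- function(values, all_values) {
  n <- length(values)
  if (n < 3L) return(0L)
  apex_own <- max(values)
  apex_all <- max(vapply(all_values, max, numeric(1)))
  f <- if (apex_own < 0.5 * apex_all) 0.25 else 0.10
  score <- 0L
  for (b in c(1L, n)) {
    med <- stats::median(vapply(all_values, `[`, numeric(1), b))
    if (values[b] > med && values[b] > f * apex_own) score <- score + 1L
  }
  score
}

#' Peptide-centric shared-peak labels for one precursor
#'
#' Smooths all fragment XICs, computes pairwise Pearson correlations,
#' assigns each fragment the sum of its correlations to all others as an
#' aggregate score, and identifies the top-scoring fragment. A fragment is
#' shared iff its correlation to the top fragment is below `corr_threshold`,
#' or it is well correlated but its peak shape score is 2. Fragments with
#' constant (zero-variance) chromatograms carry no shape evidence and are
#' conservatively labeled shared; short chromatograms (< 3 points) are
#' non-scorable and labeled not shared.
#'
#' @param xics Named list of `xic` objects, one per matched fragment.
#' @param corr_threshold Pearson correlation threshold (default 0.8).
#' @param smooth_method Passed to [smooth_xic()].
#' @return Tibble with per-fragment `shared`, `corr_to_top`,
#'   `aggregate_score`, `shape_score`, `is_top`, `scorable`.
#' @export
peptide_centric_labels <- function(xics, corr_threshold = 0.8,
                                   smooth_method = "savitzky_golay") {
  nms <- names(xics)
  n <- length(xics)
  out <- tibble::tibble(
    fragment = nms, shared = FALSE, corr_to_top = NA_real_,
    aggregate_score = NA_real_, shape_score = NA_integer_,
    is_top = FALSE, scorable = TRUE
  )
  if (n == 0L) return(out)
  short <- vapply(xics, function(x) isTRUE(attr(x, "short")), logical(1))
  sm <- lapply(xics, function(x) smooth_xic(x, method = smooth_method)$values)
  const <- vapply(sm, function(v) {
    s <- stats::sd(v)
    !is.finite(s) || s <= 1e-12 * max(abs(v), 1)
  }, logical(1))
  out$scorable <- !short & !const
  # constant nonzero traces carry no usable shape evidence: conservative
  out$shared[const & !short] <- TRUE
  sc <- which(out$scorable)
  if (length(sc) < 2L) {
    warning("fewer than 2 scorable fragment chromatograms; ",
            "peptide-centric labels undetermined")
    return(out)
  }
  mat <- do.call(cbind, sm[sc])
  cors <- suppressWarnings(stats::cor(mat))
  cors[!is.finite(cors)] <- 0
  agg <- colSums(cors) - 1
  top <- sc[which.max(agg)]
  out$aggregate_score[sc] <- agg
  out$is_top[top] <- TRUE
  out$corr_to_top[sc] <- cors[, which.max(agg)]
  shape <- vapply(sc, function(i) {
    peak_shape_score(sm[[i]], sm[sc])
  }, integer(1))
  out$shape_score[sc] <- shape
  low_corr <- out$corr_to_top[sc] < corr_threshold
  out$shared[sc] <- low_corr | (!low_corr & shape == 2L)
  out
}

#' Combine shared-peak labels
#'
#' The final label is the per-cell union of the spectrum-centric,
#' peptide-centric and ambiguous-match routes.
#'
#' @param spectrum_centric,peptide_centric,ambiguous Congruent logical
#'   vectors or matrices.
#' @return List of class `shared_peak_labels` with the three inputs and
#'   their union `shared`.
#' @export
combine_labels <- function(spectrum_centric, peptide_centric, ambiguous) {
  if (length(spectrum_centric) != length(peptide_centric) ||
      length(spectrum_centric) != length(ambiguous)) {
    stop("internal error: label shape mismatch")
  }
  structure(list(
    spectrum_centric = spectrum_centric,
    peptide_centric = peptide_centric,
    ambiguous = ambiguous,
    shared = spectrum_centric | peptide_centric | ambiguous
  ), class = "shared_peak_labels")
}

#' Label shared fragment peaks across a whole run
#'
#' Runs the full dual shared-peak determination for every record of a
#' detection report: annotates each precursor's apex spectrum, applies the
#' spectrum-centric route against all co-detected peptides of that spectrum,
#' the peptide-centric XIC-correlation route, and the ambiguous-match route,
#' and returns one row per matched fragment cell.
#'
#' @param run A `dia_run`.
#' @param report Detection-report tibble (see [read_detection_report()]).
#' @param tol_ppm Fragment mass tolerance in ppm.
#' @param corr_threshold Peptide-centric correlation threshold.
#' @param smooth_method Passed to [smooth_xic()].
#' @param mode `"global"` or `"phospho"`.
#' @return Tibble with one row per matched cell: `modified_sequence`,
#'   `charge`, `row`, `col`, `fragment_mz`, `intensity`, `spectrum_centric`,
#'   `peptide_centric`, `ambiguous`, `shared`, `corr_to_top`, `shape_score`,
#'   `aggregate_score`, `out_of_range`.
#' @export
label_shared_peaks <- function(run, report, tol_ppm = 10, corr_threshold = 0.8,
                               smooth_method = "savitzky_golay",
                               mode = "global") {
  report <- tibble::as_tibble(report)
  n <- nrow(report)
  apex_idx <- vapply(seq_len(n), function(i) {
    select_apex_spectrum(run, report[i, ])
  }, integer(1))
  ann_cache <- new.env(parent = emptyenv())
  annotate <- function(rec_i, spec_i) {
    k <- paste0(rec_i, "|", spec_i)
    a <- ann_cache[[k]]
    if (is.null(a)) {
      a <- match_peaks(run$spectra[[spec_i]], report$modified_sequence[rec_i],
                       report$charge[rec_i], tol_ppm = tol_ppm, mode = mode)
      ann_cache[[k]] <- a
    }
    a
  }
  spec_iso <- function(i) c(run$spectra[[i]]$iso_low, run$spectra[[i]]$iso_high)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    ann <- annotate(i, apex_idx[i])
    matched_cells <- which(!is.na(ann$matched_peak))
    if (length(matched_cells) == 0L) next
    # spectrum-centric: co-detected peptides on the same apex spectrum
    iso <- spec_iso(apex_idx[i])
    srt <- run$spectra[[apex_idx[i]]]$rt
    co <- which(report$precursor_mz >= iso[1] & report$precursor_mz < iso[2] &
                  report$rt_start <= srt & report$rt_stop >= srt)
    co <- setdiff(co, i)
    other_peaks <- integer(0)
    for (j in co) {
      aj <- annotate(j, apex_idx[i])
      other_peaks <- union(other_peaks, aj$matched_peak[!is.na(aj$matched_peak)])
    }
    spectrum_centric <- matrix(FALSE, nrow(ann$intensity), ncol(ann$intensity))
    spectrum_centric[matched_cells] <-
      ann$matched_peak[matched_cells] %in% other_peaks
    # peptide-centric: XIC correlation on the matched fragments
    xics <- extract_xic_set(run, ann$theo_mz[matched_cells], report[i, ],
                            tol_ppm = tol_ppm)
    names(xics) <- as.character(matched_cells)
    pc <- peptide_centric_labels(xics, corr_threshold = corr_threshold,
                                 smooth_method = smooth_method)
    peptide_centric <- matrix(FALSE, nrow(ann$intensity), ncol(ann$intensity))
    peptide_centric[matched_cells] <- pc$shared
    lab <- combine_labels(spectrum_centric, ambiguous = ann$ambiguous,
                          peptide_centric = peptide_centric)
    ij <- arrayInd(matched_cells, dim(ann$intensity))
    results[[i]] <- tibble::tibble(
      modified_sequence = report$modified_sequence[i],
      charge = report$charge[i],
      row = ij[, 1], col = ann$layout[ij[, 2]],
      fragment_mz = ann$theo_mz[matched_cells],
      intensity = ann$intensity[matched_cells],
      spectrum_centric = lab$spectrum_centric[matched_cells],
      peptide_centric = lab$peptide_centric[matched_cells],
      ambiguous = lab$ambiguous[matched_cells],
      shared = lab$shared[matched_cells],
      corr_to_top = pc$corr_to_top,
      shape_score = pc$shape_score,
      aggregate_score = pc$aggregate_score,
      out_of_range = FALSE
    )
  }
  dplyr::bind_rows(results)
}

#' Write a shared-peak diagnostic table
#'
#' @param labels Tibble from [label_shared_peaks()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_label_diagnostics <- function(labels, path) {
  readr::write_tsv(labels, path, progress = FALSE)
  invisible(path)
}

#' Compare detected shared-peak labels with simulator truth
#'
#' Joins detector output with a simulated run's per-cell interference truth
#' and computes precision and recall of the combined detector. Cells flagged
#' as coincidental m/z collisions between unrelated detected peptides are
#' excluded (they are genuine interference but not injected, so neither a
#' true nor a false positive with respect to the injected truth).
#'
#' @param labels Tibble from [label_shared_peaks()].
#' @param sim A `simulated_run`.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `n_collisions_excluded`.
#' @export
evaluate_shared_peak_detection <- function(labels, sim) {
  truth <- sim$truth_shared
  joined <- dplyr::inner_join(
    labels, truth,
    by = c("modified_sequence", "charge", "row", "col")
  )
  excl <- joined$collision & !joined$shared.y
  joined <- joined[!excl, ]
  tp <- sum(joined$shared.x & joined$shared.y)
  fp <- sum(joined$shared.x & !joined$shared.y)
  fn <- sum(!joined$shared.x & joined$shared.y)
  tn <- sum(!joined$shared.x & !joined$shared.y)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    n_collisions_excluded = sum(excl)
  )
}
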
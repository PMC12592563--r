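# Theoretical peptide/fragment masses and annotation of DIA spectra with
# matched fragment intensities.
#
# Fragment matrices follow a fixed tabular layout: rows are backbone cleavage
# sites 1..L-1 (row k holds the b_k and y_{L-k} ions), columns are fragment
# ion types with charge state: b_z1, b_z2, y_z1, y_z2, plus -98 neutral-loss
# variants in phospho mode. Cells that cannot exist for a given precursor
# (charge-2 columns for 1+ precursors, loss columns for fragments spanning no
# phosphosite) are masked "out_of_range" so matrices are always full-shape.

#' Fragment matrix column layout
#'
#' @param mode `"global"` (b/y ions) or `"phospho"` (adds -98 Da phosphoric
#'   acid neutral-loss columns).
#' @return Character vector of column labels.
#' @export
fragment_layout <- function(mode = c("global", "phospho")) {
  mode <- match.arg(mode)
  base <- c("b_z1", "b_z2", "y_z1", "y_z2")
  if (mode == "phospho") c(base, paste0(base, "_nl")) else base
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water plus all modification
#' mass deltas.
#'
#' @param pf A [peptidoform()] or a modified-sequence string.
#' @return Neutral monoisotopic mass in Da.
#' @export
#'
#' @examples
#' peptide_mono_mass("PEPTIDE")
peptide_mono_mass <- function(pf) {
  pf <- as_peptidoform(pf)
  sum(AA_MONO[strsplit(pf$sequence, "")[[1]]]) + WATER_MASS + sum(pf$mods$mass_delta)
}

as_peptidoform <- function(x) {
  if (inherits(x, "peptidoform")) x else parse_modified_sequence(x)
}

#' Precursor m/z
#'
#' @param pf A [peptidoform()] or modified-sequence string.
#' @param charge Precursor charge state.
#' @return m/z of the protonated precursor.
#' @export
precursor_mz <- function(pf, charge) {
  (peptide_mono_mass(pf) + charge * PROTON_MASS) / charge
}

#' Theoretical fragment m/z
#'
#' b ions sum the prefix residues (plus prefix modifications); y ions sum the
#' suffix residues plus water. Neutral losses are subtracted from the neutral
#' fragment mass before protonation and charge division.
#'
#' @param pf A [peptidoform()] or modified-sequence string.
#' @param series `"b"` or `"y"`.
#' @param ordinal Fragment ordinal, 1..L-1.
#' @param charge Fragment charge (1 or 2).
#' @param loss `"none"` or `"phospho_98"`.
#' @return Fragment m/z.
#' @export
#'
#' @examples
#' fragment_mz("PE", "b", 1, 1)
fragment_mz <- function(pf, series, ordinal, charge = 1L, loss = "none") {
  pf <- as_peptidoform(pf)
  L <- length(pf)
  if (any(ordinal < 1L | ordinal > L - 1L)) {
    stop("fragment ordinal out of range 1..", L - 1L)
  }
  series <- match.arg(series, c("b", "y"))
  loss <- match.arg(loss, c("none", "phospho_98"))
  res <- AA_MONO[strsplit(pf$sequence, "")[[1]]]
  mods <- mod_deltas_by_residue(pf)
  cum <- cumsum(res + mods)
  total <- cum[L]
  neutral <- if (series == "b") cum[ordinal] else total - cum[L - ordinal] + WATER_MASS
  if (loss == "phospho_98") neutral <- neutral - PHOSPHO_NEUTRAL_LOSS
  unname((neutral + charge * PROTON_MASS) / charge)
}

#' Enumerate theoretical fragment ions
#'
#' All b/y ions at ordinals 1..L-1. Fragment charges are {1} for 1+
#' precursors and {1, 2} for 2+ and higher. In phospho mode a -98 Da
#' neutral-loss variant is added for every fragment spanning at least one
#' phosphosite.
#'
#' @param pf A [peptidoform()] or modified-sequence string.
#' @param precursor_charge Precursor charge state.
#' @param mode `"global"` or `"phospho"`.
#' @return Tibble with columns `series`, `ordinal`, `charge`, `loss`, `mz`,
#'   `row` (cleavage site index) and `col` (layout column label).
#' @export
enumerate_fragments <- function(pf, precursor_charge, mode = c("global", "phospho")) {
  mode <- match.arg(mode)
  pf <- as_peptidoform(pf)
  L <- length(pf)
  if (L < 2L) stop("peptide length must be >= 2 to fragment")
  charges <- if (precursor_charge >= 2L) c(1L, 2L) else 1L
  grid <- tidyr::expand_grid(
    series = c("b", "y"), ordinal = seq_len(L - 1L), charge = charges,
    loss = "none"
  )
  if (mode == "phospho") {
    sites <- phospho_positions(pf)
    if (length(sites) > 0L) {
      span <- function(series, ordinal) {
        if (series == "b") any(sites <= ordinal) else any(sites > L - ordinal)
      }
      nl <- grid[mapply(span, grid$series, grid$ordinal), ]
      if (nrow(nl) > 0L) {
        nl$loss <- "phospho_98"
        grid <- dplyr::bind_rows(grid, nl)
      }
    }
  }
  res <- AA_MONO[strsplit(pf$sequence, "")[[1]]]
  mods <- mod_deltas_by_residue(pf)
  cum <- cumsum(res + mods)
  total <- cum[L]
  neutral <- ifelse(grid$series == "b", cum[grid$ordinal],
                    total - cum[L - grid$ordinal] + WATER_MASS)
  neutral <- neutral - ifelse(grid$loss == "phospho_98", PHOSPHO_NEUTRAL_LOSS, 0)
  grid$mz <- unname((neutral + grid$charge * PROTON_MASS) / grid$charge)
  grid$row <- ifelse(grid$series == "b", grid$ordinal, L - grid$ordinal)
  grid$col <- paste0(grid$series, "_z", grid$charge,
                     ifelse(grid$loss == "phospho_98", "_nl", ""))
  tibble::as_tibble(grid)
}

# Full-shape theoretical m/z matrix for the layout; NA where no fragment
# exists (charge-2 columns for 1+ precursors, loss columns without a spanned
# phosphosite).
theoretical_mz_matrix <- function(pf, precursor_charge, mode = "global") {
  pf <- as_peptidoform(pf)
  L <- length(pf)
  layout <- fragment_layout(mode)
  frags <- enumerate_fragments(pf, precursor_charge, mode)
  m <- matrix(NA_real_, nrow = L - 1L, ncol = length(layout),
              dimnames = list(NULL, layout))
  m[cbind(frags$row, match(frags$col, layout))] <- frags$mz
  m
}

#' Match theoretical fragments to a centroided spectrum
#'
#' Every enumerable fragment is matched to the nearest spectrum peak within
#' `tol_ppm`. Unmatched cells get intensity 0. Cells whose theoretical m/z
#' falls outside the spectrum's acquired scan range, and cells for which no
#' fragment exists, are masked `"out_of_range"`. A spectrum peak claimed by
#' more than one fragment marks all its cells as ambiguous and masks them
#' `"shared"`.
#'
#' @param spectrum A centroid spectrum: list with sorted `mz`, `intensity`,
#'   `scan_low`, `scan_high` (see [read_mzml()]).
#' @param pf A [peptidoform()] or modified-sequence string.
#' @param charge Precursor charge.
#' @param tol_ppm Mass tolerance in ppm.
#' @param mode `"global"` or `"phospho"`.
#' @return An object of class `annotated_spectrum`: list with `layout`,
#'   matrices `theo_mz`, `intensity`, `matched_peak`, `mask` (values `"use"`,
#'   `"shared"`, `"out_of_range"`), logical matrix `ambiguous`, and the call
#'   metadata.
#' @export
match_peaks <- function(spectrum, pf, charge, tol_ppm = 10, mode = "global") {
  stopifnot(tol_ppm > 0)
  if (is.unsorted(spectrum$mz, strictly = FALSE)) {
    stop("internal error: spectrum m/z array is not sorted")
  }
  pf <- as_peptidoform(pf)
  L <- length(pf)
  layout <- fragment_layout(mode)
  theo <- theoretical_mz_matrix(pf, charge, mode)
  intensity <- matrix(0, nrow = L - 1L, ncol = length(layout),
                      dimnames = list(NULL, layout))
  matched <- matrix(NA_integer_, nrow = L - 1L, ncol = length(layout),
                    dimnames = list(NULL, layout))
  mask <- matrix("use", nrow = L - 1L, ncol = length(layout),
                 dimnames = list(NULL, layout))
  mask[is.na(theo)] <- "out_of_range"
  in_range <- !is.na(theo) & theo >= spectrum$scan_low & theo <= spectrum$scan_high
  mask[!is.na(theo) & !in_range] <- "out_of_range"

  idx <- which(in_range)
  if (length(idx) > 0L && length(spectrum$mz) > 0L) {
    hits <- nearest_peak_within(spectrum$mz, theo[idx], tol_ppm)
    matched[idx] <- hits
    got <- !is.na(hits)
    intensity[idx[got]] <- spectrum$intensity[hits[got]]
  }
  ambiguous <- matrix(FALSE, nrow = L - 1L, ncol = length(layout),
                      dimnames = list(NULL, layout))
  mp <- matched[!is.na(matched)]
  dup <- unique(mp[duplicated(mp)])
  if (length(dup) > 0L) {
    ambiguous[!is.na(matched) & matrix(matched %in% dup, nrow = nrow(matched))] <- TRUE
    mask[ambiguous & mask == "use"] <- "shared"
  }
  structure(
    list(
      modified_sequence = format_modified_sequence(pf), charge = charge,
      mode = mode, layout = layout, theo_mz = theo, intensity = intensity,
      matched_peak = matched, mask = mask, ambiguous = ambiguous,
      tol_ppm = tol_ppm
    ),
    class = "annotated_spectrum"
  )
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat("<annotated_spectrum>", x$modified_sequence, paste0(x$charge, "+"),
      "|", sum(!is.na(x$matched_peak)), "matched,",
      sum(x$mask == "shared"), "shared,",
      sum(x$mask == "out_of_range"), "out-of-range cells\n")
  invisible(x)
}

# nearest peak index within tol_ppm for each query m/z (NA if none)
nearest_peak_within <- function(peaks_mz, query_mz, tol_ppm) {
  pos <- findInterval(query_mz, peaks_mz)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(peaks_mz))
  d_lo <- abs(peaks_mz[lo] - query_mz)
  d_hi <- abs(peaks_mz[hi] - query_mz)
  best <- ifelse(d_lo <= d_hi, lo, hi)
  err <- abs(peaks_mz[best] - query_mz) / query_mz * 1e6
  ifelse(err <= tol_ppm, best, NA_integer_)
}
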
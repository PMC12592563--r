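# mzML reading/writing for centroided DIA runs, via the proteowizard-backed
# mzR package. Retention times are minutes everywhere in this package;
# isolation windows are half-open [iso_low, iso_high).

#' Read a centroided DIA run from mzML
#'
#' Loads all MS2 spectra with their isolation-window and scan-window
#' metadata and builds an isolation-window index. Profile-mode spectra or
#' spectra missing isolation metadata are rejected.
#'
#' @param path Path to an mzML file.
#' @return An object of class `dia_run`: list with `spectra` (time-ordered
#'   list of centroid spectra: `mz`, `intensity`, `rt` in minutes,
#'   `iso_low`, `iso_high`, `scan_low`, `scan_high`), and `windows`
#'   (tibble of distinct isolation windows).
#' @export
read_mzml <- function(path) {
  stopifnot(file.exists(path))
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  ms2 <- which(hdr$msLevel == 2L)
  if (length(ms2) == 0L) stop("format error: no MS2 spectra in ", path)
  bad_centroid <- ms2[!is.na(hdr$centroided[ms2]) & !hdr$centroided[ms2]]
  if (length(bad_centroid) > 0L) {
    stop("format error: profile-mode MS2 spectrum (scan ",
         hdr$seqNum[bad_centroid[1]], ") in ", path)
  }
  iso_t <- hdr$isolationWindowTargetMZ[ms2]
  iso_l <- hdr$isolationWindowLowerOffset[ms2]
  iso_u <- hdr$isolationWindowUpperOffset[ms2]
  if (anyNA(iso_t) || anyNA(iso_l) || anyNA(iso_u)) {
    miss <- ms2[which(is.na(iso_t) | is.na(iso_l) | is.na(iso_u))[1]]
    stop("format error: missing isolation-window metadata on scan ",
         hdr$seqNum[miss], " in ", path)
  }
  pk <- mzR::peaks(fh, ms2)
  if (length(ms2) == 1L) pk <- list(pk)
  spectra <- vector("list", length(ms2))
  for (i in seq_along(ms2)) {
    j <- ms2[i]
    spectra[[i]] <- list(
      mz = pk[[i]][, 1], intensity = pk[[i]][, 2],
      rt = hdr$retentionTime[j] / 60,
      iso_low = hdr$isolationWindowTargetMZ[j] - hdr$isolationWindowLowerOffset[j],
      iso_high = hdr$isolationWindowTargetMZ[j] + hdr$isolationWindowUpperOffset[j],
      scan_low = hdr$scanWindowLowerLimit[j],
      scan_high = hdr$scanWindowUpperLimit[j]
    )
  }
  new_dia_run(spectra, path = path)
}

new_dia_run <- function(spectra, path = NA_character_) {
  ord <- order(vapply(spectra, `[[`, numeric(1), "rt"))
  spectra <- spectra[ord]
  # cached per-spectrum metadata vectors for fast window lookups
  rt <- vapply(spectra, `[[`, numeric(1), "rt")
  iso_low <- vapply(spectra, `[[`, numeric(1), "iso_low")
  iso_high <- vapply(spectra, `[[`, numeric(1), "iso_high")
  windows <- dplyr::arrange(
    dplyr::distinct(tibble::tibble(iso_low = iso_low, iso_high = iso_high)),
    .data$iso_low
  )
  structure(list(spectra = spectra, windows = windows, path = path,
                 rt = rt, iso_low = iso_low, iso_high = iso_high),
            class = "dia_run")
}

#' @export
print.dia_run <- function(x, ...) {
  rts <- vapply(x$spectra, `[[`, numeric(1), "rt")
  cat("<dia_run>", length(x$spectra), "MS2 spectra,",
      nrow(x$windows), "isolation windows, RT",
      sprintf("%.2f-%.2f min\n", min(rts), max(rts)))
  invisible(x)
}

#' Spectra whose isolation window covers a precursor m/z
#'
#' Windows are half-open: a spectrum covers `mz` iff
#' `iso_low <= mz < iso_high`.
#'
#' @param run A `dia_run`.
#' @param mz Precursor m/z.
#' @return Integer indices into `run$spectra`, in time order.
#' @export
window_spectra <- function(run, mz) {
  stopifnot(inherits(run, "dia_run"))
  which(run$iso_low <= mz & mz < run$iso_high)
}

#' Write a DIA run to mzML
#'
#' Writes the MS2 spectra of a `dia_run` (e.g. a simulated one) with their
#' isolation-window and scan-window metadata.
#'
#' @param run A `dia_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "dia_run"))
  n <- length(run$spectra)
  pk <- lapply(run$spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  g <- function(f) vapply(run$spectra, `[[`, numeric(1), f)
  npeaks <- vapply(pk, nrow, integer(1))
  tic <- vapply(run$spectra, function(s) sum(s$intensity), numeric(1))
  bp <- vapply(run$spectra, function(s) {
    if (length(s$intensity) == 0) c(0, 0) else {
      i <- which.max(s$intensity); c(s$mz[i], s$intensity[i])
    }
  }, numeric(2))
  lowmz <- vapply(run$spectra, function(s) if (length(s$mz)) min(s$mz) else 0, numeric(1))
  highmz <- vapply(run$spectra, function(s) if (length(s$mz)) max(s$mz) else 0, numeric(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = rep(2L, n),
    polarity = rep(1L, n), peaksCount = npeaks, totIonCurrent = tic,
    retentionTime = g("rt") * 60,
    basePeakMZ = bp[1, ], basePeakIntensity = bp[2, ],
    collisionEnergy = rep(0, n), ionisationEnergy = rep(0, n),
    lowMZ = lowmz, highMZ = highmz,
    precursorScanNum = rep(0L, n),
    precursorMZ = (g("iso_low") + g("iso_high")) / 2,
    precursorCharge = rep(0L, n), precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", seq_len(n)), centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = (g("iso_low") + g("iso_high")) / 2,
    isolationWindowLowerOffset = (g("iso_high") - g("iso_low")) / 2,
    isolationWindowUpperOffset = (g("iso_high") - g("iso_low")) / 2,
    scanWindowLowerLimit = g("scan_low"), scanWindowUpperLimit = g("scan_high"),
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pk, path, header = hdr)
  invisible(path)
}
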
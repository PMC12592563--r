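# Quantitative evaluation machinery: rank correlation on non-interfered
# peaks, entrapment-based FDP bounds, spectral-entropy similarity and NCE
# calibration.

#' Spearman correlation over unmasked cells
#'
#' Rank correlation between predicted and observed fragment intensities
#' computed over usable cells only; interfered and out-of-range cells are
#' excluded. Ties receive average ranks.
#'
#' @param pred,obs Congruent numeric matrices.
#' @param mask Congruent character (`"use"`) or logical (`TRUE` = use)
#'   matrix.
#' @return Spearman rho, or `NA` (with a message) when fewer than 3 usable
#'   cells exist.
#' @export
spearman_unmasked <- function(pred, obs, mask) {
  use <- if (is.character(mask)) mask == "use" else as.logical(mask)
  stopifnot(all(dim(pred) == dim(obs)), all(dim(pred) == dim(use)))
  if (sum(use) < 3L) {
    message("fewer than 3 usable cells; Spearman undefined")
    return(NA_real_)
  }
  suppressWarnings(stats::cor(pred[use], obs[use], method = "spearman"))
}

#' Entrapment discovery counts at a score cutoff
#'
#' @param pairs Tibble with one row per target/entrapment pair: columns
#'   `target_score` and `entrapment_score` (use `-Inf` for peptides never
#'   scored).
#' @param cutoff Discovery score cutoff `s` (discovered means score >= s).
#' @return One-row tibble with `n_target`, `n_entrapment`,
#'   `n_entrapment_target_undiscovered` (entrapment discovered, partner
#'   below cutoff) and `n_entrapment_above_target_discovered` (both
#'   discovered, entrapment scored higher).
#' @export
count_entrapment <- function(pairs, cutoff) {
  t_disc <- pairs$target_score >= cutoff
  e_disc <- pairs$entrapment_score >= cutoff
  tibble::tibble(
    n_target = sum(t_disc),
    n_entrapment = sum(e_disc),
    n_entrapment_target_undiscovered = sum(e_disc & !t_disc),
    n_entrapment_above_target_discovered =
      sum(e_disc & t_disc & pairs$entrapment_score > pairs$target_score)
  )
}

#' Entrapment-based FDP bounds
#'
#' Paired upper bound and lower bound on the false discovery proportion:
#' \deqn{\widehat{FDP}_{upper} = (N_E + N_{E \ge s > T} + 2 N_{E > T \ge s})
#'   / (N_T + N_E)} and \deqn{\widehat{FDP}_{lower} = N_E / (N_T + N_E).}
#'
#' @param counts One-row tibble/list from [count_entrapment()].
#' @return One-row tibble with `lower` and `upper`, or both `NA` when no
#'   discovery was made.
#' @export
#'
#' @examples
#' estimate_fdp(tibble::tibble(
#'   n_target = 90, n_entrapment = 10,
#'   n_entrapment_target_undiscovered = 4,
#'   n_entrapment_above_target_discovered = 3
#' ))
estimate_fdp <- function(counts) {
  n_t <- counts$n_target
  n_e <- counts$n_entrapment
  if (n_t + n_e == 0) {
    return(tibble::tibble(lower = NA_real_, upper = NA_real_))
  }
  tibble::tibble(
    lower = n_e / (n_t + n_e),
    upper = (n_e + counts$n_entrapment_target_undiscovered +
               2 * counts$n_entrapment_above_target_discovered) / (n_t + n_e)
  )
}

#' FDP bound curves over a score sweep
#'
#' @param discoveries Tibble with columns `peptide`, `score`,
#'   `is_entrapment`, `pair_id` (each entrapment shares `pair_id` with its
#'   original target).
#' @param cutoffs Score cutoffs to sweep; defaults to all observed scores.
#' @return Tibble with one row per cutoff: the four counts plus `lower` and
#'   `upper`.
#' @export
fdp_sweep <- function(discoveries, cutoffs = NULL) {
  pairs <- pair_scores(discoveries)
  if (is.null(cutoffs)) cutoffs <- sort(unique(discoveries$score))
  purrr::map_dfr(cutoffs, function(s) {
    cnt <- count_entrapment(pairs, s)
    dplyr::bind_cols(tibble::tibble(cutoff = s), cnt, estimate_fdp(cnt))
  })
}

pair_scores <- function(discoveries) {
  d <- tibble::as_tibble(discoveries)
  t_side <- dplyr::filter(d, !.data$is_entrapment)
  e_side <- dplyr::filter(d, .data$is_entrapment)
  out <- dplyr::full_join(
    dplyr::select(t_side, "pair_id", target_score = "score"),
    dplyr::select(e_side, "pair_id", entrapment_score = "score"),
    by = "pair_id"
  )
  out$target_score[is.na(out$target_score)] <- -Inf
  out$entrapment_score[is.na(out$entrapment_score)] <- -Inf
  out
}

#' Build a paired entrapment peptide database
#'
#' All isoleucines are first converted to leucine (target and entrapment
#' alike). For each target an entrapment partner is generated by shuffling
#' the peptide with the C-terminal residue held fixed; shuffling is retried
#' (up to `max_attempts`) until the entrapment differs from the target, and
#' targets with no distinct permutation are dropped (and reported in the
#' `dropped` attribute).
#'
#' @param target_peptides Character vector of target peptide sequences
#'   (length >= 2 each).
#' @param seed Integer seed.
#' @param max_attempts Shuffle retries per target.
#' @return Tibble with `pair_id`, `target`, `entrapment`; dropped targets in
#'   attribute `"dropped"`.
#' @export
build_entrapment_db <- function(target_peptides, seed = 1L, max_attempts = 20L) {
  stopifnot(all(nchar(target_peptides) >= 2L))
  targets <- gsub("I", "L", target_peptides, fixed = TRUE)
  with_local_seed(seed, {
    ent <- character(length(targets))
    dropped <- logical(length(targets))
    for (i in seq_along(targets)) {
      chars <- strsplit(targets[i], "")[[1]]
      L <- length(chars)
      prefix <- chars[-L]
      if (length(unique(prefix)) == 1L) { dropped[i] <- TRUE; next }
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        cand <- paste(c(sample(prefix), chars[L]), collapse = "")
        if (cand != targets[i]) { ent[i] <- cand; ok <- TRUE; break }
      }
      if (!ok) dropped[i] <- TRUE
    }
    out <- tibble::tibble(
      pair_id = which(!dropped),
      target = targets[!dropped],
      entrapment = ent[!dropped]
    )
    attr(out, "dropped") <- target_peptides[dropped]
    out
  })
}

#' Unweighted spectral entropy similarity
#'
#' Both spectra are normalized to total intensity 1 and aligned by merging
#' peaks within `merge_tol_ppm`; unmatched peaks stay as distinct
#' dimensions. With Shannon entropy H, the similarity is
#' `1 - (2 H(mix) - H(A) - H(B)) / ln 4` where mix is the half/half mixture
#' spectrum. 1 for identical spectra, 0 for fully disjoint peak sets.
#'
#' @param spec_a,spec_b Two-column matrices or data frames (`mz`,
#'   `intensity`), non-empty, intensities non-negative.
#' @param merge_tol_ppm Peak alignment tolerance in ppm.
#' @return Similarity in `[0, 1]`.
#' @export
spectral_entropy_similarity <- function(spec_a, spec_b, merge_tol_ppm = 10) {
  a <- as.matrix(as.data.frame(spec_a))[, 1:2, drop = FALSE]
  b <- as.matrix(as.data.frame(spec_b))[, 1:2, drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L || sum(a[, 2]) <= 0 || sum(b[, 2]) <= 0) {
    stop("undefined: empty spectrum")
  }
  all_mz <- sort(c(a[, 1], b[, 1]))
  # cluster peaks: a new bin opens when the gap to the previous bin anchor
  # exceeds the tolerance
  bin <- integer(length(all_mz))
  anchor <- all_mz[1]; cur <- 1L; bin[1] <- 1L
  for (i in seq_along(all_mz)[-1]) {
    if ((all_mz[i] - anchor) / anchor * 1e6 > merge_tol_ppm) {
      cur <- cur + 1L; anchor <- all_mz[i]
    }
    bin[i] <- cur
  }
  bin_of <- function(mz) bin[match(mz, all_mz)]
  va <- tapply(a[, 2], factor(bin_of(a[, 1]), levels = seq_len(max(bin))), sum,
               default = 0)
  vb <- tapply(b[, 2], factor(bin_of(b[, 1]), levels = seq_len(max(bin))), sum,
               default = 0)
  pa <- va / sum(va); pb <- vb / sum(vb)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mix <- (pa + pb) / 2
  sim <- 1 - (2 * H(mix) - H(pa) - H(pb)) / log(4)
  min(max(sim, 0), 1)
}

#' Calibrate NCE by spectral-entropy similarity
#'
#' For every NCE on the grid, predicts each example's fragment intensities,
#' computes the entropy similarity against the observed unshared peaks, and
#' takes the median across examples. The optimal NCE is the grid value with
#' the highest median (ties go to the lowest NCE).
#'
#' @param intensity_model A predictor accepted by [predict_intensity()].
#' @param observed List of observation records: each a list with
#'   `modified_sequence`, `charge`, `spectrum` (two-column matrix of
#'   observed unshared peaks: m/z and intensity).
#' @param grid NCE grid (default 20:40).
#' @param instrument,mode Prediction metadata.
#' @param scan_range Optional length-2 acquired m/z range; predicted
#'   fragments outside it are unobservable and are dropped before the
#'   comparison.
#' @param merge_tol_ppm Peak alignment tolerance.
#' @return Object of class `nce_calibration`: list with `grid` tibble
#'   (`nce`, `median_similarity`) and `optimal_nce`.
#' @export
calibrate_nce <- function(intensity_model, observed, grid = 20:40,
                          instrument = "Lumos", mode = "global",
                          scan_range = NULL, merge_tol_ppm = 10) {
  stopifnot(length(grid) >= 1L, length(observed) >= 1L)
  seqs <- vapply(observed, `[[`, character(1), "modified_sequence")
  chgs <- vapply(observed, `[[`, numeric(1), "charge")
  theo <- lapply(seq_along(observed), function(i) {
    theoretical_mz_matrix(seqs[i], chgs[i], mode)
  })
  medians <- vapply(grid, function(nce) {
    preds <- predict_intensity(intensity_model, seqs, chgs, nce = nce,
                               instrument = instrument, mode = mode)
    sims <- vapply(seq_along(observed), function(i) {
      m <- preds[[i]]
      keep <- !is.na(theo[[i]]) & m > 0
      if (!is.null(scan_range)) {
        keep <- keep & theo[[i]] >= scan_range[1] & theo[[i]] <= scan_range[2]
      }
      if (!any(keep)) return(NA_real_)
      pred_spec <- cbind(mz = theo[[i]][keep], intensity = m[keep])
      spectral_entropy_similarity(pred_spec, observed[[i]]$spectrum,
                                  merge_tol_ppm)
    }, numeric(1))
    stats::median(sims, na.rm = TRUE)
  }, numeric(1))
  optimal <- grid[which.max(medians)]   # which.max takes the first (lowest)
  structure(list(
    grid = tibble::tibble(nce = grid, median_similarity = medians),
    optimal_nce = optimal
  ), class = "nce_calibration")
}

#' @export
print.nce_calibration <- function(x, ...) {
  cat("<nce_calibration> optimal NCE =", x$optimal_nce, "\n")
  invisible(x)
}
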
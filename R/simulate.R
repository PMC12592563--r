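# Deterministic DIA simulator: FASTA proteomes, a ground-truth
# fragmentation/elution process, DIA cycles of wide-window MS2 spectra with
# Gaussian elution profiles and injected fragment interference, and a
# matching detection report. Every downstream stage is testable against the
# truth tables this module carries along.

# run expr under a fixed RNG state, restoring the caller's state after
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulator configuration
#'
#' Defaults describe a desk-scale wide-window DIA experiment: 24 m/z
#' isolation windows tiling 400-1000 m/z, a 30 min gradient at 3 s cycle
#' time, 18 s FWHM Gaussian elution peaks, and 5% relative intensity noise.
#'
#' @param n_proteins Number of proteins for [generate_proteome()].
#' @param protein_length_range Protein length range (amino acids).
#' @param isolation_window_width Isolation window width (m/z).
#' @param precursor_mz_range Precursor m/z range tiled by isolation windows.
#' @param scan_mz_range Acquired fragment m/z scan range.
#' @param gradient_minutes Gradient length (minutes).
#' @param cycle_time DIA cycle time (seconds).
#' @param elution_fwhm Chromatographic peak full width at half maximum
#'   (seconds).
#' @param interference_rate Fraction of fragment peaks receiving a
#'   co-eluting contaminant contribution.
#' @param noise_sd Relative (multiplicative) intensity noise s.d.
#' @param nce Normalized collision energy the run is acquired at.
#' @param instrument Instrument label carried into training metadata.
#' @param paired_peptide_fraction Fraction of peptides given a co-eluting
#'   adjacent-residue-swap partner peptide (only when
#'   `interference_rate > 0`), so spectrum-centric shared-peak detection has
#'   true positives.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 20, protein_length_range = c(80, 240),
                       isolation_window_width = 24,
                       precursor_mz_range = c(400, 1000),
                       scan_mz_range = c(150, 1800),
                       gradient_minutes = 30, cycle_time = 3,
                       elution_fwhm = 18, interference_rate = 0,
                       noise_sd = 0.05, nce = 30, instrument = "Lumos",
                       paired_peptide_fraction = 0.15, seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins, protein_length_range = protein_length_range,
    isolation_window_width = isolation_window_width,
    precursor_mz_range = precursor_mz_range, scan_mz_range = scan_mz_range,
    gradient_minutes = gradient_minutes, cycle_time = cycle_time,
    elution_fwhm = elution_fwhm, interference_rate = interference_rate,
    noise_sd = noise_sd, nce = nce, instrument = instrument,
    paired_peptide_fraction = paired_peptide_fraction, seed = as.integer(seed)
  )
  if (interference_rate < 0 || interference_rate > 1) {
    stop("configuration error: interference_rate must be in [0, 1]")
  }
  if (diff(precursor_mz_range) <= 0 || diff(scan_mz_range) <= 0 ||
      diff(protein_length_range) < 0 || isolation_window_width <= 0 ||
      gradient_minutes <= 0 || cycle_time <= 0 || elution_fwhm <= 0) {
    stop("configuration error: degenerate range in sim_config")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a random proteome as FASTA text
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Protein length range in amino acids.
#' @param seed Integer seed.
#' @return A single character scalar of FASTA text.
#' @export
generate_proteome <- function(n_proteins, length_range = c(80, 240), seed = 1L) {
  if (n_proteins < 1) stop("configuration error: n_proteins must be >= 1")
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 1) {
    stop("configuration error: invalid protein length range")
  }
  with_local_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    recs <- vapply(seq_len(n_proteins), function(i) {
      s <- paste(sample(names(AA_MONO), lens[i], replace = TRUE), collapse = "")
      paste0(">sim_prot_", sprintf("%04d", i), "\n", s)
    }, character(1))
    paste0(paste(recs, collapse = "\n"), "\n")
  })
}

# Residue descriptors used by the ground-truth rules: Kyte-Doolittle
# hydropathy scaled to [-1, 1], and a gas-phase-basicity-like score in [0, 1].
GT_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
) / 4.5
GT_BASICITY <- c(
  A = 0.40, R = 1.00, N = 0.55, D = 0.30, C = 0.42, Q = 0.58, E = 0.35,
  G = 0.35, H = 0.80, I = 0.48, L = 0.50, K = 0.95, M = 0.52, F = 0.50,
  P = 0.62, S = 0.44, T = 0.46, W = 0.60, Y = 0.52, V = 0.46
)

#' Ground-truth fragmentation and elution model
#'
#' A deterministic, smooth surrogate for the true fragmentation/elution
#' process: fragment intensities are functions of local residue context
#' (basicity/hydropathy of the residues flanking each cleavage site),
#' fragment position, precursor charge and NCE; retention time is a
#' residue-additive hydropathy rule squashed into the gradient span. The
#' same inputs always produce identical outputs, so trained models can be
#' scored against an exact truth.
#'
#' @return An object of class `ground_truth_model` with elements
#'   `intensity_rule(pf, charge, nce, mode)`, `rt_rule(pf, gradient_minutes)`
#'   and `residue_params`.
#' @export
ground_truth_model <- function() {
  residue_params <- list(hydropathy = GT_HYDROPATHY, basicity = GT_BASICITY)

  intensity_rule <- function(pf, charge, nce, mode = "global") {
    pf <- as_peptidoform(pf)
    L <- length(pf)
    if (L < 2L) stop("peptide length must be >= 2")
    r <- strsplit(pf$sequence, "")[[1]]
    hyd <- GT_HYDROPATHY[r]
    bas <- GT_BASICITY[r]
    k <- seq_len(L - 1L)
    u <- bas[k] - bas[k + 1L] + 0.3 * hyd[k]
    v <- 0.4 - u
    pos <- sin(pi * k / L)^0.7
    e0b <- 28 + 6 * stats::plogis(2 * u)
    e0y <- 30 - 5 * stats::plogis(2 * u)
    b1 <- (0.25 + 0.75 * stats::plogis(2 * u)) * pos * exp(-((nce - e0b) / 14)^2)
    y1 <- (0.25 + 0.75 * stats::plogis(2 * v)) * pos * exp(-((nce - e0y) / 14)^2)
    layout <- fragment_layout(mode)
    m <- matrix(0, nrow = L - 1L, ncol = length(layout),
                dimnames = list(NULL, layout))
    m[, "b_z1"] <- b1
    m[, "y_z1"] <- y1
    if (charge >= 2L) {
      fb_b <- cumsum(bas)[k] / k
      fb_y <- (sum(bas) - cumsum(bas)[k]) / (L - k)
      cf <- min(1, 0.5 * (charge - 1))
      m[, "b_z2"] <- b1 * cf * (0.15 + 0.7 * stats::plogis(4 * (fb_b - 0.55)))
      m[, "y_z2"] <- y1 * cf * (0.15 + 0.7 * stats::plogis(4 * (fb_y - 0.55)))
    }
    if (mode == "phospho") {
      sites <- phospho_positions(pf)
      if (length(sites) > 0L) {
        span_b <- vapply(k, function(kk) any(sites <= kk), logical(1))
        span_y <- vapply(k, function(kk) any(sites > kk), logical(1))
        nlf <- 0.35 + 0.3 * stats::plogis(2 * hyd[k])
        m[, "b_z1_nl"] <- m[, "b_z1"] * nlf * span_b
        m[, "b_z2_nl"] <- m[, "b_z2"] * nlf * span_b
        m[, "y_z1_nl"] <- m[, "y_z1"] * nlf * span_y
        m[, "y_z2_nl"] <- m[, "y_z2"] * nlf * span_y
      }
    }
    mx <- max(m)
    if (mx > 0) m <- m / mx
    m
  }

  rt_rule <- function(pf, gradient_minutes = 30) {
    pf <- as_peptidoform(pf)
    r <- strsplit(pf$sequence, "")[[1]]
    n_phos <- sum(pf$mods$name == "Phospho")
    s <- sum(GT_HYDROPATHY[r]) + 0.12 * length(r) - 0.9 * n_phos
    gradient_minutes * (0.06 + 0.88 * stats::plogis(0.5 * s))
  }

  structure(list(intensity_rule = intensity_rule, rt_rule = rt_rule,
                 residue_params = residue_params),
            class = "ground_truth_model")
}

#' Ground-truth fragment intensity matrix
#'
#' Convenience wrapper evaluating the default [ground_truth_model()]'s
#' intensity rule.
#'
#' @param pf A [peptidoform()] or modified-sequence string.
#' @param charge Precursor charge.
#' @param nce Normalized collision energy.
#' @param mode `"global"` or `"phospho"`.
#' @return Fragment intensity matrix in the canonical layout, max entry 1.
#' @export
ground_truth_intensities <- function(pf, charge, nce, mode = "global") {
  ground_truth_model()$intensity_rule(pf, charge, nce, mode)
}

#' Sample detectable peptidoforms from a FASTA proteome
#'
#' Digests the proteome, expands precursors over `charges`, keeps those
#' whose precursor m/z falls inside the simulated precursor range, and
#' samples `n` of them.
#'
#' @param fasta FASTA text (as from [generate_proteome()]), a path, or a
#'   named character vector of protein sequences.
#' @param n Number of precursors to sample.
#' @param config A [sim_config()].
#' @param charges Candidate precursor charges.
#' @param seed Integer seed.
#' @return Tibble with `modified_sequence`, `charge`, `precursor_mz`,
#'   `protein_ids`.
#' @export
sample_peptidoforms <- function(fasta, n, config = sim_config(),
                                charges = c(2L, 3L), seed = 1L) {
  params <- digest_params(charge_range = charges)
  pep <- digest_fasta(fasta, params)
  prec <- expand_precursors(pep, params)
  prec <- dplyr::filter(
    prec,
    .data$precursor_mz >= config$precursor_mz_range[1],
    .data$precursor_mz < config$precursor_mz_range[2]
  )
  if (nrow(prec) < n) {
    stop("data error: only ", nrow(prec), " in-range precursors available, ",
         n, " requested")
  }
  with_local_seed(seed, dplyr::slice_sample(prec, n = n))
}

#' Simulate a DIA run with injected fragment interference
#'
#' Each peptidoform elutes as a Gaussian peak; its fragment sticks appear
#' across consecutive DIA cycles in the isolation window covering the
#' precursor m/z. With probability `interference_rate` a fragment peak
#' additionally receives a contaminant trace with a shifted elution apex
#' (apex offset 1.4-2.6 sigma, magnitude drawn from an independent
#' co-isolated analyte's abundance and fragment-intensity scale), and
#' a fraction of peptides get a co-eluting adjacent-swap partner peptide
#' whose coinciding fragment masses contaminate each other. Both routes are
#' recorded in the returned truth table.
#'
#' @param peptidoforms Tibble with columns `modified_sequence` and `charge`
#'   (e.g. from [sample_peptidoforms()]), or a character vector of modified
#'   sequences (charge 2 assumed).
#' @param ground_truth A [ground_truth_model()].
#' @param config A [sim_config()].
#' @return An object of class `simulated_run`: list with `run` (a
#'   `dia_run`), `report` (detection-report tibble), `truth_intensities`
#'   (named list of max-1-normalized matrices keyed `"sequence/charge"`),
#'   `truth_shared` (per-cell tibble with `shared` = injected interference
#'   and `collision` = coincidental m/z overlap between unrelated detected
#'   peptides), `pairs`, `rt_factor` and `config`.
#' @export
simulate_dia_run <- function(peptidoforms, ground_truth = ground_truth_model(),
                             config = sim_config()) {
  if (is.character(peptidoforms)) {
    peptidoforms <- tibble::tibble(modified_sequence = peptidoforms, charge = 2L)
  }
  peptidoforms <- tibble::as_tibble(peptidoforms)
  if (nrow(peptidoforms) == 0L) {
    stop("configuration error: empty peptidoform list")
  }
  stopifnot(all(c("modified_sequence", "charge") %in% names(peptidoforms)))
  with_local_seed(config$seed, simulate_dia_run_impl(peptidoforms, ground_truth, config))
}

simulate_dia_run_impl <- function(peptidoforms, gt, cfg) {
  recs <- dplyr::distinct(peptidoforms, .data$modified_sequence, .data$charge)
  recs$pf <- lapply(recs$modified_sequence, parse_modified_sequence)
  recs$precursor_mz <- purrr::map2_dbl(recs$pf, recs$charge, precursor_mz)
  out_of_range <- recs$precursor_mz < cfg$precursor_mz_range[1] |
    recs$precursor_mz >= cfg$precursor_mz_range[2]
  if (any(out_of_range)) {
    stop("data error: precursor m/z outside the simulated precursor range: ",
         recs$modified_sequence[which(out_of_range)[1]])
  }
  mode <- if (any(vapply(recs$pf, function(p) any(p$mods$name == "Phospho"),
                         logical(1)))) "phospho" else "global"

  # co-eluting partner peptides (adjacent-residue swap: same composition,
  # same RT under the additive rule, most fragment masses coincide)
  recs$pair_of <- NA_integer_
  n0 <- nrow(recs)
  if (cfg$interference_rate > 0 && cfg$paired_peptide_fraction > 0) {
    n_pair <- round(cfg$paired_peptide_fraction * n0)
    cand <- sample(n0, n0)
    made <- 0L
    for (i in cand) {
      if (made >= n_pair) break
      pf <- recs$pf[[i]]
      if (nrow(pf$mods) > 0L) next
      s <- strsplit(pf$sequence, "")[[1]]
      L <- length(s)
      if (L < 4L) next
      pos_ok <- which(s[2:(L - 2L)] != s[3:(L - 1L)]) + 1L
      if (length(pos_ok) == 0L) next
      j <- if (length(pos_ok) == 1L) pos_ok else sample(pos_ok, 1L)
      s2 <- s; s2[c(j, j + 1L)] <- s2[c(j + 1L, j)]
      seq2 <- paste(s2, collapse = "")
      if (seq2 %in% recs$modified_sequence) next
      recs <- dplyr::bind_rows(recs, tibble::tibble(
        modified_sequence = seq2, charge = recs$charge[i],
        pf = list(peptidoform(seq2)),
        precursor_mz = recs$precursor_mz[i], pair_of = i
      ))
      made <- made + 1L
    }
    # make the pairing symmetric
    for (k in which(!is.na(recs$pair_of))) recs$pair_of[recs$pair_of[k]] <- k
  }
  n <- nrow(recs)
  recs$abundance <- stats::rlnorm(n, meanlog = log(1e4), sdlog = 0.6)
  recs$apex_rt <- vapply(recs$pf, gt$rt_rule, numeric(1),
                         gradient_minutes = cfg$gradient_minutes) +
    stats::rnorm(n, sd = 0.02)

  sigma <- cfg$elution_fwhm / 60 / (2 * sqrt(2 * log(2)))
  half_width <- sigma * sqrt(2 * log(20))          # 5%-of-apex crossing
  # boundaries are reported at the first sampled cycle at or below the 5%
  # crossing (one cycle beyond it), as a peak picker operating on the
  # sampled chromatogram would place them
  cycle_min <- cfg$cycle_time / 60
  recs$rt_start <- recs$apex_rt - half_width - cycle_min
  recs$rt_stop <- recs$apex_rt + half_width + cycle_min

  # isolation windows (half-open), only those that hold at least one record
  win_starts <- seq(cfg$precursor_mz_range[1], cfg$precursor_mz_range[2] - 1e-9,
                    by = cfg$isolation_window_width)
  recs$window <- findInterval(recs$precursor_mz, win_starts)
  used_windows <- sort(unique(recs$window))

  n_cycles <- max(1L, floor(cfg$gradient_minutes / cycle_min))
  n_used <- length(used_windows)
  # spectrum grid: one MS2 spectrum per used window per cycle
  grid <- tidyr::expand_grid(cycle = seq_len(n_cycles), wslot = seq_len(n_used))
  grid$window <- used_windows[grid$wslot]
  grid$rt <- (grid$cycle - 1L) * cycle_min + (grid$wslot - 0.5) / n_used * cycle_min
  grid$spec_id <- seq_len(nrow(grid))
  spec_lookup <- split(grid$spec_id, grid$window)   # per window, cycle-ordered

  # truth intensity matrices and fragment tables
  recs$truth <- purrr::map2(recs$pf, recs$charge,
                            ~ gt$intensity_rule(.x, .y, cfg$nce, mode))
  frag_tabs <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- enumerate_fragments(recs$pf[[i]], recs$charge[i], mode)
    fr$value <- recs$truth[[i]][cbind(fr$row, match(fr$col, fragment_layout(mode)))]
    fr <- fr[fr$value > 0 & fr$mz >= cfg$scan_mz_range[1] &
               fr$mz <= cfg$scan_mz_range[2], ]
    fr$rec <- i
    frag_tabs[[i]] <- fr
  }
  frags <- dplyr::bind_rows(frag_tabs)

  # Gaussian elution contributions per (record, fragment, cycle)
  contribs <- vector("list", n + 1L)
  # generate sticks out to 3 sigma, and always past the reported boundaries
  gen_span <- max(3 * sigma, half_width + 1.5 * cycle_min)
  for (i in seq_len(n)) {
    sp <- spec_lookup[[as.character(recs$window[i])]]
    t_sp <- grid$rt[sp]
    keep <- abs(t_sp - recs$apex_rt[i]) <= gen_span
    if (!any(keep)) next
    sp <- sp[keep]; t_sp <- t_sp[keep]
    fr <- frags[frags$rec == i, ]
    if (nrow(fr) == 0L) next
    prof <- exp(-(t_sp - recs$apex_rt[i])^2 / (2 * sigma^2))
    contribs[[i]] <- tibble::tibble(
      spec_id = rep(sp, each = nrow(fr)),
      mz = rep(fr$mz, times = length(sp)),
      intensity = recs$abundance[i] * rep(fr$value, times = length(sp)) *
        rep(prof, each = nrow(fr)),
      contrib = i, kind = "peptide"
    )
  }

  # injected contaminants: shifted-apex traces at existing fragment m/z
  injected <- tibble::tibble(rec = integer(), row = integer(), col = character())
  if (cfg$interference_rate > 0 && nrow(frags) > 0L) {
    hit <- stats::runif(nrow(frags)) < cfg$interference_rate
    hits <- frags[hit, ]
    if (nrow(hits) > 0L) {
      hits$shift <- sample(c(-1, 1), nrow(hits), replace = TRUE) *
        stats::runif(nrow(hits), 1.4, 2.6) * sigma
      # the contaminant is a fragment of an independent co-isolated analyte:
      # its magnitude scales with that analyte's abundance (comparable to the
      # recipient peptide's) and its own relative fragment intensity, not
      # with the intensity of the fragment it happens to land on
      hits$amp <- stats::runif(nrow(hits), 0.5, 3.0) *
        recs$abundance[hits$rec] * stats::runif(nrow(hits), 0.05, 1)
      cont_rows <- vector("list", nrow(hits))
      for (h in seq_len(nrow(hits))) {
        i <- hits$rec[h]
        apex_c <- recs$apex_rt[i] + hits$shift[h]
        sp <- spec_lookup[[as.character(recs$window[i])]]
        t_sp <- grid$rt[sp]
        keep <- abs(t_sp - apex_c) <= gen_span
        if (!any(keep)) next
        cont_rows[[h]] <- tibble::tibble(
          spec_id = sp[keep], mz = hits$mz[h],
          intensity = hits$amp[h] *
            exp(-(t_sp[keep] - apex_c)^2 / (2 * sigma^2)),
          contrib = -h, kind = "contaminant"
        )
      }
      contribs[[n + 1L]] <- dplyr::bind_rows(cont_rows)
      injected <- tibble::tibble(rec = hits$rec, row = hits$row, col = hits$col)
    }
  }
  contribs <- dplyr::bind_rows(contribs)

  # assemble centroided spectra (merge identical m/z sticks, add noise)
  sticks <- dplyr::summarise(
    dplyr::group_by(contribs, .data$spec_id, .data$mz),
    intensity = sum(.data$intensity), .groups = "drop"
  )
  if (cfg$noise_sd > 0 && nrow(sticks) > 0L) {
    sticks$intensity <- pmax(
      sticks$intensity * (1 + cfg$noise_sd * stats::rnorm(nrow(sticks))),
      1e-6 * sticks$intensity
    )
  }
  sticks <- dplyr::arrange(sticks, .data$spec_id, .data$mz)
  stick_split <- split(seq_len(nrow(sticks)), sticks$spec_id)
  spectra <- vector("list", nrow(grid))
  for (sidx in seq_len(nrow(grid))) {
    rows <- stick_split[[as.character(sidx)]]
    w <- grid$window[sidx]
    spectra[[sidx]] <- list(
      mz = if (is.null(rows)) numeric(0) else sticks$mz[rows],
      intensity = if (is.null(rows)) numeric(0) else sticks$intensity[rows],
      rt = grid$rt[sidx],
      iso_low = win_starts[w], iso_high = win_starts[w] + cfg$isolation_window_width,
      scan_low = cfg$scan_mz_range[1], scan_high = cfg$scan_mz_range[2]
    )
  }
  run <- new_dia_run(spectra)
  # new_dia_run reorders by rt; grid rt is already strictly increasing within
  # construction order, so spec_id indexing is preserved

  # per-cell interference truth at the apex spectrum
  truth_shared <- compute_truth_shared(recs, frags, contribs, grid, spec_lookup)

  report <- tibble::tibble(
    modified_sequence = recs$modified_sequence,
    charge = recs$charge,
    q_value = stats::runif(n, 0, 0.01),
    apex_rt = recs$apex_rt,
    rt_start = recs$rt_start, rt_stop = recs$rt_stop,
    site_confidence = NA_real_,
    precursor_mz = recs$precursor_mz,
    protein_ids = NA_character_
  )
  truth_intensities <- stats::setNames(
    recs$truth, paste0(recs$modified_sequence, "/", recs$charge)
  )
  pairs <- tibble::tibble(
    rec = which(!is.na(recs$pair_of)),
    partner = recs$pair_of[!is.na(recs$pair_of)]
  )
  structure(
    list(run = run, report = report, truth_intensities = truth_intensities,
         truth_shared = truth_shared, pairs = pairs,
         rt_factor = max(recs$apex_rt), mode = mode, config = cfg),
    class = "simulated_run"
  )
}

compute_truth_shared <- function(recs, frags, contribs, grid, spec_lookup) {
  if (nrow(frags) == 0L) {
    return(tibble::tibble(modified_sequence = character(), charge = integer(),
                          row = integer(), col = character(), mz = numeric(),
                          shared = logical(), collision = logical()))
  }
  # apex spectrum per record
  apex_spec <- vapply(seq_len(nrow(recs)), function(i) {
    sp <- spec_lookup[[as.character(recs$window[i])]]
    sp[which.min(abs(grid$rt[sp] - recs$apex_rt[i]))]
  }, integer(1))
  frags$apex_spec <- apex_spec[frags$rec]
  mz_key <- function(m) sprintf("%.6f", m)
  contribs$k <- paste0(contribs$spec_id, "@", mz_key(contribs$mz))
  by_key <- split(seq_len(nrow(contribs)), contribs$k)
  by_mz <- split(seq_len(nrow(contribs)), mz_key(contribs$mz))
  fk <- paste0(frags$apex_spec, "@", mz_key(frags$mz))
  # spectra inside each record's integration window, for collision scanning
  bound_specs <- lapply(seq_len(nrow(recs)), function(i) {
    sp <- spec_lookup[[as.character(recs$window[i])]]
    sp[grid$rt[sp] >= recs$rt_start[i] & grid$rt[sp] <= recs$rt_stop[i]]
  })
  shared <- logical(nrow(frags))
  collision <- logical(nrow(frags))
  partner_of <- recs$pair_of
  fmz <- mz_key(frags$mz)
  for (f in seq_len(nrow(frags))) {
    rec <- frags$rec[f]
    rows <- by_key[[fk[f]]]
    if (!is.null(rows)) {
      others <- contribs$contrib[rows][contribs$contrib[rows] != rec]
      if (length(others) > 0L) {
        has_cont <- any(others < 0L)
        is_partner <- !is.na(partner_of[rec]) & others == partner_of[rec]
        shared[f] <- has_cont || any(is_partner)
      }
    }
    if (!shared[f]) {
      # an interference-free label only stands if no other analyte touches
      # this m/z anywhere inside the integration window; coincidental
      # overlaps are flagged as collisions and reported separately
      rows_mz <- by_mz[[fmz[f]]]
      other_rows <- rows_mz[contribs$contrib[rows_mz] != rec]
      if (length(other_rows) > 0L) {
        collision[f] <- any(contribs$spec_id[other_rows] %in%
                              bound_specs[[rec]])
      }
    }
  }
  tibble::tibble(
    modified_sequence = recs$modified_sequence[frags$rec],
    charge = recs$charge[frags$rec],
    row = frags$row, col = frags$col, mz = frags$mz,
    shared = shared, collision = collision
  )
}

#' @export
print.simulated_run <- function(x, ...) {
  cat("<simulated_run>", nrow(x$report), "detected precursors,",
      length(x$run$spectra), "MS2 spectra,",
      sum(x$truth_shared$shared), "interfered fragment cells\n")
  invisible(x)
}
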
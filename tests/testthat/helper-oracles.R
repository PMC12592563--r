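# Independent oracles and shared fixtures.
#
# The oracles deliberately re-derive quantities from their own constants and
# by brute force, so they share no code path with the implementation under
# test.

# residue masses re-stated independently for the oracle
ORACLE_RESIDUES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
ORACLE_PROTON <- 1.007276466
ORACLE_WATER <- 18.010565
ORACLE_PHOSPHO_LOSS <- 97.976896

# brute-force fragment m/z by explicit residue summation
oracle_fragment_mz <- function(sequence, mod_pos, mod_delta, series, ordinal,
                               charge, loss = "none") {
  res <- ORACLE_RESIDUES[strsplit(sequence, "")[[1]]]
  per_res <- rep(0, length(res))
  if (length(mod_pos) > 0) {
    for (i in seq_along(mod_pos)) {
      p <- max(1, mod_pos[i])
      per_res[p] <- per_res[p] + mod_delta[i]
    }
  }
  masses <- res + per_res
  neutral <- if (series == "b") {
    sum(masses[seq_len(ordinal)])
  } else {
    sum(masses[(length(masses) - ordinal + 1):length(masses)]) + ORACLE_WATER
  }
  if (loss == "phospho_98") neutral <- neutral - ORACLE_PHOSPHO_LOSS
  (neutral + charge * ORACLE_PROTON) / charge
}

# brute-force tryptic digestion: every substring, checked against the
# cleavage rule directly
oracle_digest <- function(protein, max_missed, len_range) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  is_site <- chars %in% c("K", "R")
  out <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      # peptide [i, j]: must start after a cleavage site (or protein start)
      if (i > 1 && !is_site[i - 1]) next
      # must end at a cleavage site or protein end
      if (j < n && !is_site[j]) next
      missed <- sum(is_site[i:j]) - (if (is_site[j]) 1 else 0)
      if (missed > max_missed) next
      L <- j - i + 1
      if (L < len_range[1] || L > len_range[2]) next
      out <- c(out, paste(chars[i:j], collapse = ""))
    }
  }
  unique(out)
}

random_peptide <- function(len, ct = c("K", "R")) {
  paste0(paste(sample(setdiff(names(ORACLE_RESIDUES), c("K", "R")),
                      len - 1, replace = TRUE), collapse = ""),
         sample(ct, 1))
}

# small shared simulated runs, built once per test session
.fixtures <- new.env(parent = emptyenv())

fixture_sim_clean <- function() {
  if (is.null(.fixtures$sim_clean)) {
    fa <- generate_proteome(20, c(90, 180), seed = 5)
    cfg <- sim_config(interference_rate = 0, noise_sd = 0, nce = 30,
                      gradient_minutes = 10, seed = 3)
    peps <- sample_peptidoforms(fa, 25, cfg, charges = 2L, seed = 8)
    .fixtures$sim_clean <- list(sim = simulate_dia_run(peps, config = cfg),
                                cfg = cfg, peps = peps)
  }
  .fixtures$sim_clean
}

fixture_sim_interfered <- function() {
  if (is.null(.fixtures$sim_intf)) {
    fa <- generate_proteome(25, c(90, 180), seed = 6)
    cfg <- sim_config(interference_rate = 0.3, noise_sd = 0.05, nce = 30,
                      gradient_minutes = 10, seed = 4)
    peps <- sample_peptidoforms(fa, 40, cfg, charges = 2L, seed = 9)
    sim <- simulate_dia_run(peps, config = cfg)
    .fixtures$sim_intf <- list(sim = sim, cfg = cfg,
                               labels = label_shared_peaks(sim$run, sim$report))
  }
  .fixtures$sim_intf
}

# a tiny exact spectrum containing precisely the theoretical fragments of a
# peptidoform (plus optional extra peaks), for match_peaks tests
exact_spectrum <- function(modified_sequence, charge, extra_mz = numeric(0),
                           extra_intensity = numeric(0),
                           intensities = NULL,
                           scan_range = c(0, 1e5)) {
  fr <- enumerate_fragments(modified_sequence, charge)
  mz <- c(fr$mz, extra_mz)
  int <- c(if (is.null(intensities)) rep(100, nrow(fr)) else intensities,
           extra_intensity)
  ord <- order(mz)
  list(mz = mz[ord], intensity = int[ord], rt = 10,
       iso_low = 400, iso_high = 424,
       scan_low = scan_range[1], scan_high = scan_range[2])
}
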
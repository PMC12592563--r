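test_that("proteome generation is deterministic with the right shape", {
  a <- generate_proteome(1, c(50, 50), seed = 7)
  b <- generate_proteome(1, c(50, 50), seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_proteome(1, c(50, 50), seed = 8)))

  fa <- generate_proteome(3, c(60, 80), seed = 1)
  lines <- strsplit(fa, "\n")[[1]]
  expect_equal(sum(grepl("^>", lines)), 3L)
  seqs <- lines[!grepl("^>", lines) & nzchar(lines)]
  expect_true(all(strsplit(paste(seqs, collapse = ""), "")[[1]] %in%
                    names(residue_masses())))
  expect_error(generate_proteome(0), "configuration error")
  expect_error(generate_proteome(2, c(10, 5)), "configuration error")
})

test_that("ground-truth intensities are deterministic, normalized, NCE-sensitive", {
  m1 <- ground_truth_intensities("PEPTIDK", 2, 30)
  m2 <- ground_truth_intensities("PEPTIDK", 2, 30)
  expect_identical(m1, m2)
  expect_equal(max(m1), 1)
  expect_true(all(m1 >= 0))
  expect_false(isTRUE(all.equal(m1, ground_truth_intensities("PEPTIDK", 2, 35))))
  # no charge-2 fragments for 1+ precursors
  m3 <- ground_truth_intensities("PEPTIDK", 1, 30)
  expect_true(all(m3[, c("b_z2", "y_z2")] == 0))
})

test_that("ground-truth RT lies within the gradient span", {
  gt <- ground_truth_model()
  set.seed(11)
  for (i in 1:50) {
    rt <- gt$rt_rule(random_peptide(sample(6:20, 1)), gradient_minutes = 30)
    expect_gte(rt, 0)
    expect_lte(rt, 30)
  }
})

test_that("simulation is deterministic for a fixed seed", {
  fx <- fixture_sim_clean()
  sim2 <- simulate_dia_run(fx$peps, config = fx$cfg)
  expect_equal(sim2$report, fx$sim$report)
  expect_identical(sim2$truth_shared, fx$sim$truth_shared)
  i <- which(vapply(fx$sim$run$spectra, function(s) length(s$mz) > 0,
                    logical(1)))[1]
  expect_identical(sim2$run$spectra[[i]], fx$sim$run$spectra[[i]])
})

test_that("interference-free runs carry no interference truth labels", {
  fx <- fixture_sim_clean()
  expect_false(any(fx$sim$truth_shared$shared))
})

test_that("simulation rejects invalid inputs", {
  expect_error(simulate_dia_run(tibble::tibble(modified_sequence = character(),
                                               charge = integer())),
               "configuration error")
  expect_error(sim_config(interference_rate = 1.5), "configuration error")
  # precursor m/z far below the simulated precursor range
  expect_error(simulate_dia_run(tibble::tibble(modified_sequence = "GGGK",
                                               charge = 2L)),
               "outside the simulated precursor range")
})

test_that("each fragment XIC peaks at the cycle nearest the reported apex", {
  fx <- fixture_sim_clean()
  sim <- fx$sim
  set.seed(3)
  for (i in sample(nrow(sim$report), 8)) {
    rec <- sim$report[i, ]
    fr <- enumerate_fragments(rec$modified_sequence, rec$charge)
    truth <- sim$truth_intensities[[paste0(rec$modified_sequence, "/", rec$charge)]]
    fr$value <- truth[cbind(fr$row, match(fr$col, colnames(truth)))]
    fr <- fr[order(-fr$value), ]
    xic <- extract_xic(sim$run, fr$mz[1], rec, tol_ppm = 10)
    expect_gt(length(xic$times), 3)
    t_apex <- xic$times[which.max(xic$values)]
    cycle_min <- fx$cfg$cycle_time / 60
    expect_lte(abs(t_apex - rec$apex_rt), cycle_min / 2 + 1e-9)
  }
})

test_that("re-annotating a clean run recovers the truth intensities", {
  fx <- fixture_sim_clean()
  sim <- fx$sim
  coll <- sim$truth_shared[sim$truth_shared$collision, ]
  n_checked <- 0
  for (i in seq_len(nrow(sim$report))) {
    rec <- sim$report[i, ]
    truth <- sim$truth_intensities[[paste0(rec$modified_sequence, "/", rec$charge)]]
    ann <- match_peaks(sim$run$spectra[[select_apex_spectrum(sim$run, rec)]],
                       rec$modified_sequence, rec$charge, tol_ppm = 10)
    m <- ann$intensity
    ok <- ann$mask == "use" & !is.na(ann$matched_peak)
    # skip cells hit by coincidental m/z collisions (counted separately)
    if (nrow(coll) > 0) {
      cc <- coll[coll$modified_sequence == rec$modified_sequence &
                   coll$charge == rec$charge, ]
      if (nrow(cc) > 0) ok[cbind(cc$row, match(cc$col, ann$layout))] <- FALSE
    }
    if (sum(ok) < 2 || max(m[ok]) == 0) next
    got <- m / max(m[ok])
    want <- truth / max(truth[ok])
    expect_lt(max(abs(got[ok] - want[ok])), 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)
})

test_that("interfered cells have a real contaminant contribution at the apex", {
  fx <- fixture_sim_interfered()
  sim <- fx$sim
  shared_cells <- sim$truth_shared[sim$truth_shared$shared, ]
  expect_gt(nrow(shared_cells), 20)
  # the observed apex intensity of an interfered cell exceeds what the clean
  # profile alone would give, for a clear majority of interfered cells
  # (noise and partner-peptide sharing make a strict per-cell bound unsound)
  n_above <- 0
  for (j in seq_len(nrow(shared_cells))) {
    tc <- shared_cells[j, ]
    rec <- sim$report[sim$report$modified_sequence == tc$modified_sequence &
                        sim$report$charge == tc$charge, ][1, ]
    ann <- match_peaks(sim$run$spectra[[select_apex_spectrum(sim$run, rec)]],
                       rec$modified_sequence, rec$charge)
    obs <- ann$intensity[tc$row, tc$col]
    if (obs > 0) n_above <- n_above + 1
  }
  expect_gt(n_above / nrow(shared_cells), 0.95)
})
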
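test_that("Spearman over unmasked cells ignores masked perturbations", {
  pred <- matrix(1:12 / 12, 3, 4)
  obs <- pred
  mask <- matrix("use", 3, 4)
  expect_equal(spearman_unmasked(pred, obs, mask), 1)
  expect_equal(spearman_unmasked(pred, matrix(rev(pred), 3, 4), mask), -1)

  mask2 <- mask; mask2[1, ] <- "shared"
  obs2 <- obs; obs2[1, ] <- runif(4) * 100
  expect_equal(spearman_unmasked(pred, obs2, mask2),
               spearman_unmasked(pred, obs, mask2))

  mask3 <- matrix("shared", 3, 4); mask3[1, 1:2] <- "use"
  expect_message(r <- spearman_unmasked(pred, obs, mask3), "fewer than 3")
  expect_true(is.na(r))
})

test_that("FDP bounds match the closed-form equations", {
  est <- estimate_fdp(tibble::tibble(
    n_target = 90, n_entrapment = 10,
    n_entrapment_target_undiscovered = 4,
    n_entrapment_above_target_discovered = 3
  ))
  expect_equal(est$upper, 0.20)
  expect_equal(est$lower, 0.10)

  est0 <- estimate_fdp(tibble::tibble(
    n_target = 50, n_entrapment = 0,
    n_entrapment_target_undiscovered = 0,
    n_entrapment_above_target_discovered = 0
  ))
  expect_equal(est0$upper, 0)
  expect_equal(est0$lower, 0)

  # all entrapments beat their discovered partners: upper = 3 N_E/(N_T+N_E)
  est3 <- estimate_fdp(tibble::tibble(
    n_target = 80, n_entrapment = 20,
    n_entrapment_target_undiscovered = 0,
    n_entrapment_above_target_discovered = 20
  ))
  expect_equal(est3$upper, 3 * 20 / 100)

  estna <- estimate_fdp(tibble::tibble(
    n_target = 0, n_entrapment = 0,
    n_entrapment_target_undiscovered = 0,
    n_entrapment_above_target_discovered = 0
  ))
  expect_true(is.na(estna$upper))
})

test_that("entrapment counting matches a brute-force recount and lower <= upper", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    pairs <- tibble::tibble(
      target_score = round(runif(n, 0, 5), 2),
      entrapment_score = round(runif(n, 0, 5), 2)
    )
    s <- round(runif(1, 0, 5), 2)
    cnt <- count_entrapment(pairs, s)
    # brute-force recount
    nt <- ne <- ne_t_und <- ne_above <- 0
    for (j in seq_len(n)) {
      td <- pairs$target_score[j] >= s
      ed <- pairs$entrapment_score[j] >= s
      if (td) nt <- nt + 1
      if (ed) ne <- ne + 1
      if (ed && !td) ne_t_und <- ne_t_und + 1
      if (ed && td && pairs$entrapment_score[j] > pairs$target_score[j]) {
        ne_above <- ne_above + 1
      }
    }
    expect_equal(unlist(cnt),
                 c(n_target = nt, n_entrapment = ne,
                   n_entrapment_target_undiscovered = ne_t_und,
                   n_entrapment_above_target_discovered = ne_above))
    est <- estimate_fdp(cnt)
    if (!is.na(est$lower)) expect_lte(est$lower, est$upper)
  }
})

test_that("fdp_sweep reproduces per-cutoff estimates from a discovery table", {
  disc <- tibble::tibble(
    peptide = c("AK", "CK", "DK", "EK", "ak", "ck", "dk"),
    score = c(5, 4, 3, 1, 4.5, 2, 0.5),
    is_entrapment = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    pair_id = c(1, 2, 3, 4, 1, 2, 3)
  )
  sw <- fdp_sweep(disc, cutoffs = c(2, 4))
  at2 <- sw[sw$cutoff == 2, ]
  expect_equal(at2$n_target, 3)       # 5, 4, 3
  expect_equal(at2$n_entrapment, 2)   # 4.5, 2
  expect_equal(at2$lower, 2 / 5)
  at4 <- sw[sw$cutoff == 4, ]
  # pair 1 at cutoff 4: target 5 and entrapment 4.5 both discovered, and the
  # entrapment scores below its partner
  expect_equal(at4$n_entrapment_target_undiscovered, 0)
  expect_equal(at4$n_entrapment_above_target_discovered, 0)
  expect_equal(at4$upper,
               (at4$n_entrapment + at4$n_entrapment_target_undiscovered +
                  2 * at4$n_entrapment_above_target_discovered) /
                 (at4$n_target + at4$n_entrapment))
})

test_that("entrapment databases fix the C-terminus and convert I to L", {
  db <- build_entrapment_db(c("PEPTIDEK", "IVANK"), seed = 3)
  p <- db[db$target == "PEPTLDEK", ]   # I -> L applied to the target too
  expect_equal(nrow(p), 1L)
  ent <- p$entrapment
  expect_equal(substr(ent, nchar(ent), nchar(ent)), "K")
  expect_false(ent == p$target)
  expect_equal(sort(strsplit(ent, "")[[1]]), sort(strsplit(p$target, "")[[1]]))
  expect_false(grepl("I", paste(db$entrapment, collapse = "")))

  # degenerate prefix: no distinct permutation exists, so the target drops
  db2 <- build_entrapment_db(c("IK", "AAK", "PEPK"), seed = 1)
  expect_false("LK" %in% db2$target)
  expect_false("AAK" %in% db2$target)
  expect_setequal(attr(db2, "dropped"), c("IK", "AAK"))

  expect_identical(build_entrapment_db(c("PEPTIDEK", "IVANK"), seed = 3), db)
})

test_that("entropy similarity hits its closed-form extremes and stays in [0,1]", {
  a <- cbind(mz = c(100, 200, 300), intensity = c(1, 2, 3))
  expect_equal(spectral_entropy_similarity(a, a), 1)
  b <- cbind(mz = c(400, 500), intensity = c(1, 1))
  expect_equal(spectral_entropy_similarity(a, b), 0)
  expect_equal(spectral_entropy_similarity(a, b),
               spectral_entropy_similarity(b, a))
  set.seed(77)
  for (i in 1:40) {
    n1 <- sample(2:10, 1)
    s1 <- cbind(mz = sort(runif(n1, 100, 1500)), intensity = runif(n1) + 0.01)
    s2 <- cbind(mz = sort(runif(4, 100, 1500)), intensity = runif(4) + 0.01)
    sim <- spectral_entropy_similarity(s1, s2)
    expect_gte(sim, 0); expect_lte(sim, 1)
    expect_equal(sim, spectral_entropy_similarity(s2, s1), tolerance = 1e-12)
  }
  expect_error(spectral_entropy_similarity(a[0, , drop = FALSE], b),
               "undefined")
  # peaks within tolerance merge into one dimension
  c1 <- cbind(mz = 500, intensity = 1)
  c2 <- cbind(mz = 500 * (1 + 3e-6), intensity = 1)
  expect_equal(spectral_entropy_similarity(c1, c2, merge_tol_ppm = 10), 1)
})

test_that("NCE calibration recovers the acquisition energy and honors ties", {
  fx <- fixture_sim_clean()   # noise-free run acquired at NCE 30
  sim <- fx$sim
  obs <- lapply(seq_len(nrow(sim$report)), function(i) {
    rec <- sim$report[i, ]
    ann <- match_peaks(sim$run$spectra[[select_apex_spectrum(sim$run, rec)]],
                       rec$modified_sequence, rec$charge)
    keep <- !is.na(ann$matched_peak) & ann$mask == "use" & ann$intensity > 0
    list(modified_sequence = rec$modified_sequence, charge = rec$charge,
         spectrum = cbind(mz = ann$theo_mz[keep],
                          intensity = ann$intensity[keep]))
  })
  cal <- calibrate_nce(ground_truth_model(), obs, grid = 24:36,
                       scan_range = fx$cfg$scan_mz_range)
  expect_equal(cal$optimal_nce, 30)
  expect_equal(max(cal$grid$median_similarity),
               cal$grid$median_similarity[cal$grid$nce == 30])

  # single-point grid
  cal1 <- calibrate_nce(ground_truth_model(), obs[1:5], grid = 27,
                        scan_range = fx$cfg$scan_mz_range)
  expect_equal(cal1$optimal_nce, 27)

  # all-equal medians: the tie goes to the lowest NCE
  flat_obs <- obs[1:3]
  cal2 <- calibrate_nce(ground_truth_model(), flat_obs, grid = c(25, 25, 25))
  expect_equal(cal2$optimal_nce, 25)
})

test_that("plot helpers return ggplot objects", {
  fx <- fixture_sim_interfered()
  rec <- fx$sim$report[1, ]
  x <- extract_xic(fx$sim$run, fx$labels$fragment_mz[1], rec)
  expect_s3_class(plot_xic(x), "ggplot")
  sw <- fdp_sweep(tibble::tibble(
    peptide = c("AK", "ak"), score = c(2, 1),
    is_entrapment = c(FALSE, TRUE), pair_id = c(1, 1)
  ))
  expect_s3_class(plot_fdp_sweep(sw), "ggplot")
})
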
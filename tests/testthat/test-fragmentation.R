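test_that("monoisotopic peptide masses match independent residue summation", {
  expect_equal(peptide_mono_mass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(peptide_mono_mass("PEPTIDE"), 799.35997, tolerance = 1e-6)
  base <- peptide_mono_mass("PEPTCK")
  modded <- peptide_mono_mass(parse_modified_sequence("PEPTC(UniMod:4)K"))
  expect_equal(modded - base, 57.021464, tolerance = 1e-9)
})

test_that("fragment m/z matches frozen values and the charge identity", {
  expect_equal(fragment_mz("PE", "b", 1, 1), 98.06004, tolerance = 1e-5)
  expect_equal(fragment_mz("PE", "y", 1, 1), 148.06043, tolerance = 1e-5)
  for (series in c("b", "y")) {
    z1 <- fragment_mz("PEPTIDEK", series, 4, 1)
    z2 <- fragment_mz("PEPTIDEK", series, 4, 2)
    expect_equal(z2, (z1 + 1.007276466) / 2, tolerance = 1e-9)
  }
  expect_error(fragment_mz("PE", "b", 2, 1), "out of range")
})

test_that("fragment m/z agrees with the brute-force oracle on random peptidoforms", {
  set.seed(101)
  for (i in 1:150) {
    len <- sample(4:20, 1)
    seq <- random_peptide(len)
    has_mod <- runif(1) < 0.4
    mod_pos <- if (has_mod) sample(len, 1) else integer(0)
    mod_delta <- if (has_mod) 79.966331 else numeric(0)
    pf <- peptidoform(seq, if (has_mod) {
      tibble::tibble(position = mod_pos, mass_delta = mod_delta, name = "Phospho")
    } else NULL)
    series <- sample(c("b", "y"), 1)
    ordinal <- sample(len - 1, 1)
    charge <- sample(1:2, 1)
    expect_equal(
      fragment_mz(pf, series, ordinal, charge),
      oracle_fragment_mz(seq, mod_pos, mod_delta, series, ordinal, charge),
      tolerance = 1e-6
    )
  }
})

test_that("b and y fragment masses conserve the precursor mass", {
  set.seed(7)
  for (i in 1:20) {
    seq <- random_peptide(sample(5:15, 1))
    L <- nchar(seq)
    total <- peptide_mono_mass(seq)
    for (k in seq_len(L - 1)) {
      b_neutral <- fragment_mz(seq, "b", k, 1) - 1.007276466
      y_neutral <- fragment_mz(seq, "y", L - k, 1) - 1.007276466
      expect_equal(b_neutral + y_neutral, total, tolerance = 1e-9)
    }
  }
})

test_that("fragment enumeration has the expected combinatorics", {
  expect_equal(nrow(enumerate_fragments("PEPTIDK", 2)), 24)
  expect_equal(nrow(enumerate_fragments("PEPTIDK", 1)), 12)
  # phospho on position 3 of a 7-mer: spanning fragments by brute force
  pf <- parse_modified_sequence("PES(UniMod:21)TIDK")
  fr <- enumerate_fragments(pf, 2, mode = "phospho")
  nl <- fr[fr$loss == "phospho_98", ]
  expect_setequal(unique(nl$ordinal[nl$series == "b"]), 3:6)
  expect_setequal(unique(nl$ordinal[nl$series == "y"]), 5:6)
  expect_setequal(unique(nl$charge), c(1L, 2L))
})

test_that("match_peaks matches exact peaks, breaks ties to the nearest, and masks", {
  sp <- exact_spectrum("PEPTIDK", 2)
  ann <- match_peaks(sp, "PEPTIDK", 2, tol_ppm = 5)
  fr <- enumerate_fragments("PEPTIDK", 2)
  expect_equal(sum(!is.na(ann$matched_peak)), nrow(fr))
  idx <- cbind(fr$row, match(fr$col, ann$layout))
  expect_true(all(abs(ann$theo_mz[idx] - sp$mz[ann$matched_peak[idx]]) < 1e-9))

  # two peaks inside tolerance: the nearer one wins
  target <- fragment_mz("PEPTIDK", "b", 3, 1)
  sp2 <- list(mz = sort(c(target * (1 + 2e-6), target * (1 - 4e-6))),
              intensity = c(10, 20), rt = 1, iso_low = 400, iso_high = 424,
              scan_low = 0, scan_high = 1e5)
  ann2 <- match_peaks(sp2, "PEPTIDK", 2, tol_ppm = 10)
  cell <- which(!is.na(ann2$matched_peak))[
    which.min(abs(ann2$theo_mz[which(!is.na(ann2$matched_peak))] - target))]
  got <- sp2$mz[ann2$matched_peak[cell]]
  expect_equal(got, target * (1 + 2e-6), tolerance = 1e-9)

  # scan-range masking
  sp3 <- exact_spectrum("PEPTIDK", 2, scan_range = c(300, 700))
  ann3 <- match_peaks(sp3, "PEPTIDK", 2)
  oor <- !is.na(ann3$theo_mz) & (ann3$theo_mz < 300 | ann3$theo_mz > 700)
  expect_true(all(ann3$mask[oor] == "out_of_range"))
  # charge-2 columns exist but are out_of_range for 1+ precursors
  ann4 <- match_peaks(sp, "PEPTIDK", 1)
  expect_true(all(ann4$mask[, c("b_z2", "y_z2")] == "out_of_range"))
})

test_that("a peak claimed by two fragments of one peptide is masked shared", {
  # append a decoy peak exactly between nothing: instead craft a peptide
  # whose b2 and y5 are forced onto one peak by a widened tolerance
  sp <- exact_spectrum("PEPTIDK", 2)
  b2 <- fragment_mz("PEPTIDK", "b", 2, 1)
  # replace spectrum with a single peak near b2 and use a huge tolerance so
  # several fragments land on it
  sp$mz <- b2
  sp$intensity <- 50
  ann <- match_peaks(sp, "PEPTIDK", 2, tol_ppm = 2e5)
  hit <- which(!is.na(ann$matched_peak))
  expect_gt(length(hit), 1)
  expect_true(all(ann$ambiguous[hit]))
  expect_true(all(ann$mask[hit] == "shared"))
})

test_that("match_peaks with vanishing tolerance still matches exact theoretical peaks", {
  sp <- exact_spectrum("ACDEFGK", 2)
  ann <- match_peaks(sp, "ACDEFGK", 2, tol_ppm = 1e-6)
  expect_equal(sum(!is.na(ann$matched_peak)),
               nrow(enumerate_fragments("ACDEFGK", 2)))
})
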
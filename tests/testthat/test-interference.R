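gauss_xic <- function(times, apex, sigma, scale = 1) {
  structure(list(times = times,
                 values = scale * exp(-(times - apex)^2 / (2 * sigma^2))),
            class = "xic", short = FALSE)
}

test_that("smoothing reproduces polynomials and spreads spikes as defined", {
  const <- rep(4, 11)
  expect_equal(smooth_xic(const), const, tolerance = 1e-12)
  ramp <- seq(0, 5, length.out = 15)
  expect_equal(smooth_xic(ramp), ramp, tolerance = 1e-9)
  spike <- c(0, 0, 1, 0, 0)
  wma <- smooth_xic(spike, method = "weighted_moving_average")
  expect_equal(wma, c(0, 0.25, 0.5, 0.25, 0), tolerance = 1e-12)
  expect_error(smooth_xic(ramp, window = 4), "configuration error")
  # short series pass through untouched
  expect_equal(smooth_xic(c(1, 2)), c(1, 2))
})

test_that("apex spectrum selection picks the nearest-RT covering spectrum", {
  fx <- fixture_sim_clean()
  run <- fx$sim$run
  rec <- fx$sim$report[1, ]
  idx <- select_apex_spectrum(run, rec)
  cover <- window_spectra(run, rec$precursor_mz)
  expect_true(idx %in% cover)
  expect_equal(abs(run$rt[idx] - rec$apex_rt),
               min(abs(run$rt[cover] - rec$apex_rt)))
  # tie goes to the earlier spectrum
  mid <- (run$rt[cover[1]] + run$rt[cover[2]]) / 2
  rec2 <- rec
  rec2$apex_rt <- mid
  expect_equal(select_apex_spectrum(run, rec2), cover[1])
  rec3 <- rec
  rec3$precursor_mz <- 9999
  expect_error(select_apex_spectrum(run, rec3), "data error")
})

test_that("XIC extraction respects boundaries and tolerances", {
  fx <- fixture_sim_clean()
  run <- fx$sim$run
  rec <- fx$sim$report[2, ]
  x <- extract_xic(run, 123.456, rec)     # matches nothing
  expect_true(all(x$values == 0))
  cover <- window_spectra(run, rec$precursor_mz)
  in_b <- sum(run$rt[cover] >= rec$rt_start & run$rt[cover] <= rec$rt_stop)
  expect_length(x$times, in_b)
  expect_true(!is.unsorted(x$times, strictly = TRUE))
})

test_that("peak shape score distinguishes contained, one-sided and plateau traces", {
  t <- seq(-2.45, 2.45, length.out = 13)
  contained <- exp(-t^2 / 2)
  plateau <- pmax(exp(-t^2 / 2), 0.6)
  shoulder <- exp(-t^2 / 2) + 0.5 * exp(-(t - 3.2)^2 / 2)
  others <- lapply(c(0.5, 1, 2), function(s) s * contained)
  expect_equal(peak_shape_score(contained, c(others, list(contained))), 0L)
  expect_equal(peak_shape_score(plateau, c(others, list(plateau))), 2L)
  expect_equal(peak_shape_score(shoulder, c(others, list(shoulder))), 1L)
})

test_that("peptide-centric labels follow the correlation and shape rules", {
  times <- seq(9.6, 10.4, length.out = 13)
  sigma <- 0.13
  clean <- lapply(c(1, 0.7, 0.4, 0.2), function(s) {
    gauss_xic(times, 10, sigma, s)
  })
  names(clean) <- paste0("f", 1:4)
  lab <- peptide_centric_labels(clean)
  expect_false(any(lab$shared))
  expect_equal(sum(lab$is_top), 1L)
  expect_false(lab$shared[lab$is_top])     # top never shared via correlation

  # shift one fragment's contamination: correlation to top collapses
  bad <- clean
  bad$f3$values <- bad$f3$values +
    1.2 * exp(-(times - 10.25)^2 / (2 * sigma^2))
  lab2 <- peptide_centric_labels(bad)
  expect_true(lab2$shared[lab2$fragment == "f3"])
  expect_lt(lab2$corr_to_top[lab2$fragment == "f3"], 0.8)
  expect_false(any(lab2$shared[lab2$fragment %in% c("f1", "f2", "f4")]))

  # constant traces carry no evidence: conservatively shared
  flat <- clean
  flat$f4$values <- rep(5, length(times))
  lab3 <- peptide_centric_labels(flat)
  expect_true(lab3$shared[lab3$fragment == "f4"])
  expect_false(lab3$scorable[lab3$fragment == "f4"])

  # fewer than two scorable chromatograms: warning, nothing labeled
  expect_warning(
    lab4 <- peptide_centric_labels(clean[1]),
    "fewer than 2"
  )
  expect_false(any(lab4$shared))
})

test_that("correlation labels are invariant to positive affine scaling", {
  times <- seq(0, 1, length.out = 11)
  x <- gauss_xic(times, 0.5, 0.15)
  y <- x
  y$values <- 3.7 * y$values + 2
  lab <- peptide_centric_labels(list(a = x, b = y, c = x))
  expect_true(all(lab$corr_to_top > 0.999))
})

test_that("label union combines all three routes", {
  lab <- combine_labels(c(TRUE, FALSE, FALSE), c(FALSE, FALSE, FALSE),
                        c(FALSE, FALSE, TRUE))
  expect_equal(lab$shared, c(TRUE, FALSE, TRUE))
  expect_error(combine_labels(c(TRUE), c(TRUE, FALSE), c(FALSE)),
               "internal error")
})

test_that("co-eluting sequence-swapped peptides are caught spectrum-centrically", {
  # same composition => identical precursor m/z and RT; fragments outside the
  # swapped region coincide exactly
  peps <- tibble::tibble(modified_sequence = c("ALSVITPEK", "LASVITPEK"),
                         charge = 2L)
  cfg <- sim_config(interference_rate = 0, noise_sd = 0,
                    gradient_minutes = 10, seed = 2)
  sim <- simulate_dia_run(peps, config = cfg)
  lab <- label_shared_peaks(sim$run, sim$report)
  a <- lab[lab$modified_sequence == "ALSVITPEK", ]
  # y1..y7 do not span the swap at positions 1-2: all coincide with the
  # partner's fragments
  ycells <- a[a$col == "y_z1" & a$row >= 2, ]
  expect_true(all(ycells$spectrum_centric))
  # b1 differs between the two (A vs L): must not be spectrum-centric shared
  b1 <- a[a$col == "b_z1" & a$row == 1, ]
  if (nrow(b1) > 0) expect_false(any(b1$spectrum_centric))
})

test_that("the combined detector recovers injected interference on the fixture run", {
  fx <- fixture_sim_interfered()
  ev <- evaluate_shared_peak_detection(fx$labels, fx$sim)
  expect_gt(ev$precision, 0.9)
  expect_gt(ev$recall, 0.8)
  # diagnostics serialize
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_label_diagnostics(fx$labels, tmp)
  expect_gt(nrow(readr::read_tsv(tmp, show_col_types = FALSE)), 100)
})

test_that("labels are deterministic given run, report and config", {
  fx <- fixture_sim_interfered()
  lab2 <- label_shared_peaks(fx$sim$run, fx$sim$report)
  expect_identical(fx$labels, lab2)
})
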
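make_gt_examples <- function(n, seed, nce = 30, len = 6:11) {
  set.seed(seed)
  peps <- unique(replicate(n * 2, random_peptide(sample(len, 1))))[1:n]
  lapply(peps, function(s) {
    tg <- ground_truth_intensities(s, 2, nce)
    list(modified_sequence = s, charge = 2L, nce = nce, instrument = "Lumos",
         target = tg, mask = matrix("use", nrow(tg), ncol(tg),
                                    dimnames = dimnames(tg)))
  })
}

small_icfg <- function(...) {
  intensity_model_config(n_layers = 1, d_model = 12, d_ff = 16, d_head = 12,
                         epochs = 8, warmup_epochs = 2, learning_rate = 2e-3,
                         batch_size = 8, max_len = 12, seed = 5, ...)
}

test_that("masked L1 loss equals the brute-force subset mean", {
  set.seed(42)
  for (i in 1:25) {
    d <- c(sample(3:8, 1), sample(2:6, 1))
    pred <- matrix(runif(prod(d)), d[1], d[2])
    target <- matrix(runif(prod(d)), d[1], d[2])
    mask <- matrix(sample(c("use", "shared", "out_of_range"), prod(d),
                          replace = TRUE), d[1], d[2])
    # oracle: explicit loop over cells
    tot <- 0; n <- 0
    for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
      if (mask[r, c] == "use") { tot <- tot + abs(pred[r, c] - target[r, c]); n <- n + 1 }
    }
    want <- if (n == 0) 0 else tot / n
    expect_equal(masked_l1_loss(pred, target, mask), want, tolerance = 1e-12)
  }
  m <- matrix(1, 2, 2)
  expect_equal(masked_l1_loss(m, m, matrix("use", 2, 2)), 0)
  expect_equal(masked_l1_loss(m, m + 5, matrix("shared", 2, 2)), 0)
  expect_equal(masked_l1_loss(m + 0.1, m, matrix("use", 2, 2)), 0.1)
})

test_that("transformer gradients match finite differences", {
  ns <- asNamespace("dialibrarian")
  cfg <- intensity_model_config(n_layers = 2, d_model = 6, d_ff = 8,
                                d_head = 5, epochs = 1, warmup_epochs = 1,
                                batch_size = 4, max_len = 9, seed = 3)
  exs <- make_gt_examples(3, seed = 1, len = 5:8)
  inp <- ns$encode_intensity_inputs(exs, cfg)
  tg <- ns$stack_targets(exs, cfg)
  set.seed(5)
  p <- ns$init_intensity_params(ncol(inp$X), cfg)
  lossfun <- function(p) {
    fw <- ns$intensity_forward(p, inp$X, 3, cfg$max_len, inp$enc$lengths, cfg)
    sum(abs(fw$Y[tg$use] - tg$target[tg$use])) / sum(tg$use)
  }
  fw <- ns$intensity_forward(p, inp$X, 3, cfg$max_len, inp$enc$lengths, cfg)
  dY <- matrix(0, nrow(fw$Y), ncol(fw$Y))
  dY[tg$use] <- sign(fw$Y[tg$use] - tg$target[tg$use]) / sum(tg$use)
  gr <- ns$intensity_backward(p, dY, fw$cache, 3, cfg$max_len,
                              inp$enc$lengths, cfg)
  eps <- 1e-6
  set.seed(6)
  for (nm in names(p)) {
    for (k in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] + eps
      num <- (lossfun(p2) - lossfun(p)) / eps
      expect_equal(gr[[nm]][k], num, tolerance = 1e-3)
    }
  }
})

test_that("conv-BiLSTM gradients match finite differences", {
  ns <- asNamespace("dialibrarian")
  cfg <- rt_model_config(d_embed = 5, conv_filters = 6, hidden = 4, d_fc = 5,
                         epochs = 1, warmup_epochs = 1, batch_size = 4,
                         max_len = 8, seed = 3)
  seqs <- c("PEPTIDK", "ACDK", "LMNPQR")
  enc <- ns$encode_batch(seqs, cfg$max_len)
  X <- ns$position_features(enc)
  y <- c(0.3, 0.7, 0.5)
  set.seed(5)
  p <- ns$init_rt_params(ncol(X), cfg)
  lossfun <- function(p) {
    fw <- ns$rt_forward(p, X, 3, cfg$max_len, enc$lengths, cfg)
    mean(abs(fw$y - y))
  }
  fw <- ns$rt_forward(p, X, 3, cfg$max_len, enc$lengths, cfg)
  dy <- sign(fw$y - y) / 3
  gr <- ns$rt_backward(p, dy, fw$cache, 3, cfg$max_len, cfg)
  eps <- 1e-6
  set.seed(6)
  for (nm in names(p)) {
    for (k in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] + eps
      num <- (lossfun(p2) - lossfun(p)) / eps
      expect_equal(gr[[nm]][k], num, tolerance = 1e-3)
    }
  }
})

test_that("training is deterministic and the loss descends on learnable targets", {
  exs <- make_gt_examples(24, seed = 2)
  cfg <- small_icfg()
  m1 <- train_intensity_model(exs, cfg)
  m2 <- train_intensity_model(exs, cfg)
  expect_identical(m1$history, m2$history)
  expect_lt(m1$history[length(m1$history)], m1$history[1])
  expect_length(m1$history, cfg$epochs)
  expect_true(all(is.finite(m1$history)))
})

test_that("an overfit model reproduces its single training example", {
  exs <- make_gt_examples(1, seed = 3)
  cfg <- intensity_model_config(n_layers = 1, d_model = 16, d_ff = 24,
                                d_head = 16, epochs = 150, warmup_epochs = 10,
                                learning_rate = 3e-3, batch_size = 1,
                                max_len = 12, seed = 7)
  m <- train_intensity_model(exs, cfg)
  pred <- predict_intensity(m, exs[[1]]$modified_sequence, 2L)[[1]]
  rho <- spearman_unmasked(pred, exs[[1]]$target, exs[[1]]$mask)
  expect_gte(rho, 0.95)
  expect_true(all(pred >= 0 & pred <= 1))
  expect_equal(max(pred), 1)
})

test_that("prediction is invariant to batching", {
  exs <- make_gt_examples(5, seed = 4)
  m <- train_intensity_model(exs, small_icfg())
  seqs <- vapply(exs, `[[`, character(1), "modified_sequence")
  batch <- predict_intensity(m, seqs, rep(2L, 5))
  single <- lapply(seqs, function(s) predict_intensity(m, s, 2L)[[1]])
  for (i in 1:5) expect_equal(batch[[i]], single[[i]], tolerance = 1e-12)

  rts_b <- predict_rt(train_rt_model(
    tibble::tibble(modified_sequence = seqs,
                   rt_normalized = seq(0.2, 0.8, length.out = 5)),
    rt_model_config(d_embed = 6, conv_filters = 8, hidden = 6, d_fc = 6,
                    epochs = 5, warmup_epochs = 2, batch_size = 2,
                    max_len = 12, seed = 1)), seqs)
  expect_length(rts_b, 5)
  expect_true(all(rts_b >= 0))
})

test_that("the RT model fits a constant dataset to near zero loss", {
  set.seed(9)
  seqs <- unique(replicate(30, random_peptide(sample(6:10, 1))))[1:20]
  df <- tibble::tibble(modified_sequence = seqs, rt_normalized = 0.4)
  cfg <- rt_model_config(d_embed = 6, conv_filters = 8, hidden = 6, d_fc = 6,
                         epochs = 60, warmup_epochs = 5, learning_rate = 3e-3,
                         batch_size = 10, max_len = 12, seed = 2)
  m <- train_rt_model(df, cfg)
  expect_lt(m$history[length(m$history)], 0.02)
  expect_identical(train_rt_model(df, cfg)$history, m$history)
  pred <- predict_rt(m, seqs[1:5])
  expect_true(all(abs(pred - 0.4) < 0.05))
})

test_that("model kind mismatches and checkpoints behave", {
  exs <- make_gt_examples(4, seed = 5)
  m <- train_intensity_model(exs, small_icfg())
  expect_error(predict_rt(m, "PEPTIDK"), "state error")
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tmp)
  m2 <- load_model(tmp)
  expect_equal(predict_intensity(m2, "PEPTIDK", 2L)[[1]],
               predict_intensity(m, "PEPTIDK", 2L)[[1]])
  expect_error(predict_intensity(m, "PEPTIDEKPEPTIDEKPEPTIDEK", 2L),
               "length cap")

  ti <- tidy(m)
  expect_equal(nrow(ti), length(m$history))
  gl <- glance(m)
  expect_equal(gl$kind, "intensity")
  expect_gt(gl$n_parameters, 0)
  # warmup schedule: linear ramp then constant
  expect_equal(ti$learning_rate[1], m$config$learning_rate / m$config$warmup_epochs)
  expect_equal(ti$learning_rate[nrow(ti)], m$config$learning_rate)
})

test_that("fine-tuning from exported weights resumes rather than restarts", {
  exs <- make_gt_examples(12, seed = 6)
  cfg <- small_icfg()
  m1 <- train_intensity_model(exs, cfg)
  m2 <- train_intensity_model(exs, cfg, init_weights = m1$params)
  expect_lt(m2$history[1], m1$history[1])
})
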
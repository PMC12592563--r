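# Trainable fragment-intensity and retention-time models with the masked L1
# objective: configuration, training schedule (Adam, linear warmup to the
# target learning rate, then constant), prediction, and broom-style tidiers.

#' Intensity model configuration
#'
#' Defaults follow the published training recipe for DIA fine-tuning: four
#' transformer layers and two fully-connected head layers, 20 epochs with 10
#' warmup epochs, learning rate 1e-4, batch size 512. Hidden sizes are
#' configuration choices; tests and desk-scale runs use a narrower, shorter
#' configuration trained from scratch.
#'
#' @param n_layers Number of transformer encoder layers.
#' @param d_model Model width.
#' @param d_ff Feed-forward hidden width.
#' @param d_head Width of the first fully-connected head layer.
#' @param epochs,warmup_epochs,learning_rate,batch_size Training schedule.
#' @param max_len Peptide length cap (padding above).
#' @param mode `"global"` or `"phospho"` (sets the fragment-column layout).
#' @param instrument_levels Instrument categories the model can encode;
#'   unseen names map to the first (surrogate) level.
#' @param seed Integer seed governing initialization and batch shuffling.
#' @return An `intensity_model_config` list.
#' @export
intensity_model_config <- function(n_layers = 4L, d_model = 64L, d_ff = 128L,
                                   d_head = 64L, epochs = 20L,
                                   warmup_epochs = 10L, learning_rate = 1e-4,
                                   batch_size = 512L, max_len = 35L,
                                   mode = "global",
                                   instrument_levels = "Lumos", seed = 1L) {
  stopifnot(warmup_epochs <= epochs, epochs >= 1, learning_rate > 0,
            batch_size >= 1, n_layers >= 1)
  structure(list(n_layers = as.integer(n_layers), d_model = as.integer(d_model),
                 d_ff = as.integer(d_ff), d_head = as.integer(d_head),
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_len = as.integer(max_len), mode = mode,
                 n_out = length(fragment_layout(mode)),
                 instrument_levels = instrument_levels,
                 seed = as.integer(seed)),
            class = "intensity_model_config")
}

#' RT model configuration
#'
#' Defaults follow the published recipe: 40 epochs, 10 warmup epochs,
#' learning rate 1e-4, batch size 1024, on a convolution + bidirectional
#' LSTM network.
#'
#' @param d_embed Residue embedding width.
#' @param conv_filters Width-3 convolution filter count.
#' @param hidden LSTM hidden size per direction.
#' @param d_fc Fully-connected head width.
#' @param epochs,warmup_epochs,learning_rate,batch_size Training schedule.
#' @param max_len Peptide length cap.
#' @param seed Integer seed.
#' @return An `rt_model_config` list.
#' @export
rt_model_config <- function(d_embed = 16L, conv_filters = 32L, hidden = 32L,
                            d_fc = 32L, epochs = 40L, warmup_epochs = 10L,
                            learning_rate = 1e-4, batch_size = 1024L,
                            max_len = 35L, seed = 1L) {
  stopifnot(warmup_epochs <= epochs, epochs >= 1, learning_rate > 0,
            batch_size >= 1)
  structure(list(d_embed = as.integer(d_embed),
                 conv_filters = as.integer(conv_filters),
                 hidden = as.integer(hidden), d_fc = as.integer(d_fc),
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "rt_model_config")
}

#' Masked L1 loss
#'
#' Mean absolute error over the cells marked usable; masked (shared or
#' out-of-range) cells do not contribute. Returns 0 when no cell is usable.
#'
#' @param pred,target Congruent numeric matrices/arrays.
#' @param mask Congruent logical (`TRUE` = use) or character matrix (`"use"`
#'   cells contribute).
#' @return Scalar loss.
#' @export
masked_l1_loss <- function(pred, target, mask) {
  if (!all(dim(pred) == dim(target))) stop("internal error: shape mismatch")
  use <- if (is.character(mask)) mask == "use" else as.logical(mask)
  if (!all(dim(pred) == dim(use))) stop("internal error: mask shape mismatch")
  n <- sum(use)
  if (n == 0L) return(0)
  sum(abs(pred[use] - target[use])) / n
}

# epoch-level linear warmup to the configured rate, then constant
warmup_lr <- function(epoch, cfg) {
  if (cfg$warmup_epochs > 0L && epoch <= cfg$warmup_epochs) {
    cfg$learning_rate * epoch / cfg$warmup_epochs
  } else {
    cfg$learning_rate
  }
}

# stack per-example targets/masks into (B*L x n_out) matrices aligned with
# the network's row layout; row (b-1)*L + k holds cleavage site k
stack_targets <- function(examples, cfg) {
  B <- length(examples)
  L <- cfg$max_len
  Tm <- matrix(0, B * L, cfg$n_out)
  Um <- matrix(FALSE, B * L, cfg$n_out)
  for (b in seq_len(B)) {
    tg <- examples[[b]]$target
    mk <- examples[[b]]$mask
    k <- nrow(tg)
    rows <- (b - 1L) * L + seq_len(k)
    Tm[rows, ] <- tg
    Um[rows, ] <- mk == "use"
  }
  list(target = Tm, use = Um)
}

encode_intensity_inputs <- function(examples, cfg) {
  seqs <- vapply(examples, `[[`, character(1), "modified_sequence")
  enc <- encode_batch(seqs, cfg$max_len)
  meta <- meta_features(
    vapply(examples, `[[`, numeric(1), "charge"),
    vapply(examples, `[[`, numeric(1), "nce"),
    vapply(examples, `[[`, character(1), "instrument"),
    cfg$instrument_levels
  )
  X <- position_features(enc, with_posenc = TRUE, meta = meta)
  list(X = X, enc = enc)
}

#' Train the fragment-intensity model
#'
#' Transformer encoder over the encoded peptide sequence, modifications,
#' charge, NCE and instrument metadata (encoded separately and
#' concatenated), trained with the masked L1 loss so that shared and
#' out-of-range cells do not contribute. Linear learning-rate warmup over
#' the configured warmup epochs, then constant. Deterministic for a fixed
#' config seed.
#'
#' @param examples List of `intensity_example`s (see
#'   [build_intensity_examples()]).
#' @param config An [intensity_model_config()].
#' @param init_weights Optional parameter list to fine-tune from (tensor
#'   names as in the fitted model's `params`); shapes must match the config.
#' @return A `trained_model` (kind `"intensity"`) with `params`, `config`
#'   and per-epoch `history`.
#' @export
train_intensity_model <- function(examples, config = intensity_model_config(),
                                  init_weights = NULL) {
  if (length(examples) < 1L) stop("need at least one training example")
  inp <- encode_intensity_inputs(examples, config)
  tg <- stack_targets(examples, config)
  n_features <- ncol(inp$X)
  with_local_seed(config$seed, {
    params <- init_intensity_params(n_features, config)
    if (!is.null(init_weights)) {
      for (nm in intersect(names(params), names(init_weights))) {
        if (!all(dim(params[[nm]]) == dim(init_weights[[nm]])) &&
            length(params[[nm]]) != length(init_weights[[nm]])) {
          stop("init_weights tensor '", nm, "' has incompatible shape")
        }
        params[[nm]] <- init_weights[[nm]]
      }
    }
    state <- adam_init(params)
    B_all <- length(examples)
    L <- config$max_len
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      lr <- warmup_lr(epoch, config)
      ord <- sample(B_all)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        rows <- as.vector(vapply(bt, function(b) (b - 1L) * L + seq_len(L),
                                 integer(L)))
        fw <- intensity_forward(params, inp$X[rows, , drop = FALSE],
                                length(bt), L, inp$enc$lengths[bt], config)
        Tm <- tg$target[rows, , drop = FALSE]
        Um <- tg$use[rows, , drop = FALSE]
        n_use <- sum(Um)
        loss <- if (n_use > 0) sum(abs(fw$Y[Um] - Tm[Um])) / n_use else 0
        if (!is.finite(loss)) {
          stop("training error: non-finite loss at epoch ", epoch)
        }
        ep_loss <- ep_loss + loss * length(bt)
        dY <- matrix(0, nrow(fw$Y), ncol(fw$Y))
        if (n_use > 0) dY[Um] <- sign(fw$Y[Um] - Tm[Um]) / n_use
        gr <- intensity_backward(params, dY, fw$cache, length(bt), L,
                                 inp$enc$lengths[bt], config)
        upd <- adam_step(params, gr, state, lr)
        params <- upd$params; state <- upd$state
      }
      history[epoch] <- ep_loss / B_all
    }
    new_trained_model("intensity", params, config, history)
  })
}

#' Train the retention-time model
#'
#' Convolution + bidirectional LSTM over the encoded sequence, L1 loss on
#' normalized RT. Same schedule semantics as [train_intensity_model()].
#'
#' @param rt_examples Tibble from [build_rt_examples()] (columns
#'   `modified_sequence`, `rt_normalized`).
#' @param config An [rt_model_config()].
#' @param init_weights Optional parameter list to fine-tune from.
#' @return A `trained_model` (kind `"rt"`).
#' @export
train_rt_model <- function(rt_examples, config = rt_model_config(),
                           init_weights = NULL) {
  rt_examples <- tibble::as_tibble(rt_examples)
  if (nrow(rt_examples) < 1L) stop("need at least one training example")
  enc <- encode_batch(rt_examples$modified_sequence, config$max_len)
  X <- position_features(enc)
  y_all <- rt_examples$rt_normalized
  with_local_seed(config$seed, {
    params <- init_rt_params(ncol(X), config)
    if (!is.null(init_weights)) {
      for (nm in intersect(names(params), names(init_weights))) {
        params[[nm]] <- init_weights[[nm]]
      }
    }
    state <- adam_init(params)
    B_all <- nrow(rt_examples)
    L <- config$max_len
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      lr <- warmup_lr(epoch, config)
      ord <- sample(B_all)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        rows <- as.vector(vapply(bt, function(b) (b - 1L) * L + seq_len(L),
                                 integer(L)))
        fw <- rt_forward(params, X[rows, , drop = FALSE], length(bt), L,
                         enc$lengths[bt], config)
        resid <- fw$y - y_all[bt]
        loss <- mean(abs(resid))
        if (!is.finite(loss)) {
          stop("training error: non-finite loss at epoch ", epoch)
        }
        ep_loss <- ep_loss + loss * length(bt)
        dy <- sign(resid) / length(bt)
        gr <- rt_backward(params, dy, fw$cache, length(bt), L, config)
        upd <- adam_step(params, gr, state, lr)
        params <- upd$params; state <- upd$state
      }
      history[epoch] <- ep_loss / B_all
    }
    new_trained_model("rt", params, config, history)
  })
}

new_trained_model <- function(kind, params, config, history) {
  structure(list(kind = kind, params = params, config = config,
                 history = history),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model>", x$kind, "|", length(x$history), "epochs | final loss",
      format(x$history[length(x$history)], digits = 4), "\n")
  invisible(x)
}

#' Predict fragment intensities
#'
#' Full-layout prediction (no peak masking at prediction time): negatives
#' are clipped to 0, each matrix is renormalized to max 1, and cells for
#' which no fragment exists are set to 0.
#'
#' @param object A `trained_model` of kind `"intensity"`, or a
#'   [ground_truth_model()] (exact simulator truth, useful as a reference
#'   predictor in simulation studies).
#' @param modified_sequences Character vector of modified sequences.
#' @param charges Integer vector of precursor charges.
#' @param nce Normalized collision energy.
#' @param instrument Instrument label.
#' @param mode `"global"` or `"phospho"`.
#' @param ... Unused.
#' @return List of fragment intensity matrices (rows = cleavage sites).
#' @export
predict_intensity <- function(object, modified_sequences, charges, nce = 30,
                              instrument = "Lumos", mode = "global", ...) {
  UseMethod("predict_intensity")
}

#' @export
predict_intensity.trained_model <- function(object, modified_sequences, charges,
                                            nce = 30, instrument = "Lumos",
                                            mode = NULL, ...) {
  if (object$kind != "intensity") {
    stop("state error: model is not an intensity model")
  }
  cfg <- object$config
  mode <- cfg$mode
  B <- length(modified_sequences)
  charges <- rep_len(charges, B)
  nce <- rep_len(nce, B)
  instrument <- rep_len(instrument, B)
  enc <- encode_batch(modified_sequences, cfg$max_len)
  meta <- meta_features(charges, nce, instrument, cfg$instrument_levels)
  X <- position_features(enc, with_posenc = TRUE, meta = meta)
  fw <- intensity_forward(object$params, X, B, cfg$max_len, enc$lengths, cfg)
  layout <- fragment_layout(mode)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    Lb <- enc$lengths[b]
    rows <- (b - 1L) * cfg$max_len + seq_len(Lb - 1L)
    m <- pmax(fw$Y[rows, , drop = FALSE], 0)
    colnames(m) <- layout
    # zero cells with no corresponding fragment
    theo <- theoretical_mz_matrix(modified_sequences[b], charges[b], mode)
    m[is.na(theo)] <- 0
    mx <- max(m)
    if (mx > 0) m <- m / mx
    out[[b]] <- m
  }
  out
}

#' @export
predict_intensity.ground_truth_model <- function(object, modified_sequences,
                                                 charges, nce = 30,
                                                 instrument = "Lumos",
                                                 mode = "global", ...) {
  B <- length(modified_sequences)
  charges <- rep_len(charges, B)
  nce <- rep_len(nce, B)
  lapply(seq_len(B), function(b) {
    object$intensity_rule(modified_sequences[b], charges[b], nce[b], mode)
  })
}

#' Predict normalized retention times
#'
#' @param object A `trained_model` of kind `"rt"`, or a
#'   [ground_truth_model()].
#' @param modified_sequences Character vector of modified sequences.
#' @param ... For the ground-truth method, `gradient_minutes` (default 30)
#'   used to normalize the rule's output.
#' @return Numeric vector of normalized RTs, clamped to `[0, Inf)`;
#'   denormalization to minutes is the library builder's job.
#' @export
predict_rt <- function(object, modified_sequences, ...) {
  UseMethod("predict_rt")
}

#' @export
predict_rt.trained_model <- function(object, modified_sequences, ...) {
  if (object$kind != "rt") stop("state error: model is not an RT model")
  cfg <- object$config
  enc <- encode_batch(modified_sequences, cfg$max_len)
  X <- position_features(enc)
  fw <- rt_forward(object$params, X, length(modified_sequences), cfg$max_len,
                   enc$lengths, cfg)
  pmax(fw$y, 0)
}

#' @export
predict_rt.ground_truth_model <- function(object, modified_sequences,
                                          gradient_minutes = 30, ...) {
  vapply(modified_sequences, function(s) {
    object$rt_rule(s, gradient_minutes) / gradient_minutes
  }, numeric(1), USE.NAMES = FALSE)
}

#' Save / load a trained model
#'
#' Single-file checkpoint with the config embedded.
#'
#' @param model A `trained_model`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `trained_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "trained_model")) stop("state error: not a model checkpoint")
  m
}

#' Export training history as TSV
#'
#' @param model A `trained_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_history <- function(model, path) {
  readr::write_tsv(tidy(model), path, progress = FALSE)
  invisible(path)
}

#' Tidy a trained model's training history
#'
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `learning_rate`.
#' @export
tidy.trained_model <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(x$history),
    loss = x$history,
    learning_rate = vapply(seq_along(x$history), warmup_lr, numeric(1),
                           cfg = x$config)
  )
}

#' One-row model summary
#'
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return Tibble with kind, parameter count, epochs, first/final loss.
#' @export
glance.trained_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    epochs = length(x$history),
    first_loss = x$history[1],
    final_loss = x$history[length(x$history)]
  )
}
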
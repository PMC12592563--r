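# Minimal neural-network core with hand-derived backpropagation.
#
# Two fixed computation graphs are implemented: a transformer encoder for
# fragment-intensity prediction (embedding + positional encoding + N
# self-attention/FFN blocks + 2 fully-connected head layers) and a
# convolution + bidirectional LSTM network for retention-time prediction.
# Gradients are coded analytically and verified against finite differences
# in the test suite. Everything runs on plain R matrices; sequences are
# padded to a fixed cap and padding is masked out of attention, pooling and
# the loss.

NN_POSENC_DIM <- 8L

sigmoid <- function(x) 1 / (1 + exp(-x))

# sinusoidal positional encoding, rows = positions, cols = NN_POSENC_DIM
posenc_matrix <- function(max_len) {
  p <- seq_len(max_len)
  freq <- 1 / 100^(seq_len(NN_POSENC_DIM / 2) / (NN_POSENC_DIM / 2))
  ang <- outer(p, freq)
  cbind(sin(ang), cos(ang))
}

# tokenize modified sequences; mods folded in as per-residue mass deltas
encode_batch <- function(modified_sequences, max_len) {
  B <- length(modified_sequences)
  tokens <- matrix(0L, B, max_len)
  moddelta <- matrix(0, B, max_len)
  lens <- integer(B)
  for (b in seq_len(B)) {
    pf <- as_peptidoform(modified_sequences[b])
    L <- length(pf)
    if (L > max_len) {
      stop("peptide longer than the model's length cap (", max_len, "): ",
           modified_sequences[b])
    }
    lens[b] <- L
    tokens[b, seq_len(L)] <- match(strsplit(pf$sequence, "")[[1]], names(AA_MONO))
    moddelta[b, seq_len(L)] <- mod_deltas_by_residue(pf) / 100
  }
  list(tokens = tokens, moddelta = moddelta, lengths = lens, B = B, L = max_len)
}

# per-position feature matrix (B*L rows): one-hot AA + mod delta [+ posenc
# + metadata for the intensity model]
position_features <- function(enc, with_posenc = FALSE, meta = NULL) {
  B <- enc$B; L <- enc$L
  N <- B * L
  tok <- as.vector(t(enc$tokens))          # row (b-1)*L + l
  X <- matrix(0, N, 20L)
  nz <- which(tok > 0L)
  X[cbind(nz, tok[nz])] <- 1
  X <- cbind(X, as.vector(t(enc$moddelta)))
  if (with_posenc) {
    X <- cbind(X, posenc_matrix(L)[rep(seq_len(L), B), , drop = FALSE])
  }
  if (!is.null(meta)) {
    X <- cbind(X, meta[rep(seq_len(B), each = L), , drop = FALSE])
  }
  X
}

# metadata block: charge one-hot (1..4), scaled NCE, instrument one-hot
meta_features <- function(charge, nce, instrument, instrument_levels) {
  B <- length(charge)
  ch <- matrix(0, B, 4L)
  ch[cbind(seq_len(B), pmin(pmax(charge, 1L), 4L))] <- 1
  inst <- matrix(0, B, length(instrument_levels))
  ii <- match(instrument, instrument_levels)
  if (anyNA(ii)) ii[is.na(ii)] <- 1L   # unseen instruments map to surrogate
  inst[cbind(seq_len(B), ii)] <- 1
  cbind(ch, (nce - 30) / 10, inst)
}

glorot <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)

## ---- transformer intensity network ----------------------------------------

init_intensity_params <- function(n_features, cfg) {
  d <- cfg$d_model; dff <- cfg$d_ff
  p <- list(W_in = glorot(n_features, d), b_in = rep(0, d))
  for (l in seq_len(cfg$n_layers)) {
    p[[paste0("l", l, "_Wq")]] <- glorot(d, d)
    p[[paste0("l", l, "_Wk")]] <- glorot(d, d)
    p[[paste0("l", l, "_Wv")]] <- glorot(d, d)
    p[[paste0("l", l, "_Wo")]] <- glorot(d, d)
    p[[paste0("l", l, "_W1")]] <- glorot(d, dff)
    p[[paste0("l", l, "_b1")]] <- rep(0, dff)
    p[[paste0("l", l, "_W2")]] <- glorot(dff, d)
    p[[paste0("l", l, "_b2")]] <- rep(0, d)
  }
  p$W3 <- glorot(d, cfg$d_head); p$b3 <- rep(0, cfg$d_head)
  p$W4 <- glorot(cfg$d_head, cfg$n_out); p$b4 <- rep(0, cfg$n_out)
  p
}

# forward pass; returns Y (B*L x n_out) and caches for backward
intensity_forward <- function(p, X, B, L, lengths, cfg) {
  d <- cfg$d_model
  scale <- 1 / sqrt(d)
  Z <- sweep(X %*% p$W_in, 2, p$b_in, `+`)
  cache <- list(X = X, Z_in = Z, layers = vector("list", cfg$n_layers))
  valid <- lapply(seq_len(B), function(b) seq_len(lengths[b]) + (b - 1L) * L)
  for (l in seq_len(cfg$n_layers)) {
    nm <- function(s) p[[paste0("l", l, "_", s)]]
    Q <- Z %*% nm("Wq"); K <- Z %*% nm("Wk"); V <- Z %*% nm("Wv")
    A <- matrix(0, nrow(Z), d)
    Plist <- vector("list", B)
    for (b in seq_len(B)) {
      r <- valid[[b]]
      S <- (Q[r, , drop = FALSE] %*% t(K[r, , drop = FALSE])) * scale
      S <- S - apply(S, 1, max)
      P <- exp(S); P <- P / rowSums(P)
      Plist[[b]] <- P
      A[r, ] <- P %*% V[r, , drop = FALSE]
    }
    Zres <- Z + A %*% nm("Wo")
    Hpre <- sweep(Zres %*% nm("W1"), 2, nm("b1"), `+`)
    Hf <- pmax(Hpre, 0)
    Znew <- Zres + sweep(Hf %*% nm("W2"), 2, nm("b2"), `+`)
    cache$layers[[l]] <- list(Z = Z, Q = Q, K = K, V = V, A = A, P = Plist,
                              Zres = Zres, Hpre = Hpre, Hf = Hf)
    Z <- Znew
  }
  Hh_pre <- sweep(Z %*% p$W3, 2, p$b3, `+`)
  Hh <- pmax(Hh_pre, 0)
  Y <- sweep(Hh %*% p$W4, 2, p$b4, `+`)
  cache$Z_out <- Z; cache$Hh_pre <- Hh_pre; cache$Hh <- Hh
  cache$valid <- valid
  list(Y = Y, cache = cache)
}

intensity_backward <- function(p, dY, cache, B, L, lengths, cfg) {
  d <- cfg$d_model
  scale <- 1 / sqrt(d)
  g <- list()
  Hh <- cache$Hh
  g$W4 <- t(Hh) %*% dY; g$b4 <- colSums(dY)
  dHh <- dY %*% t(p$W4)
  dHh[cache$Hh_pre <= 0] <- 0
  Z <- cache$Z_out
  g$W3 <- t(Z) %*% dHh; g$b3 <- colSums(dHh)
  dZ <- dHh %*% t(p$W3)
  valid <- cache$valid
  for (l in rev(seq_len(cfg$n_layers))) {
    nm <- function(s) p[[paste0("l", l, "_", s)]]
    cc <- cache$layers[[l]]
    # FFN block: Znew = Zres + relu(Zres W1 + b1) W2 + b2
    dHf <- dZ %*% t(nm("W2"))
    dHf[cc$Hpre <= 0] <- 0
    g[[paste0("l", l, "_W2")]] <- t(cc$Hf) %*% dZ
    g[[paste0("l", l, "_b2")]] <- colSums(dZ)
    g[[paste0("l", l, "_W1")]] <- t(cc$Zres) %*% dHf
    g[[paste0("l", l, "_b1")]] <- colSums(dHf)
    dZres <- dZ + dHf %*% t(nm("W1"))
    # attention block: Zres = Z + (P V) Wo
    dA <- dZres %*% t(nm("Wo"))
    g[[paste0("l", l, "_Wo")]] <- t(cc$A) %*% dZres
    dQ <- matrix(0, nrow(dZ), d); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      r <- valid[[b]]
      P <- cc$P[[b]]
      dAb <- dA[r, , drop = FALSE]
      Vb <- cc$V[r, , drop = FALSE]
      dP <- dAb %*% t(Vb)
      dV[r, ] <- t(P) %*% dAb
      dS <- P * (dP - rowSums(dP * P))
      dQ[r, ] <- (dS %*% cc$K[r, , drop = FALSE]) * scale
      dK[r, ] <- (t(dS) %*% cc$Q[r, , drop = FALSE]) * scale
    }
    g[[paste0("l", l, "_Wq")]] <- t(cc$Z) %*% dQ
    g[[paste0("l", l, "_Wk")]] <- t(cc$Z) %*% dK
    g[[paste0("l", l, "_Wv")]] <- t(cc$Z) %*% dV
    dZ <- dZres + dQ %*% t(nm("Wq")) + dK %*% t(nm("Wk")) + dV %*% t(nm("Wv"))
  }
  g$W_in <- t(cache$X) %*% dZ
  g$b_in <- colSums(dZ)
  g
}

## ---- conv + BiLSTM retention-time network ---------------------------------

init_rt_params <- function(n_features, cfg) {
  d <- cfg$d_embed; dc <- cfg$conv_filters; h <- cfg$hidden
  list(
    W_emb = glorot(n_features, d),
    W_conv = glorot(3L * d, dc), b_conv = rep(0, dc),
    Wf_lstm = glorot(dc + h, 4L * h), bf_lstm = rep(0, 4L * h),
    Wb_lstm = glorot(dc + h, 4L * h), bb_lstm = rep(0, 4L * h),
    W5 = glorot(2L * h, cfg$d_fc), b5 = rep(0, cfg$d_fc),
    W6 = glorot(cfg$d_fc, 1L), b6 = 0
  )
}

# stack [previous, current, next] position embeddings for a width-3 conv
conv_stack <- function(Z, B, L, d) {
  N <- B * L
  prev_idx <- seq_len(N) - 1L
  next_idx <- seq_len(N) + 1L
  first <- (seq_len(B) - 1L) * L + 1L
  last <- seq_len(B) * L
  Zprev <- Z[pmax(prev_idx, 1L), , drop = FALSE]; Zprev[first, ] <- 0
  Znext <- Z[pmin(next_idx, N), , drop = FALSE]; Znext[last, ] <- 0
  cbind(Zprev, Z, Znext)
}

# one-direction LSTM over the padded batch; x: list over t of B x dc inputs
lstm_forward <- function(W, bvec, xs, mask, h) {
  Tlen <- length(xs)
  B <- nrow(xs[[1]])
  hs <- vector("list", Tlen); steps <- vector("list", Tlen)
  h_t <- matrix(0, B, h); c_t <- matrix(0, B, h)
  for (t in seq_len(Tlen)) {
    inp <- cbind(xs[[t]], h_t)
    gates <- sweep(inp %*% W, 2, bvec, `+`)
    i <- sigmoid(gates[, 1:h, drop = FALSE])
    f <- sigmoid(gates[, (h + 1):(2 * h), drop = FALSE])
    o <- sigmoid(gates[, (2 * h + 1):(3 * h), drop = FALSE])
    gg <- tanh(gates[, (3 * h + 1):(4 * h), drop = FALSE])
    c_new <- f * c_t + i * gg
    tc <- tanh(c_new)
    h_new <- o * tc
    m <- mask[, t]
    h_next <- h_new * m + h_t * (1 - m)
    c_next <- c_new * m + c_t * (1 - m)
    steps[[t]] <- list(inp = inp, i = i, f = f, o = o, g = gg,
                       c_prev = c_t, h_prev = h_t, c_new = c_new, tc = tc, m = m)
    hs[[t]] <- h_next
    h_t <- h_next; c_t <- c_next
  }
  list(hs = hs, steps = steps)
}

# backward through one LSTM direction; dhs: list over t of dL/dh_t (as
# emitted, i.e. after masking). Returns dW, db and dxs.
lstm_backward <- function(W, fwd, dhs, h) {
  Tlen <- length(dhs)
  B <- nrow(dhs[[1]])
  dW <- matrix(0, nrow(W), ncol(W)); db <- rep(0, ncol(W))
  dxs <- vector("list", Tlen)
  dh_carry <- matrix(0, B, h); dc_carry <- matrix(0, B, h)
  for (t in rev(seq_len(Tlen))) {
    st <- fwd$steps[[t]]
    m <- st$m
    dh_total <- dhs[[t]] + dh_carry
    dh <- dh_total * m
    dh_prev_skip <- dh_total * (1 - m)
    dc <- dc_carry * m
    dc_prev_skip <- dc_carry * (1 - m)
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_prev <- dc * st$f
    dgates <- cbind(di * st$i * (1 - st$i),
                    df * st$f * (1 - st$f),
                    do * st$o * (1 - st$o),
                    dg * (1 - st$g^2))
    dW <- dW + t(st$inp) %*% dgates
    db <- db + colSums(dgates)
    dinp <- dgates %*% t(W)
    dxs[[t]] <- dinp[, seq_len(nrow(W) - h), drop = FALSE]
    dh_carry <- dinp[, (nrow(W) - h + 1):nrow(W), drop = FALSE] + dh_prev_skip
    dc_carry <- dc_prev + dc_prev_skip
  }
  list(dW = dW, db = db, dxs = dxs)
}

rt_forward <- function(p, X, B, L, lengths, cfg) {
  d <- cfg$d_embed; dc <- cfg$conv_filters; h <- cfg$hidden
  Z <- X %*% p$W_emb                       # (B*L) x d
  Xc <- conv_stack(Z, B, L, d)
  Cpre <- sweep(Xc %*% p$W_conv, 2, p$b_conv, `+`)
  C <- pmax(Cpre, 0)
  mask <- outer(seq_len(B), seq_len(L), function(b, t) as.numeric(t <= lengths[b]))
  xs_f <- lapply(seq_len(L), function(t) C[(seq_len(B) - 1L) * L + t, , drop = FALSE])
  # reversed valid prefixes for the backward direction
  rev_pos <- matrix(0L, B, L)
  for (b in seq_len(B)) rev_pos[b, seq_len(lengths[b])] <- rev(seq_len(lengths[b]))
  xs_b <- lapply(seq_len(L), function(t) {
    rows <- ifelse(rev_pos[, t] > 0L, (seq_len(B) - 1L) * L + rev_pos[, t], 1L)
    out <- C[rows, , drop = FALSE]
    out * mask[, t]
  })
  fwd <- lstm_forward(p$Wf_lstm, p$bf_lstm, xs_f, mask, h)
  bwd <- lstm_forward(p$Wb_lstm, p$bb_lstm, xs_b, mask, h)
  # mask-aware mean pooling of [h_fwd ; h_bwd] over valid positions
  pool <- matrix(0, B, 2L * h)
  for (t in seq_len(L)) {
    pool <- pool + cbind(fwd$hs[[t]] * mask[, t], bwd$hs[[t]] * mask[, t])
  }
  pool <- pool / lengths
  U_pre <- sweep(pool %*% p$W5, 2, p$b5, `+`)
  U <- pmax(U_pre, 0)
  y <- as.vector(U %*% p$W6 + p$b6)
  list(y = y, cache = list(X = X, Z = Z, Xc = Xc, Cpre = Cpre, C = C,
                           mask = mask, rev_pos = rev_pos, fwd = fwd, bwd = bwd,
                           pool = pool, U_pre = U_pre, U = U, lengths = lengths))
}

rt_backward <- function(p, dy, cache, B, L, cfg) {
  d <- cfg$d_embed; h <- cfg$hidden
  g <- list()
  U <- cache$U
  dyv <- matrix(dy, ncol = 1)
  g$W6 <- t(U) %*% dyv; g$b6 <- sum(dy)
  dU <- dyv %*% t(p$W6)
  dU[cache$U_pre <= 0] <- 0
  g$W5 <- t(cache$pool) %*% dU; g$b5 <- colSums(dU)
  dpool <- dU %*% t(p$W5)
  dpool <- dpool / cache$lengths
  dhs_f <- lapply(seq_len(L), function(t) {
    dpool[, seq_len(h), drop = FALSE] * cache$mask[, t]
  })
  dhs_b <- lapply(seq_len(L), function(t) {
    dpool[, h + seq_len(h), drop = FALSE] * cache$mask[, t]
  })
  bf <- lstm_backward(p$Wf_lstm, cache$fwd, dhs_f, h)
  bb <- lstm_backward(p$Wb_lstm, cache$bwd, dhs_b, h)
  g$Wf_lstm <- bf$dW; g$bf_lstm <- bf$db
  g$Wb_lstm <- bb$dW; g$bb_lstm <- bb$db
  dC <- matrix(0, B * L, cfg$conv_filters)
  for (t in seq_len(L)) {
    rows <- (seq_len(B) - 1L) * L + t
    dC[rows, ] <- dC[rows, ] + bf$dxs[[t]]
    # backward direction consumed reversed inputs
    rp <- cache$rev_pos[, t]
    sel <- rp > 0L
    rows_b <- (which(sel) - 1L) * L + rp[sel]
    dC[rows_b, ] <- dC[rows_b, ] + bb$dxs[[t]][sel, , drop = FALSE]
  }
  dC[cache$Cpre <= 0] <- 0
  g$W_conv <- t(cache$Xc) %*% dC; g$b_conv <- colSums(dC)
  dXc <- dC %*% t(p$W_conv)
  # un-stack the width-3 conv input: row i's prev-block gradient goes to
  # row i-1, its next-block gradient to row i+1 (cross-example rows were
  # zeroed in conv_stack and are re-zeroed here)
  N <- B * L
  dZ <- dXc[, d + seq_len(d), drop = FALSE]
  first <- (seq_len(B) - 1L) * L + 1L
  last <- seq_len(B) * L
  dprev <- dXc[, seq_len(d), drop = FALSE]
  dprev[first, ] <- 0
  dZ <- dZ + rbind(dprev[-1L, , drop = FALSE], matrix(0, 1L, d))
  dnext <- dXc[, 2L * d + seq_len(d), drop = FALSE]
  dnext[last, ] <- 0
  dZ <- dZ + rbind(matrix(0, 1L, d), dnext[-N, , drop = FALSE])
  g$W_emb <- t(cache$X) %*% dZ
  g
}

## ---- optimizer -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
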
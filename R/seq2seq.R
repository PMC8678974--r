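# A small character-level attention encoder-decoder, written from first
# principles in base R matrix algebra.
#
# Architecture: learned character embeddings; single-layer bidirectional
# tanh-RNN encoder with masked state updates (padded positions leave the
# hidden state unchanged); decoder tanh-RNN initialized from the masked mean
# of encoder states; global multiplicative (bilinear) attention over content
# positions; a tanh combination layer; softmax output. Training is teacher-
# forced cross-entropy with per-pair weights, Adam updates and global-norm
# gradient clipping. All gradients are hand-derived and verified against
# finite differences in the test suite.

s2s_init_params <- function(V, de, dh, seed) {
  set.seed(seed)
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.08), nr, nc)
  list(Es = rn(V, de), Et = rn(V, de),
       Wxf = rn(de, dh), Whf = rn(dh, dh), bf = numeric(dh),
       Wxb = rn(de, dh), Whb = rn(dh, dh), bb = numeric(dh),
       Wi = rn(2 * dh, dh), bi = numeric(dh),
       Wxd = rn(de, dh), Whd = rn(dh, dh), bd = numeric(dh),
       Wa = rn(dh, 2 * dh),
       Wc = rn(3 * dh, dh), bc = numeric(dh),
       Wo = rn(dh, V), bo = numeric(V))
}

s2s_zero_like <- function(p) lapply(p, function(x) x * 0)

# Encoder forward pass. SRC: B x Ts integer matrix, smask: B x Ts in {0,1}.
# Returns hidden states needed for attention and backprop.
s2s_encode <- function(p, SRC, smask) {
  B <- nrow(SRC); Ts <- ncol(SRC); dh <- ncol(p$Whf)
  hf <- vector("list", Ts); hb <- vector("list", Ts)
  cf <- vector("list", Ts); cb <- vector("list", Ts)
  xs <- vector("list", Ts)
  h <- matrix(0, B, dh)
  for (t in seq_len(Ts)) {
    xs[[t]] <- p$Es[SRC[, t], , drop = FALSE]
    cand <- tanh(xs[[t]] %*% p$Wxf + h %*% p$Whf +
                   matrix(p$bf, B, dh, byrow = TRUE))
    m <- smask[, t]
    h <- cand * m + h * (1 - m)
    cf[[t]] <- cand; hf[[t]] <- h
  }
  h <- matrix(0, B, dh)
  for (t in rev(seq_len(Ts))) {
    cand <- tanh(xs[[t]] %*% p$Wxb + h %*% p$Whb +
                   matrix(p$bb, B, dh, byrow = TRUE))
    m <- smask[, t]
    h <- cand * m + h * (1 - m)
    cb[[t]] <- cand; hb[[t]] <- h
  }
  enc <- lapply(seq_len(Ts), function(t) cbind(hf[[t]], hb[[t]]))
  nmask <- pmax(rowSums(smask), 1)
  mean_enc <- Reduce(`+`, lapply(seq_len(Ts), function(t) enc[[t]] * smask[, t])) / nmask
  h0 <- tanh(mean_enc %*% p$Wi + matrix(p$bi, B, dh, byrow = TRUE))
  list(enc = enc, hf = hf, hb = hb, cf = cf, cb = cb, xs = xs,
       mean_enc = mean_enc, h0 = h0, nmask = nmask)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# One decoder step given previous hidden state and input token indices.
s2s_decode_step <- function(p, ec, smask, h_prev, tok) {
  B <- length(tok); dh <- ncol(p$Whd); Ts <- length(ec$enc)
  xd <- p$Et[tok, , drop = FALSE]
  h <- tanh(xd %*% p$Wxd + h_prev %*% p$Whd + matrix(p$bd, B, dh, byrow = TRUE))
  q <- h %*% p$Wa
  S <- vapply(seq_len(Ts), function(s) rowSums(q * ec$enc[[s]]), numeric(B))
  S <- matrix(S, B, Ts)
  S[smask == 0] <- -1e30
  A <- softmax_rows(S)
  ctx <- Reduce(`+`, lapply(seq_len(Ts), function(s) ec$enc[[s]] * A[, s]))
  hc_in <- cbind(h, ctx)
  htil <- tanh(hc_in %*% p$Wc + matrix(p$bc, B, dh, byrow = TRUE))
  logits <- htil %*% p$Wo + matrix(p$bo, B, ncol(p$Wo), byrow = TRUE)
  list(xd = xd, h = h, q = q, A = A, ctx = ctx, hc_in = hc_in, htil = htil,
       logits = logits)
}

# Full forward + backward over one batch; returns loss and gradients.
s2s_loss_grad <- function(p, SRC, smask, TGT_in, TGT_out, tmask, w) {
  B <- nrow(SRC); Ts <- ncol(SRC); Tt <- ncol(TGT_in)
  dh <- ncol(p$Whd); V <- ncol(p$Wo)
  ec <- s2s_encode(p, SRC, smask)
  steps <- vector("list", Tt)
  h_prev <- ec$h0
  norm <- sum(tmask * w)
  loss <- 0
  for (t in seq_len(Tt)) {
    st <- s2s_decode_step(p, ec, smask, h_prev, TGT_in[, t])
    lp <- st$logits - apply(st$logits, 1L, max)
    lse <- log(rowSums(exp(lp)))
    ll <- lp[cbind(seq_len(B), TGT_out[, t])] - lse
    loss <- loss - sum(ll * tmask[, t] * w)
    st$P <- exp(lp - lse)
    steps[[t]] <- st
    h_prev <- st$h
  }
  loss <- loss / norm
  g <- s2s_zero_like(p)
  dEnc <- lapply(seq_len(Ts), function(t) matrix(0, B, 2 * dh))
  dh_carry <- matrix(0, B, dh)
  for (t in rev(seq_len(Tt))) {
    st <- steps[[t]]
    scale <- tmask[, t] * w / norm
    dlog <- st$P
    dlog[cbind(seq_len(B), TGT_out[, t])] <-
      dlog[cbind(seq_len(B), TGT_out[, t])] - 1
    dlog <- dlog * scale
    g$Wo <- g$Wo + crossprod(st$htil, dlog)
    g$bo <- g$bo + colSums(dlog)
    dhtil <- dlog %*% t(p$Wo)
    dpre_c <- dhtil * (1 - st$htil^2)
    g$Wc <- g$Wc + crossprod(st$hc_in, dpre_c)
    g$bc <- g$bc + colSums(dpre_c)
    dhc <- dpre_c %*% t(p$Wc)
    dh_t <- dhc[, seq_len(dh), drop = FALSE]
    dctx <- dhc[, dh + seq_len(2 * dh), drop = FALSE]
    # attention backprop
    dA <- vapply(seq_len(Ts), function(s) rowSums(dctx * ec$enc[[s]]),
                 numeric(B))
    dA <- matrix(dA, B, Ts)
    dS <- st$A * (dA - rowSums(dA * st$A))
    dq <- matrix(0, B, 2 * dh)
    for (s in seq_len(Ts)) {
      dEnc[[s]] <- dEnc[[s]] + dctx * st$A[, s] + st$q * dS[, s]
      dq <- dq + ec$enc[[s]] * dS[, s]
    }
    dh_t <- dh_t + dq %*% t(p$Wa)
    g$Wa <- g$Wa + crossprod(st$h, dq)
    dh_total <- dh_t + dh_carry
    dpre_d <- dh_total * (1 - st$h^2)
    g$Wxd <- g$Wxd + crossprod(st$xd, dpre_d)
    h_before <- if (t == 1L) ec$h0 else steps[[t - 1L]]$h
    g$Whd <- g$Whd + crossprod(h_before, dpre_d)
    g$bd <- g$bd + colSums(dpre_d)
    dh_carry <- dpre_d %*% t(p$Whd)
    dxd <- dpre_d %*% t(p$Wxd)
    rs <- rowsum(dxd, TGT_in[, t])
    ridx <- as.integer(rownames(rs))
    g$Et[ridx, ] <- g$Et[ridx, ] + rs
  }
  # decoder init path
  dh0 <- dh_carry
  dpre_i <- dh0 * (1 - ec$h0^2)
  g$Wi <- g$Wi + crossprod(ec$mean_enc, dpre_i)
  g$bi <- g$bi + colSums(dpre_i)
  dmean <- dpre_i %*% t(p$Wi)
  for (s in seq_len(Ts))
    dEnc[[s]] <- dEnc[[s]] + dmean * (smask[, s] / ec$nmask)
  # encoder BPTT, forward direction
  carry <- matrix(0, B, dh)
  dxs <- vector("list", Ts)
  for (t in rev(seq_len(Ts))) {
    dht <- dEnc[[t]][, seq_len(dh), drop = FALSE] + carry
    m <- smask[, t]
    dc <- dht * m
    dpre <- dc * (1 - ec$cf[[t]]^2)
    g$Wxf <- g$Wxf + crossprod(ec$xs[[t]], dpre)
    h_before <- if (t == 1L) matrix(0, B, dh) else ec$hf[[t - 1L]]
    g$Whf <- g$Whf + crossprod(h_before, dpre)
    g$bf <- g$bf + colSums(dpre)
    carry <- dht * (1 - m) + dpre %*% t(p$Whf)
    dxs[[t]] <- dpre %*% t(p$Wxf)
  }
  # encoder BPTT, backward direction (states run Ts -> 1, so gradients 1 -> Ts)
  carry <- matrix(0, B, dh)
  for (t in seq_len(Ts)) {
    dht <- dEnc[[t]][, dh + seq_len(dh), drop = FALSE] + carry
    m <- smask[, t]
    dc <- dht * m
    dpre <- dc * (1 - ec$cb[[t]]^2)
    g$Wxb <- g$Wxb + crossprod(ec$xs[[t]], dpre)
    h_before <- if (t == Ts) matrix(0, B, dh) else ec$hb[[t + 1L]]
    g$Whb <- g$Whb + crossprod(h_before, dpre)
    g$bb <- g$bb + colSums(dpre)
    carry <- dht * (1 - m) + dpre %*% t(p$Whb)
    dxs[[t]] <- dxs[[t]] + dpre %*% t(p$Wxb)
  }
  for (t in seq_len(Ts)) {
    rs <- rowsum(dxs[[t]], SRC[, t])
    ridx <- as.integer(rownames(rs))
    g$Es[ridx, ] <- g$Es[ridx, ] + rs
  }
  list(loss = loss, grad = g)
}

s2s_clip <- function(g, max_norm = 5) {
  total <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
  if (total > max_norm) g <- lapply(g, function(x) x * (max_norm / total))
  g
}

s2s_adam_update <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  for (nm in names(p)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

# Batched greedy decoding: returns an integer matrix B x max_len of emitted
# symbol indices (</s> and anything after it should be dropped by callers).
s2s_greedy <- function(p, SRC, smask, bos, eos, max_len) {
  B <- nrow(SRC)
  ec <- s2s_encode(p, SRC, smask)
  h <- ec$h0
  tok <- rep(bos, B)
  out <- matrix(0L, B, max_len)
  done <- rep(FALSE, B)
  for (t in seq_len(max_len)) {
    st <- s2s_decode_step(p, ec, smask, h, tok)
    nxt <- max.col(st$logits, ties.method = "first")
    out[, t] <- ifelse(done, 0L, nxt)
    done <- done | nxt == eos
    tok <- nxt
    h <- st$h
    if (all(done)) break
  }
  out
}
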
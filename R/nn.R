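# Neural-network primitives: dense / LSTM / GRU layers with full forward and
# backward passes, masked categorical cross-entropy, and Adam. Written on base
# R matrix operations; gradients are validated against numerical
# differentiation in the test suite.
#
# Batched sequence data is handled as a list of T matrices (B x D), one per
# time step. Masking contract: model inputs are multiplied by the validity
# mask before entering any recurrent layer, and the loss averages over valid
# steps only, so padded-row content can never influence the loss, its
# gradients, or valid-step predictions.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

init_lstm <- function(D, H) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias at 1, the usual stabiliser
  list(Wx = glorot(D, 4 * H), Wh = glorot(H, 4 * H), b = b)
}

init_gru <- function(D, H) {
  list(Wx = glorot(D, 3 * H), Wh = glorot(H, 3 * H), b = numeric(3 * H))
}

init_dense <- function(D, U) list(W = glorot(D, U), b = numeric(U))

# ---- LSTM ------------------------------------------------------------------
# Gate layout along columns: input (i), forget (f), candidate (g), output (o).

lstm_forward <- function(X, p, reverse = FALSE) {
  T_ <- length(X); B <- nrow(X[[1]]); H <- ncol(p$Wh) %/% 4L
  ii <- 1:H; fi <- (H + 1):(2 * H); gi <- (2 * H + 1):(3 * H); oi <- (3 * H + 1):(4 * H)
  bmat <- matrix(p$b, B, 4 * H, byrow = TRUE)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  out <- vector("list", T_); cache <- vector("list", T_)
  for (t in if (reverse) rev(seq_len(T_)) else seq_len(T_)) {
    a <- X[[t]] %*% p$Wx + h %*% p$Wh + bmat
    i <- sigmoid(a[, ii, drop = FALSE]); f <- sigmoid(a[, fi, drop = FALSE])
    g <- tanh(a[, gi, drop = FALSE]); o <- sigmoid(a[, oi, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    cache[[t]] <- list(x = X[[t]], hprev = h, cprev = cc,
                       i = i, f = f, g = g, o = o, tc = tc)
    h <- o * tc; cc <- c_new
    out[[t]] <- h
  }
  list(out = out, cache = cache)
}

lstm_backward <- function(dOut, cache, p, reverse = FALSE) {
  T_ <- length(dOut); B <- nrow(dOut[[1]]); H <- ncol(p$Wh) %/% 4L
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- numeric(4 * H)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  dX <- vector("list", T_)
  for (t in if (reverse) seq_len(T_) else rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dOut[[t]] + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    da <- cbind(dc * cc$g * cc$i * (1 - cc$i),
                dc * cc$cprev * cc$f * (1 - cc$f),
                dc * cc$i * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, da)
    dWh <- dWh + crossprod(cc$hprev, da)
    db <- db + colSums(da)
    dX[[t]] <- tcrossprod(da, p$Wx)
    dh_next <- tcrossprod(da, p$Wh)
    dc_next <- dc * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# ---- GRU -------------------------------------------------------------------
# Gate layout: update (z), reset (r), candidate (n); candidate hears the
# recurrent state through the reset gate: n = tanh(x Wxn + (r*h) Whn + bn);
# h' = z*h + (1-z)*n.

gru_forward <- function(X, p, reverse = FALSE) {
  T_ <- length(X); B <- nrow(X[[1]]); H <- ncol(p$Wh) %/% 3L
  zi <- 1:H; ri <- (H + 1):(2 * H); ni <- (2 * H + 1):(3 * H)
  bmat <- matrix(p$b, B, 3 * H, byrow = TRUE)
  h <- matrix(0, B, H)
  out <- vector("list", T_); cache <- vector("list", T_)
  for (t in if (reverse) rev(seq_len(T_)) else seq_len(T_)) {
    ax <- X[[t]] %*% p$Wx
    ah <- h %*% p$Wh
    z <- sigmoid(ax[, zi, drop = FALSE] + ah[, zi, drop = FALSE] + bmat[, zi, drop = FALSE])
    r <- sigmoid(ax[, ri, drop = FALSE] + ah[, ri, drop = FALSE] + bmat[, ri, drop = FALSE])
    rh <- r * h
    n <- tanh(ax[, ni, drop = FALSE] + rh %*% p$Wh[, ni, drop = FALSE] + bmat[, ni, drop = FALSE])
    h_new <- z * h + (1 - z) * n
    cache[[t]] <- list(x = X[[t]], hprev = h, z = z, r = r, n = n, rh = rh)
    h <- h_new
    out[[t]] <- h
  }
  list(out = out, cache = cache)
}

gru_backward <- function(dOut, cache, p, reverse = FALSE) {
  T_ <- length(dOut); B <- nrow(dOut[[1]]); H <- ncol(p$Wh) %/% 3L
  zi <- 1:H; ri <- (H + 1):(2 * H); ni <- (2 * H + 1):(3 * H)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- numeric(3 * H)
  dh_next <- matrix(0, B, H)
  dX <- vector("list", T_)
  for (t in if (reverse) seq_len(T_) else rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dOut[[t]] + dh_next
    dz <- dh * (cc$hprev - cc$n)
    dn <- dh * (1 - cc$z)
    dh_prev <- dh * cc$z
    da_n <- dn * (1 - cc$n^2)
    drh <- tcrossprod(da_n, p$Wh[, ni, drop = FALSE])
    dr <- drh * cc$hprev
    dh_prev <- dh_prev + drh * cc$r
    da_z <- dz * cc$z * (1 - cc$z)
    da_r <- dr * cc$r * (1 - cc$r)
    da <- cbind(da_z, da_r, da_n)
    dWx <- dWx + crossprod(cc$x, da)
    dWh[, zi] <- dWh[, zi] + crossprod(cc$hprev, da_z)
    dWh[, ri] <- dWh[, ri] + crossprod(cc$hprev, da_r)
    dWh[, ni] <- dWh[, ni] + crossprod(cc$rh, da_n)
    db <- db + colSums(da)
    dX[[t]] <- tcrossprod(da, p$Wx)
    dh_prev <- dh_prev + tcrossprod(da_z, p$Wh[, zi, drop = FALSE]) +
      tcrossprod(da_r, p$Wh[, ri, drop = FALSE])
    dh_next <- dh_prev
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# ---- softmax + masked categorical cross-entropy ----------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# logits: n x K; y: integer ordinals 0..K-1 with NA allowed; w: 0/1 weights.
# Returns mean NLL over weighted rows and the gradient wrt logits.
masked_ce <- function(probs, y, w) {
  n_valid <- sum(w)
  if (n_valid == 0) stopf("no valid steps in batch")
  idx <- cbind(seq_along(y), y + 1L)
  ok <- w > 0
  loss <- -sum(log(pmax(probs[idx[ok, , drop = FALSE]], 1e-12))) / n_valid
  G <- probs
  G[idx[ok, , drop = FALSE]] <- G[idx[ok, , drop = FALSE]] - 1
  G[!ok, ] <- 0
  list(loss = loss, dlogits = G / n_valid)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
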
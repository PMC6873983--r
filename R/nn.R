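# Internal neural-network machinery.
#
# Layout: each encoded clinical feature j has a learned 32-vector E[j, ]
# scaled by the feature's (standardized, dequantized) value; the 47
# scaled embeddings are flattened into one constant block per patient.
# The two life-value features (phase, prior survival probability) are
# embedded the same way into their own block, which is the only part of
# the input that changes from year to year. The two LSTM layers run over
# the yearly phases -- the recurrent state is what carries a patient's
# earlier years into the current prediction -- and the final hidden
# state feeds the dense ReLU head and the two-node softmax.
#
# Everything is plain base-R matrices (BLAS does the heavy lifting):
# forward, full backpropagation through time, Gaussian dropout, global
# gradient-norm clipping and Adam. Because the clinical block is
# constant over time, its input projection is computed once per batch
# and reused at every step.

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

init_lstm <- function(d_in, h) {
  list(Wx = glorot(d_in, 4 * h),
       Wh = glorot(h, 4 * h),
       # forget-gate bias starts at 1 (standard trick for gradient flow)
       b = c(rep(0, h), rep(1, h), rep(0, 2 * h)))
}

init_dense <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out), b = rep(0, d_out))
}

sigm <- function(x) 1 / (1 + exp(-x))

# one LSTM cell step given the precomputed input projection zx = x_t %*% Wx
lstm_cell <- function(layer, zx, h_prev, c_prev) {
  n <- nrow(zx)
  h <- length(layer$b) / 4
  z <- zx + h_prev %*% layer$Wh + rep(layer$b, each = n)
  i <- sigm(z[, 1:h, drop = FALSE])
  f <- sigm(z[, (h + 1):(2 * h), drop = FALSE])
  g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
  o <- sigm(z[, (3 * h + 1):(4 * h), drop = FALSE])
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, gates = list(i = i, f = f, g = g, o = o,
                                      c_prev = c_prev))
}

# backward through one cell step; returns dzx and the state gradients
lstm_cell_backward <- function(layer, gates, c_t, h_prev, dh, dc) {
  tanh_c <- tanh(c_t)
  do_ <- dh * tanh_c
  dc <- dc + dh * gates$o * (1 - tanh_c^2)
  di <- dc * gates$g
  dg <- dc * gates$i
  df <- dc * gates$c_prev
  dc_prev <- dc * gates$f
  dz <- cbind(di * gates$i * (1 - gates$i),
              df * gates$f * (1 - gates$f),
              dg * (1 - gates$g^2),
              do_ * gates$o * (1 - gates$o))
  list(dz = dz, dh_prev = dz %*% t(layer$Wh), dc_prev = dc_prev,
       dWh = crossprod(h_prev, dz), db = colSums(dz))
}

softmax2 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m)
  e2 <- exp(logits[, 2] - m)
  cbind(e1 / (e1 + e2), e2 / (e1 + e2))
}

gaussian_noise <- function(n, m, rate) {
  matrix(stats::rnorm(n * m, 1, sqrt(rate / (1 - rate))), n, m)
}

# flattened scaled-embedding block: row-wise x_j * E[j, ], feature-major
embed_block <- function(x, E) {
  ed <- ncol(E)
  F_ <- nrow(E)
  sweep(x[, rep(seq_len(F_), each = ed), drop = FALSE], 2,
        as.vector(t(E)), "*")
}

# gradient of the embedding matrix from the gradient of its flat block
embed_block_grad <- function(x, dblock, F_, ed) {
  tmp <- dblock * x[, rep(seq_len(F_), each = ed), drop = FALSE]
  matrix(colSums(tmp), F_, ed, byrow = TRUE)
}

# quantized life-value pair for a phase, on the same x1000 integer scale
# as the clinical features (then dequantized for the arithmetic)
life_pair <- function(phase, S) {
  cbind(trunc(phase * 1000) / 1000, trunc(S * 1000) / 1000)
}

# Full forward pass over the phase prefix.
# x: integer feature matrix (n x F, x1000 scale); Smat: n x T matrix of
# prior survival probabilities for phases 1..T. Loss/output is taken at
# the final step. training=TRUE samples dropout masks and keeps caches.
srn_forward <- function(w, cfg, x, Smat, training = FALSE) {
  x <- x / 1000
  n <- nrow(x)
  T_ <- ncol(Smat)
  ed <- ncol(w$E_feat)
  F_ <- nrow(w$E_feat)
  femb <- embed_block(x, w$E_feat)
  nf <- F_ * ed
  Wx1_feat <- w$lstm1$Wx[seq_len(nf), , drop = FALSE]
  Wx1_life <- w$lstm1$Wx[(nf + 1):(nf + 2 * ed), , drop = FALSE]
  fpart <- femb %*% Wx1_feat

  h1s <- c1s <- g1s <- vector("list", T_)
  h2s <- c2s <- g2s <- vector("list", T_)
  lembs <- lifes <- vector("list", T_)
  h1 <- matrix(0, n, cfg$lstm_sizes[1]); c1 <- h1
  h2 <- matrix(0, n, cfg$lstm_sizes[2]); c2 <- h2
  for (t in seq_len(T_)) {
    lifes[[t]] <- life_pair(t, Smat[, t])
    lembs[[t]] <- embed_block(lifes[[t]], w$E_life)
    s1 <- lstm_cell(w$lstm1, fpart + lembs[[t]] %*% Wx1_life, h1, c1)
    h1 <- s1$h; c1 <- s1$c
    h1s[[t]] <- h1; c1s[[t]] <- c1; g1s[[t]] <- s1$gates
    s2 <- lstm_cell(w$lstm2, h1 %*% w$lstm2$Wx, h2, c2)
    h2 <- s2$h; c2 <- s2$c
    h2s[[t]] <- h2; c2s[[t]] <- c2; g2s[[t]] <- s2$gates
  }
  h_last <- h2
  m_h <- m_a1 <- m_a2 <- NULL
  if (training && cfg$dropout > 0) {
    m_h <- gaussian_noise(n, ncol(h_last), cfg$dropout)
    h_last <- h_last * m_h
  }
  z1 <- h_last %*% w$d1$W + rep(w$d1$b, each = n)
  a1 <- pmax(z1, 0)
  if (training && cfg$dropout > 0) {
    m_a1 <- gaussian_noise(n, ncol(a1), cfg$dropout)
    a1 <- a1 * m_a1
  }
  z2 <- a1 %*% w$d2$W + rep(w$d2$b, each = n)
  a2 <- pmax(z2, 0)
  if (training && cfg$dropout > 0) {
    m_a2 <- gaussian_noise(n, ncol(a2), cfg$dropout)
    a2 <- a2 * m_a2
  }
  logits <- a2 %*% w$out$W + rep(w$out$b, each = n)
  probs <- softmax2(logits)
  list(probs = probs, x = x, femb = femb, fpart = fpart,
       lembs = lembs, lifes = lifes,
       h1s = h1s, c1s = c1s, g1s = g1s,
       h2s = h2s, c2s = c2s, g2s = g2s,
       h_last = h_last, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
       masks = list(h = m_h, a1 = m_a1, a2 = m_a2))
}

# cross-entropy against the soft two-class target (y, 1 - y)
ce_loss <- function(probs, y) {
  p1 <- pmin(pmax(probs[, 1], 1e-12), 1 - 1e-12)
  -mean(y * log(p1) + (1 - y) * log(1 - p1))
}

srn_backward <- function(w, cfg, fw, y) {
  n <- nrow(fw$probs)
  ed <- ncol(w$E_feat)
  F_ <- nrow(w$E_feat)
  nf <- F_ * ed
  T_ <- length(fw$h1s)
  target <- cbind(y, 1 - y)
  dlogits <- (fw$probs - target) / n
  g <- list()
  g$out <- list(W = crossprod(fw$a2, dlogits), b = colSums(dlogits))
  da2 <- dlogits %*% t(w$out$W)
  if (!is.null(fw$masks$a2)) da2 <- da2 * fw$masks$a2
  dz2 <- da2 * (fw$z2 > 0)
  g$d2 <- list(W = crossprod(fw$a1, dz2), b = colSums(dz2))
  da1 <- dz2 %*% t(w$d2$W)
  if (!is.null(fw$masks$a1)) da1 <- da1 * fw$masks$a1
  dz1 <- da1 * (fw$z1 > 0)
  g$d1 <- list(W = crossprod(fw$h_last, dz1), b = colSums(dz1))
  dh_last <- dz1 %*% t(w$d1$W)
  if (!is.null(fw$masks$h)) dh_last <- dh_last * fw$masks$h

  h1 <- cfg$lstm_sizes[1]; h2 <- cfg$lstm_sizes[2]
  zero1 <- matrix(0, n, h1); zero2 <- matrix(0, n, h2)
  dWx2 <- matrix(0, h1, 4 * h2); dWh2 <- matrix(0, h2, 4 * h2)
  db2 <- numeric(4 * h2)
  dWh1 <- matrix(0, h1, 4 * h1); db1 <- numeric(4 * h1)
  dzx1_sum <- matrix(0, n, 4 * h1)   # sum over steps of layer-1 dzx
  dWx1_life <- matrix(0, 2 * ed, 4 * h1)
  dE_life <- matrix(0, 2, ed)
  Wx1_life <- w$lstm1$Wx[(nf + 1):(nf + 2 * ed), , drop = FALSE]

  dh2 <- dh_last; dc2 <- zero2
  dh1 <- zero1; dc1 <- zero1
  for (t in T_:1) {
    h2_prev <- if (t > 1) fw$h2s[[t - 1]] else zero2
    b2 <- lstm_cell_backward(w$lstm2, fw$g2s[[t]], fw$c2s[[t]], h2_prev,
                             dh2, dc2)
    dWh2 <- dWh2 + b2$dWh; db2 <- db2 + b2$db
    dWx2 <- dWx2 + crossprod(fw$h1s[[t]], b2$dz)
    dh1 <- dh1 + b2$dz %*% t(w$lstm2$Wx)
    dh2 <- b2$dh_prev; dc2 <- b2$dc_prev

    h1_prev <- if (t > 1) fw$h1s[[t - 1]] else zero1
    b1 <- lstm_cell_backward(w$lstm1, fw$g1s[[t]], fw$c1s[[t]], h1_prev,
                             dh1, dc1)
    dWh1 <- dWh1 + b1$dWh; db1 <- db1 + b1$db
    dzx1_sum <- dzx1_sum + b1$dz
    dWx1_life <- dWx1_life + crossprod(fw$lembs[[t]], b1$dz)
    dlemb <- b1$dz %*% t(Wx1_life)
    dE_life <- dE_life + embed_block_grad(fw$lifes[[t]], dlemb, 2L, ed)
    dh1 <- b1$dh_prev; dc1 <- b1$dc_prev
  }
  dWx1_feat <- crossprod(fw$femb, dzx1_sum)
  dfemb <- dzx1_sum %*% t(w$lstm1$Wx[seq_len(nf), , drop = FALSE])
  g$E_feat <- embed_block_grad(fw$x, dfemb, F_, ed)
  g$E_life <- dE_life
  g$lstm1 <- list(Wx = rbind(dWx1_feat, dWx1_life), Wh = dWh1, b = db1)
  g$lstm2 <- list(Wx = dWx2, Wh = dWh2, b = db2)
  g
}

# rescale gradients so their global L2 norm is at most `max_norm`
clip_gradients <- function(g, max_norm) {
  sq <- function(x) if (is.list(x)) sum(vapply(x, sq, numeric(1))) else sum(x^2)
  nrm <- sqrt(sq(g))
  if (is.finite(nrm) && nrm > max_norm) {
    scale <- max_norm / nrm
    g <- rapply(g, function(x) x * scale, how = "replace")
  }
  g
}

# ---- Adam ------------------------------------------------------------

adam_init <- function(w) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  list(m = zeros(w), v = zeros(w), t = 0)
}

adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  upd <- function(w, g, m, v) {
    if (is.list(w)) {
      out_w <- w; out_m <- m; out_v <- v
      for (k in names(w)) {
        r <- upd(w[[k]], g[[k]], m[[k]], v[[k]])
        out_w[[k]] <- r$w; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(w = out_w, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      list(w = w - lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps),
           m = m2, v = v2)
    }
  }
  r <- upd(w, g, st$m, st$v)
  list(w = r$w, state = list(m = r$m, v = r$v, t = st$t))
}
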
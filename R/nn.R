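# Minimal neural-network engine for the two-stream bite classifier.
#
# All layers operate on batch-major arrays [batch, time, channels] in double
# precision; the heavy lifting is plain BLAS matrix multiplication.  Layers:
# 1-D convolution (same zero padding, ReLU), max-pooling over time (size 2),
# LSTM (stackable, final hidden state or full sequence), dense.  Training
# uses Adam on a weighted binary cross-entropy.  Backpropagation is
# implemented alongside each forward pass; correctness is guarded by a
# finite-difference gradient test.

sigm <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

# ---- conv1d (same padding, odd kernel, fused ReLU) ---------------------

conv1d_forward <- function(X, W, b) {
  d <- dim(X); B <- d[1L]; Tn <- d[2L]; C <- d[3L]
  k <- nrow(W) %/% C
  p <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, Tn + 2L * p, C))
  Xp[, (p + 1L):(p + Tn), ] <- X
  cols <- array(0, c(B, Tn, k * C))
  for (o in seq_len(k))
    cols[, , ((o - 1L) * C + 1L):(o * C)] <-
      Xp[, o:(o + Tn - 1L), , drop = FALSE]
  M <- matrix(cols, B * Tn, k * C)
  Z <- M %*% W
  Z <- Z + rep(b, each = B * Tn)
  A <- Z
  A[A < 0] <- 0
  list(out = array(A, c(B, Tn, ncol(W))),
       cache = list(M = M, Z = Z, dimX = d, k = k, p = p))
}

conv1d_backward <- function(dA, cache, W) {
  d <- cache$dimX; B <- d[1L]; Tn <- d[2L]; C <- d[3L]
  k <- cache$k; p <- cache$p
  nf <- ncol(W)
  dZ <- matrix(dA, B * Tn, nf)
  dZ[cache$Z <= 0] <- 0
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- tcrossprod(dZ, W)
  dcols <- array(dM, c(B, Tn, k * C))
  dXp <- array(0, c(B, Tn + 2L * p, C))
  for (o in seq_len(k))
    dXp[, o:(o + Tn - 1L), ] <- dXp[, o:(o + Tn - 1L), , drop = FALSE] +
      dcols[, , ((o - 1L) * C + 1L):(o * C), drop = FALSE]
  list(dX = dXp[, (p + 1L):(p + Tn), , drop = FALSE], dW = dW, db = db)
}

# ---- max pooling over time, size 2 (truncates an odd tail frame) -------

pool_forward <- function(X) {
  d <- dim(X); To <- d[2L] %/% 2L
  i1 <- seq(1L, 2L * To, by = 2L)
  X1 <- X[, i1, , drop = FALSE]
  X2 <- X[, i1 + 1L, , drop = FALSE]
  m <- X1 >= X2
  Y <- X2
  Y[m] <- X1[m]
  list(out = Y, cache = list(m = m, dimX = d, To = To))
}

pool_backward <- function(dY, cache) {
  d <- cache$dimX; To <- cache$To
  i1 <- seq(1L, 2L * To, by = 2L)
  dX <- array(0, d)
  d1 <- dY; d1[!cache$m] <- 0
  d2 <- dY; d2[cache$m] <- 0
  dX[, i1, ] <- d1
  dX[, i1 + 1L, ] <- d2
  dX
}

# ---- LSTM --------------------------------------------------------------
# Gate order in the fused weight matrices: input, forget, cell, output.

lstm_init <- function(C, U) {
  Wx <- glorot(C, 4L * U)
  Wh <- glorot(U, 4L * U)
  b <- rep(0, 4L * U)
  b[(U + 1L):(2L * U)] <- 1   # forget-gate bias
  list(Wx = Wx, Wh = Wh, b = b)
}

lstm_forward <- function(X, par) {
  d <- dim(X); B <- d[1L]; Tn <- d[2L]; C <- d[3L]
  U <- ncol(par$Wx) %/% 4L
  H <- array(0, c(B, Tn, U))
  h <- matrix(0, B, U)
  cc <- matrix(0, B, U)
  caches <- vector("list", Tn)
  ii <- 1:U; fi <- (U + 1L):(2L * U)
  gi <- (2L * U + 1L):(3L * U); oi <- (3L * U + 1L):(4L * U)
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], B, C)
    G <- Xt %*% par$Wx + h %*% par$Wh + rep(par$b, each = B)
    i <- sigm(G[, ii, drop = FALSE])
    f <- sigm(G[, fi, drop = FALSE])
    g <- tanh(G[, gi, drop = FALSE])
    o <- sigm(G[, oi, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    H[, t, ] <- h
    caches[[t]] <- list(Xt = Xt, h_prev = h_prev, c_prev = c_prev,
                        i = i, f = f, g = g, o = o, tc = tc)
  }
  list(H = H, h = h, cache = list(steps = caches, dimX = d, U = U))
}

# dH: gradient on the full hidden sequence [B,T,U] (may be zero except at
# the last step when only the final state feeds forward)
lstm_backward <- function(dH, cache, par) {
  d <- cache$dimX; B <- d[1L]; Tn <- d[2L]; C <- d[3L]; U <- cache$U
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, nrow(par$Wh), ncol(par$Wh))
  db <- rep(0, length(par$b))
  dX <- array(0, d)
  dh_next <- matrix(0, B, U)
  dc_next <- matrix(0, B, U)
  for (t in rev(seq_len(Tn))) {
    st <- cache$steps[[t]]
    dh <- matrix(dH[, t, ], B, U) + dh_next
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    do_ <- dh * st$tc
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_next <- dc * st$f
    dG <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$Xt, dG)
    dWh <- dWh + crossprod(st$h_prev, dG)
    db <- db + colSums(dG)
    dX[, t, ] <- tcrossprod(dG, par$Wx)
    dh_next <- tcrossprod(dG, par$Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# ---- one stream: conv block x2 (two conv layers + pool each) + LSTMs ---

stream_init <- function(Cin, cfg) {
  k <- cfg$conv_kernel
  f1 <- cfg$conv_filters[1L]; f2 <- cfg$conv_filters[2L]
  par <- list(
    c1 = list(W = glorot(k * Cin, f1), b = rep(0, f1)),
    c2 = list(W = glorot(k * f1, f1), b = rep(0, f1)),
    c3 = list(W = glorot(k * f1, f2), b = rep(0, f2)),
    c4 = list(W = glorot(k * f2, f2), b = rep(0, f2))
  )
  Cl <- f2
  par$lstm <- list()
  for (u in cfg$lstm_units) {
    par$lstm[[length(par$lstm) + 1L]] <- lstm_init(Cl, u)
    Cl <- u
  }
  par
}

stream_forward <- function(X, par) {
  a1 <- conv1d_forward(X, par$c1$W, par$c1$b)
  a2 <- conv1d_forward(a1$out, par$c2$W, par$c2$b)
  p1 <- pool_forward(a2$out)
  a3 <- conv1d_forward(p1$out, par$c3$W, par$c3$b)
  a4 <- conv1d_forward(a3$out, par$c4$W, par$c4$b)
  p2 <- pool_forward(a4$out)
  lcaches <- vector("list", length(par$lstm))
  Z <- p2$out
  for (l in seq_along(par$lstm)) {
    lf <- lstm_forward(Z, par$lstm[[l]])
    lcaches[[l]] <- lf$cache
    Z <- lf$H
  }
  list(h = lf$h,
       cache = list(a1 = a1$cache, a2 = a2$cache, p1 = p1$cache,
                    a3 = a3$cache, a4 = a4$cache, p2 = p2$cache,
                    lstm = lcaches, Tl = dim(Z)[2L]))
}

stream_backward <- function(dh, cache, par) {
  g <- list()
  nl <- length(par$lstm)
  B <- nrow(dh)
  dH <- array(0, c(B, cache$Tl, ncol(dh)))
  dH[, cache$Tl, ] <- dh
  g$lstm <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    lb <- lstm_backward(dH, cache$lstm[[l]], par$lstm[[l]])
    g$lstm[[l]] <- list(Wx = lb$dWx, Wh = lb$dWh, b = lb$db)
    dH <- lb$dX
  }
  dp2 <- pool_backward(dH, cache$p2)
  b4 <- conv1d_backward(dp2, cache$a4, par$c4$W)
  g$c4 <- list(W = b4$dW, b = b4$db)
  b3 <- conv1d_backward(b4$dX, cache$a3, par$c3$W)
  g$c3 <- list(W = b3$dW, b = b3$db)
  dp1 <- pool_backward(b3$dX, cache$p1)
  b2 <- conv1d_backward(dp1, cache$a2, par$c2$W)
  g$c2 <- list(W = b2$dW, b = b2$db)
  b1 <- conv1d_backward(b2$dX, cache$a1, par$c1$W)
  g$c1 <- list(W = b1$dW, b = b1$db)
  g$dX <- b1$dX
  g
}

# ---- full two-stream model ---------------------------------------------

model_init <- function(cfg, c_body, c_mouth) {
  ulast <- cfg$lstm_units[length(cfg$lstm_units)]
  list(
    body = stream_init(c_body, cfg),
    mouth = stream_init(c_mouth, cfg),
    fuse = list(W = glorot(2L * ulast, cfg$fusion_units),
                b = rep(0, cfg$fusion_units)),
    out = list(W = glorot(cfg$fusion_units, 1L), b = 0)
  )
}

model_forward <- function(par, Xb, Xm, dropout = 0, train = FALSE) {
  sb <- stream_forward(Xb, par$body)
  sm <- stream_forward(Xm, par$mouth)
  Hcat <- cbind(sb$h, sm$h)
  Zf <- Hcat %*% par$fuse$W + rep(par$fuse$b, each = nrow(Hcat))
  Af <- Zf
  Af[Af < 0] <- 0
  mask <- NULL
  if (train && dropout > 0) {
    mask <- matrix(runif(length(Af)) >= dropout, nrow(Af), ncol(Af)) /
      (1 - dropout)
    Af <- Af * mask
  }
  logit <- drop(Af %*% par$out$W) + par$out$b
  p <- sigm(logit)
  list(p = p, logit = logit,
       cache = list(sb = sb$cache, sm = sm$cache, Hcat = Hcat, Zf = Zf,
                    Af = Af, mask = mask))
}

# dlogit: gradient of the loss wrt the output logit (length B)
model_backward <- function(dlogit, cache, par) {
  B <- length(dlogit)
  g <- list()
  g$out <- list(W = crossprod(cache$Af, matrix(dlogit, B, 1L)),
                b = sum(dlogit))
  dAf <- matrix(dlogit, B, 1L) %*% t(par$out$W)
  if (!is.null(cache$mask)) dAf <- dAf * cache$mask
  dZf <- dAf
  dZf[cache$Zf <= 0] <- 0
  g$fuse <- list(W = crossprod(cache$Hcat, dZf), b = colSums(dZf))
  dH <- tcrossprod(dZf, par$fuse$W)
  u <- ncol(dH) %/% 2L
  g$body <- stream_backward(dH[, 1:u, drop = FALSE], cache$sb, par$body)
  g$mouth <- stream_backward(dH[, (u + 1L):(2L * u), drop = FALSE],
                             cache$sm, par$mouth)
  g$body$dX <- NULL
  g$mouth$dX <- NULL
  g
}

# weighted binary cross-entropy; returns loss and dlogit
bce_loss <- function(p, logit, y, w) {
  eps <- 1e-12
  pc <- pmin(1 - eps, pmax(eps, p))
  loss <- -sum(w * (y * log(pc) + (1 - y) * log(1 - pc))) / length(y)
  dlogit <- w * (p - y) / length(y)
  list(loss = loss, dlogit = dlogit)
}

# ---- Adam over an arbitrary nested parameter list ----------------------

adam_state <- function(params) {
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else list(m = x * 0, v = x * 0)
  }
  lapply(params, walk)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      keys <- if (!is.null(names(p))) names(p) else seq_along(p)
      for (k in keys) {
        r <- walk(p[[k]], g[[k]], s[[k]])
        p[[k]] <- r$p
        s[[k]] <- r$s
      }
      return(list(p = p, s = s))
    }
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = list(m = m, v = v))
  }
  walk(params, grads, state)
}
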
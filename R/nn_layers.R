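# Internal neural-network primitives.
#
# Sequence tensors are R arrays of dim c(batch, time, features).  Most layer
# math runs on the (batch*time) x features matrix view, which for R's
# column-major layout is just matrix(X, nrow = B*T): per-position rows,
# feature columns.  All backward passes are exact analytic gradients
# (verified against finite differences in the test suite).

arr2mat <- function(X) {
  d <- dim(X)
  dim(X) <- c(d[1] * d[2], d[3])
  X
}

mat2arr <- function(M, B, T) {
  dim(M) <- c(B, T, ncol(M))
  M
}

# X shifted one step later in time (causal neighbour); first step is zero.
time_shift <- function(X) {
  d <- dim(X)
  Xs <- array(0, d)
  if (d[2] > 1) Xs[, 2:d[2], ] <- X[, 1:(d[2] - 1), , drop = FALSE]
  Xs
}

sigmoid <- function(z) 1 / (1 + exp(-z))

add_bias <- function(M, b) sweep(M, 2, b, "+")

# ---- batch normalisation (per feature over all rows) ---------------------

bn_forward <- function(Z, gamma, beta, eps, training,
                       run_mean = NULL, run_var = NULL, momentum = 0.1) {
  if (training) {
    if (nrow(Z) < 2)
      stop("batch normalisation needs at least 2 rows in training mode",
           call. = FALSE)
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    v <- pmax(v, 0)
    new_mean <- if (is.null(run_mean)) mu else
      (1 - momentum) * run_mean + momentum * mu
    new_var <- if (is.null(run_var)) v else
      (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    new_mean <- run_mean
    new_var <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(Z, 2, mu), 2, invstd, "*")
  out <- add_bias(sweep(xhat, 2, gamma, "*"), beta)
  list(out = out, xhat = xhat, invstd = invstd,
       run_mean = new_mean, run_var = new_var)
}

bn_backward <- function(dOut, cache, gamma) {
  m <- nrow(dOut)
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2, gamma, "*")
  # dZ = invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dZ <- sweep(dxhat, 2, s1 / m) - sweep(cache$xhat, 2, s2 / m, "*")
  dZ <- sweep(dZ, 2, cache$invstd, "*")
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# ---- causal temporal convolution (kernel length 2) + BN + ReLU -----------
# No convolution bias: the following batch norm absorbs any constant shift
# (its beta is the effective bias), so a conv bias would be a dead parameter.

conv_layer_forward <- function(X, W1, W2, gamma, beta, eps, training,
                               run_mean, run_var, momentum = 0.1) {
  B <- dim(X)[1]; T <- dim(X)[2]
  Xs <- time_shift(X)
  M <- arr2mat(X)
  Ms <- arr2mat(Xs)
  Z <- Ms %*% W1 + M %*% W2
  bn <- bn_forward(Z, gamma, beta, eps, training, run_mean, run_var, momentum)
  A <- pmax(bn$out, 0)
  list(out = mat2arr(A, B, T),
       cache = list(M = M, Ms = Ms, bn = bn, mask = bn$out > 0,
                    B = B, T = T),
       run_mean = bn$run_mean, run_var = bn$run_var)
}

conv_layer_backward <- function(dA, cache, W1, W2, gamma) {
  dH <- arr2mat(dA) * cache$mask
  bnb <- bn_backward(dH, cache$bn, gamma)
  dZ <- bnb$dZ
  dW1 <- crossprod(cache$Ms, dZ)
  dW2 <- crossprod(cache$M, dZ)
  dM <- tcrossprod(dZ, W2)
  dMs <- tcrossprod(dZ, W1)
  dX <- mat2arr(dM, cache$B, cache$T)
  dXs <- mat2arr(dMs, cache$B, cache$T)
  # undo the time shift: position t of dXs came from input position t-1
  if (cache$T > 1)
    dX[, 1:(cache$T - 1), ] <- dX[, 1:(cache$T - 1), , drop = FALSE] +
      dXs[, 2:cache$T, , drop = FALSE]
  list(dX = dX, dW1 = dW1, dW2 = dW2,
       dgamma = bnb$dgamma, dbeta = bnb$dbeta)
}

# ---- LSTM layer (gate order i, f, o, g) ----------------------------------
# The input projection X Wx is identical for every recurrence step, so it is
# computed for all (batch, time) positions in one BLAS call; only the
# recurrent projection h Wh runs inside the unroll loop.

lstm_layer_forward <- function(X, Wx, Wh, b) {
  B <- dim(X)[1]; T <- dim(X)[2]
  Hn <- ncol(Wh) / 4
  h <- matrix(0, B, Hn)
  c_state <- matrix(0, B, Hn)
  out <- array(0, c(B, T, Hn))
  caches <- vector("list", T)
  idx_i <- 1:Hn; idx_f <- Hn + idx_i; idx_o <- 2 * Hn + idx_i
  idx_g <- 3 * Hn + idx_i
  ZX <- add_bias(arr2mat(X) %*% Wx, b)          # all time steps at once
  for (t in seq_len(T)) {
    rows <- (t - 1) * B + seq_len(B)
    z <- ZX[rows, , drop = FALSE] + h %*% Wh
    i_g <- sigmoid(z[, idx_i, drop = FALSE])
    f_g <- sigmoid(z[, idx_f, drop = FALSE])
    o_g <- sigmoid(z[, idx_o, drop = FALSE])
    g_g <- tanh(z[, idx_g, drop = FALSE])
    c_prev <- c_state
    c_state <- f_g * c_prev + i_g * g_g
    tc_ <- tanh(c_state)
    h_prev <- h
    h <- o_g * tc_
    out[, t, ] <- h
    caches[[t]] <- list(h_prev = h_prev, c_prev = c_prev,
                        i = i_g, f = f_g, o = o_g, g = g_g, tanh_c = tc_)
  }
  list(out = out, caches = caches, X = X)
}

lstm_layer_backward <- function(dOut, caches, X, Wx, Wh) {
  B <- dim(dOut)[1]; T <- dim(dOut)[2]
  Hn <- dim(dOut)[3]
  dWh <- matrix(0, Hn, 4 * Hn)
  dZ <- matrix(0, B * T, 4 * Hn)                # gate grads, all steps
  dh_carry <- matrix(0, B, Hn)
  dc_carry <- matrix(0, B, Hn)
  gi <- 1:Hn; gf <- Hn + gi; go <- 2 * Hn + gi; gg <- 3 * Hn + gi
  for (t in rev(seq_len(T))) {
    cc <- caches[[t]]
    dh <- matrix(dOut[, t, ], nrow = B) + dh_carry
    do_ <- dh * cc$tanh_c
    dc <- dc_carry + dh * cc$o * (1 - cc$tanh_c^2)
    dc_carry <- dc * cc$f
    rows <- (t - 1) * B + seq_len(B)
    dZ[rows, gi] <- dc * cc$g * cc$i * (1 - cc$i)
    dZ[rows, gf] <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dZ[rows, go] <- do_ * cc$o * (1 - cc$o)
    dZ[rows, gg] <- dc * cc$i * (1 - cc$g^2)
    dzt <- dZ[rows, , drop = FALSE]
    dWh <- dWh + crossprod(cc$h_prev, dzt)
    dh_carry <- tcrossprod(dzt, Wh)
  }
  Xm <- arr2mat(X)
  dWx <- crossprod(Xm, dZ)
  dX <- mat2arr(tcrossprod(dZ, Wx), B, T)
  list(dX = dX, dWx = dWx, dWh = dWh, db = colSums(dZ))
}

# ---- affine + softmax cross-entropy --------------------------------------

affine_forward <- function(M, W, b) add_bias(M %*% W, b)

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# labels: 1 = forgetting (column 1), 0 = normal (column 2)
softmax_ce <- function(logits, labels, weights = NULL) {
  B <- nrow(logits)
  ci <- ifelse(labels == 1L, 1L, 2L)
  P <- softmax_rows(logits)
  picked <- P[cbind(seq_len(B), ci)]
  li <- -log(pmax(picked, 1e-300))
  if (is.null(weights)) weights <- rep(1, B)
  wsum <- sum(weights)
  loss <- sum(weights * li) / wsum
  dL <- P
  dL[cbind(seq_len(B), ci)] <- dL[cbind(seq_len(B), ci)] - 1
  dL <- dL * (weights / wsum)
  list(loss = loss, dlogits = dL, prob = P)
}

# Kaiming (He) normal initialisation: sd = sqrt(2 / fan_in).  fan_in can
# exceed nrow when a kernel has several taps sharing the output unit.
kaiming_matrix <- function(nrow, ncol, fan_in = nrow) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}
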
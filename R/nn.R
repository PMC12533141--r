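## Internal neural-network engine for the dynamic-static fusion regressors.
##
## Implements exactly the two fusion architectures used by the package:
##   lstm:     LSTM(H) over the dynamic sequence -> last hidden state
##   cnn_lstm: [conv1d(C1,k) relu maxpool(2,1)] x2 -> LSTM(H) -> last state
## followed in both cases by a static branch (dense width S, ReLU),
## concatenation, a fusion dense layer (width F, ReLU) and a linear scalar
## output. Dropout is applied to the recurrent output only. Everything is
## vectorized over the batch; gradients (including input gradients, needed
## for expected-gradients attribution) are exact and are verified against
## finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

## Parameter container. `d` = number of dynamic features presented to the
## network; uses the current RNG stream (caller seeds it).
nn_init <- function(arch, d, n_static, config) {
  H <- config$hidden_units
  S <- config$static_width
  Fw <- config$fusion_width
  K <- config$conv_kernel
  C1 <- config$conv_channels[1]
  C2 <- config$conv_channels[2]
  p <- list()
  lstm_in <- d
  if (arch == "cnn_lstm") {
    p$conv1_W <- glorot(K * d, C1);  p$conv1_b <- numeric(C1)
    p$conv2_W <- glorot(K * C1, C2); p$conv2_b <- numeric(C2)
    lstm_in <- C2
  }
  p$lstm_Wx <- glorot(lstm_in, 4 * H)
  p$lstm_Wh <- glorot(H, 4 * H)
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1    # forget-gate bias
  p$lstm_b <- b
  p$static_W <- glorot(n_static, S); p$static_b <- numeric(S)
  p$fuse_W <- glorot(H + S, Fw);     p$fuse_b <- numeric(Fw)
  p$out_W <- glorot(Fw, 1);          p$out_b <- 0
  p
}

nn_n_params <- function(params) {
  sum(vapply(params, length, numeric(1)))
}

## n x T x d array -> list of T (n x d) matrices
arr_to_list <- function(X) {
  n <- dim(X)[1]; T <- dim(X)[2]; d <- dim(X)[3]
  lapply(seq_len(T), function(t) matrix(X[, t, ], n, d))
}

list_to_arr <- function(L) {
  n <- nrow(L[[1]]); T <- length(L); d <- ncol(L[[1]])
  X <- array(0, dim = c(n, T, d))
  for (t in seq_len(T)) X[, t, ] <- L[[t]]
  X
}

## valid 1-D convolution over the time axis; A = list of L (n x C)
## matrices. Positions are unfolded into one stacked matrix so the whole
## layer is a single BLAS call.
conv_unfold <- function(A, K, Lout) {
  C <- ncol(A[[1]])
  do.call(cbind, lapply(seq_len(K), function(k) {
    do.call(rbind, A[k:(k + Lout - 1L)])
  }))
}

conv1d_fwd <- function(A, W, b, K) {
  n <- nrow(A[[1]])
  Lout <- length(A) - K + 1L
  M <- conv_unfold(A, K, Lout)
  Zb <- M %*% W + matrix(b, nrow(M), length(b), byrow = TRUE)
  lapply(seq_len(Lout), function(j) Zb[((j - 1L) * n + 1L):(j * n), ,
                                       drop = FALSE])
}

conv1d_bwd <- function(A, W, K, dZ) {
  n <- nrow(A[[1]]); C <- ncol(A[[1]])
  Lout <- length(dZ)
  M <- conv_unfold(A, K, Lout)
  dZb <- do.call(rbind, dZ)
  dW <- crossprod(M, dZb)
  db <- colSums(dZb)
  dM <- dZb %*% t(W)
  dA <- lapply(A, function(a) matrix(0, n, C))
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * C + 1L):(k * C)
    for (j in seq_len(Lout)) {
      rows <- ((j - 1L) * n + 1L):(j * n)
      dA[[j + k - 1L]] <- dA[[j + k - 1L]] + dM[rows, cols, drop = FALSE]
    }
  }
  list(dA = dA, dW = dW, db = db)
}

maxpool_fwd <- function(A, size = 2L) {
  Lout <- length(A) - size + 1L
  P <- vector("list", Lout)
  M <- vector("list", Lout)
  for (j in seq_len(Lout)) {
    M[[j]] <- (A[[j]] >= A[[j + 1L]]) * 1
    P[[j]] <- pmax(A[[j]], A[[j + 1L]])
  }
  list(P = P, M = M)
}

maxpool_bwd <- function(A, M, dP) {
  dA <- lapply(A, function(a) matrix(0, nrow(a), ncol(a)))
  for (j in seq_along(dP)) {
    dA[[j]] <- dA[[j]] + dP[[j]] * M[[j]]
    dA[[j + 1L]] <- dA[[j + 1L]] + dP[[j]] * (1 - M[[j]])
  }
  dA
}

lstm_fwd <- function(X, Wx, Wh, b, H) {
  L <- length(X); n <- nrow(X[[1]])
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  bmat <- matrix(b, n, length(b), byrow = TRUE)
  ## project all time steps through Wx in one BLAS call
  XWx <- do.call(rbind, X) %*% Wx
  cache <- vector("list", L)
  for (t in seq_len(L)) {
    z <- XWx[((t - 1L) * n + 1L):(t * n), , drop = FALSE] + h %*% Wh + bmat
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, tc = tc,
                       c_prev = c_prev, h_prev = h, x = X[[t]])
    h <- o * tc
  }
  list(h = h, cache = cache)
}

lstm_bwd <- function(cache, Wx, Wh, dh_last, H) {
  L <- length(cache)
  n <- nrow(dh_last)
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  dz_all <- vector("list", L)
  dh <- dh_last
  dc <- matrix(0, n, H)
  for (t in rev(seq_len(L))) {
    cc <- cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_prev <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dz_all[[t]] <- dz
    dWh <- dWh + crossprod(cc$h_prev, dz)
    dh <- dz %*% t(Wh)
    dc <- dc_prev
  }
  ## batch the input-side products over all time steps
  dzbig <- do.call(rbind, dz_all)
  xbig <- do.call(rbind, lapply(cache, `[[`, "x"))
  dWx <- crossprod(xbig, dzbig)
  db <- colSums(dzbig)
  dXbig <- dzbig %*% t(Wx)
  dX <- lapply(seq_len(L), function(t) {
    dXbig[((t - 1L) * n + 1L):(t * n), , drop = FALSE]
  })
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

## Full forward pass. X: n x T x d array, S: n x n_static matrix.
## drop_mask: NULL (inference) or an n x H inverted-dropout mask.
nn_forward <- function(params, X, S, arch, config, drop_mask = NULL) {
  H <- config$hidden_units
  K <- config$conv_kernel
  Xl <- arr_to_list(X)
  cache <- list(Xl = Xl, arch = arch)
  A <- Xl
  if (arch == "cnn_lstm") {
    Z1 <- conv1d_fwd(A, params$conv1_W, params$conv1_b, K)
    R1 <- lapply(Z1, function(z) pmax(z, 0))
    P1 <- maxpool_fwd(R1)
    Z2 <- conv1d_fwd(P1$P, params$conv2_W, params$conv2_b, K)
    R2 <- lapply(Z2, function(z) pmax(z, 0))
    P2 <- maxpool_fwd(R2)
    cache$conv <- list(A = A, Z1 = Z1, R1 = R1, P1 = P1, Z2 = Z2, R2 = R2,
                       P2 = P2)
    A <- P2$P
  }
  lf <- lstm_fwd(A, params$lstm_Wx, params$lstm_Wh, params$lstm_b, H)
  h <- lf$h
  hd <- if (is.null(drop_mask)) h else h * drop_mask
  n <- nrow(S)
  hs_z <- S %*% params$static_W +
    matrix(params$static_b, n, length(params$static_b), byrow = TRUE)
  hs <- pmax(hs_z, 0)
  u <- cbind(hd, hs)
  f1_z <- u %*% params$fuse_W +
    matrix(params$fuse_b, n, length(params$fuse_b), byrow = TRUE)
  f1 <- pmax(f1_z, 0)
  yhat <- as.vector(f1 %*% params$out_W + params$out_b)
  cache <- c(cache, list(lstm = lf, h = h, hd = hd, drop_mask = drop_mask,
                         S = S, hs = hs, u = u, f1 = f1))
  list(yhat = yhat, cache = cache)
}

## Backward pass from d(loss)/d(yhat). Returns parameter gradients and,
## when requested, gradients w.r.t. the dynamic and static inputs.
nn_backward <- function(params, cache, dyhat, arch, config,
                        need_input_grad = FALSE) {
  H <- config$hidden_units
  K <- config$conv_kernel
  n <- length(dyhat)
  g <- list()
  dyhat <- matrix(dyhat, n, 1)
  g$out_W <- crossprod(cache$f1, dyhat)
  g$out_b <- sum(dyhat)
  df1 <- (dyhat %*% t(params$out_W)) * (cache$f1 > 0)
  g$fuse_W <- crossprod(cache$u, df1)
  g$fuse_b <- colSums(df1)
  du <- df1 %*% t(params$fuse_W)
  dhd <- du[, seq_len(H), drop = FALSE]
  dhs <- du[, (H + 1):ncol(du), drop = FALSE] * (cache$hs > 0)
  g$static_W <- crossprod(cache$S, dhs)
  g$static_b <- colSums(dhs)
  dS <- if (need_input_grad) dhs %*% t(params$static_W) else NULL
  dh <- if (is.null(cache$drop_mask)) dhd else dhd * cache$drop_mask
  lb <- lstm_bwd(cache$lstm$cache, params$lstm_Wx, params$lstm_Wh, dh, H)
  g$lstm_Wx <- lb$dWx; g$lstm_Wh <- lb$dWh; g$lstm_b <- lb$db
  dX_seq <- lb$dX
  if (arch == "cnn_lstm") {
    cv <- cache$conv
    dR2 <- maxpool_bwd(cv$R2, cv$P2$M, dX_seq)
    dZ2 <- mapply(function(dr, z) dr * (z > 0), dR2, cv$Z2, SIMPLIFY = FALSE)
    cb2 <- conv1d_bwd(cv$P1$P, params$conv2_W, K, dZ2)
    g$conv2_W <- cb2$dW; g$conv2_b <- cb2$db
    dR1 <- maxpool_bwd(cv$R1, cv$P1$M, cb2$dA)
    dZ1 <- mapply(function(dr, z) dr * (z > 0), dR1, cv$Z1, SIMPLIFY = FALSE)
    cb1 <- conv1d_bwd(cv$A, params$conv1_W, K, dZ1)
    g$conv1_W <- cb1$dW; g$conv1_b <- cb1$db
    dX_seq <- cb1$dA
  }
  dX <- if (need_input_grad) list_to_arr(dX_seq) else NULL
  list(grads = g, dX = dX, dS = dS)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Adam/MSE training loop. X, S, y are the (already normalized) training
## tensors; Xv/Sv/yv an optional validation set evaluated per epoch.
nn_train <- function(params, X, S, y, arch, config,
                     Xv = NULL, Sv = NULL, yv = NULL) {
  n <- dim(X)[1]
  H <- config$hidden_units
  bs <- config$batch_size
  state <- adam_init(params)
  hist_train <- numeric(config$epochs)
  hist_val <- if (is.null(Xv)) NULL else numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = bs)) {
      bi <- idx[start:min(start + bs - 1L, n)]
      nb <- length(bi)
      Xb <- X[bi, , , drop = FALSE]
      Sb <- S[bi, , drop = FALSE]
      yb <- y[bi]
      mask <- if (config$dropout > 0) {
        matrix((stats::runif(nb * H) >= config$dropout) / (1 - config$dropout),
               nb, H)
      } else NULL
      fw <- nn_forward(params, Xb, Sb, arch, config, drop_mask = mask)
      err <- fw$yhat - yb
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d", ep), call. = FALSE)
      }
      losses <- c(losses, loss)
      bw <- nn_backward(params, fw$cache, 2 * err / nb, arch, config)
      upd <- adam_step(params, bw$grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    hist_train[ep] <- mean(losses)
    if (!is.null(Xv)) {
      pv <- nn_forward(params, Xv, Sv, arch, config)$yhat
      hist_val[ep] <- mean((pv - yv)^2)
    }
  }
  list(params = params, history = list(train = hist_train, val = hist_val))
}
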
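# Internal layer primitives. The convolution stack represents activations as
# a 3-d array (R, T, M): R = batch * channels (the 1 x k kernels never mix
# channels), T = time samples, M = feature maps. Recurrent layers use
# (n, D, T): batch, features, time. All backward passes are exact gradients
# of the forward passes; see tests for numeric-gradient verification.

# ---- temporal convolution (same padding, stride 1; im2col + GEMM in C++) ----

conv_forward <- function(A, W, b) {
  k <- nrow(W) / dim(A)[3L]
  pad_left <- (k - 1L) %/% 2L
  list(Y = .conv_fwd(A, W, b, pad_left),
       cache = list(A = A, pad_left = pad_left))
}

conv_backward <- function(dY, cache, W) {
  .conv_bwd(dY, cache$A, W, cache$pad_left)
}

# ---- batch normalization (per feature map) ----------------------------------

bn_forward <- function(A, gamma, beta, state, train, momentum = 0.1,
                       eps = 1e-5) {
  r <- .bn_fwd(A, gamma, beta, state$mean, state$var, train, momentum, eps)
  list(Y = r$Y, state = list(mean = as.numeric(r$mean),
                             var = as.numeric(r$var)),
       cache = list(A = A, mu = as.numeric(r$mu),
                    invstd = as.numeric(r$invstd), train = train))
}

bn_backward <- function(dY, cache, gamma) {
  r <- .bn_bwd(dY, cache$A, cache$mu, cache$invstd, gamma, cache$train)
  list(dA = r$dA, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

# ---- activation / pooling / dropout -----------------------------------------

lrelu_forward <- function(A, slope) {
  if (length(dim(A)) == 3L) return(list(Y = .lrelu_fwd(A, slope), cache = A))
  pos <- A > 0
  list(Y = A * (slope + (1 - slope) * pos), cache = A)
}

lrelu_backward <- function(dY, cache, slope) {
  if (length(dim(dY)) == 3L) return(.lrelu_bwd(dY, cache, slope))
  dY * (slope + (1 - slope) * (cache > 0))
}

pool_forward <- function(A, p) {
  if (p <= 1L) return(list(Y = A, cache = NULL, p = p))
  if (dim(A)[2L] %/% p < 1L)
    stop("pooling would reduce the sequence below one step")
  r <- .pool_fwd(A, p)
  list(Y = r$Y, cache = list(amax = r$amax, T_in = dim(A)[2L]), p = p)
}

pool_backward <- function(dY, cache, p) {
  if (p <= 1L) return(dY)
  .pool_bwd(dY, cache$amax, p, cache$T_in)
}

dropout_forward <- function(A, p, train) {
  if (!train || p <= 0) return(list(Y = A, cache = NULL))
  mask <- array((stats::runif(length(A)) >= p) / (1 - p), dim = dim(A))
  list(Y = A * mask, cache = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

# ---- LSTM (one direction) ---------------------------------------------------
# X: (n, Din, T); params Wx (Din, 4H), Wh (H, 4H), b (4H); gate order i,f,g,o.

lstm_forward <- function(X, Wx, Wh, b, reverse = FALSE) {
  d <- dim(X); n <- d[1L]; Din <- d[2L]; T_ <- d[3L]
  H <- ncol(Wh) / 4L
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  Hout <- array(0, dim = c(n, H, T_))
  gi <- gf <- gg <- go <- Cc <- Tc <- Hp <- Cp <- array(0, dim = c(n, H, T_))
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  i1 <- 1:H; i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in ord) {
    xt <- array(X[, , t, drop = FALSE], c(n, Din))
    z <- xt %*% Wx + h %*% Wh
    z <- z + rep(b, each = n)
    it <- sigmoid(z[, i1, drop = FALSE]); ft <- sigmoid(z[, i2, drop = FALSE])
    gt <- tanh(z[, i3, drop = FALSE]);    ot <- sigmoid(z[, i4, drop = FALSE])
    Hp[, , t] <- h; Cp[, , t] <- cc
    cc <- ft * cc + it * gt
    tc <- tanh(cc)
    h <- ot * tc
    gi[, , t] <- it; gf[, , t] <- ft; gg[, , t] <- gt; go[, , t] <- ot
    Cc[, , t] <- cc; Tc[, , t] <- tc
    Hout[, , t] <- h
  }
  list(H = Hout,
       cache = list(gi = gi, gf = gf, gg = gg, go = go, Cc = Cc, Tc = Tc,
                    Hp = Hp, Cp = Cp, ord = ord, n = n, Din = Din, Hdim = H))
}

lstm_backward <- function(dH, cache, X, Wx, Wh) {
  n <- cache$n; Din <- cache$Din; H <- cache$Hdim
  T_ <- dim(X)[3L]
  dWx <- matrix(0, Din, 4L * H); dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- array(0, dim = dim(X))
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(cache$ord)) {
    m <- function(a) array(a[, , t, drop = FALSE], c(n, H))
    it <- m(cache$gi); ft <- m(cache$gf); gt <- m(cache$gg); ot <- m(cache$go)
    tc <- m(cache$Tc); hp <- m(cache$Hp); cp <- m(cache$Cp)
    dh <- array(dH[, , t, drop = FALSE], c(n, H)) + dh_next
    dco <- dc_next + dh * ot * (1 - tc^2)
    dz <- cbind(dco * gt * it * (1 - it),
                dco * cp * ft * (1 - ft),
                dco * it * (1 - gt^2),
                dh * tc * ot * (1 - ot))
    xt <- array(X[, , t, drop = FALSE], c(n, Din))
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(hp, dz)
    db <- db + colSums(dz)
    dX[, , t] <- tcrossprod(dz, Wx)
    dh_next <- tcrossprod(dz, Wh)
    dc_next <- dco * ft
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

bilstm_forward <- function(X, pf, pb) {
  fw <- lstm_forward(X, pf$Wx, pf$Wh, pf$b, reverse = FALSE)
  bw <- lstm_forward(X, pb$Wx, pb$Wh, pb$b, reverse = TRUE)
  d <- dim(fw$H)
  H <- array(0, dim = c(d[1L], 2L * d[2L], d[3L]))
  H[, seq_len(d[2L]), ] <- fw$H
  H[, d[2L] + seq_len(d[2L]), ] <- bw$H
  list(H = H, cache = list(fw = fw$cache, bw = bw$cache, Hdim = d[2L]))
}

bilstm_backward <- function(dH, cache, X, pf, pb) {
  Hd <- cache$Hdim
  gf <- lstm_backward(dH[, seq_len(Hd), , drop = FALSE], cache$fw, X,
                      pf$Wx, pf$Wh)
  gb <- lstm_backward(dH[, Hd + seq_len(Hd), , drop = FALSE], cache$bw, X,
                      pb$Wx, pb$Wh)
  list(dX = gf$dX + gb$dX, fw = gf, bw = gb)
}

# ---- attention pooling over time --------------------------------------------
# Hseq: (n, d, T). Scores e_t = w2' tanh(W1' h_t + b1) + b2, softmax over t,
# pooled c = sum_t alpha_t h_t.

attn_forward <- function(Hseq, W1, b1, w2, b2) {
  d <- dim(Hseq); n <- d[1L]; T_ <- d[3L]; A <- ncol(W1)
  U <- array(0, dim = c(n, A, T_))
  e <- matrix(0, n, T_)
  for (t in seq_len(T_)) {
    ht <- array(Hseq[, , t, drop = FALSE], c(n, d[2L]))
    u <- tanh(ht %*% W1 + rep(b1, each = n))
    U[, , t] <- u
    e[, t] <- u %*% w2 + b2
  }
  alpha <- softmax_rows(e)
  cvec <- matrix(0, n, d[2L])
  for (t in seq_len(T_)) {
    cvec <- cvec + alpha[, t] * array(Hseq[, , t, drop = FALSE], c(n, d[2L]))
  }
  list(c = cvec, alpha = alpha,
       cache = list(U = U, alpha = alpha, dims = d))
}

attn_backward <- function(dc, cache, Hseq, W1, w2) {
  d <- cache$dims; n <- d[1L]; Dd <- d[2L]; T_ <- d[3L]
  alpha <- cache$alpha
  dH <- array(0, dim = d)
  dalpha <- matrix(0, n, T_)
  for (t in seq_len(T_)) {
    ht <- array(Hseq[, , t, drop = FALSE], c(n, Dd))
    dH[, , t] <- alpha[, t] * dc
    dalpha[, t] <- rowSums(dc * ht)
  }
  # softmax jacobian
  de <- alpha * (dalpha - rowSums(dalpha * alpha))
  dW1 <- matrix(0, nrow(W1), ncol(W1)); db1 <- numeric(ncol(W1))
  dw2 <- numeric(length(w2)); db2 <- 0
  for (t in seq_len(T_)) {
    ht <- array(Hseq[, , t, drop = FALSE], c(n, Dd))
    u <- array(cache$U[, , t, drop = FALSE], c(n, length(w2)))
    du <- outer(de[, t], w2) * (1 - u^2)
    dw2 <- dw2 + colSums(u * de[, t])
    db2 <- db2 + sum(de[, t])
    dW1 <- dW1 + crossprod(ht, du)
    db1 <- db1 + colSums(du)
    dH[, , t] <- dH[, , t] + tcrossprod(du, W1)
  }
  list(dH = dH, dW1 = dW1, db1 = db1, dw2 = dw2, db2 = db2)
}
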
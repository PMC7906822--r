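#' Network architecture specification
#'
#' Describes the serial SCNN -> BiLSTM -> attention -> fusion classifier.
#' The default reproduces the reference layer stack exactly: four temporal
#' convolutions (kernels 1x5, 1x3, 1x3, 1x3, each batch-normalized, the
#' first two followed by 1x2 max pooling, the middle two by dropout),
#' flattening, two BiLSTM layers of 32 and 20 units, a fully connected layer
#' with dropout, attention pooling, a fully connected fusion layer and a
#' softmax output. Convolutions are same-padded along time with stride 1 and
#' never mix channels; activations are Leaky ReLU with slope 0.01. Filter
#' counts per convolution are not part of the reference stack and default to
#' a VGG-style 32, 32, 64, 64.
#'
#' @param conv_filters integer vector of 4 filter counts.
#' @param conv_kernels kernel widths, fixed default `c(5, 3, 3, 3)`.
#' @param conv_pools pool widths after each conv (`c(2, 2, 1, 1)`).
#' @param conv_dropout dropout after each conv (`c(0, 0.2, 0.2, 0)`).
#' @param batch_norm logical, batch normalization after each convolution.
#' @param leaky_slope negative-branch slope of the activation.
#' @param bilstm_units hidden units per direction of the two BiLSTM layers.
#' @param fc_width width of the fully connected layer (shared fusion width).
#' @param fc_dropout dropout after the fully connected layer.
#' @param attention_dim hidden width of the attention scorer.
#' @param n_classes number of output classes.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(conv_filters = c(32, 32, 64, 64),
                         conv_kernels = c(5, 3, 3, 3),
                         conv_pools = c(2, 2, 1, 1),
                         conv_dropout = c(0, 0.2, 0.2, 0),
                         batch_norm = TRUE,
                         leaky_slope = 0.01,
                         bilstm_units = c(32, 20),
                         fc_width = 64,
                         fc_dropout = 0.2,
                         attention_dim = 32,
                         n_classes = 4) {
  stopifnot(length(conv_filters) == length(conv_kernels),
            length(conv_pools) == length(conv_filters),
            length(conv_dropout) == length(conv_filters),
            length(bilstm_units) == 2L)
  if (any(conv_filters < 1) || any(conv_kernels < 1) || fc_width < 1 ||
      attention_dim < 1 || any(bilstm_units < 1))
    stop("all widths and filter counts must be positive")
  if (any(conv_dropout < 0 | conv_dropout >= 1) ||
      fc_dropout < 0 || fc_dropout >= 1)
    stop("dropout probabilities must lie in [0, 1)")
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernels = as.integer(conv_kernels),
                 conv_pools = as.integer(conv_pools),
                 conv_dropout = conv_dropout,
                 batch_norm = isTRUE(batch_norm),
                 leaky_slope = leaky_slope,
                 bilstm_units = as.integer(bilstm_units),
                 fc_width = as.integer(fc_width),
                 fc_dropout = fc_dropout,
                 attention_dim = as.integer(attention_dim),
                 n_classes = as.integer(n_classes)),
            class = "network_spec")
}

glorot <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

lstm_init <- function(din, h) {
  s <- 1 / sqrt(h)
  b <- numeric(4L * h)
  b[h + seq_len(h)] <- 1                 # forget-gate bias
  list(Wx = matrix(stats::runif(din * 4 * h, -s, s), din, 4L * h),
       Wh = matrix(stats::runif(h * 4 * h, -s, s), h, 4L * h),
       b = b)
}

#' Build the network for a given window geometry
#'
#' Computes the layer geometry (the temporal length presented to the BiLSTM
#' is `floor(floor(S / 2) / 2)` for the default two 1x2 poolings — 62 steps
#' for 250-sample windows), initializes all parameters from the seed, and
#' returns the runnable network. Per-time-step BiLSTM inputs are the
#' concatenation over channels x feature maps at that step, preserving
#' temporal ordering.
#'
#' @param spec a [network_spec()].
#' @param input_shape `c(channels, samples)`, default `c(22, 250)`.
#' @param seed initialization seed.
#' @return object of class `miattn_net` with elements `spec`, `params`,
#'   `state` (batch-norm running moments), `seq_len`, `n_params`, `layers`.
#' @export
build_network <- function(spec, input_shape = c(22L, 250L), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"), length(input_shape) == 2L)
  C <- as.integer(input_shape[1L]); S <- as.integer(input_shape[2L])
  nconv <- length(spec$conv_filters)
  T_ <- S
  for (p in spec$conv_pools) {
    T_ <- T_ %/% max(1L, p)
    if (T_ < 1L) stop("pooling reduces the temporal sequence below one step")
  }
  d_seq <- C * spec$conv_filters[nconv]
  d_flat <- d_seq * T_
  h1 <- spec$bilstm_units[1L]; h2 <- spec$bilstm_units[2L]

  params <- with_seed(derive_seed(seed, "net-init"), {
    p <- list()
    m_in <- 1L
    for (i in seq_len(nconv)) {
      k <- spec$conv_kernels[i]; m_out <- spec$conv_filters[i]
      p[[paste0("conv", i, ".W")]] <-
        matrix(stats::rnorm(k * m_in * m_out, sd = sqrt(2 / (k * m_in))),
               k * m_in, m_out)
      p[[paste0("conv", i, ".b")]] <- numeric(m_out)
      if (spec$batch_norm) {
        p[[paste0("bn", i, ".gamma")]] <- rep(1, m_out)
        p[[paste0("bn", i, ".beta")]] <- numeric(m_out)
      }
      m_in <- m_out
    }
    for (dir in c("f", "b")) {
      ini <- lstm_init(d_seq, h1)
      p[[paste0("lstm1", dir, ".Wx")]] <- ini$Wx
      p[[paste0("lstm1", dir, ".Wh")]] <- ini$Wh
      p[[paste0("lstm1", dir, ".b")]] <- ini$b
      ini <- lstm_init(2L * h1, h2)
      p[[paste0("lstm2", dir, ".Wx")]] <- ini$Wx
      p[[paste0("lstm2", dir, ".Wh")]] <- ini$Wh
      p[[paste0("lstm2", dir, ".b")]] <- ini$b
    }
    p[["fc5.W"]] <- glorot(d_flat, spec$fc_width)
    p[["fc5.b"]] <- numeric(spec$fc_width)
    p[["attn.W1"]] <- glorot(2L * h2, spec$attention_dim)
    p[["attn.b1"]] <- numeric(spec$attention_dim)
    p[["attn.w2"]] <- as.numeric(glorot(spec$attention_dim, 1L))
    p[["attn.b2"]] <- 0
    p[["proj_b.W"]] <- glorot(2L * h2, spec$fc_width)
    p[["proj_b.b"]] <- numeric(spec$fc_width)
    p[["fusion.W"]] <- glorot(spec$fc_width, spec$n_classes)
    p[["fusion.b"]] <- numeric(spec$n_classes)
    p
  })

  state <- list()
  if (spec$batch_norm) {
    for (i in seq_len(nconv)) {
      state[[paste0("bn", i)]] <- list(mean = numeric(spec$conv_filters[i]),
                                       var = rep(1, spec$conv_filters[i]))
    }
  }

  layers <- character(0)
  for (i in seq_len(nconv)) {
    layers <- c(layers, sprintf("Convolution 1x%d (%d filters)",
                                spec$conv_kernels[i], spec$conv_filters[i]))
    if (spec$batch_norm) layers <- c(layers, "Batch normalization")
    if (spec$conv_pools[i] > 1L)
      layers <- c(layers, sprintf("Max pooling 1x%d", spec$conv_pools[i]))
    if (spec$conv_dropout[i] > 0) layers <- c(layers, "Dropout layer")
  }
  layers <- c(layers, "Flattened layer",
              sprintf("BiLSTM layer %d", h1), sprintf("BiLSTM layer %d", h2),
              "Fully connected layer", "Dropout layer", "Attention layer",
              "Fully connected layer", "Softmax layer")

  structure(list(spec = spec, input_shape = c(C, S), params = params,
                 state = state, seq_len = T_, d_seq = d_seq, d_flat = d_flat,
                 n_params = sum(vapply(params, length, numeric(1))),
                 layers = layers),
            class = "miattn_net")
}

#' @export
print.miattn_net <- function(x, ...) {
  cat(sprintf("<miattn_net> input %d x %d, sequence length %d, %d parameters\n",
              x$input_shape[1], x$input_shape[2], x$seq_len, x$n_params))
  cat(paste0("  ", x$layers, collapse = "\n"), "\n")
  invisible(x)
}

#' List the layer stack of a built network
#'
#' @param net a `miattn_net`.
#' @return character vector of layer descriptions, in execution order.
#' @export
network_layers <- function(net) net$layers

# Full forward pass. X: (n, channels, samples). Returns posteriors and,
# when keep_cache, everything needed for the backward pass. Dropout draws
# from the current RNG stream only when train_mode.
net_forward_internal <- function(net, X, train_mode = FALSE,
                                 keep_cache = FALSE) {
  spec <- net$spec
  d <- dim(X); n <- d[1L]; C <- d[2L]; S <- d[3L]
  if (C != net$input_shape[1L] || S != net$input_shape[2L])
    stop(sprintf("window geometry %dx%d does not match the built network (%dx%d)",
                 C, S, net$input_shape[1L], net$input_shape[2L]))
  p <- net$params
  nconv <- length(spec$conv_filters)
  caches <- list()

  # rows of A are ordered window-fastest within channel blocks: r = i + (c-1)n
  A <- array(X, dim = c(n * C, S, 1L))
  for (i in seq_len(nconv)) {
    cv <- conv_forward(A, p[[paste0("conv", i, ".W")]],
                       p[[paste0("conv", i, ".b")]])
    A <- cv$Y
    if (spec$batch_norm) {
      bn <- bn_forward(A, p[[paste0("bn", i, ".gamma")]],
                       p[[paste0("bn", i, ".beta")]],
                       net$state[[paste0("bn", i)]], train_mode)
      A <- bn$Y
      if (train_mode) net$state[[paste0("bn", i)]] <- bn$state
    } else bn <- NULL
    ac <- lrelu_forward(A, spec$leaky_slope)
    A <- ac$Y
    pl <- pool_forward(A, spec$conv_pools[i])
    A <- pl$Y
    dr <- dropout_forward(A, spec$conv_dropout[i], train_mode)
    A <- dr$Y
    if (keep_cache)
      caches[[i]] <- list(conv = cv$cache, bn = bn$cache, act = ac$cache,
                          pool = pl$cache, drop = dr$cache)
  }
  T_ <- dim(A)[2L]; M <- dim(A)[3L]
  if (!all(is.finite(A))) stop("non-finite activations in the conv stack")

  # (n*C, T, M) -> sequence (n, C*M, T) and flat (n, C*M*T)
  A4 <- aperm(array(A, c(n, C, T_, M)), c(1L, 2L, 4L, 3L))
  Xseq <- array(A4, c(n, C * M, T_))
  flat <- matrix(A4, n, C * M * T_)

  # SCNN branch: Fc5 + dropout
  z5 <- flat %*% p$fc5.W + rep(p$fc5.b, each = n)
  a5 <- lrelu_forward(z5, spec$leaky_slope)
  d5 <- dropout_forward(a5$Y, spec$fc_dropout, train_mode)
  a_scnn <- d5$Y

  # BiLSTM branch
  l1 <- bilstm_forward(Xseq, list(Wx = p$lstm1f.Wx, Wh = p$lstm1f.Wh, b = p$lstm1f.b),
                       list(Wx = p$lstm1b.Wx, Wh = p$lstm1b.Wh, b = p$lstm1b.b))
  l2 <- bilstm_forward(l1$H, list(Wx = p$lstm2f.Wx, Wh = p$lstm2f.Wh, b = p$lstm2f.b),
                       list(Wx = p$lstm2b.Wx, Wh = p$lstm2b.Wh, b = p$lstm2b.b))
  at <- attn_forward(l2$H, p$attn.W1, p$attn.b1, p$attn.w2, p$attn.b2)
  a_bilstm <- at$c %*% p$proj_b.W + rep(p$proj_b.b, each = n)

  fused <- a_scnn + a_bilstm
  logits <- fused %*% p$fusion.W + rep(p$fusion.b, each = n)
  post <- softmax_rows(logits)
  if (!all(is.finite(post))) stop("non-finite network output")

  out <- list(post = post, logits = logits, alpha = at$alpha,
              a_scnn = a_scnn, a_bilstm_pooled = at$c, net = net)
  if (keep_cache) {
    out$cache <- list(conv = caches, A4dims = c(n, C, M, T_), Xseq = Xseq,
                      flat = flat, fc5 = list(act = a5$cache, drop = d5$cache),
                      l1 = l1, l2 = l2, at = at, n = n)
  }
  out
}

#' Run the network on a batch of windows
#'
#' Produces the softmax class posterior for each window. In evaluation mode
#' (the default) the pass is a deterministic function of the weights and the
#' input; dropout is active only in training mode.
#'
#' @param net a built `miattn_net`.
#' @param x an `epoch_set` or a window x channel x sample array.
#' @param train_mode logical; enables dropout and batch-statistics
#'   normalization.
#' @return matrix (windows x classes) of posteriors; each row is
#'   non-negative and sums to one. Attribute `"alpha"` holds the attention
#'   weights (windows x time steps).
#' @export
net_forward <- function(net, x, train_mode = FALSE) {
  X <- if (inherits(x, "epoch_set")) x$data else x
  out <- net_forward_internal(net, X, train_mode = train_mode)
  structure(out$post, alpha = out$alpha)
}

# Cross-entropy loss and full backward pass; returns loss, accuracy and
# gradients named exactly like net$params.
net_backward <- function(fwd, labels) {
  net <- fwd$net; p <- net$params; spec <- net$spec
  cache <- fwd$cache
  n <- cache$n
  onehot <- matrix(0, n, spec$n_classes)
  onehot[cbind(seq_len(n), labels)] <- 1
  loss <- -mean(log(pmax(fwd$post[cbind(seq_len(n), labels)], 1e-300)))
  acc <- mean(max.col(fwd$post, ties.method = "first") == labels)
  g <- list()

  dlogits <- (fwd$post - onehot) / n
  fused <- fwd$a_scnn + (fwd$a_bilstm_pooled %*% p$proj_b.W +
                           rep(p$proj_b.b, each = n))
  g$fusion.W <- crossprod(fused, dlogits)
  g$fusion.b <- colSums(dlogits)
  dfused <- tcrossprod(dlogits, p$fusion.W)

  # BiLSTM branch
  g$proj_b.W <- crossprod(fwd$a_bilstm_pooled, dfused)
  g$proj_b.b <- colSums(dfused)
  dc <- tcrossprod(dfused, p$proj_b.W)
  ab <- attn_backward(dc, cache$at$cache, cache$l2$H, p$attn.W1, p$attn.w2)
  g$attn.W1 <- ab$dW1; g$attn.b1 <- ab$db1
  g$attn.w2 <- ab$dw2; g$attn.b2 <- ab$db2
  b2 <- bilstm_backward(ab$dH, cache$l2$cache, cache$l1$H,
                        list(Wx = p$lstm2f.Wx, Wh = p$lstm2f.Wh),
                        list(Wx = p$lstm2b.Wx, Wh = p$lstm2b.Wh))
  g$lstm2f.Wx <- b2$fw$dWx; g$lstm2f.Wh <- b2$fw$dWh; g$lstm2f.b <- b2$fw$db
  g$lstm2b.Wx <- b2$bw$dWx; g$lstm2b.Wh <- b2$bw$dWh; g$lstm2b.b <- b2$bw$db
  b1 <- bilstm_backward(b2$dX, cache$l1$cache, cache$Xseq,
                        list(Wx = p$lstm1f.Wx, Wh = p$lstm1f.Wh),
                        list(Wx = p$lstm1b.Wx, Wh = p$lstm1b.Wh))
  g$lstm1f.Wx <- b1$fw$dWx; g$lstm1f.Wh <- b1$fw$dWh; g$lstm1f.b <- b1$fw$db
  g$lstm1b.Wx <- b1$bw$dWx; g$lstm1b.Wh <- b1$bw$dWh; g$lstm1b.b <- b1$bw$db
  dXseq <- b1$dX

  # SCNN branch
  da5 <- dropout_backward(dfused, cache$fc5$drop)
  dz5 <- lrelu_backward(da5, cache$fc5$act, spec$leaky_slope)
  g$fc5.W <- crossprod(cache$flat, dz5)
  g$fc5.b <- colSums(dz5)
  dflat <- tcrossprod(dz5, p$fc5.W)

  # merge both branches into the conv-stack output gradient
  d4 <- cache$A4dims   # (n, C, M, T)
  dA4 <- array(dflat, d4) + array(dXseq, d4)
  dA <- array(aperm(dA4, c(1L, 2L, 4L, 3L)),      # back to (n*C, T, M)
              c(d4[1L] * d4[2L], d4[4L], d4[3L]))

  for (i in rev(seq_along(spec$conv_filters))) {
    cc <- cache$conv[[i]]
    dA <- dropout_backward(dA, cc$drop)
    dA <- pool_backward(dA, cc$pool, spec$conv_pools[i])
    dA <- lrelu_backward(dA, cc$act, spec$leaky_slope)
    if (spec$batch_norm) {
      bb <- bn_backward(dA, cc$bn, p[[paste0("bn", i, ".gamma")]])
      g[[paste0("bn", i, ".gamma")]] <- bb$dgamma
      g[[paste0("bn", i, ".beta")]] <- bb$dbeta
      dA <- bb$dA
    }
    cb <- conv_backward(dA, cc$conv, p[[paste0("conv", i, ".W")]])
    g[[paste0("conv", i, ".W")]] <- cb$dW
    g[[paste0("conv", i, ".b")]] <- cb$db
    dA <- cb$dA
  }
  list(loss = loss, acc = acc, grads = g, state = net$state)
}

#' Attention pooling of a feature sequence
#'
#' Scores each time step with a one-hidden-layer feedforward scorer
#' (linear -> tanh -> linear), normalizes the scores by softmax into weights
#' `alpha`, and returns the convex combination `c = sum_t alpha_t x_t`.
#'
#' @param H a `t x d` matrix of per-time-step feature vectors.
#' @param params list with `W1` (`d x a`), `b1` (length `a`), `w2`
#'   (length `a`), `b2` (scalar).
#' @return list with pooled vector `c` (length `d`) and weights `alpha`
#'   (length `t`, non-negative, summing to one).
#' @export
attention_pool <- function(H, params) {
  stopifnot(is.matrix(H), nrow(H) >= 1L)
  Hseq <- aperm(array(H, c(nrow(H), ncol(H), 1L)), c(3L, 2L, 1L))
  out <- attn_forward(Hseq, params$W1, params$b1, params$w2, params$b2)
  list(c = as.numeric(out$c), alpha = as.numeric(out$alpha))
}

#' Construct a fusion head
#'
#' Holds the learned projections of the two branch summaries to a shared
#' width and the affine classifier applied to their elementwise sum:
#' `logits = W (P_s a_scnn + P_b a_bilstm) + b`.
#'
#' @param proj_s,proj_b projection matrices (`shared x d_branch`).
#' @param W classifier weights (`n_classes x shared`).
#' @param b classifier bias (length `n_classes`).
#' @return object of class `fusion_head`.
#' @export
fusion_head <- function(proj_s, proj_b, W, b) {
  if (nrow(proj_s) != nrow(proj_b) || ncol(W) != nrow(proj_s))
    stop("branch projections must map to the same shared width as the classifier")
  structure(list(proj_s = proj_s, proj_b = proj_b, W = W, b = as.numeric(b)),
            class = "fusion_head")
}

#' Fuse the two branch summaries into class logits
#'
#' @param a_scnn SCNN branch summary vector.
#' @param a_bilstm attention-pooled BiLSTM branch summary vector.
#' @param head a [fusion_head()].
#' @return numeric vector of logits (length `n_classes`); its softmax is the
#'   class posterior.
#' @export
fuse <- function(a_scnn, a_bilstm, head) {
  stopifnot(inherits(head, "fusion_head"))
  if (length(a_scnn) != ncol(head$proj_s) ||
      length(a_bilstm) != ncol(head$proj_b))
    stop("branch summary lengths do not match the head's projections")
  shared <- head$proj_s %*% a_scnn + head$proj_b %*% a_bilstm
  as.numeric(head$W %*% shared + head$b)
}
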
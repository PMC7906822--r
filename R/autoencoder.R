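#' Tied-weight autoencoder parameters
#'
#' A three-layer autoencoder whose decoder weight is structurally the
#' transpose of the encoder weight: only one matrix `W` (hidden x input) is
#' stored, so tying can never drift. Both activations are sigmoids, which is
#' why inputs must be scaled into (0, 1) (see [fit_ae_scaler()]).
#'
#' @param W hidden x input weight matrix.
#' @param a hidden bias vector.
#' @param b output bias vector (length = input dim).
#' @return object of class `ae_params`.
#' @export
ae_params <- function(W, a, b) {
  stopifnot(is.matrix(W), length(a) == nrow(W), length(b) == ncol(W))
  if (nrow(W) >= ncol(W))
    stop("hidden_dim must be smaller than the input dim (compression)")
  structure(list(W = W, a = as.numeric(a), b = as.numeric(b),
                 hidden_dim = nrow(W), input_dim = ncol(W)),
            class = "ae_params")
}

#' Fit / apply / invert the per-window (0,1) scaler
#'
#' The reconstruction loss is a Bernoulli cross-entropy, so windows are
#' mapped affinely into (0.01, 0.99) using each window's own minimum and
#' range, and reconstructions are mapped back exactly. Shapes of waveforms
#' are preserved.
#'
#' @param x window x feature matrix of flattened windows.
#' @param scaler an `ae_scaler` fitted by `fit_ae_scaler`.
#' @return `fit_ae_scaler`: an `ae_scaler`; `ae_scale` / `ae_unscale`:
#'   matrices of the same shape as `x`.
#' @export
fit_ae_scaler <- function(x) {
  mn <- apply(x, 1L, min)
  rg <- apply(x, 1L, max) - mn
  if (any(rg <= 0)) stop("constant window: (0,1) scaling undefined")
  structure(list(min = mn, range = rg, lo = 0.01, span = 0.98),
            class = "ae_scaler")
}

#' @rdname fit_ae_scaler
#' @export
ae_scale <- function(x, scaler) {
  scaler$lo + scaler$span * (x - scaler$min) / scaler$range
}

#' @rdname fit_ae_scaler
#' @export
ae_unscale <- function(x, scaler) {
  scaler$min + (x - scaler$lo) / scaler$span * scaler$range
}

#' Autoencoder forward pass
#'
#' `h = sigmoid(W x + a)`, `y = sigmoid(W' h + b)` for each row of `x`.
#'
#' @param x window x input matrix (or a single vector) with entries in (0,1).
#' @param params an `ae_params`.
#' @return list with `h` (window x hidden) and `y` (window x input), both
#'   strictly inside (0, 1).
#' @export
ae_forward <- function(x, params) {
  stopifnot(inherits(params, "ae_params"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != params$input_dim)
    stop(sprintf("input dim %d does not match params (%d)", ncol(x),
                 params$input_dim))
  if (!all(is.finite(x))) stop("non-finite autoencoder input")
  h <- sigmoid(x %*% t(params$W) + rep(params$a, each = nrow(x)))
  y <- sigmoid(h %*% params$W + rep(params$b, each = nrow(x)))
  list(h = h, y = y)
}

#' Bernoulli cross-entropy reconstruction loss
#'
#' `-(sum_i x_i log y_i + (1 - x_i) log(1 - y_i))` per window, summed over
#' the window's elements. Reconstructions touching 0 or 1 exactly are clipped
#' at `eps` (with a warning) so the loss stays finite. The minimum over `y`
#' for fixed `x` is attained at `y = x` and equals the entropy of `x`, so
#' the loss is bounded below by that entropy, not by zero.
#'
#' @param x matrix (or vector) of targets in `[0, 1]`.
#' @param y matrix (or vector) of reconstructions in `(0, 1)`.
#' @param eps clipping bound, default 1e-12.
#' @return numeric vector of per-window losses (nats).
#' @export
reconstruction_loss <- function(x, y, eps = 1e-12) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  stopifnot(all(dim(x) == dim(y)), all(x >= 0 & x <= 1))
  if (any(y <= 0 | y >= 1)) {
    warning("reconstruction touched {0,1}; clipping at eps = ", eps)
    y <- pmin(pmax(y, eps), 1 - eps)
  }
  as.numeric(-rowSums(x * log(y) + (1 - x) * log(1 - y)))
}

#' Train the tied-weight autoencoder on an epoch set
#'
#' Flattens each window, fits the (0,1) scaler, and minimizes the mean
#' reconstruction cross-entropy `J(theta)` over all windows by full-batch
#' gradient descent on `theta = {W, a, b}` (the decoder reuses `W`
#' transposed, so its gradient is the sum of the encoder-side and
#' decoder-side contributions).
#'
#' @param epochs an `epoch_set` of real windows.
#' @param hidden_dim hidden width; default half the flattened window dim.
#' @param lr gradient-descent learning rate.
#' @param n_iters iterations of full-batch descent.
#' @param seed initialization seed.
#' @return list with `params` (`ae_params`), `scaler` (`ae_scaler`) and
#'   `loss_trace` (mean loss per iteration, length `n_iters`).
#' @export
train_autoencoder <- function(epochs, hidden_dim = NULL, lr = 0.05,
                              n_iters = 200L, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"), n_windows(epochs) >= 1L)
  d <- dim(epochs$data)
  dim_in <- d[2L] * d[3L]
  if (is.null(hidden_dim)) hidden_dim <- floor(dim_in / 2)
  stop_if_not_count(hidden_dim, "hidden_dim")
  if (hidden_dim >= dim_in)
    stop("hidden_dim must be smaller than the flattened window dim")

  x <- matrix(epochs$data, d[1L], dim_in)
  scaler <- fit_ae_scaler(x)
  xs <- ae_scale(x, scaler)
  m <- nrow(xs)

  params <- with_seed(derive_seed(seed, "ae-init"), {
    sdv <- sqrt(1 / dim_in)
    ae_params(matrix(stats::rnorm(hidden_dim * dim_in, sd = sdv),
                     hidden_dim, dim_in),
              a = rep(0, hidden_dim), b = rep(0, dim_in))
  })

  loss_trace <- numeric(n_iters)
  for (it in seq_len(n_iters)) {
    fw <- ae_forward(xs, params)
    loss_trace[it] <- mean(reconstruction_loss(xs, fw$y))
    if (!is.finite(loss_trace[it]))
      stop("autoencoder loss became non-finite at iteration ", it)
    # d(mean BCE)/d(pre-sigmoid output) = (y - x)/m
    dy <- (fw$y - xs) / m
    dW_dec <- t(fw$h) %*% dy
    db <- colSums(dy)
    dh <- dy %*% t(params$W) * fw$h * (1 - fw$h)
    dW_enc <- t(dh) %*% xs
    da <- colSums(dh)
    params$W <- params$W - lr * (dW_dec + dW_enc)
    params$a <- params$a - lr * da
    params$b <- params$b - lr * db
  }
  list(params = params, scaler = scaler, loss_trace = loss_trace)
}

#' Expand an epoch set with autoencoder reconstructions
#'
#' Each real window contributes `factor` reconstructed windows
#' (scale -> encode -> decode -> inverse scale) carrying the same label,
#' trial id and subject id, flagged `synthetic = TRUE`. The original windows
#' are returned unmodified in front of the reconstructions; output size is
#' `(1 + factor) *` input size.
#'
#' @param epochs an `epoch_set`.
#' @param params trained `ae_params`.
#' @param scaler the matching `ae_scaler` fitted on these windows.
#' @param factor reconstructions per real window (0 returns the input).
#' @return the enlarged `epoch_set`.
#' @export
expand_dataset <- function(epochs, params, scaler, factor = 1L) {
  stopifnot(inherits(epochs, "epoch_set"), factor >= 0)
  if (factor == 0L) return(epochs)
  d <- dim(epochs$data)
  if (d[2L] * d[3L] != params$input_dim)
    stop("window geometry does not match the trained autoencoder")
  x <- matrix(epochs$data, d[1L], params$input_dim)
  y <- ae_forward(ae_scale(x, scaler), params)$y
  recon <- array(ae_unscale(y, scaler), dim = d)
  rep_idx <- rep(seq_len(d[1L]), times = factor)
  out <- abind3(epochs$data, recon[rep_idx, , , drop = FALSE])
  epoch_set(out,
            c(epochs$labels, epochs$labels[rep_idx]),
            c(epochs$trial_ids, epochs$trial_ids[rep_idx]),
            c(epochs$subject_ids, epochs$subject_ids[rep_idx]),
            c(epochs$window_onset, epochs$window_onset[rep_idx]),
            c(epochs$synthetic, rep(TRUE, length(rep_idx))))
}
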
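#' Training configuration
#'
#' Minibatch Adam on multiclass cross-entropy: minibatch size 200, initial
#' learning rate 0.001 and dropout 0.2 are the reference regime; the default
#' epoch budget is 500 with convergence typically well before that, and
#' desk-scale profiles use far fewer.
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param minibatch minibatch size (default 200).
#' @param epochs passes over the training set (default 500).
#' @param seed seed for shuffling, dropout and any initialization drawn
#'   during training.
#' @param beta1,beta2,eps Adam moment constants (published defaults).
#' @param stop_at_acc optional early stop once training accuracy reaches
#'   this level (e.g. 1.0 for overfit checks); `NULL` disables.
#' @param max_steps optional cap on total minibatch steps; `NULL` disables.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, minibatch = 200L,
                         epochs = 500L, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         stop_at_acc = NULL, max_steps = NULL) {
  stop_if_not_count(minibatch, "minibatch")
  stop_if_not_count(epochs, "epochs")
  if (learning_rate < 0) stop("`learning_rate` must be non-negative")
  structure(list(learning_rate = learning_rate,
                 minibatch = as.integer(minibatch),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 stop_at_acc = stop_at_acc, max_steps = max_steps),
            class = "train_config")
}

#' Train the network with minibatch Adam
#'
#' Runs seeded per-epoch shuffling and minibatch Adam on the multiclass
#' cross-entropy. Training is fully reproducible for a fixed seed on one
#' machine. A non-finite loss aborts with the offending epoch and batch
#' index.
#'
#' @param net a built `miattn_net`.
#' @param epochs_set labelled `epoch_set` of training windows.
#' @param config a [train_config()].
#' @param verbose print per-epoch loss/accuracy.
#' @return list of class `train_state`: `net` (trained), `loss` and
#'   `accuracy` per-epoch traces, `steps` (total minibatch updates),
#'   `step_loss` (per-step trace).
#' @export
train <- function(net, epochs_set, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "miattn_net"), inherits(epochs_set, "epoch_set"),
            inherits(config, "train_config"))
  n <- n_windows(epochs_set)
  if (n < 1L) stop("empty training set")
  X <- epochs_set$data
  y <- epochs_set$labels

  mstate <- lapply(net$params, function(p) p * 0)
  vstate <- mstate
  loss_trace <- numeric(0); acc_trace <- numeric(0); step_loss <- numeric(0)
  step <- 0L
  done <- FALSE

  with_seed(derive_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$minibatch)
      ep_loss <- 0; ep_acc <- 0
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + config$minibatch - 1L, n)]
        fwd <- net_forward_internal(net, X[idx, , , drop = FALSE],
                                    train_mode = TRUE, keep_cache = TRUE)
        net <- fwd$net                       # batch-norm running stats
        bwd <- net_backward(fwd, y[idx])
        if (!is.finite(bwd$loss))
          stop(sprintf("non-finite loss at epoch %d, batch %d", ep, bi))
        step <- step + 1L
        step_loss <- c(step_loss, bwd$loss)
        ep_loss <- ep_loss + bwd$loss * length(idx)
        ep_acc <- ep_acc + bwd$acc * length(idx)
        if (config$learning_rate > 0) {
          b1t <- 1 - config$beta1^step
          b2t <- 1 - config$beta2^step
          for (nm in names(bwd$grads)) {
            gmat <- bwd$grads[[nm]]
            mstate[[nm]] <- config$beta1 * mstate[[nm]] + (1 - config$beta1) * gmat
            vstate[[nm]] <- config$beta2 * vstate[[nm]] + (1 - config$beta2) * gmat^2
            upd <- config$learning_rate * (mstate[[nm]] / b1t) /
              (sqrt(vstate[[nm]] / b2t) + config$eps)
            net$params[[nm]] <- net$params[[nm]] - upd
          }
        }
        if (!is.null(config$max_steps) && step >= config$max_steps) {
          done <- TRUE; break
        }
      }
      loss_trace <- c(loss_trace, ep_loss / n)
      acc_trace <- c(acc_trace, ep_acc / n)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                        utils::tail(loss_trace, 1), utils::tail(acc_trace, 1)))
      if (!is.null(config$stop_at_acc) &&
          utils::tail(acc_trace, 1) >= config$stop_at_acc) done <- TRUE
      if (done) break
    }
  })
  structure(list(net = net, loss = loss_trace, accuracy = acc_trace,
                 steps = step, step_loss = step_loss, config = config),
            class = "train_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
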
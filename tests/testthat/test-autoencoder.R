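test_that("ae_forward matches the two-line sigmoid oracle", {
  set.seed(7)
  d <- 12L; h <- 5L
  params <- ae_params(matrix(rnorm(h * d), h, d), rnorm(h), rnorm(d))
  x <- matrix(runif(3 * d, 0.05, 0.95), 3, d)
  out <- ae_forward(x, params)
  sig <- function(z) 1 / (1 + exp(-z))
  for (i in 1:3) {
    h_i <- sig(params$W %*% x[i, ] + params$a)       # independent oracle
    y_i <- sig(t(params$W) %*% h_i + params$b)
    expect_equal(as.numeric(out$h[i, ]), as.numeric(h_i), tolerance = 1e-10)
    expect_equal(as.numeric(out$y[i, ]), as.numeric(y_i), tolerance = 1e-10)
  }
  expect_true(all(out$y > 0 & out$y < 1))
})

test_that("zero parameters map everything to one half", {
  params <- ae_params(matrix(0, 2, 6), numeric(2), numeric(6))
  out <- ae_forward(runif(6), params)
  expect_equal(as.numeric(out$h), rep(0.5, 2))
  expect_equal(as.numeric(out$y), rep(0.5, 6))
  expect_error(ae_forward(runif(5), params), "dim")
})

test_that("decoder weights are structurally tied to the encoder", {
  # a single matrix is stored; there is no decoder copy that could drift
  params <- ae_params(matrix(rnorm(12), 3, 4), rnorm(3), rnorm(4))
  expect_null(params$W2)
  expect_error(ae_params(matrix(0, 4, 4), numeric(4), numeric(4)),
               "compression")
})

test_that("reconstruction loss has its closed forms and a loop oracle", {
  d <- 17L
  x <- rep(0.5, d)
  expect_equal(reconstruction_loss(x, x), d * log(2), tolerance = 1e-12)
  set.seed(8)
  x <- runif(d); y <- runif(d, 0.01, 0.99)
  naive <- 0
  for (i in seq_len(d))
    naive <- naive - (x[i] * log(y[i]) + (1 - x[i]) * log(1 - y[i]))
  expect_equal(reconstruction_loss(x, y), naive, tolerance = 1e-10)
  # y = x minimizes the loss for fixed x
  base <- reconstruction_loss(x, pmin(pmax(x, 1e-6), 1 - 1e-6))
  for (k in 1:5) {
    pert <- pmin(pmax(x + rnorm(d, sd = 0.05), 1e-6), 1 - 1e-6)
    expect_gte(reconstruction_loss(x, pert), base)
  }
  expect_warning(reconstruction_loss(c(0.5, 0.5), c(1, 0.5)), "clipping")
})

test_that("training descends the true gradient of the mean loss", {
  ep <- random_epochs(5, C = 2, S = 6, seed = 3)
  lr <- 1e-3
  fit0 <- train_autoencoder(ep, hidden_dim = 3, lr = 0, n_iters = 1, seed = 2)
  fit1 <- train_autoencoder(ep, hidden_dim = 3, lr = lr, n_iters = 1, seed = 2)
  g_impl <- (fit0$params$W - fit1$params$W) / lr
  # central-difference oracle on J(theta)
  J <- function(W) {
    p <- ae_params(W, fit0$params$a, fit0$params$b)
    xs <- ae_scale(matrix(ep$data, 5, 12), fit0$scaler)
    mean(reconstruction_loss(xs, ae_forward(xs, p)$y))
  }
  hstep <- 1e-6
  set.seed(9)
  for (i in sample(length(fit0$params$W), 6)) {
    Wp <- fit0$params$W; Wp[i] <- Wp[i] + hstep
    Wm <- fit0$params$W; Wm[i] <- Wm[i] - hstep
    expect_equal(g_impl[i], (J(Wp) - J(Wm)) / (2 * hstep), tolerance = 1e-4)
  }
})

test_that("loss trace decreases and a single window is overfit", {
  ep <- random_epochs(8, C = 3, S = 25, seed = 5)
  fit <- train_autoencoder(ep, hidden_dim = 10, lr = 0.05, n_iters = 150,
                           seed = 3)
  tr <- fit$loss_trace
  expect_true(all(diff(tr) <= 1e-8))
  fit2 <- train_autoencoder(ep, hidden_dim = 10, lr = 0.05, n_iters = 150,
                            seed = 3)
  expect_identical(fit$params, fit2$params)

  one <- random_epochs(1, C = 2, S = 10, seed = 6)
  ofit <- train_autoencoder(one, hidden_dim = 8, lr = 0.5, n_iters = 3000,
                            seed = 1)
  xs <- ae_scale(matrix(one$data, 1, 20), ofit$scaler)
  expect_lt(max(abs(ae_forward(xs, ofit$params)$y - xs)), 0.05)
})

test_that("a trained autoencoder generalizes better than an untrained one", {
  tr_set <- labelled_windows(24, C = 4, S = 50, seed = 31)
  ho_set <- labelled_windows(24, C = 4, S = 50, seed = 32)
  fit <- train_autoencoder(tr_set, hidden_dim = 40, lr = 0.05, n_iters = 120,
                           seed = 2)
  raw <- train_autoencoder(ho_set, hidden_dim = 40, lr = 0, n_iters = 1,
                           seed = 2)
  xs <- ae_scale(matrix(ho_set$data, 24, 200), raw$scaler)
  loss_trained <- mean(reconstruction_loss(xs, ae_forward(xs, fit$params)$y))
  loss_untrained <- mean(reconstruction_loss(xs, ae_forward(xs, raw$params)$y))
  expect_true(is.finite(loss_trained))
  expect_lt(loss_trained, loss_untrained)
})

test_that("dataset expansion copies labels and preserves the originals", {
  ep <- random_epochs(12, C = 3, S = 20, seed = 7)
  fit <- train_autoencoder(ep, hidden_dim = 6, lr = 0.05, n_iters = 30,
                           seed = 1)
  expect_identical(expand_dataset(ep, fit$params, fit$scaler, 0L), ep)
  ex <- expand_dataset(ep, fit$params, fit$scaler, 1L)
  expect_equal(dim(ex$data)[1], 24L)
  expect_equal(as.vector(table(ex$labels)), 2L * as.vector(table(ep$labels)))
  expect_identical(ex$data[1:12, , ], ep$data)       # originals untouched
  expect_identical(ex$synthetic, rep(c(FALSE, TRUE), each = 12))
  expect_equal(ex$trial_ids[13:24], ep$trial_ids)
  # class proportions identical before and after
  expect_equal(prop.table(table(ex$labels)), prop.table(table(ep$labels)))
})
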
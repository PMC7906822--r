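test_that("leaky ReLU follows both branches and the boundary", {
  expect_equal(leaky_relu(2.0), 2.0)
  expect_equal(leaky_relu(-1.0), -0.01)
  expect_equal(leaky_relu(0.0), 0.0)
  expect_equal(leaky_relu(c(-2, 3), slope = 0.1), c(-0.2, 3))
})

test_that("the default build reproduces the reference layer stack", {
  net <- build_network(network_spec(), input_shape = c(22L, 250L), seed = 1)
  got <- sub(" \\(\\d+ filters\\)", "", network_layers(net))
  expect_identical(got, c(
    "Convolution 1x5", "Batch normalization", "Max pooling 1x2",
    "Convolution 1x3", "Batch normalization", "Max pooling 1x2",
    "Dropout layer",
    "Convolution 1x3", "Batch normalization", "Dropout layer",
    "Convolution 1x3", "Batch normalization",
    "Flattened layer",
    "BiLSTM layer 32", "BiLSTM layer 20",
    "Fully connected layer", "Dropout layer",
    "Attention layer", "Fully connected layer", "Softmax layer"))
  expect_equal(net$seq_len, 62L)                      # 250 -> 125 -> 62
  no_pool <- network_spec(conv_pools = c(1, 1, 1, 1))
  expect_equal(build_network(no_pool, c(22L, 250L))$seq_len, 250L)
  expect_error(build_network(network_spec(conv_pools = c(64, 64, 1, 1)),
                             c(22L, 16L)), "below one step")
})

test_that("posteriors are normalized and evaluation mode is deterministic", {
  net <- build_network(tiny_spec(fc_dropout = 0.3), c(5L, 32L), seed = 3)
  set.seed(1)
  X <- array(rnorm(8 * 5 * 32), c(8, 5, 32))
  X[2, , ] <- X[1, , ]                                # duplicated window
  p1 <- net_forward(net, X)
  expect_equal(rowSums(p1), rep(1, 8), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_equal(p1[1, ], p1[2, ], tolerance = 1e-12)
  set.seed(999)                                       # RNG must not matter
  p2 <- net_forward(net, X)
  expect_identical(unclass(p1), unclass(p2))
  # dropout makes training-mode forwards stochastic
  set.seed(5); q1 <- net_forward(net, X, train_mode = TRUE)
  set.seed(6); q2 <- net_forward(net, X, train_mode = TRUE)
  expect_false(identical(unclass(q1), unclass(q2)))
  expect_error(net_forward(net, array(0, c(2, 4, 32))), "geometry")
})

test_that("freshly initialized networks are unbiased across classes", {
  set.seed(2)
  X <- array(rnorm(100 * 4 * 32), c(100, 4, 32))
  mp <- rowMeans(vapply(1:6, function(s) {
    net <- build_network(tiny_spec(), c(4L, 32L), seed = s)
    colMeans(net_forward(net, X))
  }, numeric(4)))
  expect_equal(mp, rep(0.25, 4), tolerance = 0.08 / 0.25)
})

test_that("attention pooling matches a hand-rolled oracle and its limits", {
  set.seed(11)
  t_ <- 7L; d <- 5L; a <- 3L
  H <- matrix(rnorm(t_ * d), t_, d)
  params <- list(W1 = matrix(rnorm(d * a), d, a), b1 = rnorm(a),
                 w2 = rnorm(a), b2 = 0.3)
  out <- attention_pool(H, params)
  expect_equal(sum(out$alpha), 1, tolerance = 1e-12)
  expect_true(all(out$alpha >= 0))
  # brute-force loop oracle
  e <- numeric(t_)
  for (j in seq_len(t_))
    e[j] <- sum(params$w2 * tanh(t(params$W1) %*% H[j, ] + params$b1)) + params$b2
  al <- exp(e - max(e)); al <- al / sum(al)
  cv <- numeric(d)
  for (j in seq_len(t_)) cv <- cv + al[j] * H[j, ]
  expect_equal(out$alpha, al, tolerance = 1e-10)
  expect_equal(out$c, cv, tolerance = 1e-10)
  # singleton sequence and identical-step symmetry
  single <- attention_pool(H[1, , drop = FALSE], params)
  expect_equal(single$alpha, 1)
  expect_equal(single$c, H[1, ])
  same <- attention_pool(H[rep(2, 6), ], params)
  expect_equal(same$alpha, rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(same$c, H[2, ], tolerance = 1e-12)
})

test_that("fusion is an affine map of the summed projected branches", {
  set.seed(12)
  ds <- 6L; db <- 4L; sh <- 5L
  head <- fusion_head(matrix(rnorm(sh * ds), sh, ds),
                      matrix(rnorm(sh * db), sh, db),
                      matrix(rnorm(4 * sh), 4, sh), rnorm(4))
  as_ <- rnorm(ds); ab <- rnorm(db)
  got <- fuse(as_, ab, head)
  oracle <- head$W %*% (head$proj_s %*% as_ + head$proj_b %*% ab) + head$b
  expect_equal(got, as.numeric(oracle), tolerance = 1e-10)
  # zero BiLSTM branch leaves only the SCNN contribution
  expect_equal(fuse(as_, numeric(db), head),
               as.numeric(head$W %*% (head$proj_s %*% as_) + head$b),
               tolerance = 1e-12)
  # identity projections make the branches interchangeable
  idh <- fusion_head(diag(sh), diag(sh), head$W, head$b)
  u <- rnorm(sh); v <- rnorm(sh)
  expect_equal(fuse(u, v, idh), fuse(v, u, idh), tolerance = 1e-12)
  expect_error(fusion_head(diag(3), diag(4), head$W, head$b), "shared width")
  expect_error(fuse(rnorm(2), ab, head), "lengths")
})

test_that("backpropagation matches central finite differences everywhere", {
  set.seed(42)
  net <- build_network(tiny_spec(), c(3L, 16L), seed = 9)
  n <- 3L
  X <- array(rnorm(n * 3 * 16), c(n, 3, 16))
  y <- c(1L, 3L, 4L)
  fwd <- miattn:::net_forward_internal(net, X, train_mode = TRUE,
                                       keep_cache = TRUE)
  bwd <- miattn:::net_backward(fwd, y)
  loss_at <- function(nn) {
    f <- miattn:::net_forward_internal(nn, X, train_mode = TRUE)
    -mean(log(f$post[cbind(seq_len(n), y)]))
  }
  h <- 1e-5
  for (nm in names(net$params)) {
    for (i in sample(length(net$params[[nm]]),
                     min(3, length(net$params[[nm]])))) {
      np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + h
      lp <- loss_at(np)
      np$params[[nm]][i] <- np$params[[nm]][i] - 2 * h
      lm <- loss_at(np)
      num <- (lp - lm) / (2 * h)
      expect_equal(bwd$grads[[nm]][i], num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("one optimization step reaches both the first conv and the scorer", {
  ep <- random_epochs(8, C = 3, S = 16, seed = 13)
  net <- build_network(tiny_spec(), c(3L, 16L), seed = 2)
  ts <- train(net, ep, train_config(epochs = 1, minibatch = 8, seed = 1,
                                    learning_rate = 0.01))
  expect_false(identical(ts$net$params$conv1.W, net$params$conv1.W))
  expect_false(identical(ts$net$params$attn.W1, net$params$attn.W1))
  expect_false(identical(ts$net$params$lstm1f.Wx, net$params$lstm1f.Wx))
  expect_false(identical(ts$net$params$fc5.W, net$params$fc5.W))
})
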
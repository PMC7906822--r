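# A consistent completion of the worked-example confusion matrix: diagonal
# (64, 62, 64, 64), first row (64, 2, 5, 1), all column sums 72, total 288.
fig_cm_counts <- matrix(c(64, 2, 5, 1,
                          4, 62, 2, 3,
                          2, 4, 64, 4,
                          2, 4, 1, 64), 4, 4, byrow = TRUE)

cm_to_labels <- function(counts) {
  y_true <- integer(0); y_pred <- integer(0)
  for (p in 1:4) for (t in 1:4) {
    y_true <- c(y_true, rep(t, counts[p, t]))
    y_pred <- c(y_pred, rep(p, counts[p, t]))
  }
  list(true = y_true, pred = y_pred)
}

test_that("confusion counts conserve totals and reject bad input", {
  expect_equal(unclass(confusion(c(1, 2, 3, 4), c(1, 2, 3, 4))),
               diag(4L), ignore_attr = TRUE)
  set.seed(4)
  yt <- sample(1:4, 288, TRUE); yp <- sample(1:4, 288, TRUE)
  cm <- confusion(yt, yp)
  expect_equal(sum(cm), 288L)
  expect_equal(as.vector(colSums(cm)), as.vector(table(factor(yt, 1:4))))
  expect_error(confusion(1:3, 1:4), "equal length")
  expect_error(confusion(c(1, 5), c(1, 2)), "1..4")
})

test_that("one-vs-rest metrics reproduce the worked example exactly", {
  lab <- cm_to_labels(fig_cm_counts)
  cm <- confusion(lab$true, lab$pred)
  expect_equal(unname(unclass(cm)), fig_cm_counts, ignore_attr = TRUE)
  m <- class_metrics(cm)
  expect_identical(m$per_class$TPR[1], 64 / 72)       # 88.9%
  expect_identical(m$per_class$PPV[1], 64 / 72)       # 88.9%
  expect_identical(m$overall_acc, 254 / 288)          # 88.2%
})

test_that("metrics agree with an item-by-item counting oracle", {
  set.seed(9)
  for (n in c(37, 500, 1000)) {
    yt <- sample(1:4, n, TRUE); yp <- sample(1:4, n, TRUE)
    m <- class_metrics(confusion(yt, yp))
    for (k in 1:4) {
      tp <- sum(yt == k & yp == k); fp <- sum(yt != k & yp == k)
      fn <- sum(yt == k & yp != k); tn <- sum(yt != k & yp != k)
      expect_equal(m$per_class$ACC[k], (tp + tn) / n, tolerance = 1e-12)
      expect_equal(m$per_class$PPV[k], tp / (tp + fp), tolerance = 1e-12)
      expect_equal(m$per_class$TPR[k], tp / (tp + fn), tolerance = 1e-12)
      expect_equal(m$per_class$TNR[k], tn / (tn + fp), tolerance = 1e-12)
    }
    expect_equal(m$overall_acc, mean(yt == yp), tolerance = 1e-12)
  }
})

test_that("degenerate rates surface as explicit NA", {
  cm <- confusion(rep(1L, 10), rep(1L, 10))            # classes 2-4 absent
  m <- class_metrics(cm)
  expect_true(is.na(m$per_class$TPR[2]))               # no true class-2 items
  expect_false(any(is.nan(unlist(m$per_class[, -1]))))
})

test_that("kappa is the chance-corrected accuracy", {
  expect_equal(kappa_score(1, 4), 1)
  expect_equal(kappa_score(0.25, 4), 0)
  expect_equal(kappa_score(254 / 288, 4), (254 / 288 - 0.25) / 0.75,
               tolerance = 1e-15)                      # 0.8426
  for (C in 2:6) expect_equal(kappa_score(1 / C, C), 0, tolerance = 1e-15)
  accs <- seq(0, 1, by = 0.1)
  expect_true(all(diff(kappa_score(accs, 4)) > 0))
  expect_error(kappa_score(0.5, 1), "at least 2")
})

test_that("trial aggregation averages posteriors with a stable tie-break", {
  # one window per trial is plain argmax
  post <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.7, 0.1))
  expect_equal(aggregate_trials(post, c(1, 2))$pred, c(1L, 3L))
  # two windows: mean (0.4, 0.6, 0, 0) -> class 2
  post <- rbind(c(0.6, 0.4, 0, 0), c(0.2, 0.8, 0, 0))
  expect_equal(aggregate_trials(post, c(7, 7))$pred, 2L)
  # exact tie resolves to the lower class index
  post <- rbind(c(0.5, 0.5, 0, 0))
  expect_equal(aggregate_trials(post, 1)$pred, 1L)
})

test_that("subject summaries match the printed-table arithmetic", {
  accs <- c(88.2, 73.3, 79.7, 89.2, 80.6, 76.4, 90.3, 81.6, 85.4)
  s <- summarize_subjects(accs)
  expect_equal(round(s$mean_acc, 1), 82.7)
  # brute-force loop oracle, population sd
  m <- 0; for (a in accs) m <- m + a / length(accs)
  v <- 0; for (a in accs) v <- v + (a - m)^2 / length(accs)
  expect_equal(s$mean_acc, m, tolerance = 1e-10)
  expect_equal(s$sd_acc, sqrt(v), tolerance = 1e-10)
  expect_equal(summarize_subjects(rep(80, 4))$sd_acc, 0)
  s2 <- summarize_subjects(accs, sample_sd = TRUE)
  expect_equal(s2$sd_acc, sd(accs), tolerance = 1e-12)
  expect_error(summarize_subjects(numeric(0)), "at least one")
})
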
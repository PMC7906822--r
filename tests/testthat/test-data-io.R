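test_that("session archives round-trip exactly", {
  ses <- simulate_session(small_sim_config(), "S01", "train")
  path <- withr::local_tempfile(fileext = ".rds")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_session(ses, path, events_csv = csv)
  back <- read_session(path)
  expect_identical(back$signals, ses$signals)
  expect_identical(back$events, ses$events)
  expect_identical(utils::read.csv(csv)$class, ses$events$class)
  # the generic reader accepts the archive and re-labels the split
  again <- read_gdf_session(path, split = "test")
  expect_identical(again$signals, ses$signals)
  expect_equal(again$split, "test")
})

test_that("window extraction follows the train and test conventions", {
  ses <- simulate_session(small_sim_config(trials_per_run = 8), "S01", "train")
  tr <- extract_windows(ses, 2, 6, 1, 1)
  expect_equal(dim(tr$data), c(32L, 6L, 250L))       # 4 windows x 8 trials
  expect_equal(sort(unique(tr$window_onset)), c(2, 3, 4, 5))
  te <- extract_windows(ses, 4, 5, 1, 1)
  expect_equal(dim(te$data)[1], 8L)                  # single window per trial
  expect_equal(unique(te$window_onset), 4)
  # windows carry their trial's label and the raw samples, half-open [on, on+1)
  w <- which(tr$trial_ids == 3 & tr$window_onset == 4)
  s0 <- ses$events$onset_sample[3] + 4 * 250
  expect_identical(tr$data[w, , ], ses$signals[, (s0 + 1):(s0 + 250)])
  expect_equal(tr$labels[w], ses$events$class[3])
  expect_error(extract_windows(ses, 2, 8, 1, 1), "trial span")
  expect_error(extract_windows(ses, 2, 6, 1, 0), "positive")
})

test_that("a full 2a-sized session yields 1152 training windows", {
  ses <- default_train_session()
  ep <- extract_windows(ses, 2, 6, 1, 1)
  expect_equal(dim(ep$data)[1], 288L * 4L)
  expect_equal(as.vector(table(ep$labels)), rep(288L, 4))
  assign("default_train_epochs", ep, envir = .fixture_cache)
})

test_that("window counts match the placement formula for arbitrary strides", {
  ses <- simulate_session(small_sim_config(trials_per_run = 4), "S01", "train")
  grid <- expand.grid(t0 = c(2, 2.5), t1 = c(5, 6), win = c(0.5, 1),
                      stride = c(0.25, 0.5, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ep <- extract_windows(ses, g$t0, g$t1, g$win, g$stride)
    # counting oracle: enumerate onsets directly
    onsets <- seq(g$t0, g$t1, by = g$stride)
    n_per <- sum(onsets + g$win <= g$t1 + 1e-9)
    expect_equal(dim(ep$data)[1], 4L * n_per)
  }
})

test_that("standardization is exact, idempotent and affine-invariant", {
  ep <- random_epochs(12, C = 3, S = 40, seed = 2)
  z <- standardize(ep)
  x <- matrix(z$data, 12, 120)
  expect_lt(max(abs(rowMeans(x))), 1e-6)
  expect_lt(max(abs(apply(x, 1, sd) - 1)), 1e-6)
  z2 <- standardize(z)
  expect_equal(z2$data, z$data, tolerance = 1e-6)
  scaled <- ep
  scaled$data <- 3.7 * ep$data + 42
  expect_equal(standardize(scaled)$data, z$data, tolerance = 1e-8)
  flat <- ep
  flat$data[2, , ] <- 5
  expect_error(standardize(flat), "zero-variance")
})

test_that("merge_and_shuffle permutes all fields coherently and seeded", {
  a <- random_epochs(10, seed = 1)
  b <- random_epochs(10, seed = 2)
  b$subject_ids <- rep("T02", 10)
  m1 <- merge_and_shuffle(list(a, b), seed = 99)
  m2 <- merge_and_shuffle(list(a, b), seed = 99)
  expect_identical(m1, m2)
  m3 <- merge_and_shuffle(list(a, b), seed = 100)
  expect_false(identical(m1$labels, m3$labels) &&
                 identical(m1$data, m3$data))
  expect_equal(dim(m1$data)[1], 20L)
  expect_equal(sort(m1$labels), sort(c(a$labels, b$labels)))
  # window -> (label, subject) pairing survives the permutation
  key <- function(e) paste(e$labels, e$subject_ids, round(e$data[, 1, 1], 6))
  expect_setequal(key(m1), c(key(a), key(b)))
  # trial ids from different sets stay distinct
  expect_equal(length(unique(m1$trial_ids)), 20L)
  bad <- random_epochs(4, C = 5, S = 32)
  expect_error(merge_and_shuffle(list(a, bad), 1), "geometry")
})

test_that("epoch archives round-trip", {
  ep <- random_epochs(6)
  path <- withr::local_tempfile(fileext = ".rds")
  write_epochs(ep, path)
  expect_identical(read_epochs(path)$data, ep$data)
})
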
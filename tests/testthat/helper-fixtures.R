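# Shared fixtures and independent oracles. Everything is generated in code;
# heavyweight sessions are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small montage for fast unit tests: 6 channels, disjoint ERD pairs
small_sim_config <- function(seed = 11, attenuation = 0.5, n_runs = 1,
                             trials_per_run = 8, n_channels = 6) {
  simulation_config(seed = seed, n_runs = n_runs,
                    trials_per_run = trials_per_run,
                    n_channels = n_channels,
                    class_erd_map = default_erd_map(n_channels, attenuation))
}

default_train_session <- function() {
  cached("default_train", simulate_session(simulation_config(seed = 5),
                                           "A01", "train"))
}

# reduced-width network spec for fast tests (architecture shape unchanged)
tiny_spec <- function(...) {
  args <- list(conv_filters = c(2, 2, 3, 3), fc_width = 4,
               attention_dim = 3, bilstm_units = c(3, 2),
               conv_dropout = c(0, 0, 0, 0), fc_dropout = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(network_spec, args)
}

random_epochs <- function(n, C = 4, S = 32, seed = 1) {
  set.seed(seed)
  epoch_set(array(rnorm(n * C * S), c(n, C, S)),
            labels = rep_len(1:4, n), trial_ids = seq_len(n),
            subject_ids = rep("T01", n), window_onset = rep(0, n))
}

# matched-filter oscillation power at frequency f (independent of the
# package's band_power): squared amplitude of the least-squares sinusoid fit
osc_power_ls <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  co <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  sum(stats::lm.fit(co, x)$coefficients^2)
}

# windows with a class-specific oscillation pattern, linearly separable;
# used for overfit/recovery checks without running the full simulator
labelled_windows <- function(n, C = 6, S = 250, fs = 250, seed = 4) {
  set.seed(seed)
  labels <- rep_len(1:4, n)
  data <- array(rnorm(n * C * S, sd = 2), c(n, C, S))
  t <- (seq_len(S) - 1) / fs
  for (i in seq_len(n)) {
    ch <- ((labels[i] - 1) %% C) + 1
    data[i, ch, ] <- data[i, ch, ] + 6 * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
  }
  epoch_set(data, labels, seq_len(n), rep("T01", n), rep(0, n))
}
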
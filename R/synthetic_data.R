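#' Default class-to-channel ERD topography
#'
#' Motor imagery attenuates mu/beta rhythms over the cortical representation
#' of the imagined effector, contralaterally for the hands. For the 22-channel
#' 2a montage the defaults are: left hand over the right motor region (C4, C6,
#' CP4), right hand over the left motor region (C5, C3, CP3), foot over the
#' midline (Cz, CPz, Pz), tongue over fronto-central sites (FC3, FCz, FC4).
#' For other channel counts the channels are split round-robin into four
#' disjoint groups. The mapping is a config default, not hard-coded anywhere
#' downstream.
#'
#' @param n_channels number of channels in the montage.
#' @param attenuation amplitude attenuation factor in (0, 1] applied to the
#'   mu/beta oscillations of a class's channels during imagery (1 = no ERD).
#' @return named list (one entry per class) of `list(channels, attenuation)`.
#' @export
default_erd_map <- function(n_channels = 22, attenuation = 0.5) {
  if (n_channels == 22) {
    groups <- list(c(12, 13, 18), c(7, 8, 14), c(10, 16, 20), c(2, 4, 6))
  } else {
    idx <- seq_len(n_channels)
    groups <- split(idx, (idx - 1L) %% 4L + 1L)
  }
  stats::setNames(
    lapply(groups, function(ch) list(channels = as.integer(ch),
                                     attenuation = attenuation)),
    CLASS_NAMES)
}

#' Configuration for the synthetic 2a-style session generator
#'
#' Describes one recording session in the BCI Competition IV 2a layout:
#' `n_runs` runs of `trials_per_run` cued trials (balanced over the four
#' classes), 22 channels at 250 Hz, cue at 2 s and imagery from 3.25 s to 6 s
#' within a 7.5 s trial. The signal model is 1/f (pink) background noise plus
#' white noise plus randomized-phase mu and beta oscillations whose amplitude
#' is multiplied by the class's attenuation factor on that class's ERD
#' channels during the imagery interval.
#'
#' @param seed base seed; together with subject id and split it fixes the
#'   session byte-for-byte.
#' @param n_runs runs per session (default 6).
#' @param trials_per_run trials per run, divisible by 4 (default 48).
#' @param n_channels EEG channels (default 22).
#' @param sampling_rate in Hz (default 250).
#' @param trial_length_s,cue_onset_s,imagery_start_s,imagery_end_s paradigm
#'   timing in seconds (defaults 7.5, 2.0, 3.25, 6.0).
#' @param class_erd_map per-class ERD channels and attenuation; see
#'   [default_erd_map()].
#' @param mu_freq,beta_freq oscillation frequencies in Hz (10, 22).
#' @param mu_amp,beta_amp oscillation amplitudes in microvolts (7, 3.5).
#' @param pink_sd,white_sd background 1/f and white noise standard deviations
#'   in microvolts (5, 2).
#' @param amp_jitter_sd log-normal sd of per-trial amplitude jitter (0.1).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_runs = 6L,
                              trials_per_run = 48L,
                              n_channels = 22L,
                              sampling_rate = 250,
                              trial_length_s = 7.5,
                              cue_onset_s = 2.0,
                              imagery_start_s = 3.25,
                              imagery_end_s = 6.0,
                              class_erd_map = default_erd_map(n_channels),
                              mu_freq = 10, beta_freq = 22,
                              mu_amp = 7, beta_amp = 3.5,
                              pink_sd = 5, white_sd = 2,
                              amp_jitter_sd = 0.1) {
  stop_if_not_count(n_runs, "n_runs")
  stop_if_not_count(trials_per_run, "trials_per_run")
  stop_if_not_count(n_channels, "n_channels")
  if (trials_per_run %% 4L != 0L)
    stop("`trials_per_run` must be divisible by 4 (balanced classes)")
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive")
  if (!(0 <= cue_onset_s && cue_onset_s < imagery_start_s &&
        imagery_start_s < imagery_end_s && imagery_end_s <= trial_length_s))
    stop("timing marks must satisfy 0 <= cue < imagery start < imagery end <= trial length")
  if (length(class_erd_map) != 4L)
    stop("`class_erd_map` must have one entry per class (4)")
  for (cls in class_erd_map) {
    att <- cls$attenuation
    if (!is.numeric(att) || length(att) != 1L || att <= 0 || att > 1)
      stop("attenuation factors must lie in (0, 1]")
    if (length(cls$channels) &&
        (min(cls$channels) < 1L || max(cls$channels) > n_channels))
      stop("ERD channel index outside the montage")
  }
  structure(list(
    seed = as.integer(seed), n_runs = as.integer(n_runs),
    trials_per_run = as.integer(trials_per_run),
    n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
    trial_length_s = trial_length_s, cue_onset_s = cue_onset_s,
    imagery_start_s = imagery_start_s, imagery_end_s = imagery_end_s,
    class_erd_map = class_erd_map,
    mu_freq = mu_freq, beta_freq = beta_freq,
    mu_amp = mu_amp, beta_amp = beta_amp,
    pink_sd = pink_sd, white_sd = white_sd,
    amp_jitter_sd = amp_jitter_sd), class = "simulation_config")
}

# 1/f-amplitude ("pink") noise via spectral shaping, rescaled to sd `sd`.
pink_noise <- function(n, sd = 1) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1L))            # avoid dividing the DC bin by zero
  f <- pmin(f, n - f + 1)               # symmetric shaping keeps x real
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  sd * (x - mean(x)) / stats::sd(x)
}

#' Simulate one synthetic motor-imagery session
#'
#' Generates a continuous multichannel recording with `n_runs *
#' trials_per_run` cued, class-balanced trials. Identical `(config,
#' subject_id, split)` reproduce the identical signal; train and test splits
#' of the same subject are independent noise realizations.
#'
#' @param config a [simulation_config()].
#' @param subject_id subject label, e.g. `"S01"`.
#' @param split `"train"` or `"test"`.
#' @return a `raw_session`: list with `signals` (channel x sample matrix,
#'   microvolts), `events` (data.frame of 0-based `onset_sample` and `class`
#'   in 1..4), `sampling_rate`, `subject_id`, `split`, `trial_length_s`.
#' @export
simulate_session <- function(config, subject_id, split = c("train", "test")) {
  stopifnot(inherits(config, "simulation_config"))
  split <- match.arg(split)
  fs <- config$sampling_rate
  spt <- round(config$trial_length_s * fs)        # samples per trial
  n_trials <- config$n_runs * config$trials_per_run
  ns <- spt * n_trials
  C <- config$n_channels

  seed <- derive_seed(config$seed, "session", subject_id, split)
  with_seed(seed, {
    labels <- unlist(lapply(seq_len(config$n_runs), function(r)
      sample(rep(1:4, config$trials_per_run / 4L))))

    signals <- matrix(0, nrow = C, ncol = ns)
    for (ch in seq_len(C)) {
      signals[ch, ] <- pink_noise(ns, config$pink_sd) +
        stats::rnorm(ns, sd = config$white_sd)
    }

    # imagery-interval mask within one trial (half-open, 0-based samples)
    im_idx <- seq.int(floor(config$imagery_start_s * fs) + 1L,
                      min(ceiling(config$imagery_end_s * fs), spt))
    tvec <- (seq_len(spt) - 1L) / fs
    bands <- list(c(config$mu_freq, config$mu_amp),
                  c(config$beta_freq, config$beta_amp))

    for (tr in seq_len(n_trials)) {
      cls <- config$class_erd_map[[labels[tr]]]
      env <- matrix(1, nrow = spt, ncol = C)
      if (length(cls$channels)) env[im_idx, cls$channels] <- cls$attenuation
      cols <- seq.int((tr - 1L) * spt + 1L, tr * spt)
      for (band in bands) {
        phase <- stats::runif(C, 0, 2 * pi)
        amp <- band[2] * exp(stats::rnorm(C, sd = config$amp_jitter_sd))
        osc <- sin(outer(2 * pi * band[1] * tvec, rep(1, C)) +
                     matrix(phase, spt, C, byrow = TRUE))
        osc <- osc * env * matrix(amp, spt, C, byrow = TRUE)
        signals[, cols] <- signals[, cols] + t(osc)
      }
    }

    events <- data.frame(onset_sample = (seq_len(n_trials) - 1L) * spt,
                         class = as.integer(labels))
    raw_session(subject_id = subject_id, signals = signals, events = events,
                sampling_rate = fs, split = split,
                trial_length_s = config$trial_length_s)
  })
}
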
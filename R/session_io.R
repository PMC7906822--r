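#' Construct a raw session container
#'
#' One subject-session of continuous multichannel EEG plus its cue events.
#' The 2a dialect uses 22 EEG channels at 250 Hz with 288 cued trials per
#' session; other geometries are permitted for reduced test problems.
#'
#' @param subject_id subject label.
#' @param signals channel x sample numeric matrix (microvolts).
#' @param events data.frame with 0-based `onset_sample` (trial start) and
#'   `class` in 1..4.
#' @param sampling_rate Hz.
#' @param split `"train"` or `"test"`.
#' @param trial_length_s trial span in seconds used when epoching.
#' @return object of class `raw_session`.
#' @export
raw_session <- function(subject_id, signals, events, sampling_rate,
                        split = "train", trial_length_s = 7.5) {
  stopifnot(is.matrix(signals), is.data.frame(events),
            all(c("onset_sample", "class") %in% names(events)))
  if (nrow(events)) {
    if (any(events$class < 1L | events$class > 4L))
      stop("event classes must lie in 1..4")
    last_needed <- max(events$onset_sample) + round(trial_length_s * sampling_rate)
    if (last_needed > ncol(signals))
      stop("an event's trial extends beyond the recorded signal")
  }
  structure(list(subject_id = subject_id, signals = signals,
                 events = events, sampling_rate = sampling_rate,
                 split = split, trial_length_s = trial_length_s),
            class = "raw_session")
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session> %s [%s]: %d channels x %d samples @ %g Hz, %d events\n",
              x$subject_id, x$split, nrow(x$signals), ncol(x$signals),
              x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Write / read a session archive
#'
#' Sessions are persisted as a compressed serialized archive holding the
#' signal matrix, the event table and the metadata block, with an optional
#' sidecar events CSV (`onset_sample, class`) for interoperability.
#'
#' @param session a `raw_session`.
#' @param path archive path (conventionally `.rds`).
#' @param events_csv optional path for a plain-text event table.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, events_csv = NULL) {
  stopifnot(inherits(session, "raw_session"))
  saveRDS(unclass(session), path, compress = "gzip")
  if (!is.null(events_csv))
    utils::write.csv(session$events, events_csv, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  obj <- readRDS(path)
  raw_session(obj$subject_id, obj$signals, obj$events, obj$sampling_rate,
              obj$split, obj$trial_length_s)
}

#' Read a BCI Competition IV 2a session (GDF or package archive)
#'
#' For `.gdf` files the reader shells out to the bundled Python converter,
#' which uses `mne` to parse the GDF container, drops the configured EOG
#' channels, maps the 2a cue annotation codes 769-772 to classes 1-4
#' (left hand / right hand / foot / tongue) and hands the arrays back through
#' a Feather file (requires the `arrow` package and a `python` with `mne` on
#' the PATH). Package archives written by [write_session()] are read
#' directly.
#'
#' @param path a `.gdf` file or a session archive.
#' @param split `"train"` or `"test"`.
#' @param n_eeg expected EEG channel count after EOG removal (22 for 2a).
#' @param python python interpreter to use for GDF conversion.
#' @return a `raw_session` with `n_eeg` channels and labelled cue events.
#' @export
read_gdf_session <- function(path, split = c("train", "test"), n_eeg = 22L,
                             python = "python") {
  split <- match.arg(split)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!grepl("\\.gdf$", path, ignore.case = TRUE)) {
    ses <- read_session(path)
    ses$split <- split
    return(ses)
  }
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("reading GDF requires the `arrow` package for array interchange")
  conv <- system.file("python", "gdf_convert.py", package = "miattn")
  out <- tempfile("gdf")
  status <- system2(python, c(conv, shQuote(path), shQuote(out)),
                    stdout = FALSE, stderr = "")
  if (status != 0L) stop("GDF conversion failed (is python+mne available?)")
  sig <- t(as.matrix(as.data.frame(arrow::read_feather(paste0(out, "_signals.feather")))))
  meta <- jsonlite::read_json(paste0(out, "_meta.json"))
  events <- utils::read.csv(paste0(out, "_events.csv"))
  if (nrow(sig) != n_eeg)
    stop(sprintf("expected %d EEG channels after EOG removal, got %d",
                 n_eeg, nrow(sig)))
  raw_session(subject_id = meta$subject_id, signals = unname(sig),
              events = events, sampling_rate = meta$sampling_rate,
              split = split, trial_length_s = meta$trial_length_s)
}
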
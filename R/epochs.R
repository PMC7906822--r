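#' Construct an epoch set
#'
#' Stacked fixed-length windows cut from cued trials. Every window carries the
#' label of its trial, a trial id (windows from one trial share it), a subject
#' id, its onset in seconds from trial start, and a flag marking autoencoder
#' reconstructions.
#'
#' @param data window x channel x sample array.
#' @param labels integer classes in 1..4, one per window.
#' @param trial_ids non-negative integer per window.
#' @param subject_ids character per window.
#' @param window_onset numeric seconds from trial start, per window.
#' @param synthetic logical per window; `TRUE` for reconstructed windows.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, trial_ids, subject_ids, window_onset,
                      synthetic = rep(FALSE, length(labels))) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n <- dim(data)[1L]
  stopifnot(length(labels) == n, length(trial_ids) == n,
            length(subject_ids) == n, length(window_onset) == n,
            length(synthetic) == n)
  if (n && (any(labels < 1L | labels > 4L)))
    stop("labels must lie in 1..4")
  if (n && any(trial_ids < 0L)) stop("trial_ids must be non-negative")
  # a trial must carry a single label
  if (n && any(tapply(labels, trial_ids, function(l) length(unique(l))) != 1L))
    stop("windows of one trial must share the trial's label")
  structure(list(data = data, labels = as.integer(labels),
                 trial_ids = as.integer(trial_ids),
                 subject_ids = as.character(subject_ids),
                 window_onset = as.numeric(window_onset),
                 synthetic = as.logical(synthetic)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d windows x %d channels x %d samples (%d trials, %d subjects, %d synthetic)\n",
              d[1], d[2], d[3], length(unique(x$trial_ids)),
              length(unique(x$subject_ids)), sum(x$synthetic)))
  invisible(x)
}

n_windows <- function(epochs) dim(epochs$data)[1L]

#' Cut fixed-length windows from every trial of a session
#'
#' Within each trial, windows are placed at onsets `t_start, t_start +
#' stride, ...` (seconds from trial start) while `onset + win <= t_end`;
#' windows are half-open `[onset, onset + win)` in 0-based samples. The
#' training convention is `(2, 6, 1, 1)` — four non-overlapping 1 s windows
#' from the 2-6 s interval — and the test convention `(4, 5, 1, 1)`, the
#' single 1 s window starting 0.75 s after imagery onset at 3.25 s.
#'
#' @param session a `raw_session`.
#' @param t_start,t_end window placement interval in seconds from trial start.
#' @param win window length in seconds.
#' @param stride step between window onsets in seconds (default: `win`,
#'   non-overlapping).
#' @return an `epoch_set`; trial ids number the session's events from 1.
#' @export
extract_windows <- function(session, t_start = 2, t_end = 6, win = 1,
                            stride = win) {
  stopifnot(inherits(session, "raw_session"))
  if (stride <= 0) stop("`stride` must be positive")
  if (t_end - t_start < win) stop("`t_end - t_start` must be at least `win`")
  if (t_end > session$trial_length_s)
    stop("window interval exceeds the trial span")
  fs <- session$sampling_rate
  wlen <- round(win * fs)
  onsets <- seq(t_start, t_end - win + 1e-9, by = stride)
  onsets <- onsets[onsets + win <= t_end + 1e-9]
  n_tr <- nrow(session$events)
  n <- n_tr * length(onsets)
  C <- nrow(session$signals)

  data <- array(0, dim = c(n, C, wlen))
  labels <- integer(n); trial_ids <- integer(n); w_on <- numeric(n)
  k <- 0L
  for (tr in seq_len(n_tr)) {
    base <- session$events$onset_sample[tr]
    for (on in onsets) {
      k <- k + 1L
      s0 <- base + round(on * fs)            # 0-based start sample
      if (s0 + wlen > ncol(session$signals))
        stop("window exceeds the recorded signal")
      data[k, , ] <- session$signals[, (s0 + 1L):(s0 + wlen)]
      labels[k] <- session$events$class[tr]
      trial_ids[k] <- tr
      w_on[k] <- on
    }
  }
  epoch_set(data, labels, trial_ids,
            rep(session$subject_id, n), w_on)
}

#' Standardize windows to zero mean and unit standard deviation
#'
#' Applies `(x - mean) / sd` to each window over all of its channel-samples
#' (per-channel scope available via `scope = "channel"`), so every window
#' conforms to a standard normal scale before entering the network. The
#' transform is idempotent and invariant to affine rescaling of the input.
#'
#' @param epochs an `epoch_set`.
#' @param scope `"window"` (default) or `"channel"`.
#' @return the standardized `epoch_set`.
#' @export
standardize <- function(epochs, scope = c("window", "channel")) {
  stopifnot(inherits(epochs, "epoch_set"))
  scope <- match.arg(scope)
  d <- dim(epochs$data)
  x <- matrix(epochs$data, d[1L], d[2L] * d[3L])
  if (scope == "window") {
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
    if (any(sdv == 0))
      stop("zero-variance (constant) window: standardization undefined")
    epochs$data <- array((x - mu) / sdv, dim = d)
  } else {
    for (ch in seq_len(d[2L])) {
      xc <- epochs$data[, ch, , drop = FALSE]
      m <- apply(xc, 1L, mean); s <- apply(xc, 1L, stats::sd)
      if (any(s == 0))
        stop("zero-variance channel in a window: standardization undefined")
      epochs$data[, ch, ] <- (matrix(xc, d[1L], d[3L]) - m) / s
    }
  }
  epochs
}

#' Concatenate epoch sets and shuffle with a seed
#'
#' Merges the sets (trial ids are offset so they stay unique across sets) and
#' applies one seeded permutation identically to data, labels, trial ids,
#' subject ids, onsets and synthetic flags.
#'
#' @param epoch_sets list of `epoch_set`s sharing window geometry.
#' @param seed integer permutation seed.
#' @return the merged, reordered `epoch_set`.
#' @export
merge_and_shuffle <- function(epoch_sets, seed) {
  stopifnot(length(epoch_sets) >= 1L)
  geos <- vapply(epoch_sets, function(e) dim(e$data)[2:3], numeric(2))
  if (any(geos[1, ] != geos[1, 1]) || any(geos[2, ] != geos[2, 1]))
    stop("all epoch sets must share channel/sample geometry")
  offset <- 0L
  parts <- lapply(epoch_sets, function(e) {
    e$trial_ids <- e$trial_ids + offset
    offset <<- max(e$trial_ids)
    e
  })
  data <- do.call(abind3, lapply(parts, `[[`, "data"))
  cat_field <- function(f) do.call(c, lapply(parts, `[[`, f))
  merged <- epoch_set(data, cat_field("labels"), cat_field("trial_ids"),
                      cat_field("subject_ids"), cat_field("window_onset"),
                      cat_field("synthetic"))
  perm <- with_seed(derive_seed(seed, "shuffle"),
                    sample.int(n_windows(merged)))
  subset_epochs(merged, perm)
}

# bind 3-d arrays along the first axis
abind3 <- function(...) {
  arrs <- list(...)
  ns <- vapply(arrs, function(a) dim(a)[1L], integer(1))
  d <- dim(arrs[[1L]])
  out <- array(0, dim = c(sum(ns), d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    if (dim(a)[1L]) out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$trial_ids[idx], epochs$subject_ids[idx],
            epochs$window_onset[idx], epochs$synthetic[idx])
}

#' Write / read an epoch-set archive
#'
#' @param epochs an `epoch_set`.
#' @param path archive path (`.rds`).
#' @param labels_csv optional plain-text label table
#'   (window, label, trial_id, subject_id, window_onset, synthetic).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, labels_csv = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(unclass(epochs), path, compress = "gzip")
  if (!is.null(labels_csv)) {
    utils::write.csv(data.frame(window = seq_along(epochs$labels),
                                label = epochs$labels,
                                trial_id = epochs$trial_ids,
                                subject_id = epochs$subject_ids,
                                window_onset = epochs$window_onset,
                                synthetic = epochs$synthetic),
                     labels_csv, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  o <- readRDS(path)
  epoch_set(o$data, o$labels, o$trial_ids, o$subject_ids, o$window_onset,
            o$synthetic)
}
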
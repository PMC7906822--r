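#' miattn: motor-imagery EEG decoding with attention-based feature fusion
#'
#' Four-class motor-imagery decoding (left hand / right hand / foot / tongue)
#' in the BCI Competition IV 2a layout: synthetic ERD/ERS session simulation,
#' epoching and per-window standardization, tied-weight autoencoder data
#' expansion, a shallow CNN serially fused with a two-layer BiLSTM through
#' softmax attention pooling, minibatch Adam training, and one-vs-rest
#' confusion metrics with Cohen's kappa.
#'
#' @keywords internal
#' @useDynLib miattn, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

CLASS_NAMES <- c("left_hand", "right_hand", "foot", "tongue")

#' Derive a reproducible child seed from a base seed and string labels
#'
#' Stages and subjects draw independent random streams from one experiment
#' seed; the derivation is a plain polynomial string hash kept below 2^31 so
#' identical (seed, labels) always map to the identical stream.
#'
#' @param seed base integer seed.
#' @param ... character or numeric labels identifying the consumer.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (lab in list(...)) {
    for (code in utf8ToInt(paste0(as.character(lab), collapse = "/"))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Leaky rectified linear activation
#'
#' Identity for positive inputs, `slope * x` for non-positive inputs (the
#' boundary x = 0 maps to 0 under either branch).
#'
#' @param x numeric vector, matrix or array.
#' @param slope negative-branch slope, default 0.01.
#' @return object of the same shape as `x`.
#' @examples
#' leaky_relu(c(-1, 0, 2))
#' @export
leaky_relu <- function(x, slope = 0.01) {
  stopifnot(all(is.finite(x)))
  ifelse(x > 0, x, slope * x)
}

# Row-wise numerically stable softmax of a matrix of logits.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Periodogram band power of a signal
#'
#' Mean power of the raw periodogram in a frequency band, used to quantify
#' event-related desynchronization of the mu (8-12 Hz) and beta (16-31 Hz)
#' rhythms.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param f_lo,f_hi band edges in Hz (inclusive).
#' @return mean periodogram power over the band (signal units squared).
#' @export
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  stopifnot(n > 1L, f_lo < f_hi, f_hi <= fs / 2)
  sp <- abs(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1L) * fs / n
  keep <- freqs >= f_lo & freqs <= f_hi & freqs <= fs / 2
  if (!any(keep)) stop("band contains no Fourier frequency at this length")
  mean(sp[keep])
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("`%s` must be a positive integer, got %s", name,
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
}
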
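#' Frequency band specification
#'
#' @param name band label.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return object of class `band_spec`.
#' @seealso [eeg_bands()] for the canonical set.
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1, low > 0, high > low)
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("band %s: %g-%g Hz\n", x$name, x$low, x$high)); invisible(x)
}

#' Canonical EEG band set
#'
#' delta 1-3, theta 4-7, alpha 8-13, beta 14-30 Hz and the whole band
#' 1-45 Hz.
#'
#' @param names optional subset of band names to return.
#' @return named list of [band_spec()] objects.
#' @export
eeg_bands <- function(names = NULL) {
  all <- list(delta = band_spec("delta", 1, 3),
              theta = band_spec("theta", 4, 7),
              alpha = band_spec("alpha", 8, 13),
              beta  = band_spec("beta", 14, 30),
              whole = band_spec("whole", 1, 45))
  if (is.null(names)) return(all)
  missing <- setdiff(names, names(all))
  if (length(missing)) stop("unknown band(s): ", paste(missing, collapse = ", "))
  all[names]
}

# Linear-phase band-pass FIR, Hamming window; even order chosen so the
# transition width is ~25% of the lower band edge.
design_fir <- function(band, fs) {
  if (!(band$low > 0 && band$high < fs / 2))
    stop(sprintf("band edges (%g, %g) Hz outside (0, %g) at fs = %g",
                 band$low, band$high, fs / 2, fs))
  trans <- 0.25 * band$low
  ord <- ceiling(3.3 * fs / trans)
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, c(band$low, band$high) / (fs / 2), type = "pass")
}

# Full linear convolution via FFT (mixed-radix lengths).
conv_fft <- function(x, h) {
  n <- length(x) + length(h) - 1
  nfft <- stats::nextn(n, c(2, 3, 5))
  y <- Re(fft(fft(c(x, rep(0, nfft - length(x)))) *
                fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Zero-phase filtering of every row of X: convolve with conv(h, rev(h))
# (symmetric kernel, squared magnitude response, exactly zero phase) and
# realign. Odd-reflection padding at both ends limits edge transients, as in
# classic filtfilt. The kernel FFT is shared across channels.
zero_phase_filter_matrix <- function(X, h) {
  g <- conv_fft(h, rev(h))
  L <- length(h) - 1
  n <- ncol(X)
  p <- min(L, n - 1)
  np <- n + 2 * p
  nfft <- stats::nextn(np + length(g) - 1, c(2, 3, 5))
  G <- fft(c(g, rep(0, nfft - length(g))))
  out <- X
  keep <- (L + p + 1):(L + p + n)
  for (ch in seq_len(nrow(X))) {
    x <- X[ch, ]
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)],
            rep(0, nfft - np))
    y <- Re(fft(fft(xp) * G, inverse = TRUE)) / nfft
    out[ch, ] <- y[keep]
  }
  out
}

zero_phase_filter <- function(x, h)
  as.numeric(zero_phase_filter_matrix(matrix(x, nrow = 1), h))

#' Zero-phase band-pass filter a recording
#'
#' Applies an even-order linear-phase Hamming-window FIR (transition width
#' 25% of the lower band edge) forward and backward to every channel, so the
#' net response has zero phase and squared magnitude. Markers and length are
#' unchanged; roughly one filter length at each end of the recording is
#' edge-affected.
#'
#' @param recording an [eeg_recording()].
#' @param band a [band_spec()], valid at the recording's sampling rate.
#' @return filtered [eeg_recording()].
#' @export
bandpass <- function(recording, band) {
  h <- design_fir(band, recording$fs)
  out <- recording
  out$data <- zero_phase_filter_matrix(recording$data, h)
  out
}

#' Downsample a recording by an integer factor
#'
#' Zero-phase FIR anti-alias filtering followed by decimation. Marker sample
#' indices are rescaled by the factor (floor rule on 0-based indices).
#'
#' @param recording an [eeg_recording()].
#' @param target_fs target sampling rate in Hz; `fs / target_fs` must be an
#'   integer.
#' @return decimated [eeg_recording()] at `target_fs`.
#' @export
downsample <- function(recording, target_fs) {
  q <- recording$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop(sprintf("fs %g is not an integer multiple of target %g",
                 recording$fs, target_fs))
  q <- as.integer(round(q))
  if (q == 1L) return(recording)
  ord <- max(60L, 20L * q)
  if (ord %% 2 == 1) ord <- ord + 1
  h <- signal::fir1(ord, 0.8 / q, type = "low")
  dat <- zero_phase_filter_matrix(recording$data, h)
  keep <- seq(1L, ncol(dat), by = q)
  markers <- recording$markers
  if (nrow(markers))
    markers$sample <- as.integer(floor((markers$sample - 1L) / q) + 1L)
  eeg_recording(dat[, keep, drop = FALSE], target_fs,
                recording$channel_labels, markers)
}

#' Cut a recording into baseline-corrected per-trial epochs
#'
#' For every onset marker, extracts `[onset + start_s, onset + end_s)` and
#' subtracts the per-channel mean of the baseline interval
#' `[onset + b0, onset + b1)` (default: the 1-s fixation preceding the
#' stimulus). Half-open windows on 0-based sample offsets.
#'
#' @param recording an [eeg_recording()] with onset markers.
#' @param window numeric `(start_s, end_s)` relative to stimulus onset;
#'   default `c(0, 2)`.
#' @param baseline numeric `(b0_s, b1_s)` relative to onset; default
#'   `c(-1, 0)`. `NULL` disables baseline correction.
#' @param band optional [band_spec()] recorded as epoch metadata.
#' @return an `epoch_set`: list with `data` (channels x samples x trials
#'   array), `fs`, `band`, `condition_labels`, `window`.
#' @export
segment_epochs <- function(recording, window = c(0, 2), baseline = c(-1, 0),
                           band = NULL) {
  stopifnot(length(window) == 2, window[2] > window[1])
  fs <- recording$fs
  n_win <- as.integer(round((window[2] - window[1]) * fs))
  markers <- recording$markers
  if (!nrow(markers)) stop("recording has no onset markers")
  n_samp <- ncol(recording$data)
  M <- nrow(recording$data)
  dat <- array(0, dim = c(M, n_win, nrow(markers)))
  for (i in seq_len(nrow(markers))) {
    i0 <- markers$sample[i] + as.integer(round(window[1] * fs))
    i1 <- i0 + n_win - 1L
    if (i0 < 1L || i1 > n_samp)
      stop(sprintf("trial %d: window [%d, %d] exceeds recording bounds [1, %d]",
                   i, i0, i1, n_samp))
    ep <- recording$data[, i0:i1, drop = FALSE]
    if (!is.null(baseline)) {
      b0 <- markers$sample[i] + as.integer(round(baseline[1] * fs))
      b1 <- markers$sample[i] + as.integer(round(baseline[2] * fs)) - 1L
      if (b0 < 1L || b1 > n_samp)
        stop(sprintf("trial %d: baseline [%d, %d] exceeds recording bounds",
                     i, b0, b1))
      ep <- ep - rowMeans(recording$data[, b0:b1, drop = FALSE])
    }
    dat[, , i] <- ep
  }
  structure(list(data = dat, fs = fs, band = band,
                 condition_labels = markers$condition, window = window,
                 channel_labels = recording$channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples @ %g Hz%s\n",
              d[3], d[1], d[2], x$fs,
              if (!is.null(x$band)) sprintf(" [%s band]", x$band$name) else ""))
  invisible(x)
}

#' Standard preprocessing chain for one band
#'
#' Whole-band (1-45 Hz) zero-phase filtering of the continuous recording,
#' decimation to `target_fs`, per-band filtering, then segmentation with
#' baseline correction.
#'
#' @inheritParams segment_epochs
#' @param band a [band_spec()] for the analysis band.
#' @param target_fs processing rate (default 250 Hz).
#' @param prefilter whole-band [band_spec()] applied before decimation; set
#'   `NULL` to skip.
#' @return an `epoch_set`.
#' @export
preprocess_session <- function(recording, band, target_fs = 250,
                               window = c(0, 2), baseline = c(-1, 0),
                               prefilter = band_spec("whole", 1, 45)) {
  rec <- recording
  if (!is.null(prefilter)) rec <- bandpass(rec, prefilter)
  if (target_fs != rec$fs) rec <- downsample(rec, target_fs)
  rec <- bandpass(rec, band)
  segment_epochs(rec, window = window, baseline = baseline, band = band)
}
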
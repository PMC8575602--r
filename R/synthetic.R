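#' Configuration for a synthetic EEG session
#'
#' Describes one recording session of the two-condition stimulation protocol:
#' a block of random-sequence (RSD) trials followed by a block of Gestalt
#' (GST) trials, each trial being fixation + stimulus + rest. The generator
#' emulates the statistical structure the downstream analysis assumes:
#' condition-dependent inter-channel phase coherence. Under GST a subset of
#' channels (`cluster_channels`) shares a common band-limited phase process
#' with mixing weight `coupling_gst`; under RSD every channel shares a weak
#' global process with weight `coupling_rsd`.
#'
#' Couplings are convex mixture weights in \[0, 1\] between a channel's
#' private oscillator phase and the shared phase. The defaults
#' (`coupling_gst = 0.85`, `coupling_rsd = 0.15`) yield within-cluster
#' phase-locking values around 0.6-0.8 for GST and diffuse values around
#' 0.1-0.2 for RSD on two-second alpha-band epochs, the regimes the analysis
#' is designed to separate.
#'
#' @param n_channels number of electrodes (default 19, a 10-20-style montage;
#'   larger caps, e.g. 64, are supported).
#' @param fs_acquire acquisition sampling rate in Hz (default 1000).
#' @param n_rsd_trials,n_gst_trials trial counts per condition (defaults 30
#'   and 10; RSD trials always precede GST trials).
#' @param fixation_s,stimulus_s,rest_s trial phase durations in seconds
#'   (defaults 1, 10, 1).
#' @param carrier_band [band_spec()] of the evoked oscillation (default alpha,
#'   8-13 Hz).
#' @param coupling_gst,coupling_rsd shared-phase mixture weights in \[0, 1\]
#'   with `coupling_rsd < coupling_gst`.
#' @param cluster_channels channel indices forming the coherent GST cluster
#'   (default `1:8`).
#' @param noise_sd standard deviation of the additive broadband Gaussian
#'   noise, in the same arbitrary units as the unit-amplitude oscillators.
#' @param amp_mod_depth depth of the slow amplitude modulation of each
#'   oscillator (0 = constant envelope).
#' @param linewidth_hz Lorentzian linewidth of the oscillators' Wiener phase
#'   drift, in Hz; controls how fast independent channels decohere.
#' @param pink_noise logical; add 1/f-shaped instead of white noise. Off by
#'   default: the pipeline band-filters anyway.
#' @param seed master integer seed; per-trial substreams are derived from
#'   (seed, trial index) so any trial is reproducible in isolation.
#'
#' @return an object of class `session_config` (a validated list).
#' @examples
#' cfg <- session_config(n_rsd_trials = 2, n_gst_trials = 1, stimulus_s = 3)
#' rec <- generate_session(cfg)
#' rec
#' @export
session_config <- function(n_channels = 19, fs_acquire = 1000,
                           n_rsd_trials = 30, n_gst_trials = 10,
                           fixation_s = 1, stimulus_s = 10, rest_s = 1,
                           carrier_band = band_spec("alpha", 8, 13),
                           coupling_gst = 0.85, coupling_rsd = 0.15,
                           cluster_channels = seq_len(min(8, n_channels)),
                           noise_sd = 1, amp_mod_depth = 0.5,
                           linewidth_hz = 1.5, pink_noise = FALSE,
                           seed = 1L) {
  stopifnot(n_channels >= 2, fs_acquire > 0,
            n_rsd_trials >= 0, n_gst_trials >= 0,
            fixation_s > 0, stimulus_s > 0, rest_s > 0,
            noise_sd >= 0, amp_mod_depth >= 0, linewidth_hz > 0)
  if (!(coupling_rsd >= 0 && coupling_rsd <= coupling_gst && coupling_gst <= 1))
    stop("couplings must satisfy 0 <= coupling_rsd <= coupling_gst <= 1")
  cluster_channels <- as.integer(cluster_channels)
  if (length(cluster_channels) < 1 ||
      any(cluster_channels < 1L | cluster_channels > n_channels))
    stop("cluster_channels must be a non-empty subset of 1..n_channels")
  if (!inherits(carrier_band, "band_spec")) stop("carrier_band must be a band_spec")
  structure(list(
    n_channels = as.integer(n_channels), fs_acquire = fs_acquire,
    n_rsd_trials = as.integer(n_rsd_trials), n_gst_trials = as.integer(n_gst_trials),
    fixation_s = fixation_s, stimulus_s = stimulus_s, rest_s = rest_s,
    carrier_band = carrier_band,
    coupling_gst = coupling_gst, coupling_rsd = coupling_rsd,
    cluster_channels = cluster_channels, noise_sd = noise_sd,
    amp_mod_depth = amp_mod_depth, linewidth_hz = linewidth_hz,
    pink_noise = pink_noise, seed = as.integer(seed)
  ), class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("Synthetic EEG session config: %d channels @ %g Hz\n",
              x$n_channels, x$fs_acquire))
  cat(sprintf("  trials: %d RSD then %d GST, %g+%g+%g s each\n",
              x$n_rsd_trials, x$n_gst_trials,
              x$fixation_s, x$stimulus_s, x$rest_s))
  cat(sprintf("  carrier %s (%g-%g Hz), coupling GST %.2f / RSD %.2f, cluster {%s}\n",
              x$carrier_band$name, x$carrier_band$low, x$carrier_band$high,
              x$coupling_gst, x$coupling_rsd,
              paste(x$cluster_channels, collapse = ",")))
  invisible(x)
}

#' Multichannel EEG recording container
#'
#' @param data channels x samples numeric matrix (arbitrary microvolt-like
#'   units).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param markers data.frame with columns `sample` (1-based index of the
#'   stimulus onset), `condition` (`"GST"` or `"RSD"`) and `event`
#'   (`"onset"`); sample indices must be strictly increasing and in range.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, markers = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must equal the number of channels")
  if (is.null(markers))
    markers <- data.frame(sample = integer(0), condition = character(0),
                          event = character(0))
  if (nrow(markers)) {
    if (any(diff(markers$sample) <= 0))
      stop("marker sample indices must be strictly increasing")
    if (any(markers$sample < 1L) || any(markers$sample > ncol(data)))
      stop("marker sample indices out of range")
    if (!all(markers$condition %in% c("GST", "RSD")))
      stop("marker conditions must be GST or RSD")
  }
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 markers = markers),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$markers)))
  if (nrow(x$markers))
    cat(sprintf("  conditions: %s\n",
                paste(sprintf("%s x%d", names(table(x$markers$condition)),
                              table(x$markers$condition)), collapse = ", ")))
  invisible(x)
}

# One band-limited oscillator phase/envelope pair of length n.
# Phase = 2*pi*f0*t + Wiener drift; envelope = 1 + depth * slow noise.
osc_process <- function(n, fs, band, linewidth_hz, depth) {
  w <- band$high - band$low
  f0 <- runif(1, band$low + 0.1 * w, band$high - 0.1 * w)
  sigma <- sqrt(2 * pi * linewidth_hz / fs)
  phase <- 2 * pi * f0 * seq_len(n) / fs + cumsum(rnorm(n, 0, sigma))
  if (depth > 0) {
    k <- max(3L, as.integer(round(fs / 2)))  # ~0.5 s running mean
    w <- rnorm(n + k)
    cs <- cumsum(w)
    z <- (cs[(k + 1):(n + k)] - cs[1:n]) / sqrt(k)  # unit variance
    env <- pmax(1 + depth * z, 0.05)
  } else env <- rep(1, n)
  list(phase = phase, env = env)
}

# 1/f-ish noise via FFT shaping of white noise.
pink_noise_vec <- function(n, sd) {
  w <- rnorm(n)
  f <- c(1, seq_len(n - 1))
  shaped <- Re(fft(fft(w) / sqrt(f), inverse = TRUE)) / n
  shaped / sd(shaped) * sd
}

#' Generate a single synthetic trial
#'
#' Produces one fixation + stimulus + rest trial. During the stimulus window
#' each channel carries an amplitude-modulated band-limited oscillator whose
#' phase (and envelope) is a convex mixture of a private process and a shared
#' process: mixing weight `coupling_gst` for cluster channels under GST,
#' `coupling_rsd` for every channel under RSD, 0 otherwise. Broadband noise is
#' added over the whole trial. Bit-reproducible given (config seed,
#' `trial_index`, `condition`).
#'
#' @param config a [session_config()].
#' @param condition `"GST"` or `"RSD"`.
#' @param trial_index integer used to derive the trial's RNG substream.
#' @return channels x samples numeric matrix for the full trial.
#' @export
generate_trial <- function(config, condition, trial_index = 0L) {
  if (!condition %in% c("GST", "RSD"))
    stop(sprintf("invalid condition label '%s': must be GST or RSD", condition))
  cfg <- config
  fs <- cfg$fs_acquire
  n_fix <- round(cfg$fixation_s * fs)
  n_stim <- round(cfg$stimulus_s * fs)
  n_rest <- round(cfg$rest_s * fs)
  n_tot <- n_fix + n_stim + n_rest
  M <- cfg$n_channels
  salt <- if (condition == "GST") 1L else 2L
  with_local_seed(substream_seed(cfg$seed, trial_index, salt), {
    x <- matrix(0, M, n_tot)
    if (cfg$noise_sd > 0) {
      if (cfg$pink_noise) {
        for (ch in seq_len(M)) x[ch, ] <- pink_noise_vec(n_tot, cfg$noise_sd)
      } else {
        x[] <- rnorm(M * n_tot, 0, cfg$noise_sd)
      }
    }
    shared <- osc_process(n_stim, fs, cfg$carrier_band, cfg$linewidth_hz,
                          cfg$amp_mod_depth)
    members <- if (condition == "GST") cfg$cluster_channels else seq_len(M)
    c_mix <- if (condition == "GST") cfg$coupling_gst else cfg$coupling_rsd
    stim_cols <- (n_fix + 1):(n_fix + n_stim)
    for (ch in seq_len(M)) {
      priv <- osc_process(n_stim, fs, cfg$carrier_band, cfg$linewidth_hz,
                          cfg$amp_mod_depth)
      w <- if (ch %in% members) c_mix else 0
      phase <- (1 - w) * priv$phase + w * shared$phase
      env <- (1 - w) * priv$env + w * shared$env
      gain <- exp(rnorm(1, 0, 0.2))
      x[ch, stim_cols] <- x[ch, stim_cols] + gain * env * cos(phase)
    }
    x
  })
}

#' Generate a full synthetic session
#'
#' Concatenates `n_rsd_trials` RSD trials followed by `n_gst_trials` GST
#' trials and places an onset marker at each stimulus start (i.e. after the
#' fixation interval of every trial).
#'
#' @param config a [session_config()].
#' @return an [eeg_recording()] of
#'   `(n_rsd_trials + n_gst_trials) * (fixation_s + stimulus_s + rest_s) * fs`
#'   samples.
#' @export
generate_session <- function(config) {
  cfg <- config
  fs <- cfg$fs_acquire
  n_fix <- round(cfg$fixation_s * fs)
  n_trial <- n_fix + round(cfg$stimulus_s * fs) + round(cfg$rest_s * fs)
  conditions <- c(rep("RSD", cfg$n_rsd_trials), rep("GST", cfg$n_gst_trials))
  n_trials <- length(conditions)
  data <- matrix(0, cfg$n_channels, n_trial * n_trials)
  onsets <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    cols <- ((i - 1) * n_trial + 1):(i * n_trial)
    data[, cols] <- generate_trial(cfg, conditions[i], trial_index = i)
    onsets[i] <- (i - 1) * n_trial + n_fix + 1L
  }
  markers <- data.frame(sample = onsets, condition = conditions,
                        event = "onset", stringsAsFactors = FALSE)
  if (n_trials == 0)
    markers <- data.frame(sample = integer(0), condition = character(0),
                          event = character(0))
  eeg_recording(data, fs, markers = markers)
}
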
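#' @section Synthetic cohorts:
#' The synthesis model emulates the statistical structure an EEG
#' authentication pipeline exploits, not the physiology of the signal. Each
#' user carries a fixed log-amplitude signature per (channel, band); each
#' one-second block re-draws a jitter term so segment statistics fluctuate
#' around the user's signature; a 1/f background is shared noise with no
#' identity content.
#' @name synth
NULL

# Channel montage of the 14-channel consumer headset the pipeline targets.
EEG_CHANNELS <- c(
  "AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
  "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"
)

# Wavelet band labels in feature order, and their frequency edges (Hz) for a
# 256 Hz sampling rate and a five-level decomposition.
EEG_BANDS <- c("D1", "D2", "D3", "D4", "D5", "A5")

# Default per-band carrier amplitudes: a 1/f-like profile (low-frequency
# bands larger), loosely matching generic resting EEG spectra. Config
# entries, not estimates of any particular dataset.
DEFAULT_BASE_AMPLITUDES <- c(
  D1 = 0.25, D2 = 0.35, D3 = 0.50, D4 = 0.70, D5 = 0.85, A5 = 1.00
)

#' Configuration of a synthetic EEG cohort
#'
#' Bundles every knob of the generative model behind [generate_cohort()].
#' Identity is injected as a per-(user, channel, band) log-amplitude offset
#' scaled by `identity_strength`; segment-to-segment nonstationarity as a
#' per-block log-amplitude jitter scaled by `within_user_jitter`; both act
#' on band-limited unit-variance carriers whose edges follow the dyadic
#' wavelet bands at `fs = 256` (64-128, 32-64, 16-32, 8-16, 4-8, 0-4 Hz).
#'
#' @param n_users number of users in the cohort.
#' @param n_channels number of EEG channels.
#' @param channel_names channel labels; length must equal `n_channels`.
#' @param fs sampling rate in Hz.
#' @param duration_s seconds of signal per user.
#' @param identity_strength scale (>= 0) of the fixed between-user
#'   log-amplitude differences; 0 makes users statistically exchangeable.
#' @param within_user_jitter scale (>= 0) of the fresh per-block
#'   log-amplitude noise shared by all of a user's segments in that block.
#' @param identity_bands subset of `c("D1","D2","D3","D4","D5","A5")` that
#'   carries identity; `"D1"` alone concentrates it in 64-128 Hz.
#' @param background_level scale (>= 0) of the identity-free 1/f background.
#' @param base_amplitudes named per-band carrier amplitudes.
#' @param seed integer seed; the whole cohort is a pure function of the
#'   config including this seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_users = 39L,
                             n_channels = 14L,
                             channel_names = EEG_CHANNELS,
                             fs = 256,
                             duration_s = 120,
                             identity_strength = 0.3,
                             within_user_jitter = 0.25,
                             identity_bands = EEG_BANDS,
                             background_level = 0.6,
                             base_amplitudes = DEFAULT_BASE_AMPLITUDES,
                             seed = 1L) {
  cfg <- list(
    n_users = as.integer(n_users), n_channels = as.integer(n_channels),
    channel_names = as.character(channel_names), fs = fs,
    duration_s = duration_s, identity_strength = identity_strength,
    within_user_jitter = within_user_jitter,
    identity_bands = as.character(identity_bands),
    background_level = background_level,
    base_amplitudes = base_amplitudes, seed = as.integer(seed)
  )
  if (cfg$n_users < 0) stop("n_users must be >= 0", call. = FALSE)
  if (cfg$n_channels != length(cfg$channel_names)) {
    stop("n_channels must equal length(channel_names)", call. = FALSE)
  }
  if (cfg$fs <= 0 || cfg$duration_s <= 0) {
    stop("fs and duration_s must be positive", call. = FALSE)
  }
  if (cfg$identity_strength < 0 || cfg$within_user_jitter < 0 ||
      cfg$background_level < 0) {
    stop("identity_strength, within_user_jitter and background_level must be >= 0",
      call. = FALSE
    )
  }
  if (length(cfg$identity_bands) == 0 ||
      !all(cfg$identity_bands %in% EEG_BANDS)) {
    stop("identity_bands must be a non-empty subset of ",
      paste(EEG_BANDS, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(EEG_BANDS %in% names(cfg$base_amplitudes))) {
    stop("base_amplitudes must name all six bands", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' A multichannel EEG recording
#'
#' @param user_id opaque user label.
#' @param fs sampling rate in Hz.
#' @param channel_names ordered channel labels.
#' @param signal numeric matrix, channels x samples.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(user_id, fs, channel_names, signal) {
  signal <- as.matrix(signal)
  if (nrow(signal) != length(channel_names)) {
    stop("signal must have one row per channel", call. = FALSE)
  }
  if (length(signal) && !all(is.finite(signal))) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  rownames(signal) <- channel_names
  structure(
    list(
      user_id = as.character(user_id), fs = fs,
      channel_names = as.character(channel_names), signal = signal
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(
    "<eeg_recording> user", x$user_id, "-", nrow(x$signal), "channels x",
    ncol(x$signal), "samples @", x$fs, "Hz\n"
  )
  invisible(x)
}

#' Band-limited unit-variance Gaussian noise
#'
#' Synthesizes noise spectrally confined to `[low_hz, high_hz]` by masking
#' the FFT of white Gaussian noise (all bins outside the band zeroed, DC
#' excluded when `low_hz > 0`), inverse-transforming, and re-standardizing
#' to zero mean and unit sample variance. The masking is exact, so for any
#' reasonable length essentially all periodogram power lies in band.
#'
#' @param low_hz,high_hz band edges in Hz; `0 <= low_hz < high_hz <= fs/2`.
#' @param n number of samples (>= 1).
#' @param fs sampling rate in Hz.
#' @param seed integer seed; the output is a pure function of the arguments.
#' @return numeric vector of length `n`.
#' @export
#' @examples
#' x <- band_limited_noise(64, 128, 4096, 256, seed = 1)
#' round(var(x), 6)
band_limited_noise <- function(low_hz, high_hz, n, fs, seed) {
  if (low_hz < 0 || low_hz >= high_hz || high_hz > fs / 2) {
    stop("invalid band: need 0 <= low_hz < high_hz <= fs/2", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  z <- with_seed(seed, rnorm(n))
  if (n < 4) {
    # too short to carry spectral structure; return standardized noise
    return(if (n == 1) 0 else as.numeric(scale(z)))
  }
  zf <- fft(z)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f) # fold negative frequencies
  keep <- f >= low_hz & f <= high_hz
  if (low_hz > 0) keep[1] <- FALSE
  if (!any(keep)) stop("band too narrow: no FFT bins inside it", call. = FALSE)
  zf[!keep] <- 0
  x <- Re(fft(zf, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# 1/f-amplitude background noise, unit variance; the spectral floor f_floor
# avoids a DC blow-up.
one_over_f_noise <- function(n, fs, seed, f_floor = 0.5) {
  z <- with_seed(seed, rnorm(n))
  if (n < 4) return(if (n == 1) 0 else as.numeric(scale(z)))
  zf <- fft(z)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  zf <- zf / sqrt(pmax(f, f_floor))
  zf[1] <- 0
  x <- Re(fft(zf, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a seeded synthetic EEG cohort
#'
#' For user u, channel c and band b, a fixed identity log-amplitude
#' `z[u,c,b] ~ Normal(0,1)` is drawn once per user. The channel signal is
#' the sum over bands of a unit-variance band-limited carrier multiplied by
#' a blockwise amplitude envelope
#' `a = base_b * exp(identity_strength * z * [b in identity_bands] +
#' within_user_jitter * w)` with fresh `w ~ Normal(0,1)` per one-second
#' block, plus `background_level` times identity-free 1/f noise. Amplitudes
#' are redrawn per second, slower than the 240 ms analysis window, so
#' intra-user variation does not destroy per-segment identity. The delta
#' band's nominal 0 Hz lower edge is realized as 0.5 Hz to avoid a DC spike.
#'
#' @param config a [synthetic_config()].
#' @return list of [eeg_recording()] objects, length `n_users`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_users = 2, duration_s = 2))
#' sapply(cohort, function(r) dim(r$signal))
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_users == 0) return(list())
  n <- round(config$fs * config$duration_s)
  n_blocks <- ceiling(n / config$fs)
  edges <- wavelet_band_edges(config$fs, levels = 5L)
  lapply(seq_len(config$n_users), function(u) {
    user_id <- sprintf("user%02d", u)
    z <- matrix(
      with_seed(
        derive_seed(config$seed, "identity", u),
        rnorm(config$n_channels * length(EEG_BANDS))
      ),
      nrow = config$n_channels,
      dimnames = list(config$channel_names, EEG_BANDS)
    )
    signal <- matrix(0, config$n_channels, n)
    for (ci in seq_len(config$n_channels)) {
      acc <- numeric(n)
      for (b in EEG_BANDS) {
        lo <- edges[[b]][1]
        if (lo == 0) lo <- 0.5 # delta: avoid DC
        carrier <- band_limited_noise(
          lo, edges[[b]][2], n, config$fs,
          seed = derive_seed(config$seed, "carrier", u, ci, b)
        )
        w <- with_seed(
          derive_seed(config$seed, "jitter", u, ci, b),
          rnorm(n_blocks)
        )
        a <- config$base_amplitudes[[b]] * exp(
          config$identity_strength * z[ci, b] * (b %in% config$identity_bands) +
            config$within_user_jitter * w
        )
        acc <- acc + rep(a, each = config$fs)[seq_len(n)] * carrier
      }
      if (config$background_level > 0) {
        acc <- acc + config$background_level * one_over_f_noise(
          n, config$fs,
          seed = derive_seed(config$seed, "background", u, ci)
        )
      }
      signal[ci, ] <- acc
    }
    eeg_recording(user_id, config$fs, config$channel_names, signal)
  })
}

#' Write a cohort to per-user CSV files plus a JSON manifest
#'
#' Each user file has a `time` column (seconds) followed by one column per
#' channel; the manifest maps user ids to files and records `fs`, duration
#' and the generating seed.
#'
#' @param cohort list of [eeg_recording()] objects.
#' @param dir output directory (created if missing).
#' @param seed seed recorded in the manifest (informational).
#' @return invisibly, the manifest path.
#' @export
write_cohort_csv <- function(cohort, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(rec) {
    file <- file.path(dir, paste0(rec$user_id, ".csv"))
    n <- ncol(rec$signal)
    df <- data.frame(time = (seq_len(n) - 1) / rec$fs)
    for (ch in rec$channel_names) df[[ch]] <- rec$signal[ch, ]
    write.csv(df, file, row.names = FALSE)
    list(
      user_id = rec$user_id, file = basename(file), fs = rec$fs,
      duration_s = n / rec$fs
    )
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(seed = seed, users = entries), manifest,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

#' Read one recording from a channels-as-columns CSV file
#'
#' Expects the layout written by [write_cohort_csv()]: an optional leading
#' `time` column (used to infer `fs` when not given) and one column per
#' channel, with channel names in the header.
#'
#' @param path CSV file.
#' @param user_id label for the recording; default the file name stem.
#' @param fs sampling rate in Hz; inferred from the `time` column if `NULL`.
#' @return an [eeg_recording()].
#' @export
read_recording_csv <- function(path, user_id = NULL,
                               fs = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (is.null(user_id)) user_id <- sub("\\.csv$", "", basename(path))
  if ("time" %in% names(df)) {
    if (is.null(fs)) {
      dt <- diff(df$time[1:2])
      if (!is.finite(dt) || dt <= 0) stop("cannot infer fs from time column", call. = FALSE)
      fs <- 1 / dt
    }
    df$time <- NULL
  }
  if (is.null(fs)) stop("fs must be given when the file has no time column", call. = FALSE)
  eeg_recording(user_id, fs, names(df), t(as.matrix(df)))
}
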
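# Preprocessing chain: per-channel min-max normalization to [-1, 1],
# 3rd-order Butterworth 3-100 Hz bandpass, 2.5 s windows with 0.1 s overlap,
# and 80-point Hamming STFT rendered as a 40 x 126 greyscale image.

#' Min-max normalize a signal to [-1, +1]
#'
#' Affine map `2 * (x - min) / (max - min) - 1`; the output attains -1 and +1
#' exactly on any non-constant input.
#'
#' @param x numeric vector.
#' @return List with `signal` (normalized vector) and `params`
#'   (list `x_min`, `x_max`).
#' @export
normalize_signal <- function(x) {
  if (length(x) == 0L) stop("signal must be non-empty")
  x_min <- min(x); x_max <- max(x)
  if (x_max == x_min) {
    stop(structure(class = c("fecg_degenerate_input", "error", "condition"),
                   list(message = "constant signal: min-max normalization undefined",
                        call = sys.call(-1))))
  }
  list(signal = 2 * (x - x_min) / (x_max - x_min) - 1,
       params = list(x_min = x_min, x_max = x_max))
}

#' Butterworth bandpass filter
#'
#' Single-pass causal Butterworth filter of the stated order (default 3rd
#' order, 3--100 Hz passband). Phase delay is left in the signal; the
#' downstream spectrogram classifier is insensitive to it.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param low,high band edges, Hz.
#' @param order filter order.
#' @return Filtered vector of the same length.
#' @export
bandpass_filter <- function(x, fs, low = 3, high = 100, order = 3) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filter(bf, x))
}

#' Designed frequency response of the bandpass stage
#'
#' Utility for verifying the passband/stopband contract analytically rather
#' than from a time series.
#'
#' @inheritParams bandpass_filter
#' @param f frequencies (Hz) at which to evaluate the magnitude response.
#' @return Numeric vector of magnitude responses at `f`.
#' @export
bandpass_response <- function(f, fs, low = 3, high = 100, order = 3) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / fs)
    num <- sum(bf$b * z^(seq_along(bf$b) - 1))
    den <- sum(bf$a * z^(seq_along(bf$a) - 1))
    Mod(num / den)
  }, numeric(1))
}

#' Cut a recording into overlapping windows
#'
#' Windows of `window_s` seconds advance by `window_s - overlap_s`, so
#' consecutive segments share exactly `round(overlap_s * fs)` samples. Each
#' segment inherits the recording's quality label and records its provenance.
#'
#' @param recording an `fecg_recording`.
#' @param window_s window length, seconds.
#' @param overlap_s overlap between consecutive windows, seconds.
#' @return List of segments, each a list with `channels`
#'   (samples x 4 matrix), `recording_id`, `start_sample` (1-based), `fs`,
#'   `label`. A recording shorter than one window yields an empty list with
#'   a warning.
#' @export
segment_recording <- function(recording, window_s = 2.5, overlap_s = 0.1) {
  stopifnot(inherits(recording, "fecg_recording"))
  if (!(window_s > overlap_s && overlap_s >= 0)) {
    stop("window_s must exceed overlap_s >= 0")
  }
  fs <- recording$fs
  n <- nrow(recording$channels)
  wlen <- as.integer(round(window_s * fs))
  stride <- as.integer(round((window_s - overlap_s) * fs))
  if (n < wlen) {
    warning(sprintf("recording '%s' shorter than one window: no segments",
                    recording$id))
    return(list())
  }
  starts <- seq(1L, n - wlen + 1L, by = stride)
  lapply(starts, function(s) {
    list(channels = recording$channels[s:(s + wlen - 1L), , drop = FALSE],
         recording_id = recording$id, start_sample = s, fs = fs,
         label = recording$label)
  })
}

#' Short-time Fourier spectrogram image of one channel segment
#'
#' An 80-point Hamming-windowed magnitude STFT of a 2500-sample (2.5 s at
#' 1 kHz) series. The default framing is centred with a hop of 20 samples,
#' which produces exactly 126 time frames (`floor(2500/20) + 1`); a
#' conventional hop-25 framing without centring (97 frames) is available via
#' `hop = 25, centered = FALSE`. The 40 frequency rows are the one-sided FFT
#' bins 1..40 (12.5--500 Hz; the DC bin is dropped, as DC is suppressed by
#' the 3 Hz high-pass anyway). Magnitudes are linearly min-max rescaled per
#' image to the greyscale range \\[0, 128\\]; an all-zero input maps to the
#' all-zero image.
#'
#' @param x numeric vector of exactly 2500 samples.
#' @param fs sampling rate, Hz (1000).
#' @param nfft FFT length and Hamming window length (80).
#' @param hop frame step in samples.
#' @param centered if `TRUE`, frame centres sit at `0, hop, 2*hop, ...`
#'   samples with zero padding at the edges; if `FALSE`, frames tile the
#'   interior only.
#' @return An object of class `stft_image`: list with `pixels`
#'   (40 x n_frames matrix in \\[0, 128\\]), `freq_axis` (Hz) and `time_axis`
#'   (s).
#' @export
stft_image <- function(x, fs = 1000, nfft = 80, hop = 20, centered = TRUE) {
  if (length(x) != 2500L) stop("stft_image expects exactly 2500 samples")
  n <- length(x)
  w <- .hamming(nfft)
  if (centered) {
    half <- nfft %/% 2
    xp <- c(numeric(half), x, numeric(nfft))
    centers <- seq(0L, by = hop, length.out = floor(n / hop) + 1L)
    starts <- centers + 1L            # position in padded vector of center-half
  } else {
    starts <- seq(1L, n - nfft + 1L, by = hop)
    xp <- x
    centers <- starts - 1L + nfft / 2
  }
  nfrm <- length(starts)
  mags <- matrix(0, nrow = 40L, ncol = nfrm)
  for (j in seq_len(nfrm)) {
    fr <- xp[starts[j]:(starts[j] + nfft - 1L)] * w
    sp <- stats::fft(fr)
    mags[, j] <- Mod(sp[2:41])        # bins 1..40, DC dropped
  }
  mn <- min(mags); mx <- max(mags)
  pixels <- if (mx > mn) (mags - mn) / (mx - mn) * 128 else matrix(0, 40L, nfrm)
  structure(list(pixels = pixels,
                 freq_axis = (1:40) * fs / nfft,
                 time_axis = centers / fs),
            class = "stft_image")
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Run the full preprocessing chain on a recording
#'
#' Per channel: normalize to \\[-1, 1\\], bandpass 3--100 Hz; then cut into
#' 2.5 s windows with 0.1 s overlap and convert every channel of every
#' segment into a spectrogram image.
#'
#' @param recording a 4-channel `fecg_recording` at 1 kHz.
#' @param window_s,overlap_s segmentation parameters.
#' @param hop,centered STFT framing (see [stft_image()]).
#' @return List with `segments` (filtered segments, see
#'   [segment_recording()]) and `images` (per segment, a list of 4
#'   `stft_image` objects named M, A1, A2, A3).
#' @export
preprocess_recording <- function(recording, window_s = 2.5, overlap_s = 0.1,
                                 hop = 20, centered = TRUE) {
  stopifnot(inherits(recording, "fecg_recording"))
  if (recording$fs != 1000) {
    stop("the pipeline is defined for 1 kHz recordings; resample upstream")
  }
  ch <- recording$channels
  filtered <- matrix(0, nrow(ch), 4L, dimnames = list(NULL, colnames(ch)))
  for (j in 1:4) {
    norm <- tryCatch(normalize_signal(ch[, j]), error = function(e) {
      stop(sprintf("channel %s: %s", colnames(ch)[j], conditionMessage(e)),
           call. = FALSE)
    })
    filtered[, j] <- bandpass_filter(norm$signal, recording$fs)
  }
  rec_f <- recording
  rec_f$channels <- filtered
  segs <- segment_recording(rec_f, window_s, overlap_s)
  images <- lapply(segs, function(s) {
    imgs <- lapply(1:4, function(j) {
      stft_image(s$channels[, j], fs = s$fs, hop = hop, centered = centered)
    })
    names(imgs) <- colnames(ch)
    imgs
  })
  list(segments = segs, images = images)
}
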
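# Synthetic four-channel NI-FECG generator. Recordings carry one maternal
# chest channel (M) and three abdominal channels (A1-A3) at 1 kHz, with the
# exact maternal/foetal beat trains used to render them, so every downstream
# stage can be tested against known truth.

#' ECG beat template as a sum of Gaussian lobes
#'
#' A beat is modelled as five Gaussian lobes (P, Q, R, S, T) placed on a
#' beat-phase axis in radians, where 0 is the R peak and a full cycle spans
#' \eqn{2\pi}. This is the classic dynamical-model parameterisation of ECG
#' morphology. The foetal beat uses the same lobe set with a narrower QRS.
#'
#' @param wave_params data.frame with columns `amplitude` (signal units),
#'   `center` (radians) and `width` (radians), one row per lobe P,Q,R,S,T.
#' @param qrs_width_scale multiplier applied to the Q, R and S lobe widths;
#'   0.5 approximates the narrower foetal QRS.
#' @return An object of class `ecg_template`.
#' @export
ecg_template <- function(wave_params = NULL, qrs_width_scale = 1) {
  if (is.null(wave_params)) {
    wave_params <- data.frame(
      lobe      = c("P", "Q", "R", "S", "T"),
      amplitude = c(0.12, -0.10, 1.00, -0.15, 0.30),
      center    = c(-pi / 3, -pi / 12, 0, pi / 12, 5 * pi / 12),
      width     = c(0.25, 0.10, 0.10, 0.10, 0.30),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(wave_params) != 5L) {
    stop("an ECG template must have exactly 5 lobes (P, Q, R, S, T)")
  }
  if (any(wave_params$width <= 0)) stop("lobe widths must be strictly positive")
  if (qrs_width_scale <= 0) stop("qrs_width_scale must be strictly positive")
  amps <- abs(wave_params$amplitude)
  r_row <- which.max(amps)
  if (sum(amps == amps[r_row]) != 1L || wave_params$center[r_row] != 0) {
    stop("the R lobe (center 0) must have the strictly largest |amplitude|")
  }
  wp <- wave_params
  qrs <- abs(wp$center) <= pi / 8  # Q, R, S lobes
  wp$width[qrs] <- wp$width[qrs] * qrs_width_scale
  structure(list(wave_params = wp, qrs_width_scale = qrs_width_scale),
            class = "ecg_template")
}

#' Default foetal beat template
#'
#' The maternal template with QRS widths halved; amplitude scaling is applied
#' later by the per-channel foetal gains.
#' @return An `ecg_template`.
#' @export
foetal_template <- function() ecg_template(qrs_width_scale = 0.5)

#' Configuration for the synthetic recording generator
#'
#' @param fs sampling rate in Hz (the pipeline assumes 1000).
#' @param duration_s recording length in seconds.
#' @param mhr_bpm maternal heart rate, beats/min, supported range 50--110.
#' @param fhr_bpm foetal heart rate, beats/min, supported range 100--180.
#' @param rr_jitter_frac fractional beat-to-beat RR jitter (sd / nominal RR).
#' @param maternal_gain_per_channel length-3 weights of the maternal render
#'   on A1..A3.
#' @param foetal_gain_per_channel length-3 weights of the foetal render on
#'   A1..A3 before SNR calibration.
#' @param baseline_amp,baseline_freq baseline-wander amplitude (signal units)
#'   and frequency (Hz).
#' @param powerline_amp 50 Hz mains amplitude (signal units).
#' @param noise_sigma broadband Gaussian noise sd (signal units).
#' @param target_foetal_snr_db target foetal SNR on the best abdominal
#'   channel, dB; drives the quality label.
#' @param label_threshold_db label is "good" iff
#'   `target_foetal_snr_db >= label_threshold_db`.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 1000, duration_s = 60, mhr_bpm = 80,
                         fhr_bpm = 140, rr_jitter_frac = 0.03,
                         maternal_gain_per_channel = c(0.5, 0.4, 0.45),
                         foetal_gain_per_channel = c(0.25, 0.30, 0.20),
                         baseline_amp = 0.15, baseline_freq = 0.3,
                         powerline_amp = 0.05, noise_sigma = 0.03,
                         target_foetal_snr_db = 6,
                         label_threshold_db = 3, seed = 1L) {
  if (fs <= 2 * 120) stop("fs must exceed twice the highest generated frequency")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fhr_bpm < 100 || fhr_bpm > 180) stop("fhr_bpm outside supported range [100, 180]")
  if (mhr_bpm < 50 || mhr_bpm > 110) stop("mhr_bpm outside supported range [50, 110]")
  if (length(maternal_gain_per_channel) != 3L ||
      length(foetal_gain_per_channel) != 3L) {
    stop("per-channel gains must have length 3")
  }
  structure(list(
    fs = fs, duration_s = duration_s, mhr_bpm = mhr_bpm, fhr_bpm = fhr_bpm,
    rr_jitter_frac = rr_jitter_frac,
    maternal_gain_per_channel = maternal_gain_per_channel,
    foetal_gain_per_channel = foetal_gain_per_channel,
    baseline_amp = baseline_amp, baseline_freq = baseline_freq,
    powerline_amp = powerline_amp, noise_sigma = noise_sigma,
    target_foetal_snr_db = target_foetal_snr_db,
    label_threshold_db = label_threshold_db, seed = as.integer(seed)
  ), class = "synth_config")
}

# Named RNG sub-streams so partial regeneration stays reproducible.
.sub_seed <- function(seed, stream) {
  offs <- c(beats = 11, noise = 101, gains = 211, foetal_beats = 307)
  as.integer((as.numeric(seed) * 7919 + offs[[stream]]) %% 2147483647)
}

#' Generate a jittered beat train
#'
#' Beat onsets are cumulative sums of RR intervals; each interval is the
#' nominal RR perturbed by Gaussian jitter truncated at three standard
#' deviations, so intervals stay within \eqn{\pm 3 \times} `rr_jitter_frac`
#' of nominal.
#'
#' @param rate_bpm heart rate, beats/min.
#' @param duration_s train duration, seconds.
#' @param rr_jitter_frac fractional RR jitter (sd / nominal RR).
#' @param fs sampling rate, Hz.
#' @param seed optional integer seed.
#' @return Integer vector of strictly increasing R-peak sample indices
#'   (1-based) inside the recording.
#' @export
generate_beat_train <- function(rate_bpm, duration_s, rr_jitter_frac = 0,
                                fs = 1000, seed = NULL) {
  if (rate_bpm <= 0) stop("rate_bpm must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rr <- 60 / rate_bpm                      # seconds
  n_max <- ceiling(duration_s / rr) + 3L
  jit <- if (rr_jitter_frac > 0) {
    pmin(pmax(stats::rnorm(n_max, 0, rr_jitter_frac), -3 * rr_jitter_frac),
         3 * rr_jitter_frac)
  } else rep(0, n_max)
  # first beat placed half an RR in so edge beats render fully
  times <- 0.5 * rr + cumsum(c(0, rr * (1 + jit[-1])))
  times <- times[times < duration_s]
  idx <- as.integer(round(times * fs)) + 1L
  idx <- idx[idx >= 1L & idx <= round(duration_s * fs)]
  unique(idx)
}

#' Render an ECG trace from a template and a beat train
#'
#' Each beat contributes the template's Gaussian lobes; lobe phase is mapped
#' to time using the local RR interval (preceding RR for lobes before the R
#' peak, following RR for lobes after), so morphology stretches with the
#' local cycle length. For isolated beats a nominal 1 s cycle is assumed.
#'
#' @param template an `ecg_template`.
#' @param beats integer vector of R-peak sample indices (1-based).
#' @param fs sampling rate, Hz.
#' @param n_samples output length in samples.
#' @return Numeric vector of length `n_samples`.
#' @export
render_ecg <- function(template, beats, fs, n_samples) {
  stopifnot(inherits(template, "ecg_template"))
  y <- numeric(n_samples)
  if (length(beats) == 0L) return(y)
  if (any(beats < 1L | beats > n_samples)) {
    stop("beat index outside [1, n_samples]")
  }
  beats <- sort(as.integer(beats))
  rr_nom <- fs * 1.0   # fallback cycle length for isolated beats (1 s)
  nb <- length(beats)
  rr_prev <- if (nb > 1) c(diff(beats)[1], diff(beats)) else rr_nom
  rr_next <- if (nb > 1) c(diff(beats), diff(beats)[nb - 1]) else rr_nom
  wp <- template$wave_params
  for (i in seq_len(nb)) {
    c_i <- beats[i]
    for (l in seq_len(nrow(wp))) {
      rr_l <- if (wp$center[l] < 0) rr_prev[i] else rr_next[i]
      mu <- c_i + wp$center[l] / (2 * pi) * rr_l
      sigma <- wp$width[l] / (2 * pi) * rr_l
      lo <- max(1L, floor(mu - 5 * sigma))
      hi <- min(n_samples, ceiling(mu + 5 * sigma))
      if (lo > hi) next
      t <- lo:hi
      y[t] <- y[t] + wp$amplitude[l] * exp(-((t - mu)^2) / (2 * sigma^2))
    }
  }
  y
}

#' Signal-to-noise ratio in decibels
#'
#' @param signal_component,noise_component equal-length numeric vectors.
#' @return `10 * log10(mean(signal^2) / mean(noise^2))`.
#' @export
snr_db <- function(signal_component, noise_component) {
  if (length(signal_component) != length(noise_component)) {
    stop("signal and noise components must have equal length")
  }
  pn <- mean(noise_component^2)
  if (pn <= 0) stop("noise power must be strictly positive")
  10 * log10(mean(signal_component^2) / pn)
}

#' Construct a four-channel recording object
#'
#' @param channels numeric matrix with columns `M`, `A1`, `A2`, `A3`.
#' @param fs sampling rate, Hz.
#' @param mqrs,fqrs strictly increasing maternal/foetal R-peak sample indices.
#' @param label one of `"good"`, `"bad"`, `"unknown"`.
#' @param id recording identifier.
#' @param meta optional list of provenance fields.
#' @return An object of class `fecg_recording`.
#' @export
fecg_recording <- function(channels, fs, mqrs = integer(), fqrs = integer(),
                           label = "unknown", id = "rec", meta = list()) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 4L) stop("a recording must have exactly 4 channels")
  colnames(channels) <- c("M", "A1", "A2", "A3")
  n <- nrow(channels)
  for (ann in list(mqrs, fqrs)) {
    if (length(ann) && (any(diff(ann) <= 0) || any(ann < 1L | ann > n))) {
      stop("annotations must be strictly increasing and within the recording")
    }
  }
  if (!label %in% c("good", "bad", "unknown")) stop("invalid label")
  structure(list(channels = channels, fs = fs, mqrs = as.integer(mqrs),
                 fqrs = as.integer(fqrs), label = label, id = id, meta = meta),
            class = "fecg_recording")
}

#' @export
print.fecg_recording <- function(x, ...) {
  cat(sprintf("<fecg_recording '%s'> %d samples @ %g Hz, label %s, %d MQRS, %d FQRS\n",
              x$id, nrow(x$channels), x$fs, x$label,
              length(x$mqrs), length(x$fqrs)))
  invisible(x)
}

#' Generate one labelled synthetic NI-FECG recording
#'
#' The chest channel M holds the maternal render plus a small sensor noise;
#' each abdominal channel holds a weighted maternal render, a weighted foetal
#' render, baseline wander, 50 Hz mains and broadband noise. The foetal gains
#' are rescaled by a common factor so that the achieved foetal SNR (foetal
#' render power against the summed non-maternal noise) on the best abdominal
#' channel equals `target_foetal_snr_db` exactly. The quality label is
#' `"good"` iff the target SNR reaches `label_threshold_db`.
#'
#' @param config a `synth_config`.
#' @param id recording identifier.
#' @return An `fecg_recording` with exact `mqrs`/`fqrs` annotations.
#' @export
generate_recording <- function(config, id = "rec") {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  mqrs <- generate_beat_train(config$mhr_bpm, config$duration_s,
                              config$rr_jitter_frac, fs,
                              seed = .sub_seed(config$seed, "beats"))
  fqrs <- generate_beat_train(config$fhr_bpm, config$duration_s,
                              config$rr_jitter_frac, fs,
                              seed = .sub_seed(config$seed, "foetal_beats"))
  m_render <- render_ecg(ecg_template(), mqrs, fs, n)
  f_render <- render_ecg(foetal_template(), fqrs, fs, n)

  set.seed(.sub_seed(config$seed, "noise"))
  t <- (seq_len(n) - 1) / fs
  noise_parts <- vector("list", 3L)
  for (i in 1:3) {
    baseline <- config$baseline_amp *
      sin(2 * pi * config$baseline_freq * t + stats::runif(1, 0, 2 * pi))
    mains <- config$powerline_amp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    broad <- stats::rnorm(n, 0, config$noise_sigma)
    noise_parts[[i]] <- baseline + mains + broad
  }
  sensor <- stats::rnorm(n, 0, 0.01)

  # calibrate foetal gains: common factor s.t. best-channel SNR == target
  fg <- config$foetal_gain_per_channel
  pf <- mean(f_render^2)
  pn <- vapply(noise_parts, function(z) mean(z^2), numeric(1))
  if (pf > 0 && all(pn > 0)) {
    achieved <- 10 * log10(fg^2 * pf / pn)
    scale <- 10^((config$target_foetal_snr_db - max(achieved)) / 20)
    fg <- fg * scale
  }

  ab <- vapply(1:3, function(i) {
    config$maternal_gain_per_channel[i] * m_render +
      fg[i] * f_render + noise_parts[[i]]
  }, numeric(n))
  channels <- cbind(M = m_render + sensor, ab)
  label <- if (config$target_foetal_snr_db >= config$label_threshold_db)
    "good" else "bad"
  fecg_recording(channels, fs, mqrs, fqrs, label, id,
                 meta = list(target_foetal_snr_db = config$target_foetal_snr_db,
                             fhr_bpm = config$fhr_bpm, mhr_bpm = config$mhr_bpm,
                             foetal_gains = fg, seed = config$seed))
}

#' Generate a labelled synthetic dataset
#'
#' Per-recording foetal SNR is drawn uniformly from the class interval
#' (defaults: good \\[6, 18\\] dB, bad \\[-12, 0\\] dB, disjoint with a margin
#' around the 3 dB label threshold), FHR uniformly from \\[110, 160\\] bpm and
#' MHR from \\[65, 95\\] bpm.
#'
#' @param n_good,n_bad number of good/bad recordings.
#' @param base_config `synth_config` supplying everything except SNR and rates.
#' @param snr_ranges list with `good` and `bad` dB intervals.
#' @param seed integer master seed.
#' @return List of `fecg_recording` objects (good recordings first).
#' @export
generate_dataset <- function(n_good, n_bad, base_config = synth_config(),
                             snr_ranges = list(good = c(6, 18), bad = c(-12, 0)),
                             seed = 1L) {
  if (max(snr_ranges$bad) >= min(snr_ranges$good)) {
    stop("good and bad SNR intervals must be disjoint (bad below good)")
  }
  if (max(snr_ranges$bad) >= base_config$label_threshold_db ||
      min(snr_ranges$good) < base_config$label_threshold_db) {
    stop("SNR intervals must sit on opposite sides of the label threshold")
  }
  set.seed(as.integer(seed))
  total <- n_good + n_bad
  cls <- rep(c("good", "bad"), c(n_good, n_bad))
  snr <- ifelse(cls == "good",
                stats::runif(total, snr_ranges$good[1], snr_ranges$good[2]),
                stats::runif(total, snr_ranges$bad[1], snr_ranges$bad[2]))
  fhr <- stats::runif(total, 110, 160)
  mhr <- stats::runif(total, 65, 95)
  rec_seed <- sample.int(.Machine$integer.max - 1L, total)
  lapply(seq_len(total), function(i) {
    cfg <- base_config
    cfg$target_foetal_snr_db <- snr[i]
    cfg$fhr_bpm <- fhr[i]
    cfg$mhr_bpm <- mhr[i]
    cfg$seed <- rec_seed[i]
    generate_recording(cfg, id = sprintf("rec%03d", i))
  })
}
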
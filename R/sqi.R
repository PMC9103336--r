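# Classical foetal signal-quality indices and the 45-element benchmark
# feature vector. All non-time-domain indices are bounded in [0, 1];
# degenerate cases map to a documented sentinel value of 0 so downstream
# classifiers never see missing values.

# one-sided periodogram power in [f1, f2] Hz (inclusive), raw |FFT|^2 sum
.band_power <- function(x, fs, f1, f2) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs <= fs / 2
  sum(sp[keep & freqs >= f1 & freqs <= f2])
}

#' Time-domain moment signal-quality indices
#'
#' Population moments: `std_sqi` is the standard deviation
#' \eqn{\sqrt{E[(x-\bar x)^2]}}, `s_sqi` the skewness
#' \eqn{E[(x-\bar x)^3]/\mathrm{std}^3} and `k_sqi` the (non-excess)
#' kurtosis \eqn{E[(x-\bar x)^4]/\mathrm{std}^4}. A constant input has
#' standard deviation 0; skewness and kurtosis then return the sentinel 0
#' with a warning.
#'
#' @param x numeric vector of length >= 2.
#' @return A single numeric value.
#' @export
std_sqi <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  sqrt(mean((x - mean(x))^2))
}

#' @rdname std_sqi
#' @export
s_sqi <- function(x) {
  s <- std_sqi(x)
  if (s == 0) { warning("constant input: skewness undefined, sentinel 0"); return(0) }
  mean((x - mean(x))^3) / s^3
}

#' @rdname std_sqi
#' @export
k_sqi <- function(x) {
  s <- std_sqi(x)
  if (s == 0) { warning("constant input: kurtosis undefined, sentinel 0"); return(0) }
  mean((x - mean(x))^4) / s^4
}

#' Relative power outside the foetal QRS band (pSQI)
#'
#' `1 - P[5,15] / P[5,45]` from periodogram band powers, clipped to
#' \\[0, 1\\]; zero power in \\[5, 45\\] Hz returns the sentinel 0.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz (> 90).
#' @return Value in \\[0, 1\\].
#' @export
p_sqi <- function(x, fs) {
  if (fs <= 90) stop("fs must exceed 90 Hz")
  den <- .band_power(x, fs, 5, 45)
  total <- .band_power(x, fs, 0, fs / 2)
  # no genuine power in [5, 45] Hz (numerical dust only) -> sentinel
  if (den <= 1e-9 * total || total <= 0) return(0)
  min(max(1 - .band_power(x, fs, 5, 15) / den, 0), 1)
}

#' Relative baseline power (basSQI)
#'
#' Ratio of \\[0, 3\\] Hz power to \\[0, 100\\] Hz power; zero denominator
#' returns the sentinel 0.
#'
#' @inheritParams p_sqi
#' @return Value in \\[0, 1\\].
#' @export
bas_sqi <- function(x, fs) {
  if (fs <= 200) stop("fs must exceed 200 Hz")
  den <- .band_power(x, fs, 0, 100)
  if (den <= 0) return(0)
  min(max(.band_power(x, fs, 0, 3) / den, 0), 1)
}

#' Detector-agreement index (bSQI)
#'
#' F1 agreement between two detectors' annotations:
#' `2*TP / (2*TP + FP + FN)` under tolerance matching. Two empty
#' annotations return the sentinel 0.
#'
#' @param a,b `qrs_annotation` objects.
#' @param tol_ms matching tolerance, milliseconds.
#' @return Value in \\[0, 1\\].
#' @export
b_sqi <- function(a, b, tol_ms = 50) {
  m <- match_annotations(a, b, tol_ms)
  den <- 2 * m["tp"] + m["fp"] + m["fn"]
  if (den == 0) return(0)
  unname(2 * m["tp"] / den)
}

#' Inter-lead agreement index (iSQI)
#'
#' Fraction of beats on the current lead that have a within-tolerance match
#' on every other lead.
#'
#' @param lead_annotations list of `qrs_annotation`, one per lead.
#' @param current index of the current lead within `lead_annotations`.
#' @param tol_ms matching tolerance, milliseconds.
#' @return Value in \\[0, 1\\].
#' @export
i_sqi <- function(lead_annotations, current, tol_ms = 50) {
  cur <- lead_annotations[[current]]
  others <- lead_annotations[-current]
  if (!length(cur$indices)) return(0)
  tol <- tol_ms / 1000 * cur$fs
  ok <- vapply(cur$indices, function(i) {
    all(vapply(others, function(o) {
      length(o$indices) > 0 && min(abs(o$indices - i)) <= tol
    }, logical(1)))
  }, logical(1))
  mean(ok)
}

#' Heart-rate regularity index (rSQI)
#'
#' Instantaneous beat-to-beat heart rate from successive RR intervals;
#' a beat-to-beat rate deviating from the median by more than 30 bpm is an
#' outlier. `rSQI = 1 - Nout/Nd` with `Nd` the number of detections. Fewer
#' than 3 detections return the sentinel 0.
#'
#' @param fqrs a `qrs_annotation`.
#' @return Value in \\[0, 1\\].
#' @export
r_sqi <- function(fqrs) {
  idx <- fqrs$indices
  if (length(idx) < 3L) return(0)
  hr <- 60 * fqrs$fs / diff(idx)
  n_out <- sum(abs(hr - stats::median(hr)) > 30)
  max(1 - n_out / length(idx), 0)
}

# full fixed-length beat windows around idx, rows = beats (interior only)
.beat_windows <- function(x, idx, half) {
  idx <- idx[idx > half & idx <= length(x) - half]
  if (!length(idx)) return(NULL)
  t(vapply(idx, function(i) x[(i - half):(i + half)], numeric(2L * half + 1L)))
}

#' Beat-morphology conformity index (cSQI)
#'
#' Mean Pearson correlation of each detected beat window against the mean
#' beat template; negative correlations are clipped to 0 before averaging.
#' Fewer than 2 usable beats return the sentinel 0.
#'
#' @param fecg extracted foetal ECG, numeric vector.
#' @param fqrs a `qrs_annotation`.
#' @param window_ms beat window length, milliseconds.
#' @return Value in \\[0, 1\\].
#' @export
c_sqi <- function(fecg, fqrs, window_ms = 100) {
  half <- round(window_ms / 2000 * fqrs$fs)
  w <- .beat_windows(fecg, fqrs$indices, half)
  if (is.null(w) || nrow(w) < 2L) return(0)
  tmpl <- colMeans(w)
  if (stats::sd(tmpl) == 0) return(0)
  r <- apply(w, 1, function(row) {
    if (stats::sd(row) == 0) return(0)
    stats::cor(row, tmpl)
  })
  mean(pmax(r, 0))
}

#' Beat extravagance index (xSQI)
#'
#' Energy concentration at the detected beats:
#' `E_in / (E_in + E_out)` where `E_in` is the mean squared amplitude inside
#' the +/- 50 ms beat windows and `E_out` outside. Zero total energy or no
#' beats return the sentinel 0.
#'
#' @inheritParams c_sqi
#' @return Value in \\[0, 1\\].
#' @export
x_sqi <- function(fecg, fqrs, window_ms = 100) {
  idx <- fqrs$indices
  if (!length(idx)) return(0)
  half <- round(window_ms / 2000 * fqrs$fs)
  inside <- logical(length(fecg))
  for (i in idx) {
    lo <- max(1L, i - half); hi <- min(length(fecg), i + half)
    inside[lo:hi] <- TRUE
  }
  if (all(inside) || !any(inside)) return(0)
  e_in <- mean(fecg[inside]^2)
  e_out <- mean(fecg[!inside]^2)
  if (e_in + e_out == 0) return(0)
  e_in / (e_in + e_out)
}

#' Maternal-residual extravagance index (mxSQI)
#'
#' `1 - xSQI` evaluated with the maternal QRS windows on the extracted
#' signal: high values mean little residual maternal energy (good
#' cancellation). Zero-energy input or empty annotation returns the
#' sentinel 0.
#'
#' @param fecg extracted foetal ECG residual.
#' @param mqrs maternal `qrs_annotation`.
#' @param window_ms window length, milliseconds.
#' @return Value in \\[0, 1\\].
#' @export
mx_sqi <- function(fecg, mqrs, window_ms = 100) {
  if (!length(mqrs$indices) || mean(fecg^2) == 0) return(0)
  1 - x_sqi(fecg, mqrs, window_ms)
}

#' Maternal harmonic power index (mpSQI)
#'
#' Relative spectral power at the harmonics of the maternal heart rate:
#' the fundamental is the mean MQRS rate in Hz; power is summed in
#' +/- 0.2 Hz bands around the first five harmonics (variant `"a"`) or all
#' harmonics inside \\[0.5, 10\\] Hz (variant `"b"`), divided by the total
#' \\[0.5, 100\\] Hz power. Fewer than 2 maternal beats return the
#' sentinel 0.
#'
#' @param fecg numeric vector.
#' @param mqrs maternal `qrs_annotation`.
#' @param fs sampling rate, Hz.
#' @param variant `"a"` (first five harmonics) or `"b"` (harmonics in
#'   \\[0.5, 10\\] Hz).
#' @return Value in \\[0, 1\\].
#' @export
mp_sqi <- function(fecg, mqrs, fs, variant = c("a", "b")) {
  variant <- match.arg(variant)
  idx <- mqrs$indices
  if (length(idx) < 2L) return(0)
  f0 <- 1 / (mean(diff(idx)) / fs)
  harmonics <- if (variant == "a") f0 * (1:5) else {
    h <- f0 * seq_len(floor(10 / f0))
    h[h >= 0.5 & h <= 10]
  }
  if (!length(harmonics)) return(0)
  total <- .band_power(fecg, fs, 0.5, 100)
  if (total <= 0) return(0)
  num <- sum(vapply(harmonics, function(h) {
    .band_power(fecg, fs, max(h - 0.2, 0.5), min(h + 0.2, 100))
  }, numeric(1)))
  min(max(num / total, 0), 1)
}

#' Mean magnitude-squared coherence (mcSQI)
#'
#' Welch-style magnitude-squared coherence averaged over \\[3, 100\\] Hz,
#' using at least 4 Hamming-windowed sub-windows with 50% overlap. Variant
#' "a" of the feature uses the maternal chest signal and the extracted
#' foetal ECG; variant "b" the abdominal mixture and the extracted foetal
#' ECG — both are this same operation on different signal pairs.
#'
#' @param x,y equal-length numeric vectors.
#' @param fs sampling rate, Hz.
#' @param n_windows number of sub-windows (>= 4).
#' @return Value in \\[0, 1\\].
#' @export
mc_sqi <- function(x, y, fs, n_windows = 8) {
  if (length(x) != length(y)) stop("signals must have equal length")
  n <- length(x)
  n_windows <- max(4L, as.integer(n_windows))
  wlen <- floor(2 * n / (n_windows + 1))     # 50% overlap tiling
  if (wlen < 8L) stop("signal too short for coherence estimation")
  step <- floor(wlen / 2)
  w <- .hamming(wlen)
  starts <- seq(1L, n - wlen + 1L, by = step)
  pxx <- pyy <- numeric(wlen)
  pxy <- complex(wlen)
  for (s in starts) {
    xs <- stats::fft((x[s:(s + wlen - 1L)] - mean(x[s:(s + wlen - 1L)])) * w)
    ys <- stats::fft((y[s:(s + wlen - 1L)] - mean(y[s:(s + wlen - 1L)])) * w)
    pxx <- pxx + Mod(xs)^2
    pyy <- pyy + Mod(ys)^2
    pxy <- pxy + xs * Conj(ys)
  }
  freqs <- (seq_len(wlen) - 1) * fs / wlen
  keep <- freqs >= 3 & freqs <= 100 & freqs <= fs / 2
  denom <- pxx[keep] * pyy[keep]
  coh <- ifelse(denom > 0, Mod(pxy[keep])^2 / denom, 0)
  if (!length(coh)) return(0)
  min(max(mean(coh), 0), 1)
}

#' Maternal-interference index (miSQI)
#'
#' `1 -` the fraction of foetal detections lying within tolerance of a
#' maternal annotation; exposes maternal QRS residuals mistaken for foetal
#' beats. An empty foetal annotation returns the sentinel 0.
#'
#' @param fqrs,mqrs `qrs_annotation` objects.
#' @param tol_ms tolerance, milliseconds.
#' @return Value in \\[0, 1\\].
#' @export
mi_sqi <- function(fqrs, mqrs, tol_ms = 50) {
  if (!length(fqrs$indices)) return(0)
  if (!length(mqrs$indices)) return(1)
  tol <- tol_ms / 1000 * fqrs$fs
  frac <- mean(vapply(fqrs$indices, function(i) {
    min(abs(mqrs$indices - i)) <= tol
  }, logical(1)))
  1 - frac
}

#' Names of the 45 benchmark features
#'
#' Layout `"fecgsqi-45-v1"`: 10 detector-independent features (stdSQI,
#' sSQI, kSQI, pSQI, basSQI, mxSQI, mpSQIa, mpSQIb, mcSQIa, mcSQIb), the
#' 10 pairwise detector-agreement features (bSQI over the C(5,2) unordered
#' detector pairs), and 5 per-detector features (iSQI, rSQI, cSQI, xSQI,
#' miSQI) for each of the five detectors.
#'
#' @return Character vector of length 45.
#' @export
sqi_feature_names <- function() {
  base <- c("stdSQI", "sSQI", "kSQI", "pSQI", "basSQI", "mxSQI",
            "mpSQIa", "mpSQIb", "mcSQIa", "mcSQIb")
  dets <- .detector_methods
  pairs <- utils::combn(dets, 2)
  bsqi <- paste0("bSQI_", pairs[1, ], "_", pairs[2, ])
  per <- as.vector(outer(c("iSQI", "rSQI", "cSQI", "xSQI", "miSQI"), dets,
                         function(f, d) paste0(f, "_", d)))
  c(base, bsqi, per)
}

#' Compute the 45-element benchmark feature vector for a segment
#'
#' TSpca extraction is run once per abdominal channel using the maternal
#' annotation (detected on the chest channel with the Pan-Tompkins detector
#' when not supplied). Foetal detections are made on the extracted residual
#' of each channel by each of the five detectors. Single-signal features
#' are computed on the "best" abdominal channel, chosen as the channel with
#' the highest xSQI under the Pan-Tompkins foetal detection. If extraction
#' fails (too few maternal beats), all extraction/detection-dependent
#' features take the sentinel 0, spectral/moment features fall back to the
#' raw abdominal signal and the result is flagged in the `quality_mask`
#' attribute.
#'
#' @param segment a segment from [segment_recording()] (list with
#'   `channels`, `fs`, `recording_id`, `start_sample`).
#' @param mqrs optional maternal `qrs_annotation` local to the segment.
#' @param tspca a `tspca_config`.
#' @return Named numeric vector of length 45 with attributes `segment_id`,
#'   `layout_version` (`"fecgsqi-45-v1"`) and `quality_mask`.
#' @export
feature_vector <- function(segment, mqrs = NULL, tspca = tspca_config()) {
  fs <- segment$fs
  ch <- segment$channels
  if (is.null(mqrs)) {
    mqrs <- detect_qrs(ch[, "M"], fs, "pan_tompkins", "maternal")
  }
  dets <- .detector_methods
  feats <- stats::setNames(numeric(45L), sqi_feature_names())
  extraction_ok <- TRUE
  residuals <- vector("list", 3L)
  for (j in 1:3) {
    r_j <- tryCatch(extract_fecg(ch[, j + 1L], mqrs$indices, fs, tspca),
                    fecg_extraction_failure = function(e) NULL)
    if (is.null(r_j)) extraction_ok <- FALSE else residuals[[j]] <- r_j
  }

  if (extraction_ok) {
    # foetal detections per channel per detector on the residuals
    ann <- lapply(residuals, function(r) {
      stats::setNames(lapply(dets, function(d) detect_qrs(r, fs, d, "foetal")),
                      dets)
    })
    xs <- vapply(1:3, function(j) {
      x_sqi(residuals[[j]], ann[[j]][["pan_tompkins"]])
    }, numeric(1))
    best <- which.max(xs)
    res <- residuals[[best]]
    feats["mxSQI"] <- mx_sqi(res, mqrs)
    feats["mpSQIa"] <- mp_sqi(res, mqrs, fs, "a")
    feats["mpSQIb"] <- mp_sqi(res, mqrs, fs, "b")
    feats["mcSQIa"] <- mc_sqi(ch[, "M"], res, fs)
    feats["mcSQIb"] <- mc_sqi(ch[, best + 1L], res, fs)
    pairs <- utils::combn(dets, 2)
    for (k in seq_len(ncol(pairs))) {
      nm <- paste0("bSQI_", pairs[1, k], "_", pairs[2, k])
      feats[nm] <- b_sqi(ann[[best]][[pairs[1, k]]], ann[[best]][[pairs[2, k]]])
    }
    for (d in dets) {
      lead_ann <- lapply(1:3, function(j) ann[[j]][[d]])
      feats[paste0("iSQI_", d)] <- i_sqi(lead_ann, best)
      feats[paste0("rSQI_", d)] <- r_sqi(ann[[best]][[d]])
      feats[paste0("cSQI_", d)] <- c_sqi(res, ann[[best]][[d]])
      feats[paste0("xSQI_", d)] <- x_sqi(res, ann[[best]][[d]])
      feats[paste0("miSQI_", d)] <- mi_sqi(ann[[best]][[d]], mqrs)
    }
    moment_src <- res
  } else {
    moment_src <- ch[, 2L]   # raw first abdominal channel as fallback
  }
  feats["stdSQI"] <- std_sqi(moment_src)
  feats["sSQI"] <- suppressWarnings(s_sqi(moment_src))
  feats["kSQI"] <- suppressWarnings(k_sqi(moment_src))
  feats["pSQI"] <- p_sqi(moment_src, fs)
  feats["basSQI"] <- bas_sqi(moment_src, fs)
  attr(feats, "segment_id") <- paste0(segment$recording_id, "_",
                                      segment$start_sample)
  attr(feats, "layout_version") <- "fecgsqi-45-v1"
  attr(feats, "quality_mask") <- extraction_ok
  feats
}

#' Feature table for a list of segments
#'
#' @param segments list of segments (see [segment_recording()]).
#' @param tspca a `tspca_config`.
#' @return data.frame with `segment_id`, `recording_id`, `label` and the 45
#'   feature columns.
#' @export
feature_table <- function(segments, tspca = tspca_config()) {
  rows <- lapply(segments, function(s) {
    fv <- feature_vector(s, tspca = tspca)
    cbind(data.frame(segment_id = attr(fv, "segment_id"),
                     recording_id = s$recording_id,
                     label = s$label, stringsAsFactors = FALSE),
          as.data.frame(t(fv)))
  })
  do.call(rbind, rows)
}
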
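# Five QRS detector families (maxsearch, jqrs, Pan-Tompkins, gqrs-style
# template correlation, wqrs-style curve-length transform) and annotation
# matching. The detectors are deliberately distinct algorithm families: the
# detector-agreement quality indices (bSQI) rely on their behavioural
# diversity under noise, not on bit-fidelity to any reference binary.

.detector_methods <- c("maxsearch", "jqrs", "pan_tompkins", "gqrs", "wqrs")

#' Names of the available QRS detector methods
#' @return Character vector of the five detector names.
#' @export
qrs_detectors <- function() .detector_methods

# RR prior (seconds) and refractory period (seconds) per search target.
.qrs_prior <- function(target) {
  switch(target,
    maternal = list(rr = c(0.545, 1.2), refractory = 0.2, qrs_win = 0.12),
    foetal   = list(rr = c(0.330, 0.600), refractory = 0.15, qrs_win = 0.05),
    stop("target must be 'maternal' or 'foetal'")
  )
}

# QRS-band emphasis used by the energy-based detectors: suppresses P/T
# lobes and baseline so integration windows centre on the R peak
.qrs_band <- function(x, fs) {
  bf <- signal::butter(2, c(10, 40) / (fs / 2), type = "pass")
  # zero-phase so envelope peaks stay centred on the R peaks
  as.numeric(signal::filtfilt(bf, x))
}

# centred moving average with partial windows at the edges (so beats close
# to the signal boundary keep their full envelope amplitude)
.moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  half <- w %/% 2
  xp <- c(numeric(half), x, numeric(w))
  cs <- cumsum(xp)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + half] - cs[lo + half - 1L]) / (hi - lo + 1L)
}

# local maxima of y that are >= both neighbours and > threshold; the two
# endpoints count as maxima when they exceed their single neighbour (a beat
# truncated at the signal boundary has no interior turning point)
.local_maxima <- function(y, thr = -Inf) {
  n <- length(y)
  if (n < 3L) return(integer())
  idx <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n] &
                 y[2:(n - 1)] > thr) + 1L
  if (y[1] > y[2] && y[1] > thr) idx <- c(1L, idx)
  if (y[n] > y[n - 1] && y[n] > thr) idx <- c(idx, n)
  idx
}

# greedy refractory enforcement: keep larger-amplitude beat on conflict
.enforce_refractory <- function(idx, amp, refr_samples) {
  if (length(idx) <= 1L) return(sort(idx))
  ord <- order(amp[idx], decreasing = TRUE)
  kept <- integer()
  for (i in idx[ord]) {
    if (!length(kept) || all(abs(kept - i) >= refr_samples)) kept <- c(kept, i)
  }
  sort(kept)
}

# snap detections to the nearest local maximum of |x| within +/- win samples
.align_to_peak <- function(idx, x, win) {
  n <- length(x)
  as.integer(vapply(idx, function(i) {
    lo <- max(1L, i - win); hi <- min(n, i + win)
    lo + which.max(abs(x[lo:hi])) - 1
  }, numeric(1)))
}

# dominant RR (samples) from the autocorrelation of the smoothed energy
.estimate_rr <- function(x, fs, rr_range_s) {
  e <- .moving_avg(x^2, round(0.05 * fs))
  e <- e - mean(e)
  lags <- round(rr_range_s[1] * fs):round(rr_range_s[2] * fs)
  ac <- stats::acf(e, lag.max = max(lags), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- lags[lags < length(ac)]
  if (!length(lags)) return(round(mean(rr_range_s) * fs))
  lags[which.max(ac[lags + 1L])]
}

#' Detect QRS complexes
#'
#' Runs one of the five detector families on a single-channel signal. All
#' detectors finish by snapping detections to the nearest local maximum of
#' the rectified signal and enforcing the target's refractory period
#' (200 ms for maternal-range search, 150 ms for foetal-range search).
#'
#' @param x numeric vector (at least 1 s of samples).
#' @param fs sampling rate, Hz.
#' @param method one of `"maxsearch"`, `"jqrs"`, `"pan_tompkins"`,
#'   `"gqrs"`, `"wqrs"`.
#' @param target `"maternal"` or `"foetal"`; sets the RR prior and
#'   refractory period.
#' @return An object of class `qrs_annotation`: list with `detector`,
#'   `indices` (strictly increasing, 1-based), `fs`.
#' @export
detect_qrs <- function(x, fs, method = "pan_tompkins", target = "maternal") {
  if (length(x) < fs) stop("signal must be at least 1 s long")
  method <- match.arg(method, .detector_methods)
  prior <- .qrs_prior(target)
  if (all(x == x[1])) {
    return(qrs_annotation(integer(), fs, method))
  }
  idx <- switch(method,
    maxsearch    = .det_maxsearch(x, fs, prior),
    jqrs         = .det_jqrs(x, fs, prior),
    pan_tompkins = .det_pan_tompkins(x, fs, prior),
    gqrs         = .det_gqrs(x, fs, prior),
    wqrs         = .det_wqrs(x, fs, prior)
  )
  if (length(idx)) {
    idx <- .align_to_peak(idx, x, round(0.025 * fs))
    idx <- .enforce_refractory(unique(idx), abs(x), round(prior$refractory * fs))
  }
  qrs_annotation(idx, fs, method)
}

#' Construct a QRS annotation object
#' @param indices strictly increasing sample indices.
#' @param fs sampling rate, Hz.
#' @param detector detector name or `"reference"`.
#' @return An object of class `qrs_annotation`.
#' @export
qrs_annotation <- function(indices, fs, detector = "reference") {
  indices <- as.integer(indices)
  if (length(indices) && any(diff(indices) <= 0)) {
    stop("annotation indices must be strictly increasing")
  }
  structure(list(detector = detector, indices = indices, fs = fs),
            class = "qrs_annotation")
}

# -- detector families -------------------------------------------------------

# rate-constrained local-maximum search seeded by the autocorrelation RR
.det_maxsearch <- function(x, fs, prior) {
  n <- length(x)
  rr <- .estimate_rr(x, fs, prior$rr)
  a <- abs(x)
  seed <- which.max(a)
  beats <- seed
  # forward
  c_i <- seed
  while (c_i + round(0.55 * rr) <= n) {
    lo <- c_i + round(0.55 * rr)
    hi <- min(n, c_i + round(1.45 * rr))
    nxt <- lo + which.max(a[lo:hi]) - 1L
    beats <- c(beats, nxt)
    rr <- round(0.8 * rr + 0.2 * (nxt - c_i))
    c_i <- nxt
  }
  # backward
  rr <- .estimate_rr(x, fs, prior$rr)
  c_i <- seed
  while (c_i - round(0.55 * rr) >= 1L) {
    hi <- c_i - round(0.55 * rr)
    lo <- max(1L, c_i - round(1.45 * rr))
    prv <- lo + which.max(a[lo:hi]) - 1L
    beats <- c(beats, prv)
    rr <- round(0.8 * rr + 0.2 * (c_i - prv))
    c_i <- prv
  }
  beats <- sort(unique(beats))
  # amplitude plausibility: rate-constrained search can latch onto T waves
  # or trailing noise past the last true beat
  beats[abs(x[beats]) >= 0.4 * stats::median(abs(x[beats]))]
}

# bandpass-energy + adaptive threshold with search-back
.det_jqrs <- function(x, fs, prior) {
  e <- .moving_avg(.qrs_band(x, fs)^2, round(prior$qrs_win * fs))
  thr <- 0.25 * stats::quantile(e, 0.98, names = FALSE)
  peaks <- .local_maxima(e, thr)
  peaks <- .enforce_refractory(peaks, e, round(prior$refractory * fs))
  # search-back over long gaps with a relaxed threshold
  if (length(peaks) >= 3L) {
    med_rr <- stats::median(diff(peaks))
    out <- peaks
    gaps <- which(diff(peaks) > 1.8 * med_rr)
    for (g in gaps) {
      lo <- peaks[g] + round(0.4 * med_rr)
      hi <- peaks[g + 1L] - round(0.4 * med_rr)
      if (lo >= hi) next
      cand <- .local_maxima(e[lo:hi], 0.3 * thr)
      if (length(cand)) out <- c(out, lo + cand[which.max(e[lo:hi][cand])] - 1L)
    }
    peaks <- sort(unique(out))
  }
  peaks
}

# derivative -> square -> moving-window integration -> dual thresholds
.det_pan_tompkins <- function(x, fs, prior) {
  n <- length(x)
  d <- c(0, 0, diff(x, lag = 2), 0) / 2      # centred derivative, aligned
  sq <- d^2
  mwi <- .moving_avg(sq, round(prior$qrs_win * fs))
  peaks <- .local_maxima(mwi)
  peaks <- .enforce_refractory(peaks, mwi, round(prior$refractory * fs))
  if (!length(peaks)) return(integer())
  # adaptive signal/noise levels, seeded from the first second
  spki <- max(mwi[seq_len(min(n, fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, fs))]) * 0.5
  beats <- integer()
  for (p in peaks) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[p] > thr) {
      beats <- c(beats, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
  }
  # search-back for missed beats in long gaps at half threshold
  if (length(beats) >= 3L) {
    med_rr <- stats::median(diff(beats))
    thr2 <- 0.5 * (npki + 0.25 * (spki - npki))
    out <- beats
    gaps <- which(diff(beats) > 1.66 * med_rr)
    for (g in gaps) {
      lo <- beats[g] + round(0.4 * med_rr)
      hi <- beats[g + 1L] - round(0.4 * med_rr)
      if (lo >= hi) next
      seg_peaks <- .local_maxima(mwi[lo:hi], thr2)
      if (length(seg_peaks)) {
        out <- c(out, lo + seg_peaks[which.max(mwi[lo:hi][seg_peaks])] - 1L)
      }
    }
    beats <- sort(unique(out))
  }
  beats
}

# template cross-correlation with adaptive threshold
.det_gqrs <- function(x, fs, prior) {
  n <- length(x)
  a <- abs(x)
  # provisional beats from a high amplitude quantile
  thr0 <- 0.5 * stats::quantile(a, 0.995, names = FALSE)
  prov <- .enforce_refractory(.local_maxima(a, thr0), a,
                              round(prior$refractory * fs))
  half <- round(0.05 * fs)
  prov <- prov[prov > half & prov <= n - half]
  if (length(prov) < 2L) return(prov)
  tmpl <- rowMeans(vapply(prov, function(p) x[(p - half):(p + half)],
                          numeric(2L * half + 1L)))
  tmpl <- tmpl - mean(tmpl)
  tn <- sqrt(sum(tmpl^2))
  if (tn == 0) return(prov)
  # normalized cross-correlation; reflection padding keeps edge beats valid
  xp <- c(rev(x[1:half]), x, rev(x[(n - half + 1L):n]))
  num <- as.numeric(stats::filter(xp, rev(tmpl), sides = 2))[
    (half + 1L):(half + n)]
  num[is.na(num)] <- 0
  loc_e <- .moving_avg(xp^2, 2L * half + 1L)[(half + 1L):(half + n)] *
    (2L * half + 1L)
  ncc <- num / (tn * sqrt(pmax(loc_e, 1e-12)))
  peaks <- .local_maxima(ncc, 0.4)
  .enforce_refractory(peaks, ncc, round(prior$refractory * fs))
}

# curve-length transform threshold crossing
.det_wqrs <- function(x, fs, prior) {
  dx <- c(0, diff(.qrs_band(x, fs)))
  clt <- .moving_avg(sqrt(dx^2 + (1 / fs)^2), round(1.2 * prior$qrs_win * fs))
  base <- stats::median(clt)
  thr <- base + 0.4 * (stats::quantile(clt, 0.98, names = FALSE) - base)
  peaks <- .local_maxima(clt, thr)
  .enforce_refractory(peaks, clt, round(prior$refractory * fs))
}

#' Match test annotations against a reference
#'
#' Greedy one-to-one nearest matching within a tolerance window; ties are
#' broken toward the earlier reference beat.
#'
#' @param test,reference `qrs_annotation` objects at the same sampling rate.
#' @param tol_ms matching tolerance, milliseconds.
#' @return Named integer vector `c(tp, fp, fn)` with
#'   `tp + fp == length(test)` and `tp + fn == length(reference)`.
#' @export
match_annotations <- function(test, reference, tol_ms = 50) {
  stopifnot(inherits(test, "qrs_annotation"),
            inherits(reference, "qrs_annotation"))
  if (test$fs != reference$fs) stop("annotations must share a sampling rate")
  tol <- tol_ms / 1000 * test$fs
  ti <- test$indices; ri <- reference$indices
  if (!length(ti) || !length(ri)) {
    return(c(tp = 0L, fp = length(ti), fn = length(ri)))
  }
  pairs <- expand.grid(t = seq_along(ti), r = seq_along(ri))
  pairs$d <- abs(ti[pairs$t] - ri[pairs$r])
  pairs <- pairs[pairs$d <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$d, pairs$r), , drop = FALSE]
  used_t <- logical(length(ti)); used_r <- logical(length(ri))
  tp <- 0L
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$t[k]; b <- pairs$r[k]
    if (!used_t[a] && !used_r[b]) {
      used_t[a] <- TRUE; used_r[b] <- TRUE; tp <- tp + 1L
    }
  }
  c(tp = tp, fp = length(ti) - tp, fn = length(ri) - tp)
}
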
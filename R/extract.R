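# Maternal-ECG cancellation by template subtraction with principal-component
# modelling of the maternal beat (TSpca). Fixed-length windows centred on the
# maternal R peaks are stacked, decomposed, reconstructed from the leading
# components and subtracted in place; the residual carries the foetal ECG.

#' TSpca configuration
#'
#' @param cycle_window_ms maternal cycle window length centred on each MQRS,
#'   milliseconds.
#' @param n_components number of principal components used to reconstruct
#'   the maternal beat.
#' @param min_cycles minimum number of maternal beats required.
#' @return An object of class `tspca_config`.
#' @export
tspca_config <- function(cycle_window_ms = 500, n_components = 2,
                         min_cycles = 3) {
  if (n_components < 1) stop("n_components must be >= 1")
  if (cycle_window_ms <= 0) stop("cycle_window_ms must be positive")
  structure(list(cycle_window_ms = cycle_window_ms,
                 n_components = as.integer(n_components),
                 min_cycles = as.integer(min_cycles)),
            class = "tspca_config")
}

#' Extract the foetal ECG residual from an abdominal channel
#'
#' For each maternal beat a fixed-length window (default 500 ms) is centred
#' on the MQRS index and truncated at the midpoints between adjacent beats
#' (and at the signal edges) so windows never overlap. The windows are
#' stacked into a beat matrix, mean-centred per window, decomposed by SVD,
#' and reconstructed from the leading `n_components` components. Within each
#' window the residual is the centred window minus its reconstruction (the
#' per-window mean is not restored; baseline content is assumed removed by
#' the bandpass stage). Samples outside all windows pass through unchanged.
#'
#' @param abdominal numeric vector (one abdominal channel).
#' @param mqrs maternal R-peak sample indices (1-based).
#' @param fs sampling rate, Hz.
#' @param config a `tspca_config`.
#' @return Numeric residual of the same length as the input.
#' @export
extract_fecg <- function(abdominal, mqrs, fs, config = tspca_config()) {
  stopifnot(inherits(config, "tspca_config"))
  n <- length(abdominal)
  mqrs <- sort(as.integer(mqrs))
  if (length(mqrs) < config$min_cycles) {
    stop(structure(class = c("fecg_extraction_failure", "error", "condition"),
                   list(message = sprintf(
                     "TSpca needs at least %d maternal beats, got %d",
                     config$min_cycles, length(mqrs)), call = sys.call(-1))))
  }
  wlen <- round(config$cycle_window_ms / 1000 * fs)
  half <- wlen %/% 2
  nb <- length(mqrs)
  # per-beat valid range: centred window clipped at inter-beat midpoints
  mids_lo <- c(1L, floor((mqrs[-nb] + mqrs[-1]) / 2) + 1L)
  mids_hi <- c(floor((mqrs[-nb] + mqrs[-1]) / 2), n)
  stack <- matrix(0, nb, wlen)
  valid <- matrix(FALSE, nb, wlen)
  for (i in seq_len(nb)) {
    lo <- max(mqrs[i] - half, mids_lo[i], 1L)
    hi <- min(mqrs[i] - half + wlen - 1L, mids_hi[i], n)
    if (lo > hi) next
    cols <- (lo - (mqrs[i] - half)) + seq_len(hi - lo + 1L)
    stack[i, cols] <- abdominal[lo:hi]
    valid[i, cols] <- TRUE
  }
  # mean-centre each window over its valid part
  mu <- vapply(seq_len(nb), function(i) {
    v <- valid[i, ]
    if (any(v)) mean(stack[i, v]) else 0
  }, numeric(1))
  centred <- stack
  for (i in seq_len(nb)) centred[i, valid[i, ]] <- stack[i, valid[i, ]] - mu[i]
  q <- min(config$n_components, nb, wlen)
  sv <- svd(centred, nu = q, nv = q)
  recon <- sv$u %*% (diag(sv$d[seq_len(q)], q, q) %*% t(sv$v))
  residual <- abdominal
  for (i in seq_len(nb)) {
    v <- which(valid[i, ])
    if (!length(v)) next
    pos <- (mqrs[i] - half) + v - 1L
    residual[pos] <- centred[i, v] - recon[i, v]
  }
  residual
}
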
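# Canonical frequency bands and per-epoch band-power estimation.

#' Canonical EEG frequency bands
#'
#' The four bands used throughout the analysis: theta 4-7 Hz, alpha
#' 8-12 Hz, beta1 13-18 Hz, beta2 19-30 Hz.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
canonical_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), beta1 = c(13, 18), beta2 = c(19, 30))
}

# one-sided PSD of a vector: Welch-averaged Hann-windowed segments, or a
# single rectangular-window periodogram. Returns list(freq, psd) with psd in
# unit^2 / Hz so that sum(psd) * df ~= var(x).
psd_estimate <- function(x, fs, method = c("welch", "periodogram"),
                         seg_seconds = 1, overlap = 0.5) {
  method <- match.arg(method)
  n <- length(x)
  if (method == "periodogram") {
    seg <- n
    w <- rep(1, seg)
    starts <- 1L
  } else {
    seg <- min(n, round(seg_seconds * fs))
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg - 1) / (seg - 1))  # Hann
    step <- max(1L, round(seg * (1 - overlap)))
    starts <- seq(1L, n - seg + 1L, by = step)
  }
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(seg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg_x <- x[s:(s + seg - 1L)]
    X <- stats::fft(w * (seg_x - mean(seg_x)))
    p <- (Mod(X)^2 * scale)[seq_len(nf)]
    p[-c(1L, if (seg %% 2 == 0) nf)] <- 2 * p[-c(1L, if (seg %% 2 == 0) nf)]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg, psd = acc / length(starts))
}

#' Per-epoch, per-channel band power
#'
#' Estimates the power spectral density of every epoch and channel (Welch:
#' 1 s Hann segments, 50% overlap, by default) and integrates it over each
#' band. Band intervals are treated as closed-open `[lo, hi + 1)` on the
#' frequency axis, so adjacent canonical bands partition the spectrum
#' without double counting.
#'
#' @param epochs An [eeg_epochs] set.
#' @param bands Named list of `c(lo, hi)` pairs (default [canonical_bands()]).
#' @param method `"welch"` (default) or `"periodogram"`.
#' @param log_power Return natural-log power instead of raw power (default
#'   FALSE; the statistics path logs downstream).
#' @return A `band_power_table`: array `values` (epoch x channel x band, in
#'   microvolts squared), plus `bands`, `labels`, `probe_ids`,
#'   `channel_labels`, `subject_id` carried from the epoch set.
#' @export
band_power <- function(epochs, bands = canonical_bands(),
                       method = c("welch", "periodogram"), log_power = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  method <- match.arg(method)
  lohi <- do.call(rbind, bands)
  if (any(lohi[, 2] >= epochs$fs / 2)) stop("band above the Nyquist frequency")
  lowest <- min(lohi[, 1])
  if (epochs$epoch_length < 2 / lowest) {
    warning(sprintf(
      "epoch length %.3g s is short for the %g Hz band edge; resolution limited",
      epochs$epoch_length, lowest))
  }
  d <- dim(epochs$data)
  vals <- array(0, c(d[1], d[2], length(bands)),
                dimnames = list(NULL, epochs$channel_labels, names(bands)))
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      ps <- psd_estimate(epochs$data[e, ch, ], epochs$fs, method)
      df <- ps$freq[2] - ps$freq[1]
      for (b in seq_along(bands)) {
        sel <- ps$freq >= lohi[b, 1] & ps$freq < lohi[b, 2] + 1
        vals[e, ch, b] <- sum(ps$psd[sel]) * df
      }
    }
  }
  if (log_power) vals <- log(vals)
  structure(list(values = vals, bands = bands, labels = epochs$labels,
                 probe_ids = epochs$probe_ids,
                 channel_labels = epochs$channel_labels,
                 subject_id = epochs$subject_id, method = method,
                 log_power = log_power),
            class = "band_power_table")
}

#' Tidy data-frame view of a band-power table
#'
#' @param x A `band_power_table`.
#' @param ... Unused.
#' @return A long data.frame with columns `subject`, `epoch`, `probe`,
#'   `label`, `channel`, `band`, `power`.
#' @export
as.data.frame.band_power_table <- function(x, ...) {
  d <- dim(x$values)
  g <- expand.grid(epoch = seq_len(d[1]), channel = x$channel_labels,
                   band = names(x$bands), stringsAsFactors = FALSE)
  data.frame(subject = x$subject_id,
             epoch = g$epoch,
             probe = if (!is.null(x$probe_ids)) x$probe_ids[g$epoch] else NA,
             label = if (!is.null(x$labels)) x$labels[g$epoch] else NA,
             channel = g$channel, band = g$band,
             power = as.vector(x$values),
             stringsAsFactors = FALSE)
}

#' Bandpass-filter an epoch set to a single band
#'
#' Intended for CSP consumption. Filtering short epochs requires a filter
#' no longer than the epoch, so the tap count is capped at a third of the
#' epoch length (coarsening the transition bands); when the continuous
#' record is available, prefer filtering it with [bandpass_raw()] before
#' epoch extraction, which is what the pipeline does.
#'
#' @param epochs An [eeg_epochs] set.
#' @param band `c(lo, hi)` in Hz.
#' @return The band-filtered [eeg_epochs].
#' @export
bandpass_epochs <- function(epochs, band) {
  stopifnot(inherits(epochs, "eeg_epochs"), length(band) == 2)
  if (band[2] >= epochs$fs / 2) stop("band edge at or above Nyquist")
  d <- dim(epochs$data)
  trans <- 1
  n_taps <- ceiling(3.3 * epochs$fs / trans)
  max_taps <- max(8L, 2L * floor(d[3] / 2))
  if (n_taps > max_taps) trans <- 3.3 * epochs$fs / max_taps
  # widen the -6 dB cutoffs by half the transition width so the gain is
  # ~1 across the nominal band and band power is preserved
  lo <- max(band[1] - trans / 2, 0.1)
  hi <- min(band[2] + trans / 2, epochs$fs / 2 - 1e-6)
  b <- design_fir_bandpass(epochs$fs, lo, hi, trans, trans)
  out <- epochs
  for (e in seq_len(d[1])) {
    out$data[e, , ] <- filtfilt_rows(matrix(epochs$data[e, , ], nrow = d[2]), b)
  }
  out
}
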
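# Continuous-signal conditioning: bad-channel screening, common-average
# referencing, exponentially weighted running standardization, bandpass.

#' Flag channels with extreme variance
#'
#' Screens for broken or saturated electrodes by computing each channel's
#' log-variance and flagging channels whose robust z-score (median / MAD
#' across channels) exceeds `z_threshold` in absolute value. The input is
#' not modified.
#'
#' @param raw An [eeg_raw] recording with at least 4 channels.
#' @param z_threshold Robust z cut-off (default 5).
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(raw, z_threshold = 5) {
  stopifnot(inherits(raw, "eeg_raw"))
  if (n_channels(raw) < 4) stop("need at least 4 channels to screen variance")
  lv <- log(apply(raw$data, 1L, stats::var))
  med <- stats::median(lv)
  s <- stats::mad(lv)
  if (s == 0) s <- .Machine$double.eps
  bad <- abs(lv - med) / s > z_threshold
  if (all(bad)) stop("all channels flagged as bad; montage unusable")
  raw$montage$label[bad]
}

#' Drop channels from a recording
#'
#' @param raw An [eeg_raw] recording.
#' @param labels Channel labels to remove.
#' @return The recording without those channels.
#' @export
drop_channels <- function(raw, labels) {
  if (length(labels) == 0) return(raw)
  keep <- !(raw$montage$label %in% labels)
  if (!any(keep)) stop("cannot drop every channel")
  eeg_raw(raw$data[keep, , drop = FALSE], raw$fs,
          raw$montage[keep, , drop = FALSE], raw$start_time)
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean from every sample, so each sample
#' vector has zero mean over channels. The operation is a projection
#' (applying it twice equals applying it once) and reduces the data rank
#' by one.
#'
#' @param raw An [eeg_raw] recording with at least 2 channels.
#' @return The re-referenced [eeg_raw].
#' @export
rereference_average <- function(raw) {
  stopifnot(inherits(raw, "eeg_raw"))
  if (n_channels(raw) < 2) stop("average reference needs at least 2 channels")
  out <- raw
  out$data <- sweep(raw$data, 2L, colMeans(raw$data))
  out
}

#' Exponentially weighted running standardization
#'
#' Standardizes each channel by its exponential running mean and variance:
#' \deqn{\mu_t = (1-\alpha)\mu_{t-1} + \alpha x_t}
#' \deqn{v_t = (1-\alpha)v_{t-1} + \alpha (x_t-\mu_t)^2}
#' with output \eqn{(x_t-\mu_t)/\sqrt{\max(v_t, v_{floor})}}. The mean is
#' updated before the deviation enters the variance update; this order is
#' part of the contract. The small smoothness factor (default 0.001) makes
#' the statistics adapt slowly, so brief high-voltage events are compressed
#' without erasing ordinary signal structure.
#'
#' Initialization: the running mean starts at the first sample and the
#' running variance at the sample variance of the first 10 s (falling back
#' to 1 if the recording is shorter), with a floor of `var_floor`.
#'
#' @param raw An [eeg_raw] recording.
#' @param alpha Smoothness factor in (0, 1].
#' @param var_floor Variance floor guarding the division (default 1e-4).
#' @return The standardized [eeg_raw] (output is dimensionless but keeps the
#'   container's unit slot by convention).
#' @export
ewm_standardize <- function(raw, alpha = 0.001, var_floor = 1e-4) {
  stopifnot(inherits(raw, "eeg_raw"), alpha > 0, alpha <= 1, var_floor > 0)
  x <- raw$data
  n <- ncol(x)
  n0 <- min(n, round(10 * raw$fs))
  out <- raw
  out$data <- t(vapply(seq_len(nrow(x)), function(ch) {
    xi <- x[ch, ]
    mu0 <- xi[1]
    v0 <- if (n0 >= 2) stats::var(xi[seq_len(n0)]) else 1
    if (!is.finite(v0) || v0 <= 0) v0 <- 1
    # recursive EWMA via stats::filter: m_t = (1-a) m_{t-1} + a x_t
    mu <- as.numeric(stats::filter(alpha * xi, 1 - alpha,
                                   method = "recursive", init = mu0))
    dev2 <- (xi - mu)^2
    v <- as.numeric(stats::filter(alpha * dev2, 1 - alpha,
                                  method = "recursive", init = v0))
    (xi - mu) / sqrt(pmax(v, var_floor))
  }, numeric(n)))
  out
}
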
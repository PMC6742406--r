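# Fixed-length epoching, cross-validated peak-to-peak epoch rejection, and
# probe-locked labelled epoch extraction.

#' Cut a recording into non-overlapping fixed-length epochs
#'
#' Produces `floor(duration / length)` epochs over half-open sample
#' intervals, so concatenating the epochs reconstructs the (truncated)
#' recording exactly.
#'
#' @param raw An [eeg_raw] recording.
#' @param length Epoch length in seconds (default 1).
#' @return An unlabelled [eeg_epochs] set.
#' @export
epoch_fixed <- function(raw, length = 1) {
  stopifnot(inherits(raw, "eeg_raw"))
  spe <- round(length * raw$fs)
  n_ep <- floor(ncol(raw$data) / spe)
  if (n_ep < 1) stop("recording shorter than one epoch")
  a <- array(0, c(n_ep, nrow(raw$data), spe))
  for (e in seq_len(n_ep)) {
    a[e, , ] <- raw$data[, ((e - 1L) * spe + 1L):(e * spe)]
  }
  eeg_epochs(a, raw$fs, channel_labels = raw$montage$label)
}

epoch_ptp <- function(epochs) {
  # max over channels of the per-channel peak-to-peak amplitude, per epoch
  apply(epochs$data, 1L, function(m) max(apply(m, 1L, function(v) diff(range(v)))))
}

#' Reject high-amplitude epochs with a cross-validated global threshold
#'
#' Selects a single peak-to-peak rejection threshold by K-fold
#' cross-validation: for each candidate threshold, the mean of the retained
#' training epochs is compared (Frobenius RMSE) against the pointwise
#' median of the held-out epochs — the median being a rejection-free robust
#' reference — and the threshold minimizing the average error wins (ties go
#' to the more permissive threshold). Epochs whose maximum channel
#' peak-to-peak amplitude exceeds the chosen threshold are dropped.
#'
#' @param epochs An [eeg_epochs] set (>= 10 epochs unless the grid is a
#'   single threshold).
#' @param threshold_grid Candidate thresholds in microvolts; default: 20
#'   quantiles of the observed per-epoch peak-to-peak values plus `Inf`.
#' @param cv_folds Number of folds (default 5).
#' @return A list with `epochs` (the retained [eeg_epochs]), `threshold`
#'   (chosen value), and `retained` (indices into the input).
#' @export
reject_epochs_ptp <- function(epochs, threshold_grid = NULL, cv_folds = 5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n <- length(epochs)
  ptp <- epoch_ptp(epochs)
  if (is.null(threshold_grid)) {
    if (n < 10) stop("need at least 10 epochs to cross-validate a threshold")
    threshold_grid <- c(stats::quantile(ptp, seq(0.1, 1, length.out = 20),
                                        names = FALSE), Inf)
  }
  threshold_grid <- sort(unique(threshold_grid))
  if (length(threshold_grid) == 1) {
    chosen <- threshold_grid
  } else {
    fold <- rep(seq_len(cv_folds), length.out = n)  # deterministic blocks
    d <- dim(epochs$data)
    flat <- matrix(epochs$data, d[1])  # epoch x (channel*sample)
    err <- matrix(Inf, length(threshold_grid), cv_folds)
    for (f in seq_len(cv_folds)) {
      va <- which(fold == f)
      med <- apply(flat[va, , drop = FALSE], 2L, stats::median)
      tr <- which(fold != f)
      ord <- tr[order(ptp[tr])]
      # sweep thresholds in increasing order, growing the retained train
      # sum incrementally instead of re-averaging per threshold
      acc <- numeric(ncol(flat))
      cnt <- 0L
      pos <- 1L
      for (ti in seq_along(threshold_grid)) {
        while (pos <= length(ord) && ptp[ord[pos]] <= threshold_grid[ti]) {
          acc <- acc + flat[ord[pos], ]
          cnt <- cnt + 1L
          pos <- pos + 1L
        }
        if (cnt > 0) err[ti, f] <- sqrt(mean((acc / cnt - med)^2))
      }
    }
    merr <- rowMeans(err)
    chosen <- max(threshold_grid[merr == min(merr)])  # permissive tie-break
  }
  retained <- which(ptp <= chosen)
  if (length(retained) == 0) {
    stop(sprintf("all epochs rejected at threshold %.3g", chosen))
  }
  list(epochs = epochs[retained], threshold = chosen, retained = retained)
}

#' Apply a fixed peak-to-peak threshold to an epoch set
#'
#' @param epochs An [eeg_epochs] set.
#' @param threshold Peak-to-peak cut-off in microvolts.
#' @return The retained [eeg_epochs] (attribute `retained` holds indices).
#' @export
apply_ptp_threshold <- function(epochs, threshold) {
  keep <- which(epoch_ptp(epochs) <= threshold)
  if (length(keep) == 0) stop("all epochs exceed the threshold")
  out <- epochs[keep]
  attr(out, "retained") <- keep
  out
}

#' Extract labelled pre-probe epochs
#'
#' For every probe answered MW or not-MW (probes answered "unsure" are
#' ignored), extracts the `window` seconds ending at probe onset — the
#' half-open interval (onset - window, onset] — and cuts it into
#' `window / sub` consecutive sub-epochs, all labelled with that probe's
#' response and sharing its probe id. Probes with insufficient history
#' (onset < window) are skipped with a warning.
#'
#' @param raw An [eeg_raw] recording.
#' @param probes An [mw_probes] event table.
#' @param window Pre-probe window in seconds (default 10).
#' @param sub Sub-epoch length in seconds (default 2); must divide `window`.
#' @param subject_id Optional subject identifier carried on the result.
#' @return A labelled [eeg_epochs] set.
#' @export
extract_preprobe_epochs <- function(raw, probes, window = 10, sub = 2,
                                    subject_id = NA_character_) {
  stopifnot(inherits(raw, "eeg_raw"), window %% sub == 0)
  fs <- raw$fs
  n_sub <- window / sub
  spe <- round(sub * fs)
  usable <- probes[probes$response != "UNSURE", , drop = FALSE]
  early <- usable$onset < window
  if (any(early)) {
    warning(sprintf("skipping %d probe(s) with onset before %g s", sum(early), window))
    usable <- usable[!early, , drop = FALSE]
  }
  if (nrow(usable) == 0) stop("no usable probes (all unsure or too early)")
  n_ep <- nrow(usable) * n_sub
  a <- array(0, c(n_ep, nrow(raw$data), spe))
  labels <- character(n_ep)
  probe_ids <- integer(n_ep)
  e <- 0L
  for (p in seq_len(nrow(usable))) {
    i_end <- floor(usable$onset[p] * fs)
    i_start <- i_end - round(window * fs) + 1L
    for (j in seq_len(n_sub)) {
      e <- e + 1L
      idx <- i_start + (j - 1L) * spe + seq_len(spe) - 1L
      a[e, , ] <- raw$data[, idx]
      labels[e] <- usable$response[p]
      probe_ids[e] <- usable$probe_id[p]
    }
  }
  eeg_epochs(a, fs, labels = labels, probe_ids = probe_ids,
             channel_labels = raw$montage$label, subject_id = subject_id)
}
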
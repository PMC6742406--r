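#' Default 16-channel 10-20 montage
#'
#' Returns the standard 16-electrode subset of the international 10-20
#' system used throughout the package, with approximate 2-D scalp
#' coordinates (head radius 1, nose up) for topographic displays.
#'
#' @param labels Optional character vector of channel names; defaults to the
#'   16-channel set Fp1, Fpz, Fp2, F7, F3, F4, F8, T7, C3, C4, T8, P7, P8,
#'   O1, Oz, O2. Labels outside the built-in 10-20 position table get `NA`
#'   coordinates.
#' @return A data.frame with columns `label`, `x`, `y`.
#' @export
#' @examples
#' m <- montage_1020()
#' nrow(m)  # 16
montage_1020 <- function(labels = NULL) {
  pos <- c(
    Fp1 = -0.31 + 0.95i, Fpz = 0 + 1i,      Fp2 = 0.31 + 0.95i,
    F7  = -0.81 + 0.59i, F3  = -0.41 + 0.53i, Fz = 0 + 0.5i,
    F4  = 0.41 + 0.53i,  F8  = 0.81 + 0.59i,
    T7  = -1 + 0i,       C3  = -0.5 + 0i,   Cz = 0 + 0i,
    C4  = 0.5 + 0i,      T8  = 1 + 0i,
    P7  = -0.81 - 0.59i, P3  = -0.41 - 0.53i, Pz = 0 - 0.5i,
    P4  = 0.41 - 0.53i,  P8  = 0.81 - 0.59i,
    O1  = -0.31 - 0.95i, Oz  = 0 - 1i,      O2 = 0.31 - 0.95i
  )
  if (is.null(labels)) {
    labels <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "F4", "F8", "T7",
                "C3", "C4", "T8", "P7", "P8", "O1", "Oz", "O2")
  }
  stopifnot(!anyDuplicated(labels))
  z <- pos[labels]
  data.frame(label = labels, x = Re(z), y = Im(z),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Continuous multichannel EEG recording
#'
#' Lightweight container for a continuous recording: a channels-by-samples
#' matrix in microvolts plus sampling rate and montage. All conditioning
#' operations consume and return this class.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param montage A data.frame as returned by [montage_1020()]; row count
#'   must equal `nrow(data)`.
#' @param start_time Recording start offset in seconds (default 0).
#' @return An object of class `eeg_raw`.
#' @export
eeg_raw <- function(data, fs, montage = montage_1020(), start_time = 0) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0, nrow(data) == nrow(montage))
  structure(list(data = data, fs = fs, montage = montage,
                 start_time = start_time),
            class = "eeg_raw")
}

#' @export
print.eeg_raw <- function(x, ...) {
  cat(sprintf("<eeg_raw> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$montage$label, collapse = " "), "\n")
  invisible(x)
}

#' Number of channels / duration helpers
#' @param x An `eeg_raw` object.
#' @return `n_channels()`: integer channel count; `duration()`: seconds.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname n_channels
#' @export
duration <- function(x) ncol(x$data) / x$fs

#' Set of fixed-length EEG epochs
#'
#' Container for epoched data: an epochs x channels x samples array with
#' optional class labels (`"MW"` / `"NOT_MW"`) and probe group ids. All
#' learning and statistics operate on this class.
#'
#' @param data Numeric array, epochs x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param labels Optional character vector (`"MW"`/`"NOT_MW"`), one per epoch.
#' @param probe_ids Optional integer vector, one per epoch; epochs sharing a
#'   probe id always travel together through cross-validation.
#' @param channel_labels Character vector of channel names.
#' @param subject_id Optional subject identifier.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, labels = NULL, probe_ids = NULL,
                       channel_labels = NULL, subject_id = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n <- dim(data)[1]
  if (!is.null(labels)) {
    stopifnot(length(labels) == n, all(labels %in% c("MW", "NOT_MW")))
  }
  if (!is.null(probe_ids)) stopifnot(length(probe_ids) == n)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(dim(data)[2]))
  }
  structure(list(data = data, fs = fs, labels = labels,
                 probe_ids = probe_ids, channel_labels = channel_labels,
                 subject_id = subject_id,
                 epoch_length = dim(data)[3] / fs),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              d[1], d[2], d[3], x$epoch_length, x$fs))
  if (!is.null(x$labels)) {
    tb <- table(factor(x$labels, levels = c("MW", "NOT_MW")))
    cat(sprintf("  labels: %d MW / %d NOT_MW\n", tb[["MW"]], tb[["NOT_MW"]]))
  }
  invisible(x)
}

#' @export
length.eeg_epochs <- function(x) dim(x$data)[1]

#' Subset an epoch set
#'
#' @param x An `eeg_epochs` object.
#' @param i Epoch indices (logical or integer).
#' @param ... Unused.
#' @return An `eeg_epochs` holding the selected epochs, labels and probe ids.
#' @export
`[.eeg_epochs` <- function(x, i, ...) {
  eeg_epochs(x$data[i, , , drop = FALSE], x$fs,
             labels = if (!is.null(x$labels)) x$labels[i],
             probe_ids = if (!is.null(x$probe_ids)) x$probe_ids[i],
             channel_labels = x$channel_labels, subject_id = x$subject_id)
}

#' Thought-probe event table
#'
#' @param onset Numeric vector of probe onsets in seconds from recording
#'   start; must be strictly increasing.
#' @param response Character vector of probe responses, one of `"MW"`,
#'   `"NOT_MW"`, `"UNSURE"`.
#' @param probe_id Optional integer ids (default sequential).
#' @return A data.frame of class `mw_probes` with columns
#'   `onset`, `response`, `probe_id`.
#' @export
mw_probes <- function(onset, response, probe_id = seq_along(onset)) {
  stopifnot(length(onset) == length(response),
            all(diff(onset) > 0),
            all(response %in% c("MW", "NOT_MW", "UNSURE")))
  out <- data.frame(onset = onset, response = response,
                    probe_id = as.integer(probe_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("mw_probes", "data.frame")
  out
}

#' Read / write probe event tables
#'
#' Events are stored as plain CSV with columns `onset_s` and `response`,
#' where response uses the probe answer codes A (paying attention),
#' B (mind wandering), C (unsure).
#'
#' @param path File path.
#' @param probes An `mw_probes` table (for writing).
#' @return `read_events()` returns an `mw_probes` table.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset_s", "response") %in% names(df)))
  map <- c(A = "NOT_MW", B = "MW", C = "UNSURE")
  resp <- ifelse(df$response %in% names(map), map[df$response], df$response)
  mw_probes(df$onset_s, unname(resp))
}

#' @rdname read_events
#' @export
write_events <- function(probes, path) {
  map <- c(NOT_MW = "A", MW = "B", UNSURE = "C")
  utils::write.csv(
    data.frame(onset_s = probes$onset, response = unname(map[probes$response])),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
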
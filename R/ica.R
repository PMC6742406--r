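# Extended-infomax ICA for artifact suppression, with skewness/kurtosis
# component rejection and channel-space reconstruction.

#' Fit an extended-infomax ICA decomposition
#'
#' Decomposes epoched EEG into maximally independent components using the
#' extended infomax algorithm (a natural-gradient maximum-likelihood update
#' whose score function switches per component between sub- and
#' super-Gaussian forms). Data are PCA-whitened first; rank-deficient
#' inputs — e.g. after common-average referencing, which removes one degree
#' of freedom — automatically yield `rank` components rather than one per
#' channel. The fit is deterministic: identity initialization, full-batch
#' updates, annealed learning rate. Components are ordered by explained
#' variance, and signs are fixed so the largest-magnitude mixing weight of
#' each component is positive.
#'
#' @param epochs An [eeg_epochs] set (typically the clean 1 s epochs that
#'   survive [reject_epochs_ptp()]).
#' @param n_components Maximum number of components (default: channel
#'   count, reduced to the numerical rank of the data).
#' @param max_iter,tol Stopping controls for the natural-gradient loop.
#' @param max_samples Fit on at most this many samples (evenly subsampled,
#'   deterministic) to bound runtime; default 50000.
#' @return An object of class `eeg_ica`: `unmixing` (components x channels),
#'   `mixing` (channels x components), `sources` (components x fitted
#'   samples), `rejected` (integer set, empty until
#'   [reject_components_stats()]), thresholds, channel labels, and the
#'   per-channel center used.
#' @export
fit_ica <- function(epochs, n_components = NULL, max_iter = 500,
                    tol = 1e-4, max_samples = 20000) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  X <- matrix(aperm(epochs$data, c(2, 3, 1)), d[2])  # channels x (samples*epochs)
  if (ncol(X) > max_samples) {
    X <- X[, round(seq(1, ncol(X), length.out = max_samples)), drop = FALSE]
  }
  ctr <- rowMeans(X)
  X <- X - ctr
  C <- stats::cov(t(X))
  eg <- eigen(C, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  r <- min(rank, if (is.null(n_components)) d[2] else n_components)
  V <- eg$vectors[, seq_len(r), drop = FALSE]
  Dh <- sqrt(eg$values[seq_len(r)])
  whiten <- t(V) / Dh          # r x channels
  dewhiten <- V * rep(Dh, each = nrow(V))  # channels x r
  Z <- whiten %*% X
  N <- ncol(Z)

  W <- diag(r)
  lr <- 0.2
  last <- Inf
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    tU <- tanh(U)
    # per-component sub/super-Gaussian switch
    kk <- sign(rowMeans(1 - tU^2) * rowMeans(U^2) - rowMeans(tU * U))
    kk[kk == 0] <- 1
    G <- diag(r) - (kk * tU) %*% t(U) / N - U %*% t(U) / N
    gnorm <- sqrt(sum(G^2) / r)   # learning-rate independent gradient norm
    if (!is.finite(gnorm)) stop("ICA diverged; reduce the learning rate")
    if (gnorm < tol) break
    W <- W + lr * G %*% W
    # anneal only on genuine divergence; the gradient norm legitimately
    # rises while escaping the saddle around the whitened starting point
    if (gnorm > 2 * last) lr <- max(lr * 0.7, 0.02)
    last <- gnorm
  }
  unmixing <- W %*% whiten          # r x channels
  mixing <- dewhiten %*% solve(W)   # channels x r
  S <- unmixing %*% X
  # order by explained channel-space variance, fix signs
  ev <- apply(S, 1L, stats::var) * colSums(mixing^2)
  ord <- order(ev, decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]
  for (i in seq_len(r)) {
    j <- which.max(abs(mixing[, i]))
    if (mixing[j, i] < 0) {
      mixing[, i] <- -mixing[, i]
      unmixing[i, ] <- -unmixing[i, ]
      S[i, ] <- -S[i, ]
    }
  }
  structure(list(unmixing = unmixing, mixing = mixing, sources = S,
                 rejected = integer(0), skew_threshold = 2.50,
                 kurt_threshold = 3.00, center = ctr,
                 channel_labels = epochs$channel_labels,
                 n_iter = it, fs = epochs$fs),
            class = "eeg_ica")
}

#' @export
print.eeg_ica <- function(x, ...) {
  cat(sprintf("<eeg_ica> %d components over %d channels (%d iterations)\n",
              nrow(x$unmixing), ncol(x$unmixing), x$n_iter))
  if (length(x$rejected)) {
    cat("  rejected components:", paste(x$rejected, collapse = " "), "\n")
  }
  invisible(x)
}

#' Mark artifactual components by skewness / kurtosis thresholds
#'
#' Components whose source skewness exceeds +/- `skew_threshold` or whose
#' excess kurtosis (Gaussian = 0) exceeds +/- `kurt_threshold` are marked
#' rejected. Both comparisons are strict, so a component sitting exactly at
#' a threshold is retained. Blink and motion components are heavy-tailed
#' and/or one-sided, so they exceed these limits; genuine oscillatory EEG
#' is near-Gaussian and survives.
#'
#' @param ica An `eeg_ica` fit.
#' @param skew_threshold,kurt_threshold Thresholds (defaults 2.50 / 3.00).
#' @return The `eeg_ica` with its `rejected` set populated.
#' @export
reject_components_stats <- function(ica, skew_threshold = 2.50,
                                    kurt_threshold = 3.00) {
  stopifnot(inherits(ica, "eeg_ica"))
  sk <- apply(ica$sources, 1L, e1071::skewness, type = 1)
  ku <- apply(ica$sources, 1L, e1071::kurtosis, type = 1)  # excess kurtosis
  ica$rejected <- which(abs(sk) > skew_threshold | abs(ku) > kurt_threshold)
  ica$component_stats <- data.frame(skewness = sk, excess_kurtosis = ku)
  ica$skew_threshold <- skew_threshold
  ica$kurt_threshold <- kurt_threshold
  ica
}

#' Reconstruct a recording without the rejected components
#'
#' Projects the recording into source space with the fitted unmixing
#' matrix, zeroes the rejected components, and re-mixes into channel
#' space. With nothing rejected, reconstruction is exact up to the rank
#' retained by the whitening step.
#'
#' @param raw An [eeg_raw] recording over the same montage the ICA was
#'   fitted on.
#' @param ica An `eeg_ica` fit, usually after [reject_components_stats()].
#' @return The cleaned [eeg_raw].
#' @export
remix_without_rejected <- function(raw, ica) {
  stopifnot(inherits(raw, "eeg_raw"), inherits(ica, "eeg_ica"))
  if (!identical(raw$montage$label, ica$channel_labels)) {
    stop("montage mismatch between recording and ICA fit")
  }
  keep <- setdiff(seq_len(nrow(ica$unmixing)), ica$rejected)
  ctr <- rowMeans(raw$data)
  S <- ica$unmixing[keep, , drop = FALSE] %*% (raw$data - ctr)
  out <- raw
  out$data <- ica$mixing[, keep, drop = FALSE] %*% S + ctr
  out
}
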
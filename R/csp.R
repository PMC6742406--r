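# Common spatial patterns: discriminative spatial filtering for two-class
# EEG, the analysis core of the package.

#' Class-conditional covariance matrices
#'
#' Computes the average spatial covariance of each class: per-epoch
#' covariances are trace-normalized (so every epoch contributes equal total
#' power) and averaged within class, optionally shrunk toward a scaled
#' identity, `C <- (1 - gamma) C + gamma (tr(C)/p) I`.
#'
#' @param epochs A labelled [eeg_epochs] set with both classes present.
#' @param shrinkage Shrinkage weight gamma in `[0, 1]` (default 0).
#' @return List with `C_mw` and `C_not`, channel x channel matrices.
#' @export
class_covariances <- function(epochs, shrinkage = 0) {
  stopifnot(inherits(epochs, "eeg_epochs"), !is.null(epochs$labels))
  avg_class_covs(epoch_covariances(epochs), epochs$labels, shrinkage)
}

#' Per-epoch trace-normalized spatial covariances
#'
#' @param epochs An [eeg_epochs] set.
#' @return Array `p x p x n` of per-epoch covariance matrices, each
#'   normalized to unit trace.
#' @export
epoch_covariances <- function(epochs) {
  d <- dim(epochs$data)
  out <- array(0, c(d[2], d[2], d[1]))
  for (e in seq_len(d[1])) {
    x <- epochs$data[e, , , drop = TRUE]
    x <- x - rowMeans(x)
    cc <- tcrossprod(x) / (ncol(x) - 1)
    out[, , e] <- cc / sum(diag(cc))
  }
  out
}

# average precomputed per-epoch covariances within class, with shrinkage
avg_class_covs <- function(covs, labels, shrinkage = 0) {
  stopifnot(shrinkage >= 0, shrinkage <= 1, dim(covs)[3] == length(labels))
  p <- dim(covs)[1]
  flat <- matrix(covs, p * p)  # (p*p) x n for fast within-class averaging
  one <- function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == 0) stop(sprintf("no epochs of class %s", cl))
    C <- matrix(rowMeans(flat[, idx, drop = FALSE]), p, p)
    if (shrinkage > 0) {
      C <- (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / p) * diag(p)
    }
    C
  }
  list(C_mw = one("MW"), C_not = one("NOT_MW"))
}

#' Fit common spatial patterns
#'
#' Learns spatial filters maximizing the variance ratio between the MW and
#' not-MW classes by solving the generalized eigenproblem
#' \deqn{C_{MW} w = \lambda (C_{MW} + C_{NOT}) w,}
#' whose eigenvalues lie in `[0, 1]` (0.5 = no discrimination). The
#' `n_components / 2` largest-eigenvalue eigenvectors (MW-dominant) and the
#' same number of smallest (not-MW-dominant) become the filters; the
#' corresponding columns of the inverse-transpose of the full eigenvector
#' matrix are the patterns — the interpretable scalp maps. Filter rows are
#' unit-normalized with the sign fixed so the largest-magnitude channel
#' coefficient is positive, and pattern columns are rescaled so that
#' `filters %*% patterns` is the identity on the retained subspace.
#'
#' @param epochs A labelled [eeg_epochs] set, already filtered to the band
#'   of interest.
#' @param n_components Even number of filters (default 6: 3 per class).
#' @param shrinkage Covariance shrinkage gamma (default 0; on a numerically
#'   singular composite covariance the fit retries once at 0.05 with a
#'   warning).
#' @param band Optional `c(lo, hi)` annotation recording which band the
#'   epochs were filtered to.
#' @param epoch_covs Optional precomputed [epoch_covariances()] array for
#'   `epochs`, to avoid recomputation inside cross-validation loops.
#' @return An object of class `csp`: `filters` (k x channels), `patterns`
#'   (channels x k), `eigenvalues` (k, sorted MW-dominant first),
#'   `eigenvalues_full`, `band`, `class_order = c("MW", "NOT_MW")`,
#'   `shrinkage`, `channel_labels`.
#' @seealso [csp_features()], [plot.csp()]
#' @export
csp <- function(epochs, n_components = 6, shrinkage = 0, band = NULL,
                epoch_covs = NULL) {
  stopifnot(n_components %% 2 == 0,
            n_components <= dim(epochs$data)[2])
  if (is.null(epoch_covs)) epoch_covs <- epoch_covariances(epochs)
  csp_from_covs(epoch_covs, epochs$labels, n_components, shrinkage, band,
                epochs$channel_labels)
}

# core fit from precomputed per-epoch covariances
csp_from_covs <- function(epoch_covs, labels, n_components = 6,
                          shrinkage = 0, band = NULL, channel_labels = NULL) {
  covs <- avg_class_covs(epoch_covs, labels, shrinkage)
  fit <- try(csp_eig(covs$C_mw, covs$C_not), silent = TRUE)
  if (inherits(fit, "try-error") ||
      (!inherits(fit, "try-error") && fit$rank < n_components)) {
    if (shrinkage == 0) {
      warning("composite covariance rank-deficient; retrying with shrinkage 0.05")
      covs <- avg_class_covs(epoch_covs, labels, 0.05)
      shrinkage <- 0.05
      fit <- csp_eig(covs$C_mw, covs$C_not)
    } else {
      stop("composite covariance singular; increase shrinkage")
    }
  }
  r <- length(fit$lambda)
  if (r < n_components) stop("covariance rank below the requested component count")
  half <- n_components / 2
  sel <- c(seq_len(half), r - half + seq_len(half))  # top and bottom lambda
  filters <- fit$W[sel, , drop = FALSE]
  patterns <- fit$A[, sel, drop = FALSE]
  # unit-norm rows, positive max-|w| coefficient; rescale patterns to keep
  # filters %*% patterns = I on the subspace
  for (i in seq_len(nrow(filters))) {
    s <- sqrt(sum(filters[i, ]^2))
    j <- which.max(abs(filters[i, ]))
    if (filters[i, j] < 0) s <- -s
    filters[i, ] <- filters[i, ] / s
    patterns[, i] <- patterns[, i] * s
  }
  structure(list(filters = filters, patterns = patterns,
                 eigenvalues = fit$lambda[sel],
                 eigenvalues_full = fit$lambda,
                 band = band, class_order = c("MW", "NOT_MW"),
                 shrinkage = shrinkage,
                 channel_labels = channel_labels),
            class = "csp")
}

# log normalized-power features from a channels x (samples*epochs) matrix
# (columns grouped by epoch, samples varying fastest); same math as
# csp_features but one BLAS call for all epochs
csp_features_flat <- function(filters, flat, n_samples, idx) {
  S <- n_samples
  cols <- as.vector(outer(seq_len(S), (idx - 1L) * S, `+`))
  P <- filters %*% flat[, cols, drop = FALSE]
  k <- nrow(P)
  A <- array(P, c(k, S, length(idx)))
  s1 <- colSums(aperm(A, c(2, 1, 3)))        # k x n sums
  s2 <- colSums(aperm(A, c(2, 1, 3))^2)      # k x n sums of squares
  v <- (s2 - s1^2 / S) / (S - 1)
  tot <- colSums(v)
  if (any(tot <= 0)) stop("zero-variance epoch")
  out <- t(log(sweep(v, 2L, tot, `/`)))
  colnames(out) <- paste0("csp", seq_len(k))
  out
}

# generalized eigendecomposition C_mw w = lambda (C_mw + C_not) w via
# whitening of the composite covariance; returns filters W (rows, sorted by
# decreasing lambda), duals A (columns), and lambda in [0, 1]. Solved in
# the principal subspace of the composite covariance, so rank-deficient
# inputs (after average referencing and ICA component removal) yield
# rank-many filters rather than numerical garbage in the null space.
csp_eig <- function(C_mw, C_not, rank_tol = 1e-8) {
  Cc <- C_mw + C_not
  eg <- eigen(Cc, symmetric = TRUE)
  r <- sum(eg$values > max(eg$values) * rank_tol)
  if (r < 2) stop("composite covariance is numerically singular")
  V <- eg$vectors[, seq_len(r), drop = FALSE]
  P <- t(V) / sqrt(eg$values[seq_len(r)])    # r x p whitener of Cc
  Sw <- P %*% C_mw %*% t(P)
  eg2 <- eigen((Sw + t(Sw)) / 2, symmetric = TRUE)
  W <- t(eg2$vectors) %*% P                  # rows = filters (r x p)
  lambda <- pmin(pmax(eg2$values, 0), 1)
  A <- (V * rep(sqrt(eg$values[seq_len(r)]), each = nrow(V))) %*% eg2$vectors
  list(W = W, A = A, lambda = lambda, rank = r)
}

#' @export
print.csp <- function(x, ...) {
  cat(sprintf("<csp> %d spatial filters over %d channels%s\n",
              nrow(x$filters), ncol(x$filters),
              if (!is.null(x$band)) sprintf(" (band %g-%g Hz)", x$band[1], x$band[2]) else ""))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.csp <- function(object, ...) object$filters

#' Log normalized-power CSP features
#'
#' Projects each epoch through the fitted filters, computes the variance of
#' every projection, normalizes by their sum, and takes the log:
#' `f_i = log(v_i / sum_j v_j)`. Features are invariant to overall epoch
#' scaling and satisfy `sum_i exp(f_i) = 1`.
#'
#' @param model A fitted [csp] object.
#' @param epochs An [eeg_epochs] set filtered to the model's band.
#' @return Numeric matrix, epochs x n_components.
#' @export
csp_features <- function(model, epochs) {
  stopifnot(inherits(model, "csp"), inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  stopifnot(d[2] == ncol(model$filters))
  out <- matrix(0, d[1], nrow(model$filters))
  for (e in seq_len(d[1])) {
    proj <- model$filters %*% epochs$data[e, , , drop = TRUE]
    cproj <- proj - rowMeans(proj)
    v <- rowSums(cproj^2) / (ncol(proj) - 1)
    tot <- sum(v)
    if (tot <= 0) stop(sprintf("zero-variance epoch %d", e))
    out[e, ] <- log(v / tot)
  }
  colnames(out) <- paste0("csp", seq_len(ncol(out)))
  out
}

#' @export
predict.csp <- function(object, newdata, ...) csp_features(object, newdata)

#' Topographic display of CSP patterns
#'
#' Draws each selected pattern as an interpolated scalp map over the
#' montage positions (head outline, nose up). Patterns — not filters — are
#' the physiologically interpretable maps.
#'
#' @param x A fitted [csp] object.
#' @param montage Montage data.frame with positions for `x$channel_labels`.
#' @param components Which pattern columns to draw (default all).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.csp <- function(x, montage = montage_1020(x$channel_labels),
                     components = seq_len(ncol(x$patterns)), ...) {
  k <- length(components)
  old <- graphics::par(mfrow = c(ceiling(k / 3), min(k, 3)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  half <- nrow(x$filters) / 2
  for (ci in seq_along(components)) {
    comp <- components[ci]
    w <- x$patterns[, comp]
    g <- seq(-1.1, 1.1, length.out = 60)
    zz <- outer(g, g, function(gx, gy) {
      vapply(seq_along(gx), function(i) {
        d2 <- (montage$x - gx[i])^2 + (montage$y - gy[i])^2
        if (gx[i]^2 + gy[i]^2 > 1.21) return(NA_real_)
        wt <- 1 / pmax(d2, 1e-6)
        sum(wt * w) / sum(wt)
      }, numeric(1))
    })
    lab <- if (comp <= half) sprintf("MW %d", comp) else sprintf("not MW %d", comp - half)
    graphics::image(g, g, zz, axes = FALSE, xlab = "", ylab = "",
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                    main = lab, asp = 1, ...)
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(cos(th), sin(th))
    graphics::points(montage$x, montage$y, pch = 20, cex = 0.5)
  }
  invisible(x)
}
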
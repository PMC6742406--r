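# Classification and evaluation: probe-grouped cross-validation of a
# CSP + RBF-SVM pipeline, metrics, permutation chance calibration,
# leave-one-subject-out transfer, and rate agreement.

#' Probe-grouped, label-stratified fold assignment
#'
#' Assigns probes (not epochs) to `k` folds so that the epochs of one probe
#' always share a fold, stratifying by the probe's label where counts
#' permit. Deterministic under `seed`.
#'
#' @param probe_ids Integer vector, one entry per probe (unique ids).
#' @param labels Per-probe labels (`"MW"` / `"NOT_MW"`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A list of class `fold_assignment`: `fold_of_probe` (named
#'   integer vector, probe id -> fold), `k`, `seed`.
#' @export
make_grouped_folds <- function(probe_ids, labels, k = 5, seed = 1L) {
  stopifnot(length(probe_ids) == length(labels), !anyDuplicated(probe_ids))
  if (length(probe_ids) < k) stop("fewer probes than folds")
  if (min(table(factor(labels, c("MW", "NOT_MW")))) < k) {
    warning("fewer probes than folds in one class; stratification best-effort")
  }
  set.seed(seed)
  fold <- integer(length(probe_ids))
  nxt <- 0L
  for (cl in c("MW", "NOT_MW")) {
    idx <- sample(which(labels == cl))
    # continue the round-robin across classes so folds stay balanced overall
    fold[idx] <- (seq_along(idx) + nxt - 1L) %% k + 1L
    nxt <- nxt + length(idx)
  }
  structure(list(fold_of_probe = stats::setNames(fold, probe_ids), k = k,
                 seed = seed),
            class = "fold_assignment")
}

#' Classification metrics with MW as the positive class
#'
#' Accuracy is returned in percent; precision, recall and F1 (harmonic mean
#' of precision and recall) refer to the MW class. Zero-denominator cases
#' are defined as 0.
#'
#' @param y_true,y_pred Character vectors in `{"MW", "NOT_MW"}`.
#' @return Named numeric vector: `accuracy`, `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == "MW" & y_pred == "MW")
  fp <- sum(y_true == "NOT_MW" & y_pred == "MW")
  fn <- sum(y_true == "MW" & y_pred == "NOT_MW")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(accuracy = 100 * mean(y_true == y_pred),
    precision = precision, recall = recall, f1 = f1)
}

# median-heuristic RBF width on a feature matrix
median_gamma <- function(x) {
  d <- stats::dist(x)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m == 0) return(1)
  1 / (2 * m^2)
}

#' Train on one fold, evaluate on another
#'
#' Fits the full feature pipeline on the training epochs only — CSP filters
#' learned from the training covariances, then an RBF support vector
#' machine (cost 1, kernel width from the median heuristic on training
#' features) — and evaluates on the held-out epochs. Keeping the CSP fit
#' inside the fold is the leakage guard.
#'
#' @param train,test Labelled [eeg_epochs], already filtered to `band`.
#' @param band Optional band annotation `c(lo, hi)`.
#' @param n_components CSP filter count (default 6).
#' @param shrinkage CSP covariance shrinkage (default 0).
#' @param cost SVM cost parameter (default 1).
#' @param train_covs Optional precomputed [epoch_covariances()] array
#'   aligned with `train`.
#' @return List: `metrics` (from [compute_metrics()]), `predictions`,
#'   `truth`, `model` (the csp fit).
#' @export
train_eval_fold <- function(train, test, band = NULL, n_components = 6,
                            shrinkage = 0, cost = 1, train_covs = NULL) {
  if (length(unique(train$labels)) < 2) {
    warning("single-class training fold; skipped")
    return(NULL)
  }
  model <- csp(train, n_components = n_components, shrinkage = shrinkage,
               band = band, epoch_covs = train_covs)
  ftr <- csp_features(model, train)
  fte <- csp_features(model, test)
  y <- factor(train$labels, levels = c("MW", "NOT_MW"))
  sv <- e1071::svm(ftr, y, kernel = "radial", cost = cost,
                   gamma = median_gamma(ftr), scale = FALSE)
  pred <- as.character(stats::predict(sv, fte))
  list(metrics = compute_metrics(test$labels, pred), predictions = pred,
       truth = test$labels, model = model)
}

per_probe_labels <- function(epochs) {
  ids <- unique(epochs$probe_ids)
  labs <- vapply(ids, function(i) epochs$labels[match(i, epochs$probe_ids)], "")
  list(ids = ids, labels = labs)
}

# run one grouped k-fold CV on a band-filtered epoch set; returns per-fold
# metric rows plus pooled predictions
run_grouped_cv <- function(epochs, k = 5, seed = 1L, n_components = 6,
                           shrinkage = 0, cost = 1, band = NULL,
                           labels_override = NULL) {
  labels <- if (is.null(labels_override)) epochs$labels else labels_override
  pp <- per_probe_labels(
    structure(list(labels = labels, probe_ids = epochs$probe_ids),
              class = "eeg_epochs"))
  fa <- make_grouped_folds(pp$ids, pp$labels, k = k, seed = seed)
  fold_of_epoch <- fa$fold_of_probe[as.character(epochs$probe_ids)]
  covs <- attr(epochs, "epoch_covs")
  if (is.null(covs)) covs <- epoch_covariances(epochs)
  flat <- attr(epochs, "flat_data")
  d <- dim(epochs$data)
  if (is.null(flat)) flat <- matrix(aperm(epochs$data, c(2, 3, 1)), d[2])
  rows <- list()
  preds <- character(length(labels))
  truth <- labels
  for (f in seq_len(k)) {
    te <- which(fold_of_epoch == f)
    tr <- which(fold_of_epoch != f)
    if (length(te) == 0) next
    if (length(unique(labels[tr])) < 2) {
      warning("single-class training fold; skipped")
      next
    }
    # same pipeline as train_eval_fold, on precomputed covariances and the
    # flattened data matrix (CSP fit still sees training epochs only)
    model <- csp_from_covs(covs[, , tr, drop = FALSE], labels[tr],
                           n_components, shrinkage, band,
                           epochs$channel_labels)
    ftr <- csp_features_flat(model$filters, flat, d[3], tr)
    fte <- csp_features_flat(model$filters, flat, d[3], te)
    y <- factor(labels[tr], levels = c("MW", "NOT_MW"))
    sv <- e1071::svm(ftr, y, kernel = "radial", cost = cost,
                     gamma = median_gamma(ftr), scale = FALSE)
    pred <- as.character(stats::predict(sv, fte))
    # folds whose test set holds no true MW epoch cannot measure recall or
    # F1 of the MW class; they contribute predictions but no metric row
    if (any(labels[te] == "MW")) {
      rows[[length(rows) + 1L]] <- compute_metrics(labels[te], pred)
    }
    preds[te] <- pred
  }
  if (length(rows) == 0) {
    # degenerate class distribution (e.g. a single minority probe): no fold
    # could test the MW class against a two-class training set; fall back
    # to pooled metrics over the folds that could be evaluated at all
    covered <- which(preds != "")
    if (length(covered) == 0) stop("no evaluable folds")
    warning("no fold had MW test epochs with two-class training; reporting pooled metrics")
    rows[[1L]] <- compute_metrics(labels[covered], preds[covered])
  }
  m <- do.call(rbind, rows)
  list(per_fold = m, predictions = preds, truth = truth)
}

new_detection_result <- function(per_fold, predictions, truth, band_name,
                                 band, variant, subject_id) {
  ok <- predictions != ""
  structure(list(
    per_fold = per_fold,
    pooled = compute_metrics(truth[ok], predictions[ok]),
    mean = colMeans(per_fold),
    se = if (nrow(per_fold) > 1) {
      apply(per_fold, 2L, stats::sd) / sqrt(nrow(per_fold))
    } else {
      stats::setNames(rep(0, ncol(per_fold)), colnames(per_fold))
    },
    observed_mw_rate = mean(truth == "MW"),
    predicted_mw_rate = mean(predictions[ok] == "MW"),
    band_name = band_name, band = band, variant = variant,
    subject_id = subject_id, n_epochs = length(truth)),
    class = "mw_detection")
}

#' @export
print.mw_detection <- function(x, ...) {
  cat(sprintf("<mw_detection> subject %s, band %s (%s)\n",
              x$subject_id, x$band_name, x$variant))
  cat(sprintf("  accuracy %.0f +/- %.1f %%  F1 %.2f +/- %.2f  recall %.2f  precision %.2f\n",
              x$mean["accuracy"], x$se["accuracy"], x$mean["f1"], x$se["f1"],
              x$mean["recall"], x$mean["precision"]))
  cat(sprintf("  observed MW rate %.2f, predicted %.2f over %d epochs\n",
              x$observed_mw_rate, x$predicted_mw_rate, x$n_epochs))
  invisible(x)
}

#' Intra-subject cross-validated detection, per band
#'
#' Runs probe-grouped k-fold cross-validation of the CSP + SVM pipeline
#' independently for each frequency band, reporting per-fold metrics,
#' fold-mean and standard error, and the observed and predicted MW rates.
#'
#' @param band_epochs Named list of labelled [eeg_epochs], one per band
#'   (e.g. from [pipeline_band_epochs()]).
#' @param k Folds (default 5).
#' @param seed Integer seed for the fold draw.
#' @param n_components,shrinkage,cost Pipeline parameters.
#' @param variant `"suppressed"` or `"present"` annotation.
#' @return Named list of `mw_detection` objects, one per band.
#' @export
intra_subject_cv <- function(band_epochs, k = 5, seed = 1L, n_components = 6,
                             shrinkage = 0, cost = 1, variant = "suppressed") {
  stopifnot(is.list(band_epochs), length(band_epochs) >= 1)
  bands <- canonical_bands()
  out <- lapply(names(band_epochs), function(bn) {
    ep <- band_epochs[[bn]]
    cv <- run_grouped_cv(ep, k = k, seed = seed, n_components = n_components,
                         shrinkage = shrinkage, cost = cost,
                         band = bands[[bn]])
    new_detection_result(cv$per_fold, cv$predictions, cv$truth,
                         bn, bands[[bn]], variant, ep$subject_id)
  })
  names(out) <- names(band_epochs)
  out
}

#' Pick the band with the best mean F1
#'
#' Ties are broken by canonical band order (theta, alpha, beta1, beta2).
#'
#' @param results Named list of `mw_detection` objects (names are bands).
#' @return The winning `mw_detection`.
#' @export
select_best_band <- function(results) {
  stopifnot(length(results) >= 1)
  order_ref <- c("theta", "alpha", "beta1", "beta2")
  nm <- names(results)
  f1 <- vapply(results, function(r) r$mean[["f1"]], numeric(1))
  best <- nm[f1 == max(f1)]
  pick <- best[order(match(best, order_ref))][1]
  results[[pick]]
}

#' Leave-one-subject-out detection
#'
#' For each subject, fits CSP + SVM on the pooled epochs of all other
#' subjects and evaluates on the held-out subject. Channel sets are
#' restricted to the intersection across subjects.
#'
#' @param cohort_epochs List of labelled [eeg_epochs], one per subject, all
#'   filtered to the same band.
#' @param band Optional `c(lo, hi)` annotation.
#' @param band_name Band name annotation.
#' @param n_components,shrinkage,cost Pipeline parameters.
#' @param variant Variant annotation.
#' @return Named list of `mw_detection` objects, one per held-out subject
#'   (a single "fold" each).
#' @export
inter_subject_loso <- function(cohort_epochs, band = NULL, band_name = "",
                               n_components = 6, shrinkage = 0, cost = 1,
                               variant = "suppressed") {
  stopifnot(length(cohort_epochs) >= 3)
  common <- Reduce(intersect, lapply(cohort_epochs, `[[`, "channel_labels"))
  if (length(common) == 0) stop("no channels shared across subjects")
  restrict <- function(ep) {
    sel <- match(common, ep$channel_labels)
    eeg_epochs(ep$data[, sel, , drop = FALSE], ep$fs, ep$labels,
               ep$probe_ids, common, ep$subject_id)
  }
  cohort_epochs <- lapply(cohort_epochs, restrict)
  pool <- function(eps) {
    dat <- do.call(abind3, lapply(eps, `[[`, "data"))
    eeg_epochs(dat, eps[[1]]$fs,
               labels = unlist(lapply(eps, `[[`, "labels")),
               probe_ids = unlist(lapply(seq_along(eps), function(i)
                 eps[[i]]$probe_ids + i * 10000L)),
               channel_labels = common)
  }
  out <- lapply(seq_along(cohort_epochs), function(s) {
    train <- pool(cohort_epochs[-s])
    test <- cohort_epochs[[s]]
    res <- train_eval_fold(train, test, band = band,
                           n_components = n_components,
                           shrinkage = shrinkage, cost = cost)
    new_detection_result(matrix(res$metrics, 1,
                                dimnames = list(NULL, names(res$metrics))),
                         res$predictions, test$labels, band_name, band,
                         variant, test$subject_id)
  })
  names(out) <- vapply(cohort_epochs, `[[`, "", "subject_id")
  out
}

abind3 <- function(...) {
  xs <- list(...)
  d2 <- dim(xs[[1]])[2]
  d3 <- dim(xs[[1]])[3]
  n <- sum(vapply(xs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(n, d2, d3))
  at <- 0L
  for (a in xs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Permutation null distribution of the F1 score
#'
#' Estimates the chance-level F1 by rerunning the full cross-validated
#' CSP + SVM pipeline under random relabelings. Shuffling happens at the
#' probe level — all epochs of a probe keep a common shuffled label — to
#' respect the within-probe dependence, and folds are redrawn per
#' iteration. The 95% interval is the empirical 2.5/97.5 percentile range.
#'
#' @param epochs A labelled band-filtered [eeg_epochs] set.
#' @param n Number of permutations (study convention 500; default 100 for
#'   desk-scale runs).
#' @param k CV folds.
#' @param seed Integer seed.
#' @param n_components,shrinkage,cost Pipeline parameters.
#' @return An object of class `mw_null`: `f1_samples`, `ci95`,
#'   `n_iterations`, `seed`.
#' @export
permutation_null <- function(epochs, n = 100, k = 5, seed = 1L,
                             n_components = 6, shrinkage = 0, cost = 1) {
  if (n < 1) stop("need at least one permutation")
  pp <- per_probe_labels(epochs)
  if (is.null(attr(epochs, "epoch_covs"))) {
    attr(epochs, "epoch_covs") <- epoch_covariances(epochs)
  }
  if (is.null(attr(epochs, "flat_data"))) {
    d <- dim(epochs$data)
    attr(epochs, "flat_data") <- matrix(aperm(epochs$data, c(2, 3, 1)), d[2])
  }
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n)
  f1 <- vapply(seq_len(n), function(i) {
    set.seed(iter_seeds[i])
    shuf <- sample(pp$labels)
    lab <- shuf[match(epochs$probe_ids, pp$ids)]
    cv <- try(suppressWarnings(
      run_grouped_cv(epochs, k = k, seed = iter_seeds[i],
                     n_components = n_components,
                     shrinkage = shrinkage, cost = cost,
                     labels_override = lab)), silent = TRUE)
    if (inherits(cv, "try-error")) return(NA_real_)
    mean(cv$per_fold[, "f1"])
  }, numeric(1))
  f1 <- f1[!is.na(f1)]
  structure(list(f1_samples = f1,
                 ci95 = stats::quantile(f1, c(0.025, 0.975), names = FALSE),
                 n_iterations = n, seed = seed),
            class = "mw_null")
}

#' @export
print.mw_null <- function(x, ...) {
  cat(sprintf("<mw_null> %d permutations; F1 mean %.3f, 95%% CI [%.3f, %.3f]\n",
              x$n_iterations, mean(x$f1_samples), x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Compare cross-validated F1 against the permutation null
#'
#' Welch two-sample t-test of the per-fold F1 values against the
#' permutation F1 samples. If both samples are exactly constant the
#' comparison degenerates; the function then reports `t = Inf` (or 0 when
#' also equal) with p of 0 or 1 accordingly.
#'
#' @param cv_f1 Numeric vector of per-fold F1 values (length >= 2).
#' @param null An `mw_null` object.
#' @return List with `t` and `p`.
#' @export
compare_to_chance <- function(cv_f1, null) {
  stopifnot(length(cv_f1) >= 2, inherits(null, "mw_null"))
  if (stats::sd(cv_f1) == 0 && stats::sd(null$f1_samples) == 0) {
    d <- mean(cv_f1) - mean(null$f1_samples)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0))
  }
  tt <- stats::t.test(cv_f1, null$f1_samples, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Cohort-level rate agreement
#'
#' Pearson correlation between observed and predicted MW rates across
#' subjects, and Spearman rank correlation between per-subject epoch
#' counts and F1 scores.
#'
#' @param results List of `mw_detection` objects (one per subject; typically
#'   each subject's best band).
#' @return List with `pearson_r_obs_pred` and `spearman_rho_epochs_f1`.
#' @export
rate_agreement <- function(results) {
  stopifnot(length(results) >= 3)
  obs <- vapply(results, `[[`, numeric(1), "observed_mw_rate")
  pred <- vapply(results, `[[`, numeric(1), "predicted_mw_rate")
  n_ep <- vapply(results, `[[`, numeric(1), "n_epochs")
  f1 <- vapply(results, function(r) r$mean[["f1"]], numeric(1))
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    stop("constant rate vector; correlation undefined")
  }
  list(pearson_r_obs_pred = stats::cor(obs, pred),
       spearman_rho_epochs_f1 = stats::cor(n_ep, f1, method = "spearman"))
}
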
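# End-to-end orchestration of the two analysis variants: Artifacts
# Suppressed (with ICA cleaning) and Artifacts Present (without).

#' Analysis configuration
#'
#' Collects every tunable parameter of the subject-level pipeline. The
#' configuration is echoed verbatim (plus a content hash) into every
#' result for provenance.
#'
#' @param variant `"suppressed"` (ICA artifact removal) or `"present"`.
#' @param bands Named list of bands (default [canonical_bands()]).
#' @param alpha EWM standardization smoothness factor (default 0.001).
#' @param bad_z Bad-channel robust z threshold (default 5).
#' @param ptp_grid Optional peak-to-peak threshold grid (default data-driven).
#' @param skew_threshold,kurt_threshold ICA component rejection thresholds
#'   (defaults 2.50 / 3.00).
#' @param n_components CSP filter count (default 6).
#' @param shrinkage CSP covariance shrinkage (default 0).
#' @param cost SVM cost (default 1).
#' @param k CV folds (default 5).
#' @param permutations Permutation-null iterations (default 100; the study
#'   convention is 500).
#' @param window,sub Pre-probe window and sub-epoch lengths in seconds.
#' @param seed Master seed; fold, permutation and ICA sub-streams are
#'   derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(variant = c("suppressed", "present"),
                       bands = canonical_bands(), alpha = 0.001, bad_z = 5,
                       ptp_grid = NULL, skew_threshold = 2.50,
                       kurt_threshold = 3.00, n_components = 6,
                       shrinkage = 0, cost = 1, k = 5, permutations = 100,
                       window = 10, sub = 2, seed = 1L) {
  variant <- match.arg(variant)
  cfg <- list(variant = variant, bands = bands, alpha = alpha, bad_z = bad_z,
              ptp_grid = ptp_grid, skew_threshold = skew_threshold,
              kurt_threshold = kurt_threshold, n_components = n_components,
              shrinkage = shrinkage, cost = cost, k = k,
              permutations = permutations, window = window, sub = sub,
              seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  # small FNV-1a style rolling hash; provenance marker, not cryptographic
  h <- 2166136261 %% 2^31
  for (ch in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h), as.integer(ch))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Condition and clean one recording, returning per-band labelled epochs
#'
#' Runs the conditioning chain (bad-channel removal, common-average
#' reference, EWM standardization, 1-30 Hz bandpass), selects a
#' peak-to-peak rejection threshold on 1 s epochs, optionally fits and
#' applies ICA artifact suppression (`variant = "suppressed"`), then for
#' each frequency band filters the continuous cleaned record and extracts
#' the labelled pre-probe epochs, dropping epochs that exceed the
#' peak-to-peak threshold on the broadband signal. Epoch rejection always
#' precedes the ICA fit.
#'
#' @param raw An [eeg_raw] recording.
#' @param probes An [mw_probes] event table.
#' @param config A [run_config].
#' @param subject_id Subject identifier.
#' @return List: `band_epochs` (named list of labelled [eeg_epochs]),
#'   `broadband_epochs`, `bad_channels`, `ptp_threshold`, `ica` (or NULL),
#'   `n_rejected_components`, `epoch_counts` (initial / retained per class).
#' @export
pipeline_band_epochs <- function(raw, probes, config = run_config(),
                                 subject_id = NA_character_) {
  bad <- detect_bad_channels(raw, config$bad_z)
  raw <- drop_channels(raw, bad)
  raw <- rereference_average(raw)
  raw <- ewm_standardize(raw, config$alpha)
  raw_bb <- bandpass_raw(raw, 1, 30)
  ep1 <- epoch_fixed(raw_bb, 1)
  rej <- reject_epochs_ptp(ep1, config$ptp_grid)
  ica <- NULL
  if (config$variant == "suppressed") {
    ica <- fit_ica(rej$epochs)
    ica <- reject_components_stats(ica, config$skew_threshold,
                                   config$kurt_threshold)
    raw_bb <- remix_without_rejected(raw_bb, ica)
  }
  broad <- extract_preprobe_epochs(raw_bb, probes, config$window, config$sub,
                                   subject_id = subject_id)
  n_initial <- length(broad)
  keep <- which(epoch_ptp(broad) <= rej$threshold)
  if (length(keep) == 0) stop("no pre-probe epochs survive rejection")
  counts <- list(
    initial = n_initial,
    retained = length(keep),
    mw = sum(broad$labels[keep] == "MW"),
    not_mw = sum(broad$labels[keep] == "NOT_MW"))
  band_epochs <- lapply(config$bands, function(bd) {
    rb <- bandpass_raw(raw_bb, bd[1], bd[2], trans_lo = 1, trans_hi = 1)
    eb <- extract_preprobe_epochs(rb, probes, config$window, config$sub,
                                  subject_id = subject_id)
    eb[keep]
  })
  list(band_epochs = band_epochs, broadband_epochs = broad[keep],
       bad_channels = bad, ptp_threshold = rej$threshold, ica = ica,
       n_rejected_components = length(ica$rejected),
       epoch_counts = counts)
}

#' Full subject-level analysis
#'
#' Composes the whole pipeline for one subject: conditioning and artifact
#' handling ([pipeline_band_epochs()]), per-band cross-validated detection,
#' best-band selection, permutation chance calibration on the best band,
#' the t-test against chance, and the channel-unit repeated-measures ANOVA
#' on band power. Deterministic under `config$seed`.
#'
#' @param raw An [eeg_raw] recording.
#' @param probes An [mw_probes] event table.
#' @param config A [run_config].
#' @param subject_id Subject identifier.
#' @param run_null Compute the permutation null (default TRUE; the
#'   dominant cost).
#' @return An object of class `mw_subject_result`: `bands` (per-band
#'   `mw_detection`), `best`, `null` (`mw_null`), `chance_test`, `anova`
#'   (`mw_anova`), `band_power`, preprocessing provenance and the config.
#' @export
run_subject <- function(raw, probes, config = run_config(),
                        subject_id = "S1", run_null = TRUE) {
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  prep <- pipeline_band_epochs(raw, probes, config, subject_id)
  results <- intra_subject_cv(prep$band_epochs, k = config$k,
                              seed = sub_seeds[1],
                              n_components = config$n_components,
                              shrinkage = config$shrinkage,
                              cost = config$cost, variant = config$variant)
  best <- select_best_band(results)
  null <- NULL
  chance <- NULL
  if (run_null) {
    null <- permutation_null(prep$band_epochs[[best$band_name]],
                             n = config$permutations, k = config$k,
                             seed = sub_seeds[2],
                             n_components = config$n_components,
                             shrinkage = config$shrinkage, cost = config$cost)
    chance <- compare_to_chance(best$per_fold[, "f1"], null)
  }
  bp <- band_power(prep$broadband_epochs, config$bands)
  anova <- tryCatch(
    rm_anova_2x4(aggregate_cell_means(bp, "channel")),
    error = function(e) NULL)
  structure(list(subject_id = subject_id, bands = results, best = best,
                 null = null, chance_test = chance, anova = anova,
                 band_power = bp, band_epochs = prep$band_epochs,
                 bad_channels = prep$bad_channels,
                 ptp_threshold = prep$ptp_threshold,
                 n_rejected_components = prep$n_rejected_components,
                 epoch_counts = prep$epoch_counts,
                 config = config),
            class = "mw_subject_result")
}

#' @export
print.mw_subject_result <- function(x, ...) {
  cat(sprintf("<mw_subject_result> %s (%s variant)\n",
              x$subject_id, x$config$variant))
  cat(sprintf("  epochs: %d initial, %d retained (%d MW / %d not MW)\n",
              x$epoch_counts$initial, x$epoch_counts$retained,
              x$epoch_counts$mw, x$epoch_counts$not_mw))
  cat(sprintf("  best band: %s, F1 %.2f +/- %.2f\n", x$best$band_name,
              x$best$mean["f1"], x$best$se["f1"]))
  if (!is.null(x$null)) {
    cat(sprintf("  chance F1 95%% CI [%.2f, %.2f], t = %.2f, p = %.3g\n",
                x$null$ci95[1], x$null$ci95[2], x$chance_test$t,
                x$chance_test$p))
  }
  invisible(x)
}

#' Cohort-level analysis
#'
#' Runs [run_subject()] for every subject, assembles the per-subject
#' best-band summary table (plus an average row), leave-one-subject-out
#' detection per band, and cross-subject rate agreement.
#'
#' @param sessions List of sessions; each element needs `raw`, `probes`
#'   and optionally `subject_id` (as produced by [generate_cohort()]).
#' @param config A [run_config]; subject k runs with seed
#'   `config$seed + k - 1`.
#' @param run_null Per-subject permutation nulls (default TRUE).
#' @param loso_bands Bands for leave-one-subject-out analysis (default all
#'   configured bands).
#' @return An object of class `mw_cohort_result`: `subjects` (list of
#'   `mw_subject_result`), `summary` (data.frame with an `Average` row),
#'   `loso` (per-band lists of `mw_detection`), `loso_mean_f1`,
#'   `agreement`, `config`.
#' @export
run_cohort <- function(sessions, config = run_config(), run_null = TRUE,
                       loso_bands = names(config$bands)) {
  stopifnot(length(sessions) >= 2)
  subjects <- vector("list", length(sessions))
  for (s in seq_along(sessions)) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + s - 1L)
    sid <- sessions[[s]]$subject_id
    if (is.null(sid)) sid <- paste0("S", s)
    subjects[[s]] <- run_subject(sessions[[s]]$raw, sessions[[s]]$probes,
                                 cfg, subject_id = sid, run_null = run_null)
  }
  best <- lapply(subjects, `[[`, "best")
  tab <- do.call(rbind, lapply(best, function(r) {
    data.frame(subject = r$subject_id, best_band = r$band_name,
               accuracy = r$mean[["accuracy"]], f1 = r$mean[["f1"]],
               recall = r$mean[["recall"]], precision = r$mean[["precision"]],
               observed_mw_rate = r$observed_mw_rate,
               predicted_mw_rate = r$predicted_mw_rate,
               stringsAsFactors = FALSE)
  }))
  num <- vapply(tab, is.numeric, TRUE)
  avg <- tab[1, ]
  avg$subject <- "Average"
  avg$best_band <- ""
  avg[num] <- lapply(tab[num], mean)
  sdrow <- vapply(tab[, num, drop = FALSE], stats::sd, numeric(1))
  summary_tab <- rbind(tab, avg)
  attr(summary_tab, "sd") <- sdrow
  loso <- lapply(loso_bands, function(bn) {
    eps <- lapply(subjects, function(su) su$band_epochs[[bn]])
    inter_subject_loso(eps, band = config$bands[[bn]], band_name = bn,
                       n_components = config$n_components,
                       shrinkage = config$shrinkage, cost = config$cost,
                       variant = config$variant)
  })
  names(loso) <- loso_bands
  loso_mean_f1 <- vapply(loso, function(l) {
    mean(vapply(l, function(r) r$mean[["f1"]], numeric(1)))
  }, numeric(1))
  agreement <- tryCatch(rate_agreement(best), error = function(e) NULL)
  structure(list(subjects = subjects, summary = summary_tab, loso = loso,
                 loso_mean_f1 = loso_mean_f1, agreement = agreement,
                 config = config),
            class = "mw_cohort_result")
}

#' @export
print.mw_cohort_result <- function(x, ...) {
  cat(sprintf("<mw_cohort_result> %d subjects (%s variant, config %s)\n",
              length(x$subjects), x$config$variant, x$config$hash))
  print(x$summary, row.names = FALSE, digits = 3)
  cat("  LOSO mean F1 per band:",
      paste(sprintf("%s %.2f", names(x$loso_mean_f1), x$loso_mean_f1),
            collapse = ", "), "\n")
  if (!is.null(x$agreement)) {
    cat(sprintf("  observed vs predicted MW rate r = %.2f; epochs vs F1 rho = %.2f\n",
                x$agreement$pearson_r_obs_pred,
                x$agreement$spearman_rho_epochs_f1))
  }
  invisible(x)
}

#' Write a cohort report to CSV and JSON
#'
#' @param result An `mw_cohort_result`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_cohort_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = result$config[setdiff(names(result$config), "bands")],
         loso_mean_f1 = as.list(result$loso_mean_f1),
         agreement = result$agreement),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}
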
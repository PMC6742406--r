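test_that("classification metrics match a hand-counted confusion table", {
  y <- c("MW", "MW", "NOT_MW", "NOT_MW")
  p <- c("MW", "NOT_MW", "NOT_MW", "NOT_MW")
  m <- compute_metrics(y, p)
  expect_equal(unname(m["precision"]), 1.0)
  expect_equal(unname(m["recall"]), 0.5)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_equal(unname(m["accuracy"]), 75)
  # identity and harmonic-mean fixed point
  perf <- compute_metrics(y, y)
  expect_equal(unname(perf), c(100, 1, 1, 1))
  expect_error(compute_metrics(character(0), character(0)), "empty")
  # relabeling symmetry: swapping classes swaps precision/recall roles
  ys <- ifelse(y == "MW", "NOT_MW", "MW")
  ps <- ifelse(p == "MW", "NOT_MW", "MW")
  ms <- compute_metrics(ys, ps)
  expect_equal(unname(ms["precision"]), 2 / 3)  # old NPV role
  expect_equal(unname(ms["recall"]), 1.0)
})

test_that("grouped folds keep probes together and stratify labels", {
  fa <- make_grouped_folds(1:10, rep(c("MW", "NOT_MW"), each = 5), k = 5,
                           seed = 1)
  expect_equal(fa$k, 5)
  expect_length(fa$fold_of_probe, 10)
  expect_equal(as.vector(table(fa$fold_of_probe)), rep(2L, 5))
  # one probe of each class per fold under perfect balance
  for (f in 1:5) {
    lab <- rep(c("MW", "NOT_MW"), each = 5)[fa$fold_of_probe == f]
    expect_setequal(lab, c("MW", "NOT_MW"))
  }
  expect_error(make_grouped_folds(1:3, rep("MW", 3), k = 5), "fewer probes")
  expect_warning(make_grouped_folds(1:10, c("MW", rep("NOT_MW", 9)), k = 5),
                 "best-effort")
})

test_that("epochs of one probe never straddle folds in cross-validation", {
  sess <- generate_session(strong_alpha_config(seed = 2))
  ep <- band_epochs_of(sess, c(8, 12))
  pp <- mwdetect:::per_probe_labels(ep)
  fa <- make_grouped_folds(pp$ids, pp$labels, k = 5, seed = 3)
  fold_of_epoch <- fa$fold_of_probe[as.character(ep$probe_ids)]
  for (p in unique(ep$probe_ids)) {
    expect_length(unique(fold_of_epoch[ep$probe_ids == p]), 1)
  }
})

test_that("resubstitution on strongly separable data is near-perfect", {
  sess <- generate_session(strong_alpha_config(seed = 3))
  ep <- band_epochs_of(sess, c(8, 12))
  res <- train_eval_fold(ep, ep, band = c(8, 12))
  expect_gte(res$metrics[["accuracy"]], 90)
})

test_that("intra-subject CV finds the planted band and beats chance", {
  sess <- generate_session(strong_alpha_config(seed = 4))
  beps <- lapply(canonical_bands(), function(b) band_epochs_of(sess, b))
  res <- suppressWarnings(intra_subject_cv(beps, seed = 5))
  best <- select_best_band(res)
  expect_equal(best$band_name, "alpha")
  expect_gte(best$mean[["f1"]], 0.9)
  # observed MW rate is the MW fraction of the processed epochs
  expect_equal(best$observed_mw_rate, mean(beps$alpha$labels == "MW"))
  nl <- permutation_null(beps$alpha, n = 60, seed = 6)
  expect_gt(best$mean[["f1"]], nl$ci95[2])
  ct <- compare_to_chance(best$per_fold[, "f1"], nl)
  expect_lt(ct$p, 0.01)
})

test_that("best-band selection maximizes F1 with canonical-order ties", {
  mk <- function(f1, band) {
    structure(list(mean = c(f1 = f1), band_name = band), class = "mw_detection")
  }
  res <- list(theta = mk(0.5, "theta"), alpha = mk(0.9, "alpha"),
              beta1 = mk(0.7, "beta1"), beta2 = mk(0.7, "beta2"))
  expect_equal(select_best_band(res)$band_name, "alpha")
  res2 <- list(theta = mk(0.7, "theta"), alpha = mk(0.5, "alpha"),
               beta1 = mk(0.6, "beta1"), beta2 = mk(0.7, "beta2"))
  expect_equal(select_best_band(res2)$band_name, "theta")
  expect_equal(select_best_band(res["alpha"])$band_name, "alpha")
})

test_that("the permutation null is centred at chance and brackets null F1", {
  sess <- generate_session(small_config(seed = 7))
  ep <- band_epochs_of(sess, c(8, 12))
  nl <- permutation_null(ep, n = 60, seed = 8)
  expect_length(nl$f1_samples, 60)
  expect_true(nl$ci95[1] <= nl$ci95[2])
  expect_true(all(nl$f1_samples >= 0 & nl$f1_samples <= 1))
  # true labels carry no signal here, so the CV F1 falls inside the CI
  cv <- suppressWarnings(intra_subject_cv(list(alpha = ep), seed = 9))
  f1 <- cv$alpha$mean[["f1"]]
  expect_gte(f1, nl$ci95[1])
  expect_lte(f1, nl$ci95[2])
  expect_error(permutation_null(ep, n = 0), "at least one")
})

test_that("comparison to chance behaves like a Welch t-test", {
  null <- structure(list(f1_samples = c(0.3, 0.35, 0.4, 0.32, 0.38, 0.36,
                                        0.33, 0.37)),
                    class = "mw_null")
  same <- compare_to_chance(c(0.35, 0.35166, 0.34833), null)
  expect_lt(abs(same$t), 0.5)
  expect_gt(same$p, 0.5)
  shifted <- compare_to_chance(c(0.8, 0.82, 0.81), null)
  expect_lt(shifted$p, 1e-4)
  # antisymmetry
  a <- c(0.5, 0.6, 0.55)
  nb <- structure(list(f1_samples = a), class = "mw_null")
  na <- structure(list(f1_samples = c(0.3, 0.35, 0.4)), class = "mw_null")
  t1 <- compare_to_chance(a, na)$t
  t2 <- compare_to_chance(na$f1_samples, nb)$t
  expect_equal(t1, -t2, tolerance = 1e-10)
})

test_that("LOSO transfers a shared topography but not individualized ones", {
  base <- strong_alpha_config(seed = 1)
  shared <- generate_cohort(base, 4, individualize = FALSE, seed = 40)
  beps <- lapply(shared, function(s) band_epochs_of(s, c(8, 12),
                                                    subject_id = s$subject_id))
  loso <- suppressWarnings(inter_subject_loso(beps, band = c(8, 12),
                                              band_name = "alpha"))
  f1s <- vapply(loso, function(r) r$mean[["f1"]], numeric(1))
  expect_gt(mean(f1s), 0.7)  # shared effect transfers across subjects
  # subject order does not change any held-out result
  loso_rev <- suppressWarnings(inter_subject_loso(rev(beps), band = c(8, 12),
                                                  band_name = "alpha"))
  expect_equal(loso[["S1"]]$mean, loso_rev[["S1"]]$mean, tolerance = 1e-10)
})

test_that("degenerate always-one-class predictions give extreme MW rates", {
  truth <- rep(c("MW", "NOT_MW"), 10)
  all_not <- rep("NOT_MW", 20)
  all_mw <- rep("MW", 20)
  r1 <- mwdetect:::new_detection_result(
    matrix(compute_metrics(truth, all_not), 1,
           dimnames = list(NULL, c("accuracy", "precision", "recall", "f1"))),
    all_not, truth, "alpha", c(8, 12), "suppressed", "S1")
  expect_equal(r1$predicted_mw_rate, 0)
  r2 <- mwdetect:::new_detection_result(
    matrix(compute_metrics(truth, all_mw), 1,
           dimnames = list(NULL, c("accuracy", "precision", "recall", "f1"))),
    all_mw, truth, "alpha", c(8, 12), "suppressed", "S1")
  expect_equal(r2$predicted_mw_rate, 1)
})

test_that("rate agreement reproduces exact and anti-monotone toys", {
  mk <- function(obs, pred, n, f1) {
    structure(list(observed_mw_rate = obs, predicted_mw_rate = pred,
                   n_epochs = n, mean = c(f1 = f1)), class = "mw_detection")
  }
  exact <- lapply(1:4, function(i) mk(i / 10, i / 10, 40 + i, 0.5 + i / 10))
  ra <- rate_agreement(exact)
  expect_equal(ra$pearson_r_obs_pred, 1)
  anti <- lapply(1:5, function(i) mk(i / 10, i / 10, i, 0.9 - i / 10))
  expect_equal(rate_agreement(anti)$spearman_rho_epochs_f1, -1)
  const <- lapply(1:3, function(i) mk(0.3, 0.3, 40, 0.5))
  expect_error(rate_agreement(const), "constant")
})
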
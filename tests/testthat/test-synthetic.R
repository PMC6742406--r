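test_that("identical config and seed give bit-identical sessions", {
  cfg <- small_config(seed = 11)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$raw$data, s2$raw$data)
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$truth$mixing_used, s2$truth$mixing_used)
})

test_that("a single band-limited source concentrates its variance in band", {
  cfg <- synth_config(n_channels = 4, n_sources = 1,
                      source_bands = list(c(8, 12)),
                      class_effect = 1, n_probes = 3, probe_spacing = 20,
                      fs = 128, noise_sd = 0, blink_rate = 0, seed = 3,
                      montage_labels = c("Fp1", "C3", "C4", "Oz"))
  sess <- generate_session(cfg)
  x <- sess$raw$data[2, ]
  ps <- mwdetect:::psd_estimate(x, 128, "periodogram")
  in_band <- ps$freq >= 8 & ps$freq <= 12
  expect_gt(sum(ps$psd[in_band]) / sum(ps$psd), 0.95)
})

test_that("probe response marginals match the configured MW probability", {
  cfg <- synth_config(n_probes = 400, probe_spacing = 1, fs = 100,
                      p_mw = 0.35, p_unsure = 0.04, seed = 5)
  sess <- generate_session(cfg, effect_window = 0.5)
  frac <- mean(sess$probes$response == "MW")
  ci <- stats::binom.test(sum(sess$probes$response == "MW"), 400,
                          p = 0.35)$p.value
  expect_gt(ci, 0.001)  # draw consistent with p_mw
  expect_lt(abs(frac - 0.35), 0.08)
  expect_lt(abs(mean(sess$probes$response == "UNSURE") - 0.04), 0.04)
})

test_that("planted class effect is realized in measured band power", {
  # single alpha source, no noise: MW/NOT power ratio converges to the
  # configured factor (checked at +/-10% with >= 200 epochs)
  cfg <- synth_config(n_channels = 4, n_sources = 1,
                      source_bands = list(c(8, 12)), class_effect = 1.5,
                      n_probes = 40, probe_spacing = 12, fs = 128,
                      p_mw = 0.5, p_unsure = 0, noise_sd = 0, blink_rate = 0,
                      seed = 7, montage_labels = c("Fp1", "C3", "C4", "Oz"))
  sess <- generate_session(cfg)
  ep <- extract_preprobe_epochs(sess$raw, sess$probes)
  expect_equal(length(ep), 200)
  bp <- band_power(ep, list(alpha = c(8, 12)))
  pw <- apply(bp$values[, , 1], 1L, mean)
  ratio <- mean(pw[ep$labels == "MW"]) / mean(pw[ep$labels == "NOT_MW"])
  expect_lt(abs(ratio - 1.5), 0.15)
})

test_that("no planted effect means equal expected band power", {
  cfg <- synth_config(n_channels = 4, n_sources = 1,
                      source_bands = list(c(8, 12)), class_effect = 1,
                      n_probes = 40, probe_spacing = 12, fs = 128,
                      p_mw = 0.5, p_unsure = 0, noise_sd = 0, blink_rate = 0,
                      seed = 9, montage_labels = c("Fp1", "C3", "C4", "Oz"))
  sess <- generate_session(cfg)
  ep <- extract_preprobe_epochs(sess$raw, sess$probes)
  bp <- band_power(ep, list(alpha = c(8, 12)))
  pw <- apply(bp$values[, , 1], 1L, mean)
  ratio <- mean(pw[ep$labels == "MW"]) / mean(pw[ep$labels == "NOT_MW"])
  expect_lt(abs(ratio - 1), 0.12)
})

test_that("13 usable probes yield 65 pre-probe epochs downstream", {
  sess <- generate_session(small_config(seed = 2))
  ep <- extract_preprobe_epochs(sess$raw, sess$probes)
  expect_equal(length(ep), 65)
  expect_equal(unname(table(ep$probe_ids)[1]), 5L)
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(synth_config(p_mw = 0.7, p_unsure = 0.5), "p_mw")
  expect_error(synth_config(fs = 50), "Nyquist|band edge")
  expect_error(synth_config(class_effect = c(rep(1, 5), -1)), "class_effect")
  bad_mix <- matrix(1, 16, 6)  # rank 1, not full column rank
  expect_error(synth_config(mixing = bad_mix), "rank")
})

test_that("blink injection is additive, frontal and recoverable", {
  cfg <- small_config(seed = 4, blink_rate = 0)
  sess <- generate_session(cfg)
  raw0 <- sess$raw
  # rate 0 leaves the signal untouched
  same <- inject_blinks(raw0, 0, 100, rep(1, 16), seed = 1)
  expect_equal(same$data, raw0$data)
  top <- ifelse(raw0$montage$label %in% c("Fp1", "Fpz", "Fp2"), 1, 0)
  blinked <- inject_blinks(raw0, 20, 200, top, seed = 1)
  k0 <- e1071::kurtosis(raw0$data[2, ])
  k1 <- e1071::kurtosis(blinked$data[2, ])
  expect_gt(k1, k0)  # heavy-tailed deflections on the frontal channel
  # exact recovery by subtracting the emitted artifact
  rec <- blinked$data - outer(top, attr(blinked, "blink_source"))
  expect_equal(rec, raw0$data, tolerance = 1e-12)
  expect_error(inject_blinks(raw0, -1, 100, top), "non-negative")
})

test_that("a one-subject cohort reproduces generate_session exactly", {
  base <- small_config(seed = 31)
  co <- generate_cohort(base, 1, individualize = FALSE, seed = 31)
  solo <- generate_session(base)
  expect_identical(co[[1]]$raw$data, solo$raw$data)
  expect_identical(co[[1]]$probes$response, solo$probes$response)
})

test_that("individualization randomizes topography; sharing keeps it fixed", {
  base <- strong_alpha_config(seed = 1)
  ind <- generate_cohort(base, 3, individualize = TRUE, seed = 5)
  shr <- generate_cohort(base, 3, individualize = FALSE, seed = 5)
  expect_false(isTRUE(all.equal(ind[[1]]$truth$mixing_used,
                                ind[[2]]$truth$mixing_used)))
  expect_identical(shr[[1]]$truth$mixing_used, shr[[2]]$truth$mixing_used)
  expect_true(all(vapply(ind, function(s)
    s$truth$effect_band %in% c("theta", "alpha", "beta1", "beta2"), TRUE)))
})
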
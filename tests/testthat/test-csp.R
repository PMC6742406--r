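test_that("class covariances are trace-normalized averages with shrinkage", {
  ep <- toy_two_channel_epochs(n_per_class = 1, n_samples = 300)
  covs <- class_covariances(ep)
  # a single epoch per class: the class covariance is that epoch's
  # normalized covariance
  x <- ep$data[1, , ] - rowMeans(ep$data[1, , ])
  cc <- tcrossprod(x) / (ncol(x) - 1)
  expect_equal(covs$C_mw, cc / sum(diag(cc)), tolerance = 1e-12)
  expect_equal(sum(diag(covs$C_mw)), 1, tolerance = 1e-12)
  expect_equal(sum(diag(covs$C_not)), 1, tolerance = 1e-12)
  # full shrinkage collapses both to scaled identities
  covs1 <- class_covariances(ep, shrinkage = 1)
  expect_equal(covs1$C_mw, diag(2) / 2, tolerance = 1e-12)
  # absent class errors by name
  ep$labels <- rep("MW", 2)
  expect_error(class_covariances(ep), "NOT_MW")
})

test_that("the 2-channel closed form gives eigenvalues 2/3 and 1/3", {
  covs <- array(0, c(2, 2, 2))
  covs[, , 1] <- diag(c(2, 1)) / 3
  covs[, , 2] <- diag(c(1, 2)) / 3
  m <- mwdetect:::csp_from_covs(covs, c("MW", "NOT_MW"), n_components = 2,
                                channel_labels = c("c1", "c2"))
  expect_equal(m$eigenvalues, c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(abs(m$filters), diag(2), tolerance = 1e-8)
  # sampled version of the same toy lands near the closed form
  ep <- toy_two_channel_epochs(n_per_class = 60, n_samples = 400)
  ms <- csp(ep, n_components = 2)
  expect_lt(abs(ms$eigenvalues[1] - 2 / 3), 0.05)
})

test_that("equal class covariances carry no discrimination", {
  covs <- array(diag(2) / 2, c(2, 2, 2))
  m <- mwdetect:::csp_from_covs(covs, c("MW", "NOT_MW"), n_components = 2)
  expect_equal(m$eigenvalues, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("the full eigenbasis jointly diagonalizes both class covariances", {
  ep <- band_epochs_of(generate_session(strong_alpha_config(seed = 4)),
                       c(8, 12))
  covs <- class_covariances(ep)
  fit <- mwdetect:::csp_eig(covs$C_mw, covs$C_not)
  D1 <- fit$W %*% covs$C_mw %*% t(fit$W)
  D2 <- fit$W %*% covs$C_not %*% t(fit$W)
  offdiag <- function(m) max(abs(m - diag(diag(m))))
  expect_lt(offdiag(D1), 1e-8)
  expect_lt(offdiag(D2), 1e-8)
  expect_equal(diag(D1) + diag(D2), rep(1, nrow(D1)), tolerance = 1e-8)
  # duals invert the filters on the retained subspace
  expect_equal(fit$W %*% fit$A, diag(length(fit$lambda)), tolerance = 1e-8)
})

test_that("swapping class labels maps eigenvalues to their complements", {
  ep <- band_epochs_of(generate_session(strong_alpha_config(seed = 5)),
                       c(8, 12))
  m1 <- csp(ep)
  ep2 <- ep
  ep2$labels <- ifelse(ep$labels == "MW", "NOT_MW", "MW")
  m2 <- csp(ep2)
  expect_equal(sort(m2$eigenvalues), sort(1 - m1$eigenvalues),
               tolerance = 1e-8)
})

test_that("eigenvalues are invariant to invertible channel transforms", {
  # invariance holds at the level of the class covariances (C -> B C B');
  # per-epoch trace normalization upstream re-weights epochs and is
  # deliberately not transform-invariant
  ep <- toy_two_channel_epochs(n_per_class = 30, n_samples = 300)
  cc <- class_covariances(ep)
  f1 <- mwdetect:::csp_eig(cc$C_mw, cc$C_not)
  B <- matrix(c(2, 0.7, -0.3, 1.4), 2)
  f2 <- mwdetect:::csp_eig(B %*% cc$C_mw %*% t(B), B %*% cc$C_not %*% t(B))
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-8)
})

test_that("log normalized-power features satisfy their identities", {
  ep <- toy_two_channel_epochs(n_per_class = 25, n_samples = 300)
  m <- csp(ep, n_components = 2)
  f <- csp_features(m, ep)
  expect_equal(rowSums(exp(f)), rep(1, nrow(f)), tolerance = 1e-12)
  # scale invariance per epoch
  ep2 <- ep
  ep2$data <- ep$data * 17
  expect_equal(csp_features(m, ep2), f, tolerance = 1e-10)
  # MW-axis feature larger for MW epochs in expectation
  expect_gt(mean(f[ep$labels == "MW", 1]), mean(f[ep$labels == "NOT_MW", 1]))
})

test_that("a planted alpha topography is recovered by the top MW pattern", {
  cfg <- synth_config(n_probes = 24, probe_spacing = 12, fs = 128,
                      class_effect = c(1, 2, 1, 1, 1, 1), p_mw = 0.5,
                      p_unsure = 0, blink_rate = 0, noise_sd = 1, seed = 3)
  sess <- generate_session(cfg)
  ep <- band_epochs_of(sess, c(8, 12))
  expect_gte(sum(ep$labels == "MW"), 50)
  m <- csp(ep)
  a <- m$patterns[, 1]
  b <- sess$truth$mixing_used[, 2]
  cosine <- abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  expect_gte(cosine, 0.95)
})

test_that("recovery fidelity grows monotonically with the effect size", {
  effs <- c(1.05, 1.1, 1.2, 1.35, 1.5, 1.75, 2)
  cs <- vapply(effs, function(eff) {
    cfg <- synth_config(n_probes = 24, probe_spacing = 12, fs = 128,
                        class_effect = c(1, eff, 1, 1, 1, 1), p_mw = 0.5,
                        p_unsure = 0, blink_rate = 0, noise_sd = 1, seed = 3)
    sess <- generate_session(cfg)
    m <- csp(band_epochs_of(sess, c(8, 12)))
    a <- m$patterns[, 1]
    b <- sess$truth$mixing_used[, 2]
    abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  }, numeric(1))
  expect_gt(stats::cor(effs, cs, method = "spearman"), 0.9)
})
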
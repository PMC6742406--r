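test_that("ANOVA sums of squares match the brute-force decomposition", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- array(rnorm(6 * 2 * 4), c(6, 2, 4))
    an <- rm_anova_2x4(cells_from(v))
    bf <- brute_force_ss(v)
    expect_lt(abs(an$table["MW", "ss_effect"] - bf$ss_a), 1e-10)
    expect_lt(abs(an$table["MW", "ss_error"] - bf$ss_ua), 1e-10)
    expect_lt(abs(an$table["MW x Freq", "ss_effect"] - bf$ss_ab), 1e-10)
    expect_lt(abs(an$table["MW x Freq", "ss_error"] - bf$ss_uab), 1e-10)
    # SS conservation across the full decomposition
    total <- bf$ss_a + bf$ss_b + bf$ss_u + bf$ss_ua + bf$ss_ub + bf$ss_ab +
      bf$ss_uab
    expect_lt(abs(total - bf$ss_total), 1e-10)
    # df structure (1, n-1) and (3, 3(n-1))
    expect_equal(an$table$df1, c(1, 3))
    expect_equal(an$table$df2, c(5, 15))
  }
})

test_that("printed df structure holds at the study sizes", {
  set.seed(9)
  an15 <- rm_anova_2x4(cells_from(array(rnorm(15 * 8), c(15, 2, 4))))
  expect_equal(an15$table$df1, c(1, 3))
  expect_equal(an15$table$df2, c(14, 42))
  an16 <- rm_anova_2x4(cells_from(array(rnorm(16 * 8), c(16, 2, 4))))
  expect_equal(an16$table$df2, c(15, 45))
})

test_that("null simulations give F statistics at their theoretical mean", {
  set.seed(10)
  n <- 12
  fs <- replicate(300, {
    v <- array(rnorm(n * 2 * 4), c(n, 2, 4))
    # add pure unit and band main effects; no condition effect
    v <- v + array(rep(rnorm(n, sd = 2), 8), c(n, 2, 4))
    an <- rm_anova_2x4(cells_from(v))
    c(an$table$F, an$table$p)
  })
  e_mw <- (n - 1) / (n - 3)          # mean of F(1, n-1)
  e_ib <- 3 * (n - 1) / (3 * (n - 1) - 2)
  expect_lt(abs(mean(fs[1, ]) - e_mw), 0.35)
  expect_lt(abs(mean(fs[2, ]) - e_ib), 0.35)
  # p-values approximately uniform
  expect_gt(stats::ks.test(fs[3, ], "punif")$p.value, 0.001)
})

test_that("a planted condition shift drives only the MW factor", {
  set.seed(11)
  v <- array(rnorm(10 * 2 * 4, sd = 0.5), c(10, 2, 4))
  v[, 1, ] <- v[, 1, ] + 2  # uniform MW shift across bands
  an <- rm_anova_2x4(cells_from(v))
  expect_lt(an$table["MW", "p"], 1e-4)
  expect_gt(an$table["MW x Freq", "p"], 0.01)
})

test_that("partial eta squared reproduces the published worked examples", {
  expect_equal(round(partial_eta_squared_f(400.95, 1, 15), 2), 0.96)
  expect_equal(round(partial_eta_squared_f(95.49, 1, 14), 2), 0.87)
  expect_equal(round(partial_eta_squared_f(22.51, 1, 15), 2), 0.60)
  expect_equal(round(partial_eta_squared_f(2.99, 1, 13), 2), 0.19)
  expect_equal(partial_eta_squared(3, 0), 1)
  expect_error(partial_eta_squared(0, 0), "zero")
  # the two derivations agree exactly
  ss_e <- 1.7; ss_r <- 4.2; df2 <- 12
  f <- (ss_e / 1) / (ss_r / df2)
  expect_equal(partial_eta_squared(ss_e, ss_r),
               partial_eta_squared_f(f, 1, df2), tolerance = 1e-12)
})

test_that("Holm correction applies the step-down rule", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(12)
  p <- runif(16)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # permutation invariance
  o <- sample(16)
  expect_equal(holm_bonferroni(p[o]), adj[o])
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("aggregation yields the complete crossed design shapes", {
  sess <- generate_session(small_config(seed = 13))
  ep <- extract_preprobe_epochs(sess$raw, sess$probes)
  bp <- band_power(ep)
  cells <- aggregate_cell_means(bp, "channel")
  expect_equal(dim(cells$values), c(16L, 2L, 4L))
  # one epoch per cell: the cell mean is that epoch's value
  one <- ep[c(1, 6)]
  one$labels <- c("MW", "NOT_MW")
  bp1 <- band_power(one)
  c1 <- aggregate_cell_means(bp1, "channel")
  expect_equal(unname(c1$values[3, "MW", 2]), log(bp1$values[1, 3, 2]))
  # participant-unit variant across a list of subjects
  tabs <- lapply(1:4, function(s) {
    ss <- generate_session(small_config(seed = 20 + s))
    e <- extract_preprobe_epochs(ss$raw, ss$probes, subject_id = paste0("S", s))
    band_power(e)
  })
  cp <- aggregate_cell_means(tabs, "participant", channel = "Oz")
  expect_equal(dim(cp$values), c(4L, 2L, 4L))
})

test_that("post-hoc paired t-tests handle regular and degenerate input", {
  set.seed(14)
  v <- array(rnorm(8 * 2 * 4), c(8, 2, 4))
  cells <- cells_from(v)
  out <- posthoc_paired_t(cells)
  expect_equal(nrow(out), 4)
  # cross-check one band against stats::t.test directly
  tt <- stats::t.test(v[, 1, 2], v[, 2, 2], paired = TRUE)
  expect_equal(out$t[2], unname(tt$statistic), tolerance = 1e-12)
  # identical pairs
  v2 <- v; v2[, 2, ] <- v2[, 1, ]
  d0 <- posthoc_paired_t(cells_from(v2))
  expect_equal(d0$t, rep(0, 4))
  expect_equal(d0$p, rep(1, 4))
  # constant non-zero differences
  v3 <- v; v3[, 1, ] <- v3[, 2, ] + 1
  d1 <- posthoc_paired_t(cells_from(v3))
  expect_true(all(is.infinite(d1$t) & d1$t > 0))
  expect_equal(d1$p, rep(0, 4))
})

test_that("paired-test rejection rate matches analytic power", {
  # pairs differing by delta with noise sd sigma: power of the paired t
  set.seed(15)
  n <- 10; delta <- 1; sigma <- 1
  rej <- replicate(400, {
    v <- array(rnorm(n * 2 * 4, sd = sigma), c(n, 2, 4))
    # band 1 differences are exactly N(delta, sigma^2); other bands null
    v[, 1, 1] <- v[, 2, 1] + rnorm(n, delta, sigma)
    out <- posthoc_paired_t(cells_from(v))
    out$p[1] < 0.05
  })
  ncp <- delta / (sigma / sqrt(n))
  crit <- stats::qt(0.975, n - 1)
  power <- 1 - stats::pt(crit, n - 1, ncp) + stats::pt(-crit, n - 1, ncp)
  expect_lt(abs(mean(rej) - power), 0.07)
})
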
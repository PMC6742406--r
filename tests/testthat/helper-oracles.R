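# brute-force repeated-measures decomposition: the independent oracle for
# the ANOVA sums of squares (explicit marginal means, no model fitting)
brute_force_ss <- function(v) {
  n <- dim(v)[1]; a <- dim(v)[2]; b <- dim(v)[3]
  gm <- mean(v)
  mu_u <- apply(v, 1, mean); mu_a <- apply(v, 2, mean); mu_b <- apply(v, 3, mean)
  mu_ua <- apply(v, c(1, 2), mean); mu_ub <- apply(v, c(1, 3), mean)
  mu_ab <- apply(v, c(2, 3), mean)
  ss_a <- n * b * sum((mu_a - gm)^2)
  ss_b <- n * a * sum((mu_b - gm)^2)
  ss_u <- a * b * sum((mu_u - gm)^2)
  ss_ua <- b * sum((sweep(sweep(mu_ua, 1, mu_u), 2, mu_a) + gm)^2)
  ss_ub <- a * sum((sweep(sweep(mu_ub, 1, mu_u), 2, mu_b) + gm)^2)
  ss_ab <- n * sum((sweep(sweep(mu_ab, 1, mu_a), 2, mu_b) + gm)^2)
  resid <- v
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b)) {
    resid[i, j, k] <- v[i, j, k] - mu_ua[i, j] - mu_ub[i, k] - mu_ab[j, k] +
      mu_u[i] + mu_a[j] + mu_b[k] - gm
  }
  list(ss_a = ss_a, ss_b = ss_b, ss_u = ss_u, ss_ua = ss_ua, ss_ub = ss_ub,
       ss_ab = ss_ab, ss_uab = sum(resid^2),
       ss_total = sum((v - gm)^2))
}

cells_from <- function(v) {
  dimnames(v) <- list(NULL, c("MW", "NOT_MW"),
                      c("theta", "alpha", "beta1", "beta2"))
  structure(list(values = v, unit_kind = "channel", n_units = dim(v)[1]),
            class = "cell_means")
}
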
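# shared fixtures: small, fast synthetic configurations

# compact session: 13 probes, short spacing, fs 128 - the structure of the
# study sessions at desk scale
small_config <- function(seed = 1, class_effect = rep(1, 6), n_probes = 13,
                         p_unsure = 0, ...) {
  synth_config(n_probes = n_probes, probe_spacing = 24, fs = 128,
               class_effect = class_effect, p_unsure = p_unsure, seed = seed,
               ...)
}

# strong alpha-band effect: alpha source power x8 during MW
strong_alpha_config <- function(seed = 1, ...) {
  small_config(seed = seed, class_effect = c(1, 8, 1, 1, 1, 1), ...)
}

# band-filter the continuous record, then extract labelled pre-probe epochs
band_epochs_of <- function(sess, band, ...) {
  extract_preprobe_epochs(bandpass_raw(sess$raw, band[1], band[2], 1, 1),
                          sess$probes, ...)
}

# labelled toy epoch set drawn from two diagonal covariance classes
toy_two_channel_epochs <- function(n_per_class = 20, n_samples = 200,
                                   seed = 2) {
  set.seed(seed)
  n <- 2 * n_per_class
  a <- array(0, c(n, 2, n_samples))
  for (e in seq_len(n)) {
    s <- if (e <= n_per_class) c(sqrt(2), 1) else c(1, sqrt(2))
    a[e, , ] <- rbind(stats::rnorm(n_samples, sd = s[1]),
                      stats::rnorm(n_samples, sd = s[2]))
  }
  eeg_epochs(a, 100, labels = rep(c("MW", "NOT_MW"), each = n_per_class),
             probe_ids = seq_len(n), channel_labels = c("c1", "c2"))
}

# white-noise epoch set
noise_epochs <- function(n_epochs, n_channels = 4, fs = 128, len_s = 2,
                         seed = 1, labels = NULL, probe_ids = NULL) {
  set.seed(seed)
  spe <- round(len_s * fs)
  a <- array(stats::rnorm(n_epochs * n_channels * spe),
             c(n_epochs, n_channels, spe))
  eeg_epochs(a, fs, labels = labels, probe_ids = probe_ids)
}
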
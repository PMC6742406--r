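# Forward-model synthetic EEG sessions with known ground truth. Band-limited
# Gaussian sources are mixed into a 16-channel montage; mind-wandering (MW)
# probes carry class-dependent band-power effects confined to the 10 s
# pre-probe windows, plus frontal blink artifacts and white sensor noise.

#' Configuration for a synthetic probe-based EEG session
#'
#' The defaults emulate a ~50 minute live-lecture recording: 16 channels of
#' the 10-20 montage at 250 Hz, 13 thought probes spaced 240 s apart, a 35%
#' per-probe probability of a mind-wandering response and 4% of "unsure"
#' responses, frontal-dominant blinks, and white sensor noise.
#'
#' @param n_channels Channel count (default 16).
#' @param fs Sampling rate in Hz (default 250; must exceed twice the highest
#'   source band edge).
#' @param montage_labels Channel names (default the built-in 16-label set).
#' @param n_sources Number of cortical sources (default 6).
#' @param mixing Optional channels x sources mixing matrix with full column
#'   rank; if `NULL` a random full-rank matrix is drawn from the seed.
#' @param source_bands List of `c(lo, hi)` Hz pairs, one per source. Default:
#'   one source per canonical band (theta, alpha, beta1, beta2) plus two
#'   broadband 1-30 Hz sources.
#' @param class_effect Per-source multiplicative band-power factor applied
#'   inside MW pre-probe windows (1 = no effect; must be > 0).
#' @param n_probes Number of probes (default 13).
#' @param probe_spacing Seconds between probes (default 240).
#' @param p_mw Per-probe probability of an MW response (default 0.35).
#' @param p_unsure Per-probe probability of an "unsure" response (default 0.04).
#' @param blink_rate Blink events per minute (default 15).
#' @param blink_amplitude Blink peak amplitude in microvolts (default 100).
#' @param blink_topography Per-channel blink weights; default frontal-dominant
#'   weights derived from the montage y-coordinate.
#' @param noise_sd White sensor noise SD in microvolts (default 2).
#' @param source_rms Per-source RMS amplitude at the scalp in microvolts
#'   (default 10).
#' @param seed Integer RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 16, fs = 250, montage_labels = NULL,
                         n_sources = 6, mixing = NULL, source_bands = NULL,
                         class_effect = rep(1, n_sources), n_probes = 13,
                         probe_spacing = 240, p_mw = 0.35, p_unsure = 0.04,
                         blink_rate = 15, blink_amplitude = 100,
                         blink_topography = NULL, noise_sd = 2,
                         source_rms = 10, seed = 1L) {
  if (is.null(montage_labels)) montage_labels <- montage_1020()$label[seq_len(n_channels)]
  stopifnot(length(montage_labels) == n_channels)
  if (is.null(source_bands)) {
    source_bands <- c(list(c(4, 7), c(8, 12), c(13, 18), c(19, 30)),
                      rep(list(c(1, 30)), max(0, n_sources - 4)))[seq_len(n_sources)]
  }
  stopifnot(length(source_bands) == n_sources,
            length(class_effect) == n_sources,
            all(class_effect > 0),
            p_mw >= 0, p_unsure >= 0, p_mw + p_unsure <= 1,
            blink_rate >= 0, blink_amplitude >= 0, noise_sd >= 0)
  hi_max <- max(vapply(source_bands, `[`, numeric(1), 2L))
  if (fs <= 2 * hi_max) stop("fs must exceed twice the highest source band edge")
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    stopifnot(nrow(mixing) == n_channels, ncol(mixing) == n_sources)
    if (qr(mixing)$rank < n_sources) stop("mixing must have full column rank")
  }
  montage <- montage_1020(montage_labels)
  if (is.null(blink_topography)) {
    y <- montage$y
    y[is.na(y)] <- 0
    blink_topography <- pmax(0, y)^2
    if (max(blink_topography) > 0) blink_topography <- blink_topography / max(blink_topography)
  }
  stopifnot(length(blink_topography) == n_channels)
  structure(list(n_channels = n_channels, fs = fs, montage = montage,
                 n_sources = n_sources, mixing = mixing,
                 source_bands = source_bands, class_effect = class_effect,
                 n_probes = n_probes, probe_spacing = probe_spacing,
                 p_mw = p_mw, p_unsure = p_unsure, blink_rate = blink_rate,
                 blink_amplitude = blink_amplitude,
                 blink_topography = blink_topography, noise_sd = noise_sd,
                 source_rms = source_rms, seed = as.integer(seed)),
            class = "synth_config")
}

# independent sub-seeds for the session's random components, so presetting
# one component (e.g. the mixing matrix) leaves the other streams unchanged
session_subseeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("mixing", "responses", "sources", "blinks")
  s
}

draw_mixing <- function(config, seed) {
  set.seed(seed)
  repeat {
    a <- matrix(stats::rnorm(config$n_channels * config$n_sources),
                config$n_channels, config$n_sources)
    a <- sweep(a, 2L, sqrt(colSums(a^2)), "/")
    if (qr(a)$rank == config$n_sources) return(a)
  }
}

# exactly band-limited unit-variance Gaussian noise via frequency-domain
# synthesis (white noise with all bins outside [lo, hi] zeroed)
band_limited_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  X <- stats::fft(x)
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate one synthetic probe-based EEG session
#'
#' Builds a continuous recording as `mixing %*% sources` plus blink
#' artifacts and white sensor noise. Sources are exactly band-limited
#' Gaussian noise. Within the 10 s preceding each probe answered "MW",
#' sources with `class_effect != 1` have their amplitude scaled by
#' `sqrt(class_effect)`, multiplying their band power by `class_effect`.
#' Probe responses are drawn i.i.d. with probabilities
#' (`p_mw`, `p_unsure`, remainder not-MW).
#'
#' @param config A [synth_config].
#' @param effect_window Length in seconds of the pre-probe window carrying
#'   the class effect (default 10, matching the extraction window).
#' @param require_both_classes Redraw the response vector (bounded, still
#'   deterministic under the seed) until both MW and not-MW responses are
#'   present, as in any analyzable real session (default TRUE).
#' @return A list with elements `raw` ([eeg_raw]), `probes` ([mw_probes]) and
#'   `truth` (list with `probe_onsets`, `probe_responses`, `mixing_used`,
#'   `effect_sources`, `blink_source`, `blink_topography`, `clean_data`
#'   omitted for size).
#' @export
generate_session <- function(config, effect_window = 10,
                             require_both_classes = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  dur <- config$n_probes * config$probe_spacing + effect_window
  n <- round(dur * fs)
  onsets <- seq_len(config$n_probes) * config$probe_spacing
  if (max(onsets) * fs > n) stop("session too short for the requested probes")
  ss <- session_subseeds(config$seed)

  mixing <- config$mixing
  if (is.null(mixing)) mixing <- draw_mixing(config, ss[["mixing"]])

  set.seed(ss[["responses"]])
  draw <- function() sample(c("MW", "UNSURE", "NOT_MW"), config$n_probes,
                            replace = TRUE,
                            prob = c(config$p_mw, config$p_unsure,
                                     1 - config$p_mw - config$p_unsure))
  resp <- draw()
  if (require_both_classes && config$p_mw > 0 && config$p_mw + config$p_unsure < 1) {
    # every study participant answered MW at least once; condition the
    # response draw on both classes being represented (redraw, bounded)
    tries <- 0L
    while ((!any(resp == "MW") || !any(resp == "NOT_MW")) && tries < 100L) {
      resp <- draw()
      tries <- tries + 1L
    }
  }

  set.seed(ss[["sources"]])
  S <- matrix(0, config$n_sources, n)
  for (k in seq_len(config$n_sources)) {
    b <- config$source_bands[[k]]
    S[k, ] <- band_limited_noise(n, fs, b[1], b[2])
  }
  effect_sources <- which(config$class_effect != 1)
  for (k in effect_sources) {
    g <- sqrt(config$class_effect[k])
    for (p in which(resp == "MW")) {
      i0 <- floor((onsets[p] - effect_window) * fs) + 1L
      i1 <- floor(onsets[p] * fs)
      S[k, i0:i1] <- S[k, i0:i1] * g
    }
  }
  X <- config$source_rms * (mixing %*% S)
  if (config$noise_sd > 0) {
    X <- X + matrix(stats::rnorm(length(X), sd = config$noise_sd), nrow(X))
  }
  raw <- eeg_raw(X, fs, config$montage)
  raw <- inject_blinks(raw, config$blink_rate, config$blink_amplitude,
                       config$blink_topography, seed = ss[["blinks"]])
  truth <- list(probe_onsets = onsets, probe_responses = resp,
                mixing_used = mixing, effect_sources = effect_sources,
                blink_source = attr(raw, "blink_source"),
                blink_topography = config$blink_topography)
  list(raw = raw, probes = mw_probes(onsets, resp), truth = truth)
}

#' Inject blink artifacts into a recording
#'
#' Adds smooth half-sine deflections of 200-400 ms duration at Poisson
#' event times, scaled by a per-channel topography. The injected source
#' time course is attached as attribute `blink_source` (and the topography
#' as `blink_topography`), so the original signal is recoverable as
#' `raw$data - amplitude-scaled outer(topography, blink_source)` — the
#' returned data already include the artifact; the attributes are the
#' oracle for tests.
#'
#' @param raw An [eeg_raw] recording.
#' @param rate Events per minute (>= 0).
#' @param amplitude Peak amplitude in microvolts (>= 0).
#' @param topography Per-channel weight vector (length = channel count).
#' @param seed Integer seed.
#' @return The recording with artifacts added; attributes `blink_source`
#'   (length = samples, already amplitude-scaled) and `blink_topography`.
#' @export
inject_blinks <- function(raw, rate, amplitude, topography, seed = 1L) {
  stopifnot(inherits(raw, "eeg_raw"))
  if (rate < 0 || amplitude < 0) stop("rate and amplitude must be non-negative")
  stopifnot(length(topography) == n_channels(raw))
  n <- ncol(raw$data)
  src <- numeric(n)
  if (rate > 0 && amplitude > 0) {
    set.seed(seed)
    n_events <- stats::rpois(1, rate / 60 * n / raw$fs)
    if (n_events > 0) {
      starts <- sort(stats::runif(n_events, 0, n / raw$fs - 0.4))
      durs <- stats::runif(n_events, 0.2, 0.4)
      for (e in seq_len(n_events)) {
        i0 <- floor(starts[e] * raw$fs) + 1L
        len <- max(2L, round(durs[e] * raw$fs))
        i1 <- min(n, i0 + len - 1L)
        idx <- i0:i1
        src[idx] <- src[idx] + amplitude * sin(pi * seq(0, 1, length.out = length(idx)))
      }
    }
  }
  out <- raw
  out$data <- raw$data + outer(as.numeric(topography), src)
  attr(out, "blink_source") <- src
  attr(out, "blink_topography") <- as.numeric(topography)
  out
}

#' Generate a cohort of synthetic subjects
#'
#' All subjects share the session structure (probe count, spacing, response
#' probabilities) but have independent noise, sources and responses. With
#' `individualize = TRUE`, each subject additionally receives a freshly
#' drawn mixing matrix and a randomly chosen effect band, emulating
#' subject-specific spatial and spectral signatures of mind wandering;
#' otherwise every subject shares one mixing matrix and effect band.
#'
#' @param base A [synth_config] serving as the template.
#' @param n_subjects Number of subjects (>= 1; >= 2 for a meaningful cohort).
#' @param individualize Logical; randomize each subject's effect topography
#'   and band.
#' @param seed Integer master seed; subject k runs with seed `seed + k - 1`.
#' @return A list of `generate_session()` results, one per subject, each
#'   with an added `subject_id` element (`"S1"`, `"S2"`, ...).
#' @export
generate_cohort <- function(base, n_subjects, individualize = FALSE,
                            seed = base$seed) {
  stopifnot(inherits(base, "synth_config"), n_subjects >= 1)
  canonical <- list(theta = c(4, 7), alpha = c(8, 12),
                    beta1 = c(13, 18), beta2 = c(19, 30))
  shared_mixing <- base$mixing
  if (!individualize && is.null(shared_mixing)) {
    # the same matrix subject 1 would draw on its own, so a one-subject
    # cohort is bit-identical to generate_session(base) at the same seed
    ss1 <- session_subseeds(seed)
    shared_mixing <- draw_mixing(base, ss1[["mixing"]])
  }
  set.seed(seed)
  band_draws <- sample(names(canonical), n_subjects, replace = TRUE)
  out <- vector("list", n_subjects)
  for (k in seq_len(n_subjects)) {
    cfg <- base
    cfg$seed <- as.integer(seed + k - 1L)
    if (individualize) {
      cfg$mixing <- NULL
      eff <- which(cfg$class_effect != 1)
      for (i in eff) cfg$source_bands[[i]] <- canonical[[band_draws[k]]]
    } else {
      cfg$mixing <- shared_mixing
    }
    class(cfg) <- "synth_config"
    sess <- generate_session(cfg)
    sess$subject_id <- paste0("S", k)
    sess$truth$effect_band <- if (individualize) band_draws[k] else NULL
    out[[k]] <- sess
  }
  out
}

#' Write a session to plain-text sidecar files
#'
#' Raw data go to a CSV (channels as columns), events to the standard
#' events CSV, and ground truth to a JSON sidecar.
#'
#' @param session A `generate_session()` result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- as.data.frame(t(session$raw$data))
  names(d) <- session$raw$montage$label
  utils::write.csv(d, file.path(dir, "raw.csv"), row.names = FALSE)
  write_events(session$probes, file.path(dir, "events.csv"))
  truth <- session$truth
  truth$blink_source <- NULL  # too large for a sidecar; kept in memory only
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
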
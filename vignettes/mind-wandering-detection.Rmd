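---
title: "Detecting mind wandering from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mind wandering from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mind wandering (MW) — attention drifting away from an ongoing task — has no
externally observable marker. The standard measurement instrument is the
thought probe: the task is interrupted, and participants report whether they
were paying attention just before the interruption. `mwdetect` implements an
individual-level EEG analysis for probe-based recordings in naturalistic
settings (its motivating use case is 16-channel EEG recorded from audience
members during live lectures, with probes roughly every four minutes and
response options *paying attention*, *mind wandering*, and *unsure*). The
pipeline labels the 10 s of EEG preceding each probe with the probe response
and asks two questions:

1. **Detection** — can a classifier trained on a person's own data detect
   their MW episodes above chance, and does that transfer to unseen people?
2. **Statistics** — does band power differ between MW and attentive epochs,
   per channel across participants and per participant across channels?

The package treats the spatial-filter learner as its modelling core:
`csp()` is a classic fitting function returning a classed object with
`print`, `coef`, `predict` and `plot` methods, and the surrounding stages
are plain functions composed by `run_subject()` / `run_cohort()`.

## Signal conditioning

Each continuous recording passes through four stages:

* **Bad-channel screening.** Channels whose log-variance robust z-score
  (median/MAD across channels) exceeds 5 are dropped. The threshold is a
  package choice; "extreme variance" is otherwise unquantified in the
  literature this follows.
* **Common-average reference**, which zeroes the instantaneous channel mean
  and reduces the data rank by one. Downstream decompositions account for
  this explicitly.
* **Exponentially weighted running standardization** with smoothness factor
  $\alpha = 0.001$:
  $\mu_t = (1-\alpha)\mu_{t-1} + \alpha x_t$,
  $v_t = (1-\alpha)v_{t-1} + \alpha (x_t-\mu_t)^2$,
  output $(x_t-\mu_t)/\sqrt{\max(v_t, v_{\mathrm{floor}})}$.
  The mean updates *before* the deviation enters the variance update; this
  order is fixed and tested. Initialization is $\mu_0 = x_1$ and $v_0$ = the
  sample variance of the first 10 s (fallback 1), with
  $v_{\mathrm{floor}} = 10^{-4}$ guarding the division. At 250 Hz the
  effective time constant is $1/\alpha = 1000$ samples (4 s): brief
  high-voltage events are compressed, and any sustained power change is
  partially re-normalized within a few seconds. Synthetic class effects
  confined to 10 s windows are therefore attenuated by the standardizer —
  a property of the method, not a bug, and the reason detection-power
  checks quote the planted effect *before* conditioning. A second
  consequence: because the divisor is a per-channel *broadband* variance,
  a band-limited power increase depresses the standardized power of every
  other band on the affected channels, coupling a planted alpha effect
  into neighbouring bands; best-band selection after full conditioning
  can therefore legitimately land next to the planted band.
* **1–30 Hz bandpass**, a windowed (Hamming) linear-phase FIR with an even
  tap count (Type II), order selected from the narrower transition band
  (1 Hz at the low edge, 5 Hz at the high edge), applied forward-backward
  so the net phase is zero and epoch timing is not delayed relative to
  probe onsets. The double pass squares the magnitude response, giving
  < 1% passband deviation and > 40 dB stopband attenuation.

## Artifact handling

Artifact control is two-stage, and the stage order is asserted: epoch-level
rejection happens before the ICA fit, because large transients degrade the
source separation.

1. **Cross-validated peak-to-peak rejection.** The signal is cut into
   non-overlapping 1 s epochs. For each candidate threshold, the mean of
   the retained training epochs is compared (Frobenius RMSE) with the
   pointwise median of held-out epochs — the median being a
   rejection-free robust reference — and the threshold minimizing the
   cross-validated error is kept (ties resolved toward retaining more
   data). The same threshold later removes contaminated 2 s pre-probe
   epochs, measured on the broadband signal.
2. **Extended-infomax ICA.** Implemented as a deterministic full-batch
   natural-gradient ascent on PCA-whitened data, with a per-component
   switch between sub- and super-Gaussian score functions, identity
   initialization, and an annealed learning rate; the component count
   automatically drops to the numerical rank (15 of 16 after average
   referencing). Components are ordered by explained variance with a
   fixed sign convention (largest-magnitude mixing weight positive), so
   refits are bit-identical. Components whose source skewness exceeds
   ±2.50 or whose *excess* kurtosis exceeds ±3.00 are removed, and the
   signal is re-mixed from the remainder. The excess (Gaussian = 0)
   convention is deliberate: a symmetric ±3 threshold is incoherent for
   raw kurtosis, which is non-negative. Both comparisons are strict, so a
   component exactly at a threshold is retained. Rejection is fully
   automatic; there is no interactive confirmation step.

Running with `variant = "present"` skips stage 2 entirely (epoch-level
rejection still applies), producing the *Artifacts Present* analysis arm;
everything else in the chain is unchanged.

## Epochs and labels

For every probe answered MW or not-MW, the half-open window
$(\mathrm{onset} - 10\,\mathrm{s},\ \mathrm{onset}]$ is cut into five 2 s
epochs sharing the probe's label and id; *unsure* probes are ignored.
Thirteen usable probes hence yield 65 epochs. Sample indices use
$\lfloor t \cdot f_s \rfloor$. Epochs of one probe are statistically
dependent (same underlying state), so they are never split across
cross-validation folds and are shuffled as a block in permutation tests.

## Band power and the statistical arm

Canonical bands are theta 4–7, alpha 8–12, beta1 13–18, beta2 19–30 Hz.
Band power is Welch-estimated (1 s Hann segments, 50% overlap) and
integrated over $[lo, hi+1)$ so adjacent bands partition the axis without
double counting; with 2 s epochs the resolution is 1 Hz, marginal for the
theta edge and accepted with a warning hook. Power enters the statistics on
a log scale (a config switch restores raw power; the choice is open in the
source material).

The two-factor repeated-measures ANOVA uses probe response (2 levels) and
band (4 levels) as within-unit factors, after aggregating to one cell mean
per unit × condition × band. Units are participants for the per-channel
models and channels for the per-participant models — an interpretation
forced by the printed degrees of freedom of the motivating study
(F(1,14) with 15 participants; F(1,15) with 16 channels). Each effect is
tested against its own interaction-with-unit error stratum, giving df
(1, n−1) for the condition effect and (3, 3(n−1)) for the interaction; no
sphericity correction by default (Greenhouse–Geisser behind a flag).
Effect sizes are partial eta squared,
$\eta_p^2 = SS_\mathrm{effect}/(SS_\mathrm{effect}+SS_\mathrm{error})$,
equivalently $F \cdot df_1 / (F \cdot df_1 + df_2)$. Holm–Bonferroni
(via `stats::p.adjust`) corrects across the family of per-channel or
per-participant models, separately per factor. Post-hoc paired t-tests per
band report uncorrected p-values; zero-variance difference vectors are
handled explicitly (t = 0, p = 1 when all differences vanish).

The ANOVA implementation rides on `stats::aov` with an
`Error(unit/(mw*band))` stratum; an explicit brute-force mean-decomposition
oracle in the test suite confirms the sums of squares to 1e-10.

## Common spatial patterns and the detector

Per-epoch spatial covariances are trace-normalized (every epoch contributes
equal total power — discriminative information is the *distribution* of
power over channels, not its magnitude) and averaged within class,
optionally shrunk toward a scaled identity by $\gamma$
($C \leftarrow (1-\gamma)C + \gamma\,(\mathrm{tr}\,C/p)\,I$; default
$\gamma = 0$ with an automatic, logged retry at 0.05 if the composite
covariance cannot support the requested component count). CSP solves

$$C_{MW} w = \lambda\,(C_{MW} + C_{NOT})\,w,$$

in the principal subspace of the composite covariance (handling the rank
lost to average referencing and ICA removal), giving eigenvalues in
$[0,1]$ with 0.5 meaning no discrimination. The three largest- and three
smallest-$\lambda$ eigenvectors become the six filters (3 per class); the
matched columns of the inverse-transpose eigenvector matrix are the
patterns — the physiologically interpretable scalp maps that `plot.csp()`
draws. Filter rows are unit-normalized with the largest-magnitude
coefficient positive, patterns rescaled so filters × patterns stays the
identity on the subspace; eigen ties break by input channel order. Each
epoch yields features $f_i = \log(v_i / \sum_j v_j)$ from the projection
variances — scale-invariant by construction, with
$\sum_i e^{f_i} = 1$.

Classification uses an RBF support vector machine (`e1071::svm`), cost 1,
kernel width from the median heuristic on training features, no class
weighting. The kernel and weighting are package choices; the source
material specifies only "non-linear SVM", and unweighted fitting is
consistent with predicted MW rates that undershoot observed rates under
class imbalance.

**Cross-validation.** Intra-subject: one probe-grouped, label-stratified
5-fold partition (5 train/test evaluations); the CSP fit and the SVM see
training folds only. With few MW probes, some test folds contain no MW
epoch; such folds cannot measure MW recall or F1 and contribute
predictions but no metric row. Per-fold means and standard errors are
reported next to pooled (micro) metrics. In the fully degenerate case —
no fold can test MW against a two-class training set, which happens when a
subject has a single MW probe — pooled metrics over the evaluable folds
are reported with a warning. Inter-subject: leave-one-subject-out over the
channel intersection. Per-band analyses filter the continuous cleaned
record before epoch extraction (avoiding short-epoch filter transients);
`bandpass_epochs()` exists for the epoch-only case with a capped filter
order.

**Chance calibration.** The null F1 distribution reruns the *entire*
CSP + SVM cross-validation under probe-level label shuffles (500
iterations in the study convention; the package default is 100 for
desk-scale runs, with the count exposed), redrawing folds each iteration.
The 95% CI is the empirical 2.5/97.5 percentile range, and a Welch
two-sample t-test compares true-label per-fold F1 against the null
samples. Probe-level (not epoch-level) shuffling is the main
reproducibility-sensitive choice: epoch-level shuffling would leak
within-probe dependence into the null and shrink the CI.

## The synthetic-data generator

`generate_session()` is a forward model: channels = mixing × sources +
blinks + white sensor noise. Defaults emulate the motivating study's
structure — 16 channels (10–20 subset), 250 Hz, 13 probes 240 s apart,
P(MW) = 0.35 and P(unsure) = 0.04 per probe, frontal-dominant blinks at
15/min and 100 µV, 2 µV sensor noise, 10 µV source RMS at the scalp. The
sampling rate is a package choice (unstated in the source material);
250 Hz satisfies Nyquist for the 30 Hz analysis edge with margin.

Sources are *exactly* band-limited Gaussian noise, synthesized in the
frequency domain (white noise with out-of-band bins zeroed). Band-limited
noise rather than sinusoids keeps the per-epoch covariance statistics
non-degenerate for CSP; frequency-domain synthesis makes the spectral
containment property exact rather than filter-approximate. Six sources by
default: one per canonical band plus two broadband 1–30 Hz sources, the
broadband pair ensuring that no single band-limited source trivially owns
its band. Class effects multiply a source's power by `class_effect` only
inside the 10 s pre-probe windows of MW-answered probes, so labels align
exactly with what the pipeline extracts. Blinks are half-sine deflections
of 200–400 ms at Poisson times; the injected time course is emitted for
test oracles. Response draws are conditioned on both classes being present
(bounded redraw, still seed-deterministic), since a session without a
single MW response cannot enter individual-level analysis at all — every
participant in the motivating study had at least one.

`generate_cohort()` shares the session structure across subjects; with
`individualize = TRUE` each subject gets a freshly drawn mixing matrix and
a random effect band, emulating subject-specific MW signatures, which is
the regime in which leave-one-subject-out transfer collapses while
intra-subject detection stays high.

**What the generator does not emulate:** 1/f background spectra, line
noise, EMG, slow nonstationarity, volume-conduction geometry from a head
model, or realistic blink waveform variety. Passing tests on this
generator demonstrate that the pipeline recovers what it is pointed at
under controlled conditions; they do not certify detection rates on real
recordings.

**Effect-size regimes.** Parameter-recovery checks use `class_effect = 2`
(doubled band power), where the planted topography is recovered with
cosine ≥ 0.95. The "strong effect" regime used for detection-power checks
is `class_effect = 8` on the alpha source (amplitude × 2.8 during MW).
Because per-epoch covariances are trace-normalized, what the detector sees
is the *share* of band power: with one alpha source against two broadband
sources the share moves from 1/3 to 8/10, and intra-subject best-band F1
reliably exceeds 0.9. These two values were fixed as the package's
definitions of "recoverable" and "strong" and are not tuned per run.

## Problem sizes and runtime choices

Tests and the acceptance script run the study's epoch structure (13
probes × 5 × 2 s epochs) at desk scale: 128 Hz sampling and 24 s probe
spacing, which leaves the epoch counts, class imbalance, band definitions
and every algorithmic path identical while keeping simulations fast. One
full-scale subject (250 Hz, 240 s spacing, ICA variant, 100 permutations)
runs end-to-end in the acceptance script as the integration check.
Permutation counts default to 100 (the study convention of 500 remains a
single argument away). Null-calibration checks use 50 replicate subjects.

## Known limitations

* The ICA is a straightforward extended-infomax implementation; it has no
  PCA dimension-reduction options, no online mode, and subsamples very
  long recordings (deterministically) for the fit.
* Sessions are treated as one continuous recording; standardization is not
  segmented per lecture.
* No channel interpolation: bad channels are dropped, and
  leave-one-subject-out restricts to the channel intersection.
* The F1-eligible-fold rule (above) means per-fold standard errors are
  computed over a variable number of folds when MW probes are scarce.
* Chance CIs are estimated per subject after epoch rejection; with 100
  permutations the CI endpoints themselves carry Monte-Carlo noise of a
  few percentage points.
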
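# mwdetect

Individual-level detection of mind wandering (MW) from multichannel EEG
recorded during probe-based naturalistic sessions — the motivating setting
is 16-channel EEG collected from audience members during live lectures,
interrupted roughly every four minutes by thought probes asking whether the
listener was paying attention, mind wandering, or unsure. The package is
aimed at cognitive-neurophysiology researchers who want a tested, fully
scripted version of this analysis, together with a ground-truth synthetic
generator that makes every stage verifiable without access to raw study
recordings.

## What it computes

The 10 s of EEG before each probe is cut into five 2 s epochs labelled by
the probe response ("unsure" probes are ignored). After conditioning
(bad-channel screening, common-average reference, exponential running
standardization with smoothness factor 0.001, zero-phase 1–30 Hz Type II
FIR bandpass) and two-stage artifact handling (cross-validated
peak-to-peak epoch rejection, then extended-infomax ICA with components
rejected at skewness ±2.50 / excess kurtosis ±3.00 — or skipped entirely
in the *Artifacts Present* variant), the package runs two analysis arms:

**Detection.** Per frequency band (theta 4–7, alpha 8–12, beta1 13–18,
beta2 19–30 Hz), six common spatial patterns are learned from the
generalized eigenproblem on trace-normalized class covariances

```
C_MW w = λ (C_MW + C_NOT) w,        λ ∈ [0, 1],
```

taking the 3 largest-λ and 3 smallest-λ eigenvectors as spatial filters
(their duals are the interpretable scalp patterns). Each epoch yields log
normalized-power features `f_i = log(v_i / Σ_j v_j)` that feed an RBF
support vector machine. Evaluation uses probe-grouped 5-fold
cross-validation within subjects and leave-one-subject-out across
subjects, reporting accuracy, precision, recall and `F1 =
2·precision·recall / (precision + recall)` for the MW class, plus
observed and predicted MW rates. Chance level is calibrated by rerunning
the whole pipeline under probe-level label permutations (95% CI of the
null F1) with a Welch t-test against the true-label folds.

**Statistics.** Two-factor repeated-measures ANOVAs on log band power
(probe response × band), per channel across participants and per
participant across channels, with effect sizes
`η_p² = SS_effect / (SS_effect + SS_error)`, Holm–Bonferroni correction
across models, and post-hoc paired t-tests per band.

The synthetic module (`synth_config()`, `generate_session()`,
`generate_cohort()`) simulates the whole setting — band-limited Gaussian
sources through a mixing matrix, class-dependent band-power effects
confined to the pre-probe windows, frontal blinks, sensor noise — with
known ground truth for parameter-recovery testing.

## Worked example

```r
library(mwdetect)

# one synthetic subject: 13 probes, alpha-band power x8 during MW
cfg  <- synth_config(n_probes = 13, probe_spacing = 24, fs = 128,
                     class_effect = c(1, 8, 1, 1, 1, 1), seed = 1)
sess <- generate_session(cfg)
res  <- run_subject(sess$raw, sess$probes,
                    run_config(variant = "suppressed",
                               permutations = 100, seed = 7))
res
#> <mw_subject_result> S1 (suppressed variant)
#>   epochs: 65 initial, 63 retained (20 MW / 43 not MW)
#>   best band: beta1, F1 0.94 +/- 0.03
#>   chance F1 95% CI [0.00, 0.66], t = 20.52, p = 2.6e-06
res$best
#> <mw_detection> subject S1, band beta1 (suppressed)
#>   accuracy 96 +/- 2.5 %  F1 0.94 +/- 0.03  recall 0.90  precision 1.00
#>   observed MW rate 0.32, predicted 0.29 over 63 epochs
res$anova
#> <mw_anova> repeated measures over 16 channels
#>   MW        F(1,15) = 11.75, p = 0.003739, eta_p2 = 0.44
#>   MW x Freq F(3,45) = 16.48, p = 2.282e-07, eta_p2 = 0.52
```

Reading the output: of the 65 pre-probe epochs, 63 survived peak-to-peak
rejection, 20 of them labelled MW (observed MW rate 0.32). The
cross-validated detector reaches F1 0.94 in its best band, far above the
permutation chance interval [0, 0.66], so detection for this subject is
significant (p ≈ 3e-6). The per-participant ANOVA across channels shows a
band-power difference between MW and attentive epochs (η_p² = 0.44) and a
band-dependent one (η_p² = 0.52). The planted effect sits in the alpha
band; the running standardizer redistributes a band-limited power change
across bands (see the methods vignette), which is why a neighbouring band
can win best-band selection on a given draw.

`plot(csp(res$band_epochs$alpha))` draws the learned scalp patterns;
`run_cohort()` assembles per-subject tables, leave-one-subject-out
results and observed-vs-predicted rate agreement for a list of sessions.

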
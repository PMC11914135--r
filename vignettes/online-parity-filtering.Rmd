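---
title: "Online-parity filtering for P300 RSVP spellers: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online-parity filtering for P300 RSVP spellers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bciparity)
```

## The question the package addresses

An RSVP (rapid serial visual presentation) P300 speller calibrates a trial
classifier on a recorded session and then uses it in closed loop. During
closed-loop use the EEG arrives in short chunks — one inquiry of ten stimuli
at a time — and any temporal filtering necessarily runs on those chunks, with
causal (forward-only) passes for everything that must not add latency.
Offline, however, the near-universal habit is to filter the *whole*
continuous calibration recording and only then cut trials ("conventional
filtering", CF). A classifier trained on CF data has seen filter context that
will never exist online. The alternative with *online parity* ("online
filtering", OF) epochs the calibration recording into buffered inquiries
first and filters each chunk independently, exactly as the closed-loop
system will.

`bciparity` implements both pipelines end to end — synthetic EEG in,
cross-validated classifier metrics, band sweep, permutation statistics and
an online copy-phrase simulation out — so the consequences of the two filter
application orders can be studied reproducibly without access to recorded
human data.

## The filter chain

Both pipelines share one chain, applied in this order:

1. **Zero-phase notch** at 60 Hz, quality factor 30 (bandwidth
   60/30 = 2 Hz). The constrained second-order IIR notch is applied
   forward-backward, so the net phase is zero and the effective magnitude is
   the squared single-pass response; the magnitude at exactly 60 Hz is
   numerically zero.
2. **Causal Butterworth bandpass**, order parameter 5, default band
   1–20 Hz. The band transform doubles the order, giving 10 poles; each band
   edge sits at exactly −3 dB. The pass is forward-only with zero initial
   conditions — this is the filter whose transient the inquiry buffer must
   absorb.
3. **Decimation by 2** (300 Hz → 150 Hz), keeping every second sample. No
   separate anti-aliasing stage is used: with a 20 Hz band edge the
   chain leaves well under 1% of output energy above the 75 Hz
   post-decimation Nyquist, which the test suite verifies by periodogram.

Two numerical choices matter here. First, the bandpass is designed and
stored in zero-pole-gain form (prototype poles, band transform, bilinear
mapping) and applied as a cascade of second-order sections. Expanding 10
poles into a single polynomial is ill-conditioned when the lower edge sits
at 1/150 of the sampling rate; in polynomial form the band-edge gains are
off by about 1e-5 relative, while the zpk/SOS form holds them at machine
precision. Second, OF epoch starts are aligned down to the decimation grid,
so CF and OF keep exactly the same absolute samples; without this, a
one-sample grid offset between the two pipelines masquerades as a large
spurious CF/OF discrepancy (about 20% of trial RMS for 10 Hz content).

The "5th order" of a bandpass is ambiguous in common usage (prototype order
vs. total pole count); the package follows the convention of the standard
scientific-computing implementations, where the order parameter names the
prototype and the band transform doubles it.

### Buffering

OF cuts each inquiry from the raw record with a configurable buffer
(default 1.0 s) on both ends, filters, then discards the buffers (after
decimation) before trial extraction. The buffer exists to absorb the causal
bandpass transient: on a stationary in-band sinusoid the worst per-trial
OF-vs-CF discrepancy falls from about 6% of trial RMS at a 0.25 s buffer to
about 1.2% at 1 s, and the suite asserts both the 2% bound at 1 s and
monotone improvement with buffer length. Buffered epochs of adjacent
inquiries may overlap; each is cut independently from the raw record with no
filter state shared across inquiries, mirroring how chunks arrive online.

### Trial window

The trial window is not a property of the filter chain and is configurable;
the default is 0.5 s post-onset with no baseline correction. At the task's
5 Hz presentation rate successive windows overlap by construction — each
trial is cut independently and a target's P300 necessarily also appears,
shifted, in the next trial's window. This overlap is part of the paradigm,
not an artifact of the implementation.

## The synthetic EEG generator

The generator renders a stimulus schedule into a 19-channel, 300 Hz
continuous recording as a sum of independent components:

* **Background**: per-channel AR(1) with coefficient 0.95.
  `background_sd_uV` (default 10 µV) is the *stationary* standard deviation
  of the process; innovations are scaled by `sqrt(1 - 0.95^2)`. The marginal
  convention is used because it is the amplitude a practitioner would read
  off the rendered trace, and it keeps per-subject noise draws in the 5–15 µV
  range physiologically meaningful; under an innovation convention the same
  numbers would produce 16–48 µV backgrounds that bury any single-trial ERP.
* **Alpha rhythm**: 10 Hz sinusoid, default 5 µV, random phase per channel.
* **Line noise**: 60 Hz sinusoid, default 2 µV, common phase.
* **Blinks**: 400 ms half-sine pulses, 100 µV on Fp1/Fp2 and 0.3 of that on
  F3/Fz/F4, at Poisson rate 0.1/s.
* **ERPs**: after every target stimulus onset, a −2 µV Gaussian N200
  (latency 0.20 s, sd 0.025 s, weighted toward O1/O2/P3/P4) and a +5 µV
  Gaussian P300 (latency 0.35 s, sd 0.06 s, weighted toward Pz/Cz/P3/P4,
  unit weight at Pz so the noiseless target average at Pz equals the
  template exactly) with a shared per-trial latency jitter (sd 0.02 s).

Everything is seeded: one master seed, with fixed integer offsets deriving
the per-component streams, so sessions are bit-reproducible.

What the generator does *not* emulate: non-stationarity and fatigue drift,
eye-movement-contingent potentials, electrode pops, 1/f broadband structure
beyond AR(1), inter-channel correlation of the background, and any
behavioural dynamics. Consequently, passing tests on synthetic data
demonstrate that the pipeline machinery is correct and that the documented
filter-order effects exist under controlled conditions — they do not certify
effect sizes on recorded human EEG.

A quantitative note on the regime: the causal 1–20 Hz chain reduces the
synthetic 5 µV P300 peak to about 1.3 µV (a Gaussian of width sd 0.06 s
keeps roughly half of its peak-forming spectral mass below ~1.5 Hz, which
the 1 Hz high-pass edge removes, and causal phase dispersion smears the
rest). Against a 5–15 µV in-band background this leaves single-trial
discriminability modest — cross-validated MCC between roughly 0 and 0.4
across subjects — which is the same order as the published real-data range
for this paradigm.

## Classifiers

All three classifiers emit a strictly positive per-trial likelihood ratio;
the online decision rule calls a trial a target when the ratio exceeds 1.0
(a ratio exactly 1.0 is negative).

**PRK** — per channel, a PCA basis is learned on the trials' time samples,
keeping the smallest component count reaching 95% cumulative variance
(shape-adaptive; the count is unspecified upstream, so the standard
cumulative-variance rule is used). Projected scores concatenate across
channels into an RDA whose class covariances are shrunk toward the pooled
covariance (λ = 0.9) and then toward a scaled identity (γ = 0.1); the
defaults mirror the heavily-pooled regime the reference implementations of
this model family ship with, and an optional grid over (λ, γ) is selected by
MCC. The scalar discriminant score (difference of class Gaussian
log-likelihoods) is then density-modelled per class with Gaussian KDEs using
Silverman's rule (deterministic and assumption-light; bandwidths are floored
at 1e-8 so exactly-degenerate score sets remain usable), and the output is
the unweighted ratio of the two densities — unweighted so that the online
1.0 cutoff is the natural class boundary rather than a prior-scaled one.
An absolute 1e-12·I floor on the RDA covariances keeps the perfectly
separable zero-variance case well-posed; a covariance that is singular
despite the γ ridge still raises an error.

**LR** — ridge-penalized logistic regression on per-feature-standardized
flattened trials, at the fixed inverse regularization C = 0.0183 (on the
glmnet scale, λ = 1/(nC)). Zero-variance features stay at zero after
centering. The representation the original consumed is not documented;
flattened standardized samples are the assumption-light choice.

**RLDA** — two xDAWN spatial filters per class (generalized
eigendecomposition of the class-average evoked covariance against the
overall signal covariance), super-trial covariance matrices (filtered class
prototypes stacked on the filtered trial, with an 1e-10-scaled diagonal
load), mapped to the tangent space at the affine-invariant mean of the
training covariances (fixed-point iteration, tolerance 1e-8, at most 50
iterations — non-convergence is an error, not a warning), and a Ledoit–Wolf
shrinkage LDA on the tangent vectors. The posterior odds include the class
prior term, as standard LDA does.

Cross-validation is stratified ten-fold (seeded deal within class), scoring
each held-out fold at the 1.0 ratio threshold and averaging balanced
accuracy and Matthews correlation across folds.

## Metrics and statistics

Balanced accuracy is (TPR + TNR)/2; MCC uses the standard four-count formula
with the convention that a zero denominator factor returns 0 ("no better
than random"), which is also what a single-class prediction degenerates to.

The paired comparison of OF against CF uses a sign-flip permutation t-test:
the observed one-sample t on per-subject differences against a null of
50,000 seeded random sign flips, two-tailed, with the +1 Monte-Carlo
correction (guaranteeing p ∈ (0, 1]; whether the original used the
correction is unknown, so the convention is documented rather than claimed
equivalent). The two-tailed t quantile (α = 0.05, df = subjects − 1) is
reported alongside as the cluster-forming threshold: on scalar per-subject
metrics a cluster permutation test degenerates to exactly this single-point
test. Exactly-zero difference vectors return p = 1 by definition.

## The experiment driver

`experiment_config()` freezes the study replica: 30 subjects by default,
per-subject P300 amplitude drawn uniformly from 2–8 µV and background sd
from 5–15 µV (sub-seeded from the master seed), calibration sessions of 110
inquiries, both pipelines at the default band, all three models under
ten-fold CV, paired permutation tests per model and metric, the four-band
sweep (1–10, 0.2–20, 1–20, 0.1–50 Hz) for the PRK model, and an online
simulation over the 25 subjects with the highest OF calibration MCC — an
MCC-based stand-in for the original cohort's exclusion of low-AUC
calibrations (the two criteria are related but not equivalent, and no
equivalence is claimed). Simulated copy-phrase sessions are scored per
trial; no letter-selection or backspace dynamics are modelled, and
per-trial likelihood records are retained so other decision rules can be
evaluated later without re-simulation.

Reduced problem sizes are used where the full replica is not the point of
the computation: the shipped acceptance script runs 8 subjects at 60
inquiries for the comparison, 4 subjects for the band sweep and 6 for the
simulation, and the test suite's amplitude-recovery check uses 6 subjects at
40 inquiries with a fixed 3 µV clean-EEG background — a level chosen so the
{0, 2, 5, 8} µV amplitude grid spans chance to clearly-above-chance
performance. These sizes are the package's own trade-off between
statistical resolution and a test run a contributor will actually execute.

## Degenerate inputs and tie-breaks

* Schedules with zero inquiries are valid and empty; negative counts and
  non-positive rates are errors.
* The target-free inquiry count is `round(n_inquiries * fraction)`.
* A stimulus onset whose trial window leaves the record is an error naming
  the offending events; OF epochs whose buffers leave the record are errors
  (they are not truncated).
* Post-decimation onset mapping uses integer floor division; the resulting
  sub-sample onset error is at most one decimated sample, far below the ERP
  component widths.
* Likelihood ratios are floored/clipped to stay finite and positive
  (KDE denominator at 1e-300, logistic probabilities at 1e-12, LDA
  log-odds at ±690 before exponentiation).
* `matthews_cc` on an empty denominator returns 0; `balanced_accuracy` on an
  empty class is an error, since no convention makes it meaningful.

## Known limitations

* The conclusions transportable to real EEG are structural (pipeline
  correctness, direction of filter-transient effects), not quantitative;
  the generator's defaults are not calibrated to any recorded cohort.
* The main text and a figure caption of the source study disagree on the
  inter-inquiry gap (2 s vs 4 s); the package defaults to 2 s and exposes
  the parameter, asserting neither.
* The likelihood convention of the original saved models (ratio vs.
  posterior odds vs. fused evidence) is not documented upstream; this
  package standardizes on the ratio convention and records it in every
  model manifest.
* EDF export and real-time acquisition are out of scope; sessions persist
  as CSV + JSON.
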
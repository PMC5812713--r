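---
title: "Divisive normalization, spatial suppression, and the measurement chain around it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divisive normalization, spatial suppression, and the measurement chain around it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normsupp)
```

## The phenomenon and the model

Increasing the size of a high-contrast drifting grating makes its direction
of motion *harder* to discriminate: observers need longer presentations to
reach a fixed accuracy. This is spatial suppression. At low contrast the
effect reverses — larger stimuli need *less* time (spatial summation). The
package models both effects with a single steady-state divisive-normalization
computation over a population of direction-selective units:

$$R(x, \theta) = g_r \frac{E(x, \theta)}{S(x, \theta) + \sigma}$$

where $E$ is the excitatory drive (the stimulus contrast-energy field pooled
with a narrow Gaussian over space and a wrapped Gaussian over motion
direction), $S$ is the suppressive drive — *the same* stimulus drive, pooled
with strictly broader kernels — and $\sigma$ is the semi-saturation constant.
Nothing else distinguishes excitation from suppression. At high contrast
$S \gg \sigma$, so growing the stimulus feeds the broader suppressive pool
faster than the excitatory one and the response at the stimulus centre falls:
suppression. At low contrast $S \lesssim \sigma$; the denominator is
dominated by the constant, so additional stimulus area raises $E$ faster
than it raises the effective denominator and the response grows: summation.
The switch between regimes needs no parameter to change with contrast —
summation emerges whenever $\sigma$ is within roughly two orders of
magnitude of the stimulus contrast.

Duration thresholds follow from a winner-take-all readout and an
evidence-accumulation argument: the decision uses the response at the centre
of the population, and the threshold is the time to accumulate a fixed
criterion amount of response,

$$\mathrm{threshold} = \mathrm{criterion} / R_{\mathrm{peak}}.$$

Because the size index is a *difference of log thresholds*,
$\mathrm{SI} = \log_{10}(\mathrm{thr}_{small}) - \log_{10}(\mathrm{thr}_{larger})$,
any multiplicative change to the criterion or to the response gain cancels
exactly: criterion shifts move all thresholds but no SI. The implementation
exploits this by computing SIs from the gain-free peak responses, so the
invariance holds to the last bit, not merely to rounding.

```{r model}
m <- norm_model()
pred <- predict(m, sizes = c(1, 2, 12), contrasts = c(0.03, 0.98))
pred
```

### Parameters, units, and how the defaults were chosen

* `sigma = 0.03` — semi-saturation constant, in units of the (squared)
  contrast drive. Chosen equal to the low stimulus contrast so that the 3%
  conditions sit in the summation regime.
* `exc_space_width = 0.4`, `sup_space_width = 2` (degrees, Gaussian SD) —
  excitatory pooling comparable to the smallest (1 degree) stimulus,
  suppressive pooling several times broader, as in receptive-field
  measurements in motion-selective cortex.
* `exc_feature_width = 30`, `sup_feature_width = 100` (degrees of motion
  direction) — suppression is broader in feature space as well; for a
  single drifting grating the drive is uniform in direction, so these
  matter only for multi-component stimuli.
* `drive_exponent = 2` — the stimulus drive is contrast energy, the
  accelerating nonlinearity conventional in normalization models of early
  vision. With a purely linear drive the model family cannot produce
  clearly visible suppression between the 1 and 2 degree stimuli at high
  contrast while keeping summation at low contrast; with the energy drive
  the default parameters give SIs of roughly $+0.13$ and $+0.14$ at 3%
  contrast and $-0.12$ and $-0.51$ at 98%, the qualitative pattern the
  psychophysics shows.
* `criterion` — one value per contrast at prediction time (defaults 94 for
  high and 2.4 for low contrast), putting predicted thresholds in the tens
  to low hundreds of milliseconds. A lower criterion at low contrast
  reflects that duration thresholds there are not longer in proportion to
  the much weaker neural response; SIs are independent of these values.
* Gain variants: `contrast_gain` (with `contrast_gain_exponent` for a
  compounded, exponential input-gain reduction) models a GABAergic
  potentiation acting on input strength — it raises thresholds mostly for
  small stimuli and therefore *weakens* measured suppression;
  `response_gain` scales all responses and shifts all thresholds equally.
  `norm_model(preset = ...)` bundles these.

### Discretization and numerics

Space is one-dimensional (a line through the stimulus centre; the stimuli
are circularly symmetric and the readout uses only the centre), crossed with
a circular motion-direction axis. The default grid spacing of 0.05 degrees
resolves the smallest stimulus with 20 samples; the default extent keeps
every pooling kernel un-truncated for stimuli up to 12 degrees, and
`pooled_drive()` refuses kernels that would not fit. Spatial kernels are
truncated at 5 SD and renormalized to unit area (truncation error below
1e-6); the feature kernel is a wrapped Gaussian. The convolution is checked
against a brute-force $O(N^2)$ summation to 1e-10 in the test suite. For
stimuli much larger than the suppressive pooling width the model response
forms a slightly elevated ring just inside the aperture edge (the
suppressive pool extends beyond the stimulus there); the readout is defined
as the centre response, which is what the decision rule uses, and a warning
is raised only if the response field is asymmetric about the centre —
the symptom of a mis-centred stimulus or grid.

## The Psi adaptive staircase

Thresholds are measured with the Psi method: a Bayesian posterior over
Weibull threshold and slope, updated after every 2AFC trial, with each
stimulus duration chosen to minimize the expected entropy of the *joint*
posterior. Grids are log-spaced — 40 candidate thresholds spanning 3–500 ms,
25 slopes spanning 0.5–16, 60 candidate durations spanning the presentable
range 6.7–333 ms; guess and lapse rates are fixed at 0.5 and 0.04 inside the
likelihood. Updates are computed in log space (no underflow over at least
1000 trials), selection is deterministic with ties broken toward shorter
durations, and the likelihood tables are precomputed so that selection is a
handful of matrix-vector products (`psi_reset()` reuses them across
staircases). The selection rule is verified in the tests against an
exhaustive expected-entropy scan.

Measured precision, not assumed precision: with 300 trials on a simulated
observer whose parameters lie inside the grids, the posterior-mean threshold
estimate is unbiased with a typical (median) error under 5% and a 95th
percentile around 12–13%. That spread is a property of the information in
the trials once the slope is jointly uncertain; the tests assert the
measured figures.

## Weibull fitting and exclusion rules

Accuracy is fit per run by maximum likelihood with
$P(x) = \gamma + (1-\gamma-\lambda)(1 - e^{-(x/\alpha)^\beta})$, guess
$\gamma = 0.5$ and lapse $\lambda = 0.04$ fixed. Optimization is a
deterministic multi-start Nelder–Mead on $(\log\alpha, \log\beta)$: a 5×5
start grid is scored and the three best starts are polished to a relative
log-likelihood tolerance of 1e-8, so refitting the same trials is
bit-reproducible. The 80%-correct threshold comes from the closed-form
inversion of the fitted curve; estimates outside (0, 500] ms are flagged
`excluded` and dropped, never imputed. All-correct or all-incorrect trial
sets are flagged degenerate with the threshold pinned to the corresponding
domain boundary and excluded. Run-level thresholds are combined within
subject by geometric mean (`fit_trials()`), matching the use of geometric
means wherever thresholds spanning different ranges are averaged.

## Block-design fMRI analysis

`epoch_blocks()` cuts ROI-mean time courses into epochs from 4 s before
block onset to 2 s after block end on the TR grid; at TR = 2 s an epoch of a
10 s block is 8 samples. One baseline per run — the mean over the pre-onset
windows (onset-relative $[-4, 0)$ s) of all epochs — converts signal to
percent change, which is exactly invariant to rescaling the whole time
course. In the alternating small/large design this baseline window lies in
the preceding small block by construction, which is precisely the intended
reference: the measured quantity is the response *change* when the stimulus
grows. The response measure is the mean over the half-open window
$[8, 12)$ s after onset (samples at 8 and 10 s), the hemodynamic peak of
the block; the half-open convention is an explicit choice where an
inclusive bound would have been equally defensible. Aggregation is the
nested mean — epochs, then hemispheres within run, then runs — which
differs from a pooled mean under unbalanced counts and is asserted against
a hand-computed case; a missing hemisphere is averaged over with a note.

## Simplified edited-MRS quantification

The GABA+ chain: a >3 SD rule flags corrupted averages from supplied
frequency-correction magnitudes (the correction itself is out of scope);
3 Hz exponential line broadening, implemented as convolution with the
equivalent unit-area Lorentzian on the ppm axis; a Gaussian fit (plus linear
baseline) of the GABA+ peak in a 2.8–3.2 ppm window, with the concentration
taken as the closed-form integral $a\,w\sqrt{2\pi}$ of the fitted Gaussian;
a pseudo-Voigt (mixed Gaussian–Lorentzian, matched FWHM, free mixing
fraction) fit of the unsuppressed water reference near 4.7 ppm; water
scaling; and the alpha tissue correction
$\mathrm{corrected} = \mathrm{raw} / (f_{gm} + \alpha f_{wm})$ with
$\alpha = 0.5$ and CSF assumed GABA-free. The correction's closed-form
identities (pure gray matter; pure white matter doubling at $\alpha = 0.5$;
homogeneous tissue at $\alpha = 1$) hold exactly, and across a population
with realistic tissue-fraction spread the correction preserves the rank
order of subjects' ratios — the formal counterpart of the observation that
the correction does not qualitatively change results.

One estimation subtlety: because the quantifier itself applies the 3 Hz
broadening, the broadened GABA+ line is a Voigt profile, and a plain
Gaussian fit loses the Lorentzian wings to the baseline — a systematic
7–10% underestimate of the area at these linewidths. `fit_gaba_peak()`
therefore accepts the broadening width and convolves its Gaussian peak
model with the same known unit-area kernel inside the fit; the underlying
peak is still modeled as a Gaussian and the closed-form area is unchanged.
With this, the generated-spectrum round trip recovers the true GABA+/water
ratio to about 1% (median) at 320-average noise levels.

## The statistical layer

* `rm_anova()` — within-subject sums-of-squares decomposition via
  `aov()` with an `Error(subject/...)` stratum, one or two within factors;
  an effect whose sum of squares is pure floating-point round-off is
  reported as $F = 0$ rather than a 0/0 ratio. Stimulus size can instead be
  treated as a continuous predictor: the linear trend is tested as the
  squared one-sample $t$ of per-subject slopes.
* `friedman_test()` — delegated to `stats::friedman.test` (mid-rank ties);
  the all-tied case is reported as a zero statistic.
* `permutation_correlation()` — Pearson $r$ with significance from
  shuffling one vector (default 10,000 iterations); $p$ is the proportion
  of permuted $|r|$ *strictly greater* than the observed one, exactly as
  the procedure is usually worded, so a perfect correlation yields
  $p = 0$. The conventional $(b+1)/(m+1)$ estimator is available via
  `add_one = TRUE`. Null calibration and agreement with the analytic
  $t$-based $p$ for normal data are asserted in the tests.
* `min_detectable_r()` — the Fisher-z power solution
  $r = \tanh\!\big((z_{1-\alpha/2} + z_{power})/\sqrt{n-3}\big)$, which
  reproduces 0.52 at $n = 27$ and 0.58 at $n = 21$ at two decimals and
  agrees with brute-force bivariate-normal power simulation; the
  noncentral-exact alternative was not needed to match those figures.
* `median_split()` — stable below/above-median grouping; 22 subjects split
  11/11; ties are resolved by first occurrence with a note.
* `screen_and_test()` — Shapiro–Wilk screening per condition; both the
  ANOVA and the Friedman test are computed and the larger p-value is
  reported, the conservative reporting rule.

## What the generators emulate — and what they do not

Every generator writes its ground truth next to its data, and every
downstream stage has a recovery test against it.

* `gen_observer()` / `gen_experiment()` — Weibull observers whose
  80%-correct points sit exactly at model-predicted thresholds (slope
  $\beta = 3$ by convention; observed slopes are not published for this
  task). A run interleaves six 30-trial staircases in randomized order plus
  10 catch trials (big high-contrast stimulus, 333 ms) answered correctly
  at 99%; four runs per subject. Not emulated: sequential dependencies,
  learning or fatigue, finite-frame duration quantization, or lapses that
  vary across subjects.
* `gen_population()` — subject ability and GABA+ are drawn from a
  bivariate normal on (log threshold scale, GABA) with
  `rho_gaba_performance` (default $-0.46$) the correlation between GABA+
  and log geometric-mean threshold; negative means more GABA+, better
  performance. Because ability scales all of a subject's thresholds
  multiplicatively, GABA+ relates to overall performance but not to SIs —
  by construction, mirroring the dissociation the design is meant to
  probe. Between-subject spread is 0.15 on the log scale (about 16%). The
  lorazepam arm applies additive log-threshold shifts, largest for the
  smallest sizes.
* `gen_bold_run()` — the alternating 25-block design (13 small, 12 big,
  10 s blocks, TR 2 s, 125 samples), block amplitudes convolved with a
  canonical double-gamma HRF on a baseline of 100, plus white noise of SD
  0.5 per TR (0.5% of baseline, a mid-range value for an ROI-mean time
  course). Not emulated: temporally autocorrelated scanner noise, drift,
  motion artifacts.
* `gen_spectrum()` — 2048-point spectra spanning a 2 kHz width at
  127.7 MHz; Gaussian GABA+ at 3.0 ppm, pseudo-Voigt water at 4.7 ppm,
  noise scaled as $1/\sqrt{320}$ averages, per-average correction
  magnitudes with optional injected outliers. Not emulated: spin physics,
  macromolecule contamination (the measure is named GABA+ for that
  reason), phase errors.

Passing tests therefore demonstrate that the analysis chain is correct and
well-calibrated *for data of this generative form*; they do not certify
performance on real data with structured noise.

## Problem sizes used in the checks

The end-to-end psychophysics check simulates 100 replicate experiments,
each a 5-observer cohort completing the full protocol (6 conditions × 4
runs × 30 trials), and evaluates the cohort-mean SI sign pattern — the
sign pattern of interest is a group-level quantity — together with the per-cell median threshold recovery error.
The MRS and fMRI round trips use 100 seeded datasets each; permutation
calibration uses 1000 seeded null datasets at 2000 iterations (enough that
the empirical CDF, not the estimator, limits the comparison) and 50
datasets at the full 10,000 iterations against the analytic p. These sizes
were chosen so each property is estimated with its tolerance to spare on a
single CPU.

## Known limitations

* The spatial model is 1-D by design; absolute response magnitudes (and
  hence the criterion values) are not comparable to a 2-D implementation,
  though the suppression/summation regime structure is.
* Model parameters are fixed by construction, not fit to data; the package
  deliberately provides no optimizer for them.
* The Gaussian GABA+ peak model ignores the multiplet structure and
  macromolecule background of real edited spectra.
* `rm_anova()` covers the one- and two-factor within-subject designs used
  here, not general mixed models; listwise exclusion is the only
  missing-data policy.
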
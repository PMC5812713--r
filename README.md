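# normsupp

Spatial suppression and spatial summation in human motion perception —
modeled, simulated, and measured through one reusable analysis chain.

Increasing the size of a high-contrast drifting grating makes its motion
direction *harder* to discriminate (duration thresholds rise), while at low
contrast larger stimuli become *easier*. `normsupp` implements the full
computational chain used to study this phenomenon and its proposed link to
GABAergic inhibition:

* a **divisive normalization model** of visual cortical responses,
  `R = g·E/(S + σ)`, in which the suppressive drive S is simply the
  excitatory drive E pooled over a broader spatial and direction extent —
  one computation that produces suppression at high contrast and summation
  at low contrast, with duration thresholds read out as
  `threshold = criterion / peak response`;
* the **size index** `SI = log10(threshold_small) − log10(threshold_larger)`
  (negative = suppression) and its exact invariance to criterion and
  response-gain changes;
* a **Psi adaptive staircase** (Bayesian posterior over Weibull threshold
  and slope, expected-entropy stimulus placement) and **Weibull maximum
  likelihood** psychometric fitting with fixed guess (0.5) and lapse (0.04)
  rates, 80%-correct thresholds, and 0–500 ms exclusion rules;
* **block-design fMRI ROI analysis**: epoching, one-baseline percent signal
  change, the 8–12 s peak window, and nested epoch/hemisphere/run
  aggregation;
* **simplified edited-MRS GABA+ quantification**: >3 SD artifact rejection,
  3 Hz exponential line broadening, Gaussian GABA+ and pseudo-Voigt water
  fits with closed-form integrals, water scaling, and α = 0.5 tissue
  correction;
* the **statistical layer**: repeated-measures ANOVA, Friedman test,
  Pearson correlation with permutation significance (strict-inequality
  p-value), Fisher-z minimum-detectable-correlation power analysis, and
  median splits;
* **synthetic-data generators** for every input — simulated 2AFC observers,
  trial logs, BOLD runs, edited spectra, and subject populations with a
  target GABA-performance correlation — each emitting its ground truth, so
  the entire chain is testable end to end without any external data.

## Worked example

Predict thresholds and size indices for the six size × contrast conditions,
then simulate a subject running the experiment and recover their thresholds:

```r
library(normsupp)

m <- norm_model()          # divisive normalization with default parameters
predict(m, sizes = c(1, 2, 12), contrasts = c(0.03, 0.98))
#> Model-predicted duration thresholds:
#>  contrast diameter_deg peak_response predicted_threshold_ms
#>      0.03            1       0.02120                 113.20
#>      0.03            2       0.02865                  83.76
#>      0.03           12       0.02913                  82.39
#>      0.98            1       3.12936                  30.04
#>      0.98            2       2.34783                  40.04
#>      0.98           12       0.97246                  96.66
#>
#> Size indices (negative = suppression, positive = summation):
#>  contrast pair     si
#>      0.03  1-2  0.131
#>      0.03 1-12  0.138
#>      0.98  1-2 -0.125
#>      0.98 1-12 -0.508
```

At 98% contrast the predicted threshold roughly triples from the 1° to the
12° stimulus (suppression, SI −0.51); at 3% contrast big stimuli need less
time than small ones (summation, SI +0.14). Scaling the criterion or the
response gain moves thresholds but leaves every SI bit-identical.

```r
trials <- simulate(m, nsim = 1, seed = 7, n_runs = 4)  # Psi staircases
fit_trials(trials)$subjects
#>   subject contrast_pct diameter_deg threshold_ms n_runs_used
#> 1     S01            3            1    140.22899           4
#> 2     S01           98            1     48.41779           4
#> 3     S01            3            2    126.29384           4
#> 4     S01           98            2     49.80433           4
#> 5     S01            3           12    107.95182           4
#> 6     S01           98           12    109.66300           4
```

This simulated subject drew an ability factor of about 1.4, so their true
thresholds are the model's scaled up by ~40%; the staircase-then-fit
estimates recover those subject-specific targets at the measured precision
of 4 × 30 adaptive trials per condition, and the suppression/summation
pattern (98%: 48 → 110 ms with size; 3%: 140 → 108 ms) survives intact
because size indices ignore the common scaling.

On the measurement side, `quantify_gaba()` takes an edited spectrum with a
water reference through rejection, broadening, peak fits, scaling, and
tissue correction:

```r
sp <- gen_spectrum(seed = 1)               # 320-average MEGA-PRESS-like
quantify_gaba(sp, f_gm = 0.5, f_wm = 0.4, f_csf = 0.1)
#> GABA+ estimate: raw ratio 0.004996, tissue-corrected 0.007137 (alpha = 0.5)
#>   integrals: GABA+ 4.988, water 998.3; 0 average(s) rejected
```

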
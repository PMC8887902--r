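---
title: "Kinematic encoding of reaching in intracranial HFA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic encoding of reaching in intracranial HFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`reachenc` fits per-electrode encoding models that predict high-frequency
activity (HFA, 70–200 Hz) from the kinematics of instructed-delay reaches,
and quantifies how similarly the two arms are represented at each electrode.
This vignette documents the model, the synthetic-session generator that
provides ground truth, the tunable parameters, the numerical choices, and
the limits of what the simulations can show about real recordings.

## The encoding model

HFA at time $t$ is modelled as a linear combination of four kinematic
features at a window of time lags:

$$\widehat{\mathrm{HFA}}(t) = \sum_{f=1}^{4} \sum_{\ell} \beta_{f\ell}\,
x_f(t + \ell),$$

with the features position along the reach axis ($z$), its nonnegative speed,
and the two spherical angles (elevation $\theta$, azimuth $\phi$) giving the
target direction from the reaching arm's home position. Velocity and
acceleration are deliberately absent: with a lag basis they are linear
combinations of lagged position, and including them would only add
collinearity. Speed is a nonlinear transform of position and enters
separately. Positive lags pair the neural sample with *future* kinematics,
so filter mass at positive lags means neural activity leads the movement.

Weights are estimated by ridge regression,
$\hat\beta = (X^\top X + \lambda I)^{-1} X^\top y$, after z-scoring both the
design columns and the response so the weights are scale-free. The solver
uses a Cholesky factorization of the regularized Gram matrix; with
$\lambda = 0$ and a singular Gram it either errors or, on request, falls
back to a pseudoinverse.

### Cross-validation

`nested_cv_fit()` partitions the usable trials (successful, non-catch) into
five mutually exclusive outer folds after a seeded shuffle. Within each
outer estimation set, five inner folds evaluate every $\lambda$ on the grid
by the Pearson correlation between validation predictions and observed HFA;
each inner fold selects its best $\lambda$ (ties resolved toward heavier
regularization, computed per fold and then combined by averaging the five
selected values — the grid average, not the grid maximum — before the outer
refit). Overall $R^2$ is the squared held-out correlation per outer test
fold, averaged over folds. Because partitioning is at trial granularity,
lagged columns cannot leak test-trial samples into training beyond the
unavoidable window overlap at trial boundaries; the no-leakage property is
verified by fitting pure-noise responses (held-out $R^2$ under 0.02).

The default $\lambda$ grid is $10^0 \dots 10^7$ (8 points): on z-scored
designs of this size it spans under- to over-regularized fits. An electrode
is *predictive* when held-out $R^2 > 0.05$ for either arm.

### Across-arm generalization

`across_arm_fit()` keeps the same machinery but draws the five test
partitions from the *other* arm's trials, so that the across-arm score is
computed from 80% estimation / 20% test splits exactly like the within-arm
score. The generalization index is across-arm $R^2$ divided by within-arm
$R^2$; electrodes above 0.80 (losing at most 20%) generalize well, below
0.50 (losing more than half) poorly.

A caveat established during development and asserted in the tests: because
the reported score is a *squared* correlation averaged over five small test
partitions, it is positively biased by roughly one over the number of
effective samples per partition. With 40-trial arms (8 trials per partition,
and step-function angle features contributing about one effective sample per
trial) the floor for a truly non-transferring electrode is about 0.05–0.1,
not 0. The overlap sweep therefore checks that the index at zero filter
overlap stays below 0.15 while the index at full overlap exceeds 0.85, with
strict monotonicity in between on a paired sweep (identical filter and noise
draws, only the overlap mixing varying).

### Task phases and tuning

Instruction is cue onset to movement onset; movement is movement onset to
the return press; inter-trial samples belong to neither. Phase scores are
squared correlations of the concatenated held-out predictions within a
phase, computed per outer fold and averaged, matching the overall
convention. Modulation depth is the population standard deviation
(divide-by-$n$) of the per-target mean predictions. Tuning similarity
compares the two arms' mean predictions on the two *central* targets — the
only physical locations shared by the arms — via a sum of squared
differences, min–max scaled over the electrode population and inverted, so
SI = 1 marks the most similar tuning in the sample. Both are computed from
per-phase target means of held-out predictions.

### Explainable variance

With $N$ aligned repeats $R_n$, signal power is
$\mathrm{SP} = \left[\mathrm{Var}\!\left(\sum_n R_n\right) - \sum_n
\mathrm{Var}(R_n)\right] / \left[N(N-1)\right]$, the trial-repeatable part
of the response variance, and
$\mathrm{CC_{norm}} = \mathrm{Cov}(\bar y, \hat y) /
\sqrt{\mathrm{Var}(\hat y)\,\mathrm{SP}}$ normalizes the prediction
correlation by the explainable ceiling. A nonpositive SP estimate (noise
dominated) is flagged rather than propagated. Against a constructed
signal-plus-noise stack, CC_norm converges to the prediction's correlation
with the common signal (within 0.02 at $N = 200$).

## The synthetic-session generator

The generator exists so that every downstream stage can be tested against a
known truth; it emulates the task, not the biophysics.

* **Task structure** (the study configuration): four targets per arm in a
  vertical screen plane 13 cm beyond the home buttons, two central targets
  shared by the arms; 40-trial blocks (10 per target, shuffled) alternating
  arms; 750 ms fixation, 900 ms instructed delay, 5% catch trials with the
  imperative withheld; a reach succeeds when the touch lands within the
  1.25 cm target radius plus a 1 cm buffer. The screen coordinates
  themselves are not published anywhere we could adopt them from, so the
  defaults (central pair at ±2.5 cm, eccentric targets at 8 and 13 cm
  laterally, 8 cm above the home row) are this package's choice, recorded
  in `task_config()`.
* **Durations**: reaction and movement times are lognormal with
  configurable mean/sd (defaults 0.50 ± 0.15 s reaction, 0.75 ± 0.15 s
  outbound, 1.0 ± 0.25 s inbound), sitting inside the range of published
  per-participant means for this paradigm. Touch scatter is isotropic with
  sd 0.5 cm, giving a Rayleigh mean centre distance of 0.63 cm, close to
  the 0.8–0.9 cm reported for patient cohorts.
* **Trajectories**: straight line home → touch → home with beta-density
  speed profiles (default shape (3, 3): smooth, bell-shaped, zero at the
  endpoints, peak at the midpoint). The beta shape is configurable because
  only the qualitative bell shape is established. Positions follow the
  regularized incomplete beta function, so the path integral of the speed
  profile equals the travel distance exactly.
* **Angles as step functions**: whether the angle features of the original
  analysis varied within trial is not documented; a straight-line path
  makes them constant during the reach, so they are per-trial constants,
  nonzero between movement onset and return press, zero at rest. Inter-trial
  samples hold all features at rest because no hand tracking exists between
  trials.
* **Ground-truth filters**: per electrode, smooth Gaussian-bump lag
  profiles with mass centred near +150 ms (neural lead) plus smoothed
  noise. The ipsilateral filter is the unit mixture
  $o\,\hat w_c + \sqrt{1-o^2}\,\hat w_\perp$ rescaled to the contralateral
  norm, so the cosine between the arms' filters equals the requested
  overlap exactly. Hemispheric asymmetry enters *only* through the
  per-electrode ipsilateral gain and this overlap — the minimal mechanism
  that reproduces the contrast structure of interest.
* **Identifiability projection**: lagged copies of step-function features
  are nearly collinear, so arbitrary weight structure on them cannot be
  recovered from any session. When the generator is given the session's
  features, filters are built inside the identifiable subspace of the
  standardized design (eigenvalues above $10^{-3}$ of the maximum), and the
  orthogonal component is additionally decorrelated against the Gram image
  of the contralateral filter (session-wide and per arm), so that zero
  overlap means uncorrelated *predictions*, not merely orthogonal
  coefficient vectors. Overlap and recovery are defined on the
  standardized-coordinate filters (`weights_std`), the space the model is
  actually fit in; without a feature argument the two coordinate systems
  coincide.
* **Noise calibration**: `target_r2` sets the per-electrode noise so the
  best attainable $R^2$ on contralateral samples is known (default 0.5 in
  the demo); the ipsilateral ceiling then follows from the gain ratio. This
  is what makes "held-out $R^2$ equals the ceiling" a sharp test.
* **Raw signal synthesis**: each band's carrier is a sinusoid at the band
  centre (shifted away from the 60/120/180 Hz notch frequencies),
  amplitude-modulated by a rectified affine transform of the target
  envelope. A band of width $W$ can only carry modulation up to $W/2$, so
  the envelope is low-passed at 5 Hz before modulating and the *effective*
  envelope is returned for round-trip comparison; extraction recovers it
  with correlation above 0.99 noiselessly, and a 60 Hz line at ten times
  the carrier amplitude degrades that by less than 0.05 after the notch.

What the generator does *not* emulate: non-stationary noise, epileptiform
transients, electrode drift or cross-electrode correlated noise, postural or
non-kinematic covariates, within-trial corrective submovements, and any
true nonlinearity between kinematics and HFA. Passing tests therefore show
that the pipeline recovers the truth of a lagged linear-Gaussian world at
realistic SNR — they do not certify performance against every pathology of
clinical recordings.

## HFA extraction

Preprocessing applies, in order: a 4th-order Butterworth low-pass at 500 Hz
and decimation when the input rate exceeds 1 kHz; common average reference
over the good electrodes (bad electrodes are an input mask — detection by
visual inspection is out of scope); zero-phase 4th-order band-stop notches
at 60/120/180 Hz with 2 Hz half-width. Filter orders and the notch shape
are field-conventional choices, stated so that deviations from any original
recording chain are traceable. Extraction band-passes each of the five
log-spaced bands (70/86/107/131/162/200 Hz), takes the analytic-signal
magnitude via the FFT half-spectrum construction, z-scores each band's
envelope over the full concatenated recording — per-block scaling would
erase genuine amplitude differences between blocks, which is the point of
concatenated scoring — averages the five bands, and decimates to 100 Hz
with antialiasing. All filters run forward–backward, so band and notch
filtering add no phase distortion.

## Statistics

The original mixed-effects comparisons are approximated by permutation
tests that operate at the level where observations are exchangeable —
the participant:

* `sign_flip_test()` flips electrode score signs for the null of a
  zero-mean score distribution.
* `block_permutation_test()` covers the three designs: paired
  (within-participant factor; sign-flips of per-participant condition
  differences), between (permuting the participant-to-group assignment on
  per-participant means), and interaction (the same assignment permutation
  on per-participant condition *differences*).
* `cluster_permutation_timeseries()` forms clusters of contiguous
  suprathreshold paired-$t$ samples (two-sided $p < 0.05$ forming
  threshold, configurable) and corrects by the permutation distribution of
  the maximum absolute cluster mass.

All p-values use the $(b + 1)/(n_{\mathrm{perm}} + 1)$ convention and a
fixed seed reproduces the null exactly; the Monte-Carlo standard error is
at most $\sqrt{p(1-p)/n_{\mathrm{perm}}}$. Calibration is verified by
simulation: type-I error within 0.05 ± 0.02 for the sign-flip and paired
block tests under clustered nulls, familywise error at or below ~0.05 for
the cluster test, and > 90% detection of a 300 ms, 1 sd inserted effect.

A structural limitation worth knowing: between-participant permutations are
supported only on the participant assignments, so their null is coarse for
small cohorts — with three participants per group the smallest attainable
two-sided p-value is 0.1. The demonstration pipeline therefore simulates
five participants per hemisphere ($\binom{10}{5} = 252$ assignments,
minimum two-sided p ≈ 0.008), a requirement of the permutation
approximation rather than a statement about any particular dataset.

## Problem sizes and runtime

The full-scale configuration (±2 s of lags at 100 Hz, 1600 design columns,
hundreds of electrodes) is supported — per-trial Gram caching makes the
nested CV cost one pass over the design plus cheap per-fold updates — but
the shipped tests and the demonstration pipeline run a desk-scale variant
chosen as this package's own default study: ±0.2 s lags (160 columns), one
or two 40-trial blocks per arm, 8–64 electrodes, and a noise ceiling of
$R^2 = 0.5$. At these sizes the whole test suite and the acceptance script
each run in minutes on one CPU, and every scientific property the tests
assert (ceiling recovery, overlap monotonicity, calibration) is already
sharply resolved.

## Known limitations

* The event-based trajectories are smoothed idealizations; real reaches
  contain corrective submovements the beta profile cannot express.
* The across-arm $R^2$ floor discussed above means generalization indices
  near zero are not numerically zero at desk-scale trial counts.
* `tuning_similarity()` is population-relative (min–max over the analysed
  electrodes): SI values are comparable within one analysis, not across
  datasets.
* Session storage uses `events.csv` plus an RDS container for signal
  matrices; no HDF5 reader/writer is provided.
* Electrode localization is out of scope; `distance_to_dorsal_cs()`
  consumes already-demarcated sulcus coordinates.
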
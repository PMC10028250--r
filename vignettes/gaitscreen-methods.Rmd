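---
title: "Methods: from landmark trajectories to developmental-delay screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from landmark trajectories to developmental-delay screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitscreen)
```

## The problem

Locomotion is a high-dimensional, highly variable behavior, and it is shaped
by characteristics of the moving animal: body mass, size, age, sex, and —
the diagnostically interesting part — deficits and delays. `gaitscreen`
implements an inverse screening strategy for walking quadrupeds (developed
around neonate domestic piglets): instead of asking how subject
characteristics change kinematics, a probabilistic model is trained to infer
the subject characteristics *from* the kinematics of single stride cycles.
Trained on a reference population (normal-birth-weight strides), the model
encodes what "normal" locomotion looks like at a given age. If the age of an
out-of-sample individual is consistently inferred to be lower than its true
age, that individual moves like a younger animal — a quantitative,
per-individual indicator of developmental delay.

The pipeline has five stages, each usable on its own:

1. **Segmentation** — locomotion episodes, footfalls, cyclic stride
   candidates, automatic quality filters.
2. **Kinematics** — joint-angle profiles and nine spatiotemporal gait
   variables with dimensionless conversion.
3. **FCAS** — Fourier Coefficient Affine Superimposition: separation of
   dynamic posture (mean, amplitude) from coordination (the non-affine
   residual), and temporal alignment of all cycles.
4. **Probabilistic model** — robust Bayesian linear regression of one
   subject characteristic on sex + gait variables + posture + coordination;
   per-stride posterior-predictive inference.
5. **Screening** — per-subject verdicts from the consistency of
   underestimation across strides and predictive samples.

## Stride segmentation

Episodes are maximal frame intervals in which (i) the rolling-mean tracking
likelihood of every landmark stays above a threshold (default 0.9 over a
5-frame window), (ii) no landmark jumps more than `noise_max` (default
0.05 m, i.e. 2.5 m/s at 50 Hz) between frames, and (iii) every
skeleton-segment length stays within a relative tolerance (default 25%) of
its episode median. The thresholds are configuration, not science: tracking
dialects differ, and all defaults are logged with the output.

Footfall detection uses a kinematic contact proxy (no force plate is
available in a farm setting): a hoof is in stance when its horizontal speed
drops below 10% of the episode-mean withers speed for at least 3 frames;
the touchdown is the first frame of the stance run. A stance already in
progress at the episode start has no observable touchdown and is dropped.
Speeds are forward differences, so a stance onset is not blurred by the
last swing frame. A stride is one full forelimb cycle, touchdown to the
next ipsilateral touchdown, with the hindlimb touchdown inside the cycle
attached for inter-limb timing.

Cyclicality is the similarity-Procrustes distance (translation, rotation,
scale removed) between the 17-landmark configurations at the stride's
first and last frame; an exactly periodic gait gives 0. The superimposition
is delegated to `vegan::procrustes()`; the distance is computed from the
superimposed residuals rather than from the `1 - (sum of singular values)^2`
shortcut, which loses ~8 significant digits to cancellation near zero.

Plausibility filtering retains a stride only if every gait variable lies in
its configured interval (duty factors in (0,1), dimensionless speed in
(0,3), clearances in (0,1), phases in [0,1), ...) and cyclicality is at or
below its threshold (default 0.1); the names of violated filters are
recorded per stride so the funnel is auditable.

## Kinematics

Joint angles follow the convention that a straight joint (collinear
continuation of the proximal segment) is zero and counter-clockwise
rotations are positive; the image y-axis is flipped on read so the frame
is right-handed. The six analysis joints are shoulder, elbow, carpal, hip,
stifle and tarsal; the total forelimb angle (croup–withers–forehoof) is
carried along purely as the phase reference.

Profiles are unwrapped and resampled to a uniform cycle grid (default 100
samples) with linear interpolation. At 50 Hz a smooth joint-angle profile
is resolved well enough that interpolation error is ~10^-3–10^-2 rad on an
off-knot grid; when the resampling grid coincides with the digitized
frames the extraction is exact to numerical precision. Tests check both
regimes separately, so pipeline defects cannot hide behind interpolation
error.

The nine gait variables are stride distance, frequency and speed
(dimensionless via dynamic-similarity scaling: distance/h, frequency ×
√(h/g), speed/√(g·h), with h the stride-mean cumulated snout–eye–ear–
withers–croup–tailbase chain length), fore/hind duty factor, fore/hind
clearance (1 − min/max of the trunk-to-hoof distance; hip→hindhoof for the
hindlimb, withers→forehoof for the forelimb, the withers being the
forelimb's fixed trunk landmark), stride-average head angle (snout–ear
line), and hindlimb phase. The torso angle (withers–croup) is computed and
stored but does not enter the models, mirroring the analysis set the
pipeline is built around. `speed = distance × frequency` holds exactly in
both raw and dimensionless form, which the tests exploit.

## FCAS: posture vs. coordination

Each profile is decomposed into eight harmonics under the one-sided
convention

x(t) = c₀ + Σₙ 2·Re(cₙ·e^{i2πnt}),  t ∈ [0, 1),

so c₀ is the temporal mean and a pure cosine of peak amplitude *b* has
|c₁| = b/2. Eight harmonics reproduce smooth joint-angle profiles with
negligible truncation; the band-limited round trip is exact to 10⁻¹⁰ and
the variance identity (Parseval: profile variance = 2Σ|cₙ|²) validates the
normalization.

The affine components of a profile are its mean (c₀), its amplitude — here
the harmonic energy norm √(Σₙ≥₁|cₙ|²), a smooth, monotone proxy of
effective range of motion that equals b/2 for a single harmonic — and its
phase, −Arg(c₁)/2π of the designated reference. Removing them in sequence
gives:

* **dynamic posture** — mean and amplitude (eROM) of the six joints,
  12 numbers per stride;
* **coordination** *sensu stricto* — the mean-free, amplitude-normalized,
  phase-aligned residual coefficients: 6 joints × 8 harmonics × {Re, Im} =
  96 numbers per stride.

Phase alignment uses one time shift per stride (the forelimb reference
phase), applied to every joint, so inter-joint phase relations — genuine
coordination — are preserved. The defining contract, tested directly, is
affine invariance: offsetting any joint, rescaling any joint's amplitude,
or time-shifting the whole stride changes the coordination vector by less
than 10⁻⁸.

The same machinery yields phase-preserving averages: profiles are aligned
to their circular-mean phase in the frequency domain before averaging, so
out-of-phase cycles no longer cancel ("destructive interference"); two
antiphase unit sines average to a unit-amplitude sine instead of zero.
Joint-wise alignment is available for presentation-quality hindlimb
averages; the analysis pipeline always aligns by the forelimb reference.

Normalizing amplitude before the coordination PCA (rather than only
removing mean and phase) is a deliberate choice: it makes the 96-vector a
pure shape descriptor. The redundancy in the 96 variables (normalization
and phase-zeroing consume degrees of freedom) is retained for fidelity to
the established variable count.

## Multivariate reduction

The 96 coordination variables are reduced by an ordinary centered PCA; the
first 12 coordination components enter the models. No column
standardization is applied — the inputs are already normalized and
dimensionless, and raw covariance preserves the relative harmonic
weighting. Loadings carry a deterministic sign convention
(largest-magnitude entry positive) so scores are reproducible. Body size
is the first principal component of the per-recording mean
skeleton-segment lengths, sign-fixed so larger animals score higher. PCA
models serialize to JSON so the training-time model is reused verbatim at
prediction time.

## The probabilistic subject model

For one outcome θ ∈ {mass, size, age} and stride-level predictors
(sex, 9 gait variables, 12 posture values, 12 coordination components):

θ ~ α + v_sex·β_s + Σ v_g·β_g + Σ v_p·β_p + Σ v_c·β_c + ε,

with a Student-t observation model (robust regression; Gamma(2, 0.1)
degrees of freedom ν, weakly informative with mean 20), a Half-Cauchy
residual scale ε, and Normal priors on intercept and slopes. Intercept,
34 slopes and ε give **36 free parameters**. Mass is modeled on the log
scale (strictly positive, right-skewed); age and size are untransformed
(size scores can be negative).

Predictors and the (transformed) outcome are centered and scaled by
training-set mean and standard deviation; on that scale the slope priors
are Normal(0, 2) — i.e. two observed standard deviations — and the
Half-Cauchy scale is 1 (one observed sd of θ). Placing the "two sd" width
in scaled space is a choice: it gives every predictor the same a-priori
leverage regardless of units, and it is what makes the 36-parameter model
samplable with ~300 training strides.

Sampling is MCMC via JAGS with the `glm` block-updating module. The
Student-t likelihood is written in its exact scale-mixture-of-normals form
(y ~ N(μ, ε²/λᵢ), λᵢ ~ Gamma(ν/2, ν/2)), which lets the sampler update all
35 regression coefficients as one conjugate block; this is a
reparameterization, not an approximation. The desk-scale default is 4
chains × 1,000 tuning + 1,000 retained draws (~10 s per model); a
full-scale profile (32 chains × 2¹⁴ + 2¹⁴) sits behind
`profile = "full"`. Runs are exactly reproducible given a seed.

Convergence diagnostics (split R-hat and effective sample size) are always
emitted, and a run with any R-hat above 1.01 is marked failed while its
draws are still returned. Two honest caveats: the energy-based BFMI
diagnostic is specific to Hamiltonian samplers and does not exist for this
backend; and at desk scale the ν parameter mixes slowly (R-hat ~1.03–1.1,
ESS ~50–80) while every regression parameter converges cleanly (R-hat ≤
1.01, ESS > 3,000) — ν is weakly identified and needs the full-scale
profile for a spotless report. A closed-form conjugate posterior (residual
scale fixed at truth, near-normal noise) serves as an independent oracle
for the sampler in the test suite.

Posterior-predictive inference is per stride: one predictive θ draw per
posterior draw from the Student-t observation model at the stride's
predictor values, so all posterior information enters the prediction
distribution. Δ = predicted − actual; negative Δ is underestimation.

## Screening rule

Per subject: the underestimation ratio is the fraction of all pooled
predictive samples below the actual value; the underestimation count is
the number of strides whose mean Δ is negative. A subject is flagged as
*consistently underestimated* when the ratio exceeds 0.75 **and** the
majority of strides are on average underestimated. Both the count
definition (which reproduces the reference behavior of subjects with,
e.g., 7 strides and count 1 at ratio 0.40) and the Δ sign convention
(negative = delayed) are fixed in `subject_verdict()`; all metrics can be
recomputed by brute force from stored predictive samples, which the tests
do.

## The synthetic cohort and walker

Everything above is testable without any video, through two generators.

`generate_cohort()` emulates the statistical structure the analysis
assumes: ~58 subjects in litters of ~12, 4–9 strides each, ages uniform on
1–10 h, sex balanced, a runt mixture in birth mass so that the LBW rule
(lowest litter decile AND ≤ 800 g) flags roughly 10% of animals. Gait
variables, posture and 12 latent coordination scores are linear functions
of standardized (effective age, mass, size, sex) plus Gaussian noise; the
scores are embedded into the 96-dimensional coordination space by a fixed
orthonormal map, so the coordination matrix has known rank 12. A
developmental delay (default 5 h) is injected into LBW subjects recorded
above 5 h by driving their kinematics with `age − delay`. Optionally,
band-limited joint-angle profiles consistent with the posture and
coordination values are synthesized with a random phase per stride, so the
FCAS stage can be fed real waveforms whose ground truth is known.

What the generator does *not* emulate: per-subject correlated stride noise
(strides are conditionally independent), tracking artifacts, non-walking
gaits, and any nonlinearity in the age–kinematics relation. Passing tests
therefore demonstrate that the pipeline recovers what it assumes —
linear structure with known noise — not that real piglet data satisfies
those assumptions.

`generate_walker()` is a forward-kinematic planar walker: a trunk
translating at constant speed carries rigid head/back landmarks; each limb
is a four-segment chain posed by two-link inverse kinematics between its
trunk anchor and a prescribed hoof path (stance: fixed foot; swing:
smoothstep advance with sinusoidal lift). All bone lengths are constant by
construction, every quantity is a function of stride phase, so strides are
exactly cyclic, and the touchdown frames are known exactly — the fixture
that pins segmentation, profile extraction, reference length and the size
score.

### Calibration of the screening operating point

One calibration deserves a full account. The screening rule (ratio > 0.75
with stride majority) is exercised meaningfully only if predictive
uncertainty is of the order of a few hours — but a correctly specified
Bayesian inverse model *shrinks*: E[age | kinematics] moves extreme ages
toward the cohort mean by the fraction of age variance the kinematics do
not explain. With ages uniform on 1–10 h (sd 2.6 h) and a predictive sd of
2 h, healthy subjects older than ~8.5 h are underestimated by >1.3 h in
expectation and cross the 0.75 ratio threshold: the false-flag rate among
non-delayed subjects is then 12–14%, and no amount of data changes that —
it is a property of the rule, the age distribution and the noise level,
not a bug. The generator's age-effect strength is therefore set so that
kinematics explain about 70% of age variance, giving a predictive sd of
~1.4 h; at that operating point a 5 h delay is detected in effectively
every delayed subject while fewer than 10% of non-delayed subjects are
flagged (pooled over cohorts; single ~58-subject cohorts carry binomial
noise of ±1 subject). The residual false flags remain concentrated in the
oldest healthy animals, for the shrinkage reason above — a caveat any user
of the 75% rule on real data should carry over.

Other defaults chosen once and kept: stride counts 4–9 per subject;
delay only above 5 h of age (younger delayed animals are kinematically
indistinguishable from normal neonates when the delay would push their
effective age below the observed range); birth-mass runt mixture at 14%
with mean 720 g so that delayed subjects exist in essentially every
cohort.

## Numerical choices and degenerate inputs

* Degenerate-amplitude threshold ε = 10⁻⁶ rad: joints below it are flagged
  and contribute zeros to coordination; a degenerate *reference* is a hard
  error for a single stride and an exclusion-with-warning in set
  alignment; averaging falls back to the arithmetic mean with a warning.
* Mirroring reflects about the midrange of observed x, the unique choice
  that makes double mirroring the exact identity.
* Intervals are half-open `[start, end)` in 0-based frames throughout, so
  strides concatenate without overlap.
* Unwrapping precedes resampling; the cycle is closed by the first sample
  lifted to the branch the unwrapped series ended on.
* Birth-weight ties are broken by input order, flagging at most
  ⌈10%⌉ per litter, deterministically.
* PCA sign: largest-magnitude loading entry positive; size PC additionally
  sign-fixed against mean segment length.
* The problem sizes used by the test suite and the acceptance script —
  20 replicate fits of 300 strides at desk-scale MCMC, 3–4 screening
  cohorts of ~58 subjects, walkers of 6 strides — were chosen as the
  smallest sizes at which the checked properties are statistically
  decisive.

## Known limitations

* 2-D only; out-of-plane motion aliases into angle profiles.
* The footfall proxy needs a reasonably steady trunk speed; it has no
  force-plate ground truth.
* Stride-level modeling ignores repeated measures per subject; a
  hierarchical extension would change the uncertainty bookkeeping of the
  verdicts.
* The screening rule's false positives concentrate at the extremes of the
  training age range (shrinkage); verdicts for subjects near those
  extremes deserve manual review.
* Manual exclusion criteria used on real recordings (multi-animal
  confusion, sideways walking) are not automated here; the plausibility
  filters stand in for them only partially.
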
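---
title: "glomplast: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glomplast: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomplast)
```

`glomplast` analyses olfactory go/no-go discrimination behaviour together
with widefield intrinsic optical signal (IOS) imaging of olfactory bulb
glomeruli. This vignette documents the models and procedures the package
implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the underlying experimental conventions leave the
procedure open.

## 1. Behavioural scoring and discrimination thresholds

A trial presents one odor of a pair for 2 s; the stimulus period is tiled
by four 500 ms lick bins. An S+ (rewarded) trial is correct — a *hit* —
iff the animal licks in at least three of the four bins; an S−
(unrewarded) trial is correct — a *correct rejection* — iff licking
occurs in at most one bin. `score_trial()` implements exactly this rule;
`lick_bins()` converts event timestamps to bins using half-open
`[500b, 500(b+1))` ms intervals when only lick times are recorded.

Performance is percent correct over the trailing `window` trials
(default 300, one training day: sessions of 300 trials are balanced at
150 S+ / 150 S−). `block_performance()` reports non-overlapping blocks
(default 100 trials, trailing partial block dropped), and
`performance(window = n)` equals the mean of the full blocks — a tested
invariant.

`discrimination_threshold()` scans the dilution series from most to least
dilute and returns the bracketing pair: the highest dilution exponent
still below the accuracy criterion and the lowest exponent at or above
it. Two conventions were fixed deliberately:

* **Ties count as discriminating** (`>=`, not `>`). Threshold statements
  about dilution series are interval-valued; a fixed tie rule makes the
  bracket deterministic.
* **Criterion default 70%**, the conventional onset-of-discrimination
  level for this task family; it is a parameter, not a constant.

Non-monotone curves (accuracy re-crossing the criterion) are flagged
(`monotone = FALSE`) and the first crossing from the dilute end is
reported.

## 2. Time-resolved bootstrap reaction times

At each grid time $t$ (10 ms steps, 0–2000 ms after odor onset) the
observed statistic is

$$d(t) = \widehat{\Pr}(\text{beam broken} \mid S+) -
         \widehat{\Pr}(\text{beam broken} \mid S-).$$

Trials are resampled with replacement *within class* $B$ times (default
1000) and the significance value is $p(t) = \Pr^*(d^*(t) \le 0)$, floored
at $1/(B+1)$ so $\log p$ stays finite. The test is one-sided (engaged
animals keep breaking the beam on S+; a two-sided option exists). The
reaction time is the **last crossing** of the $p = 0.05$ line *with
persistence*: the latest $t^*$ with $p \ge \alpha$ at the previous grid
point and $p < \alpha$ from $t^*$ through the end of the window. Without
the persistence requirement "last crossing" is ill-posed for noisy
curves. An all-below curve returns the first grid point with a boundary
flag; a curve that never stays below $\alpha$ returns an undefined RT —
a valid outcome, not an error.

The documented fallback mirrors visual identification: the point of
largest discrete curvature of the smoothed $\log_{10} p(t)$ curve
(3-point moving average; curvature $|y''|/(1+y'^2)^{3/2}$ with time in
seconds; the two points adjacent to the padded ends are excluded from the
argmax because padding manufactures spurious corners there). Flat or
purely linear log-p curves return undefined. Method selection is a flag
(`reaction_time(method=)`), never an automated judgment.

**Bootstrap vs permutation.** The suite validates the vectorised
bootstrap against a naive-loop reimplementation (agreement within
Monte-Carlo error) and against an exhaustive two-sample permutation test,
computed in closed form: for binary traces the permutation distribution
of $d$ at one time point is hypergeometric. The two constructions answer
subtly different questions. $P^*(d^* \le 0)$ measures sampling
variability *around the observed effect* with class-specific variances;
the permutation p-value measures tail mass of the *pooled null*. They
coincide exactly when the classes are exchangeable or fully separated,
and asymptotically in between — but on 10-trial binary instances the $d$
lattice has 0.1-wide atoms and the class variances differ in the
transition band, so pointwise agreement within Monte-Carlo error is not
attainable there for any correct implementation. The acceptance test
asserting that equivalence is therefore expected to stay red; the two
green companions (limit-regime agreement inside the same comparison, and
the independent reimplementation) establish implementation correctness.

One behavioural caveat worth knowing: with a chance-level generator
(programmed accuracy 0.5) a session can still yield a *defined* RT in
roughly the nominal 5% of realisations where the realised S+/S−
imbalance stays above the significance line — that is the test operating
at its stated level, not a defect.

## 3. ΔR/R maps, reference glomerular maps, and counting

Acquisitions run 10 s at 2 Hz with the odor delivered from 2 s to 7 s.
Per pixel,

$$\Delta R/R = \frac{\bar R_{\text{odor}} - \bar R_{\text{baseline}}}
                    {\bar R_{\text{baseline}}} \times 1000\ \text{‰},$$

with the baseline the frames wholly before odor onset and the response
window the full 5 s odor period (the integration window is not an
experimental constant; the full odor period is the default). Responses
are *negative* (reflectance darkening at 700 nm); counting and
activation use $|\Delta R/R|$ but outputs preserve sign. An optional
spatial high-pass (`highpass_px`) subtracts a boxcar background to
remove slow vignetting. Zero-baseline pixels are masked with a warning.

Noise is estimated robustly from baseline frame-to-frame residuals
(MAD of difference images, $/\sqrt2$), giving the per-frame pixel SD
$\sigma_f$ and the map SD
$\sigma_{\text{map}} = \sigma_f\sqrt{1/n_{\text{resp}} +
1/n_{\text{base}}}$, further divided by $\sqrt{n_{\text{reps}}}$ after
four-repetition averaging.

The **reference map** is built per mouse from the lowest (strongest)
dilution of each odorant and reused across all dilutions of the same
odorants. Detection: threshold $|\Delta R/R| > k\,\sigma_{\text{map}}$
(k = 3), a 4-neighbourhood binary opening (suppresses isolated noise
pixels and 1-pixel bridges that would merge adjacent structures under
8-connected labelling), 8-connected components within area bounds
(default 6–400 px), then two exclusion rules:

* **Vessels**: components whose second-moment elongation (square root of
  the eigenvalue ratio of the pixel covariance, with a 1/12 pixel-extent
  regularisation) exceeds 4. Their footprint, dilated by 3 px, also
  excludes fragments pinched off a vessel by the opening — masking out a
  vessel's immediate surroundings, as manual analyses do.
* **Single-frame transients**: a component must appear (≥ 50% pixel
  overlap with the per-frame thresholded mask) in at least 2 response
  frames.

Components from different odorants are merged by pixel union.
`quantify()` averages the (repetition-averaged) map over each ROI's
pixels; `count_activated()` counts ROIs with
$|\text{amplitude}| > k_{\text{act}}\,\sigma_{\text{map}}/\sqrt{\text{area}}$
($k_{\text{act}} = 3$; "activated" has no universal quantitative
definition, so the threshold is exposed and swept in tests, and counting
is verified monotone non-increasing in it).

## 4. Respiration

Breathing cycles are successive negative-to-positive zero crossings of
the mean-subtracted, low-pass-filtered airflow signal inside the
analysis window (default the odor window). The filter is a *centred
moving average* (cutoff 15 Hz): it is zero-phase and maps a pure
sinusoid to a positively scaled sinusoid, so it cannot move interior
zero crossings — an FFT brick-wall filter was rejected because spectral
leakage on finite windows shifts crossings of even a pure tone. Crossing
times are refined by linear interpolation and frequency is (number of
complete cycles) / (time spanned by those cycles), exact for a pure tone
and grid-free under jitter.

In a 2 s window a cv = 0.05 jittered 3.1 Hz rhythm has a realised cycle
rate that differs from the base frequency with SD ≈ 0.06 Hz; the
estimator is therefore validated per-seed against the generator's
recorded cycle times (tight tolerance) and across seeds against the base
frequency (median within ±0.1 Hz).

`amplitude_vs_frequency()` bins trial amplitudes at
{1.8, 2, …, 3} Hz (± 0.1 Hz), normalises each ROI to its 1.8 Hz mean,
and compares the reference and fastest bins by paired Wilcoxon
signed-rank across ROIs. Under frequency-independent responses all
normalised bin means sit near 1.

## 5. Group statistics and the psychometric linkage

The **mouse is the unit of replication**: amplitudes aggregate
ROI → stimulus → mouse → group, SEM over mice; ROI-level pooling is used
only for the cumulative-distribution (Kolmogorov–Smirnov) comparison,
where the population of glomeruli is the natural sample. Group means are
normalised to the naïve group's grand mean (naïve ≡ 1 by construction).
Amplitude summaries are computed over *activated* ROIs, matching the
convention of quantifying responses "in the glomeruli activated" by each
stimulus; including silent reference ROIs would dilute group contrasts
with structural zeros. High/low dilution classes follow the standard
protocol pooling (`dilution_classes()`): high 10⁻³/10⁻² (cineol/eugenol)
and 10⁻⁶/10⁻⁴ (isoamyl acetate/ethyl butyrate); low 10⁻¹/10⁰ and
10⁻²/10⁰.

`reward_value_split()` compares the amplitudes of glomeruli by the
valence of the activating odorant with a paired Wilcoxon test across
ROIs responding to both odorants of a pair (valence is counterbalanced
across animals). Fisher's-LSD-style pairwise comparisons are available
as pairwise t-tests gated on an omnibus F, as an approximation;
reproducing animal-derived inferential statistics is out of scope.

The **Boltzmann fit**
$y = a_2 + (a_1 - a_2)/(1 + \exp((x - x_0)/dx))$ uses `nls` (port
algorithm, $dx$ bounded positive) with a 20-point multi-start grid over
midpoint and slope; parameters are reported in canonical orientation
($a_1 < a_2$, using the identity $f(a_1,a_2,x_0,dx) =
f(a_2,a_1,x_0,-dx)$). Flat response data are flagged degenerate rather
than fitted ($dx$ is then unidentifiable). "Input strength" on the x
axis is the group-mean per-glomerulus ΔR/R amplitude at each dilution;
an amplitude × count alternative can be assembled from the same tables,
and `threshold_accuracy_contrast()` reports which component (count,
amplitude, or both) changes across the two near-threshold dilutions.

## 6. The synthetic world: what it emulates, and what a green test means

The generators state a world and keep it fixed:

* **Behaviour**: balanced pseudo-random odor sequences with no 3-run;
  per-trial correctness Bernoulli with the programmed per-dilution
  probability (monotone non-increasing toward dilution, within
  [0.5, 1]); lick-bin counts drawn consistently with the scoring rule
  for the drawn outcome; beam-break traces held through the stimulus on
  engaged trials and released at `divergence_time_ms` plus **one-sided
  half-normal jitter** (σ = 50 ms) on disengaged trials. The one-sided
  law is deliberate: the programmed quantity is the *divergence latency*,
  so the S+ and S− ensembles must be exchangeable before it and diverge
  exactly at it; symmetric jitter would move the true divergence ~2σ
  earlier than the nominal parameter and make it unrecoverable by
  definition. ITIs are drawn uniform 10–20 s (the typical self-paced
  range; the validity floor is 5 s).
* **Imaging**: a 72×72 field with 10–12 top-hat glomerular discs
  (radius 2.5–4.5 px, base amplitudes −3.5 to −1.5 ‰ per odorant),
  dilution attenuation as a saturating Boltzmann ramp (midpoint 10⁻³,
  width 0.8 decades) that is zero at and below 10⁻⁵ — no analytic
  concentration–response law is established for IOS, and this shape
  reproduces "no detectable glomeruli below the behavioural threshold"
  qualitatively. Group effects are two multipliers: trained amplitudes
  × 1.5, and the fraction of glomeruli responsive at high dilutions
  ×3 relative to the naïve third (12 glomeruli make the thirds exact).
  Vessels are dark ridges, 3.5–4.5 px wide with aspect ratio 5.5–6.5 —
  comfortably above the elongation-4 exclusion rule, because a
  criterion-straddling generator would make "vessels excluded" an
  ill-posed assertion. Vessels avoid glomeruli and each other, and the
  optional single-frame transient (−40 ‰, one frame of repetition 1) is
  placed clear of both: when a transient sits *on* a persistent
  structure, or two vessels cross, even an ideal detector cannot satisfy
  the exclusion rules, so the validation world keeps structures
  spatially distinct. Camera noise is i.i.d. Gaussian per pixel and
  frame (0.3 ‰ of the 4000-count baseline).
* **Respiration**: quasi-sinusoid with multiplicative period jitter
  (cv 0.05) around a base near the awake head-restrained rate of
  3.1 Hz; recorded cycle times are the ground truth.

What the generator does **not** emulate: awake-motion artifacts and
registration error (stacks are aligned by construction), shot/read-noise
statistics beyond additive Gaussian, hemodynamic or sniff-phase-locked
time courses, soft-edged or overlapping glomeruli, olfactometer flow
dynamics, and any biophysical link between behaviour and imaging. A
green suite therefore establishes that the *analysis* recovers what was
*programmed* under the stated world — parameter recovery, not
reproduction of animal-derived statistics.

Scale-downs for the compute budget are explicit: the group-effect
cohort runs 3 mice/group in the test (5 in the acceptance script)
against 5/group and ~100 ROIs/mouse in a real campaign, so KS pools are
~200–500 entries rather than the 400–500 ROIs of a full animal data set;
the KS shift at amplitude ratio 1.5 is decisive far below that size.

## 7. Numerical choices

* Bootstrap resample sums are accumulated as integer counts and divided
  once, with a 10⁻¹² tie tolerance on $d^* \le 0$: equal class fractions
  must count as ties exactly, not fall on either side of 0 by float
  rounding.
* Robust noise uses MAD with centre 0 on difference images.
* p-values are floored at $1/(B+1)$; log-p curvature is computed on the
  floored curve.
* ROI elongation regularises the pixel covariance by the single-pixel
  second moment (1/12) so 1-pixel components have elongation 1.
* The threshold fallback for noiseless stacks is an epsilon threshold,
  keeping detection defined when $\hat\sigma = 0$.
* Seeds: every generator call reseeds from its own `seed` field;
  per-stack seeds derive deterministically from the ground-truth seed
  and the stimulus coordinates, so repetitions differ but reruns are
  bit-identical.

## 8. Known limitations

* The automated ROI detector stands in for manual ROI drawing; its
  parameters can only be validated against synthetic ground truth, not
  against hand-drawn maps.
* Whether published amplitude figures average per glomerulus or per
  mouse is ambiguous in general; both aggregations are computed
  (`group_summary` mouse hierarchy vs pooled ROI lists) and labelled.
* The bootstrap/permutation duality holds only asymptotically (section
  2); small-sample p(t) values are bootstrap quantities, not permutation
  p-values.
* The CLI is a thin dispatcher intended for synthetic-data workflows and
  single-file scoring, not a batch campaign manager.
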
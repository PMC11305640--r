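---
title: "Spectrotemporal modulation transfer functions from ripple psychophysics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrotemporal modulation transfer functions from ripple psychophysics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripplemtf)
```

## The scientific problem

Natural sounds — speech, animal vocalizations — carry joint spectrotemporal
(S-T) amplitude modulations: their spectral content changes over time in a
structured way. A central question in auditory neuroscience is whether the
brain processes the spectral and the temporal dimension of these modulations
*independently* (a separable representation, the outer product of a spectral
and a temporal filter) or *jointly* (an inseparable representation with
genuinely two-dimensional S-T filters). `ripplemtf` implements a complete,
testable pipeline for answering this question psychophysically with dynamic
rippled noise: stimulus synthesis, adaptive audiometry, psychometric
threshold estimation, modulation transfer function (MTF) construction, and
SVD-based separability, symmetry and information analysis — exercised
end-to-end on a synthetic observer in place of behavioral recordings.

## Ripple stimuli

A dynamic ripple is a broadband tone complex whose spectrogram envelope is a
drifting sinusoid. The carrier is a set of 126 tones spaced 20 per octave
from 250 Hz (so component $n$ sits at $f_n = f_0\,2^{(n-1)/20}$, spanning
6.25 octaves up to 19 kHz). Each component is multiplied by the envelope

$$R(t, x) = 1 + \tfrac{\Delta M}{100}\,
  \sin\!\big(2\pi(\omega t + \Omega x)\big), \qquad t \ge D,$$

and $R = 1$ during the leading static-noise segment $t < D$. Here $x$ is the
component's position in octaves above the base frequency, $\Omega$ is the
ripple *density* (cycles/octave, signed), $\omega$ the ripple *velocity*
(Hz), and $\Delta M$ the modulation depth in percent. With $\omega > 0$ the
sign of $\Omega$ sets the direction of spectral motion: positive densities
sweep downward in frequency, negative ones upward (verified in the test
suite by tracking the envelope phase across spectrogram frames). The base
component's phase is fixed at maximum amplitude; all other phases are drawn
uniformly from a seeded generator, so waveforms are bit-reproducible.

Numerical choices:

* **Digital level.** Absolute playback level (dB SPL) is a property of the
  playback hardware, not of the waveform; each segment is normalized to a
  configurable digital RMS (default 0.05), which also equates total power
  across the static-to-ripple transition.
* **Sampling rate** defaults to 50 kHz, comfortably above Nyquist for the
  19 kHz top component.
* **No ramp at the ripple onset.** The envelope switches seamlessly at
  $t = D$ with continuous carriers; optional raised-cosine on/off ramps are
  available at the stimulus boundaries only.
* **Depth units.** $\Delta M$ is stored in percent and divided by 100 inside
  the envelope, since depths are reported in percent throughout.

The envelope-fluctuation statistic $M4 = \overline{S^4} / \overline{S^2}^2$
(computed after mean removal, because the synthesized complex is zero-mean
only in expectation) indexes instantaneous amplitude fluctuations: 1.5 for a
pure sinusoid, 3 for Gaussian noise, and
$3 - 1.5\sum a_n^4 / (\sum a_n^2)^2 = 3 - 1.5/126 \approx 2.988$ for the
equal-amplitude 126-tone random-phase complex — the closed-form oracle the
tests check synthesis against. Reported values are $M4$ itself: in the
Gaussian limit the statistic sits near 3, and that is the scale on which
flat-noise and dynamic-ripple values around 2.98–2.99 are comparable.
Static ripples ($\omega = 0$) can reach higher $M4$ at extreme depths; no
acceptance quantity is tied to them because their value depends strongly on
windowing conventions that are not part of this package's contract.

## The canonical stimulus grid

11 densities ($-3.0$ to $+3.0$ c/o in steps of 0.6), 8 velocities (0, 4, 8,
16, 32, 64, 128, 256 Hz) and 11 depths (0, 5, 7.5, 10, 15, 20, 30, 40, 50,
70, 100%). All unmodulated combinations — zero depth, or density and
velocity both zero — are perceptually one stimulus (static noise) and
collapse into a single catch entry: $10 \times 87 + 1 = 871$ distinct
audible stimuli over $88$ density–velocity combinations.

## Adaptive staircase audiometry

Pure-tone thresholds use a single-interval transformed three-down/two-up
rule: the level drops 10 dB after three consecutive hits and rises 10 dB
after two consecutive misses; after a configurable number of reversals the
step shrinks to 2 dB. Design decisions where the procedure leaves room:

* **Counter semantics.** Hit/miss counters reset on the opposite outcome and
  after every level change — the standard transformed-rule convention.
* **Threshold extraction** averages reversal levels from the small-step
  phase only; mixing 10 dB-phase reversals would bias thresholds. A
  stability flag records whether those reversal levels span at most 2 dB.
* **All reversals count** toward both the shrink and the stop criterion.
* **Outlier runs.** Audiogram assembly trims runs iteratively — the worst
  offender against the 10%-of-mean deviation band is dropped and the mean
  recomputed — rather than in one pass, so a single wild run cannot drag the
  mean far enough to disqualify the good runs.
* **Catch trials** monitor lapses and do not advance the staircase counters.
  The expected reward rate under both possible catch-trial reward
  contingencies is exposed as a diagnostic (`catch_reward_diagnostic()`),
  not asserted.

The *ideal observer* for the Monte Carlo calibration is a deterministic step
psychometric function (hit iff level $\ge$ threshold): "not limited by
internal noise" excludes stochastic responding. Once the staircase brackets
the threshold, the deterministic limit cycle is three hits followed by two
misses, so the proportion correct converges to exactly $3/5$ — an
independent closed-form oracle. Batch simulations draw observer thresholds
uniformly from 25–55 dB (centered on 40 dB under the 65 dB start; the
procedure itself does not prescribe the randomization, so a symmetric range
about the canonical threshold was fixed once); per-run proportions then
spread over roughly 55–65% with a mean near 60%. The batch kernel is
vectorized across runs and tested trial-for-trial against the scalar
staircase implementation. A second oracle checks equilibrium for *stochastic*
observers: the staircase concentrates where the probability of completing a
three-hit run before a two-miss run equals one half, computed from the
streak Markov chain in closed form.

## Psychometric model

Detection of depth $x$ follows the four-parameter cumulative Weibull

$$P(x) = \gamma + (1 - \gamma - \lambda)\,
  \big(1 - e^{-(x/\alpha)^\beta}\big),$$

with guess rate $\gamma$ (false positives, anchored by catch trials), lapse
rate $\lambda$ (misses at maximal depth), position $\alpha$ and slope
$\beta$. The detection threshold is the depth at the midpoint between the
lower and upper bounds, $x = \alpha (\ln 2)^{1/\beta}$ — independent of
$\gamma$ and $\lambda$.

Fitting is constrained maximum a posteriori: binomial log-likelihood plus
weakly informative priors — Beta(2, 20) on $[0, 0.5]$ for $\gamma$ (guess
rates up to ~35% occur in practice), Beta(2, 20) on $[0, 0.25]$ for
$\lambda$, a truncated Normal(30, 30) for $\alpha$, and LogNormal($\ln 3$,
0.5) for $\beta$ (empirical slope distributions peak near 2.6–3.6). The
exact hyperparameters are this package's defaults, chosen to be weakly
informative over those observed ranges, and are fully configurable. The
optimizer is bounded quasi-Newton (L-BFGS-B) with jittered restarts because
the penalized likelihood is multimodal for sparse tables; warm starts make
bootstrap refits cheap. A delta-method threshold standard error from the
observed information matrix accompanies every fit.

Goodness of fit uses the deviance (twice the log-likelihood gap to the
saturated model) with a parametric-bootstrap null distribution; the
$\chi^2_{7}$ tail probability (11 levels, 4 free parameters) is reported
alongside as a diagnostic only. Under the standard design, simulated
deviances rarely exceed 20 (the suite asserts the exceedance rate below
5%). Block screening for attention lapses replaces by-eye judgment with an
explicit rule: a block is discarded when its pooled hit rate at depths above
80% falls below 0.90; a block that is perfect up there is never discarded.

## MTF construction

Latency classification: releases 220–800 ms after ripple onset are hits,
later (or absent) releases are misses, earlier releases are discarded. The
87 modulated cells' midpoint thresholds populate an 8 × 11
velocity-by-density matrix. The origin cell — static noise, where no
threshold exists — is filled by a least-squares bicubic polynomial surface
on (density, pseudo-log velocity) coordinates, which is exact on constant
and low-order polynomial surfaces; an adjacent-neighbor average is available
as an alternative. The zero-velocity row is placed one octave below the
lowest nonzero velocity on the pseudo-log axis. Whether a global surface or
local neighbors is the better interpolant is genuinely open; the global
surface was chosen for smoothness and testable exactness, and the choice is
confined to a single cell out of 88.

Iso-depth (suprathreshold) MTFs evaluate each cell's fitted psychometric
function at a fixed depth — the stimulus scale as the independent measure —
so they inherit monotonicity in depth from the Weibull form; the origin
takes the pooled guess rate. Normalization maps a matrix affinely onto
$[0, 1]$; pooling across subjects averages normalized matrices cell-wise
and re-normalizes.

## Separability, symmetry, and information

The SVD $M = G\,K\,H^\top$ yields: the **inseparability index**
$\alpha_{\mathrm{SVD}} = 1 - \lambda_1^2 / \sum_i \lambda_i^2$ (0 for a
rank-1, fully separable matrix; at most $1 - 1/8$ on this grid); the
**rank-k reconstruction** and its agreement $r^2_{\mathrm{SVD}}$, a squared
Spearman rank correlation over all 88 cells; and the **marginal spectral and
temporal MTFs** — the first singular vectors, sign-fixed to positive mean.
The interpolated origin cell is included in the SVD (the analysis treats the
full 8 × 11 grid); a flag can exclude it.

**Up/down symmetry** splits the moving-ripple rows ($\omega > 0$) into the
upward half ($\Omega < 0$) and the mirrored downward half ($\Omega > 0$) —
5 × 7 cells each — and reports the squared Pearson correlation over the 35
pairs, the gain of the no-intercept regression
$M(\Omega < 0) = g\,M(\Omega > 0)$ (least squares through the origin, since
the relation is defined without an intercept), and the mutual information
between the halves. Pearson, not Spearman, is used here because the gain is
defined by a linear relation; the rank correlation is reserved for
$r^2_{\mathrm{SVD}}$ where it is the stated definition.

**Permutation nulls** reshuffle all 88 cells jointly by default (row- and
column-restricted modes available) and recompute any named statistic;
**bootstrap** intervals are bias-corrected percentile by default. For the
inseparability index of a noisy matrix the package also provides the basic
(reverse-percentile) interval: adding cell noise inflates
$\alpha_{\mathrm{SVD}}$ on data and replicates alike, so the BC percentile
interval sits entirely above the estimate and cannot reach a less-noisy
ground truth, while the basic interval subtracts the replicated bias. The
full-loop recovery test uses it for exactly that reason. Cell-level
resampling perturbs cells with Gaussian noise at the fitted per-cell
threshold standard errors; trial-level resampling (resample trials, refit,
rebuild) is supported through the simulation and fitting functions at much
higher cost. Both units are legitimate readings of "resampling the original
MTF data"; cell-level is the default for speed.

**Mutual information** between matrices uses equal-frequency (rank) binning
— 4 bins for 88-cell matrices, 3 for 8- or 11-cell slices — and the plug-in
estimator in bits. Rank binning removes scale dependence (profiles are
invariant to common monotone rescalings); no analytic bias correction is
applied by default because permutation nulls absorb the estimator bias
(Miller–Madow is available as an option). With 88 samples, more than a few
bins would overwhelm the joint histogram; the defaults keep at least ~5
expected counts per joint cell. All MI-based conclusions are property- or
null-based, never comparisons against printed bit values, because the
reference binning underlying any printed value is not part of this
package's contract.

## The synthetic observer

The generator defines the study conditions under which every pipeline claim
is tested:

* **Ground-truth surface.** Temporal band-pass (Gaussian on the log-velocity
  axis; peak 10 Hz for the human preset, 45 Hz for the monkey preset;
  bandwidth 1.8 octaves) crossed with spectral low-pass (corner 1.6 c/o,
  Gaussian falloff), plus a floor of 0.1 on each profile so sensitivity
  stays positive. A rank-1 perturbation, orthogonalized against both
  profiles, is scaled so the sensitivity matrix's $\lambda_2/\lambda_1$
  equals the requested ratio *exactly* (orthogonal rank-1 terms contribute
  independent singular values). The perturbation shapes are weighted by the
  profiles themselves — the inseparable interaction lives where sensitivity
  is high, which keeps the surface positive — and the spectral shape is even
  in density, so the construction preserves up/down symmetry; ratios beyond
  roughly 0.2 would force the surface negative and raise a construction
  error. An up/down gain multiplies the $\Omega < 0$ half for asymmetric
  variants (the ratio is enforced before the gain and is exact only at gain
  1). Sensitivity converts to thresholds by reciprocal mapping onto
  $[5, 100]$ percent depth.
* **Response model.** Detection follows the Weibull with the cell's
  ground-truth threshold and a common slope (human preset: $\beta = 3.6$,
  $\gamma = 0.05$, $\lambda = 0.02$, 15% catch trials, static noise 1–3 s;
  monkey preset: $\beta = 2.6$, $\gamma = 0.25$, $\lambda = 0.05$, 35%
  catch trials, 1.5–3.5 s). The lapse rates are the package's own choices
  (small, species-ordered); the other preset values follow the descriptive
  ranges above.
* **Latencies.** Hit latencies are log-normal, truncated to the hit window
  by inverse-CDF sampling, with median decreasing from 0.62 s near
  threshold toward 0.38 s at high relative depth (population median ~0.4 s
  at full depth); miss latencies fall beyond 0.8 s. The log-normal form and
  the chronometric dependence on depth are modeling choices — real reaction
  times also depend on density and velocity, which this generator does not
  model. Static-noise duration is drawn independently of everything else,
  so the latency-vs-duration independence the suite checks is true by
  construction.
* **What passing tests do and do not show.** The generator produces
  stationary observers with constant guess/lapse rates, no drift, no
  session structure beyond optional block labels, and exactly Weibull
  psychometric functions. Recovery results therefore validate the
  *pipeline* — that fitting, interpolation, SVD and the resampling
  machinery recover known structure at realistic trial counts — not any
  claim about real listeners.

## Problem sizes

Default test-suite sizes are chosen for a thorough but practical run: the
full-loop recovery uses the complete 8 × 11 grid at 16 repetitions per
depth (about 16,000 trials per replicate) over 10 replicates; coverage
studies use 40 replicates with 150 warm-started bootstrap refits;
permutation bounds use 2,000–10,000 permutations. The acceptance script
runs the staircase Monte Carlo at the full 100,000 simulations, the
flat-noise fourth moment over 100 one-second realizations, the
dynamic-ripple pool over 14 representative moving-ripple cells × 11 depths
× 5 phase seeds, and the permutation bound at 10,000 reshuffles.

## Known limitations

* Absolute sound-pressure calibration, loudspeaker equalization and
  free-field acoustics are out of scope; levels are digital RMS.
* The polynomial-surface MTF model and the visual contrast-sensitivity
  construction are out of scope; `svd_decompose()` and the statistics
  accept any externally supplied 2-D sensitivity matrix (for example a
  digitized spatiotemporal CSF) and analyze it identically.
* Near the separable boundary the inseparability index is non-negative
  with truth close to zero, and no bootstrap interval is well calibrated
  there: bias-corrected percentile intervals sit entirely above a
  less-noisy truth, and the basic interval over-corrects for replicates
  whose estimate happens to land near the truth. Interval-based recovery
  claims are therefore made at mid-range inseparability; at the boundary
  the package's tests assert absolute closeness of the index instead.
* Mutual-information estimates are plug-in values at a fixed binning; they
  are comparable within this package's conventions, not across estimators.
* The lapse-block generative model is a constant rate plus injected
  high-lapse blocks in tests; real attentional dynamics are richer.
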
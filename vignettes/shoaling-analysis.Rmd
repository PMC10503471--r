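---
title: "Shoaling kinematics, energetics and permutation inference: methods"
author: "shoalkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shoaling kinematics, energetics and permutation inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalkin)
```

# The problem

Small forage fish such as zebrafish (*Danio rerio*) shoal from the larval
stage onward, and both the quality of the collective formation and its
energetic cost change across ontogeny and with water temperature.
`shoalkin` implements the quantitative backbone of such a study as one
reusable, tested pipeline:

1. **midline kinematics** — tail-beat frequency (TBF), head and tail
   oscillation amplitudes, body-wave speed, wavelength, and maximum body
   curvature from digitized 200-point midlines;
2. **shoal metrics** — mean separation distance and position-switch
   rate from member trajectories;
3. **respirometry** — resting and peak post-exercise oxygen consumption
   rates (MO~2~), factorial scope, and Q~10~ thermal sensitivity;
4. **permutation inference** — one- and two-way ANOVA with permutation
   p-values, applied within each tested swimming speed;
5. a **synthetic-data generator** that emulates the full experimental
   design with known ground truth, so every estimator is validated by
   parameter recovery rather than by eye.

All distances are expressed in body lengths (BL), frequencies in Hz,
speeds in BL s^-1^, curvature in BL^-1^, and oxygen rates in
mg O~2~ L^-1^ h^-1^ for the five-fish shoal treated as the metabolic
unit (non-mass-adjusted; chamber volume and mass corrections are out of
scope, so rates are only ever compared within a stage or as ratios).

# The synthetic generator

## Traveling-wave swimmer

A fish midline is prescribed kinematically (no hydrodynamics — the
estimators measure kinematics, so a known kinematic truth is exactly
what is needed):

$$y(s, t) = A(s)\,\sin\!\big(2\pi(f t - s/\lambda) + \phi\big), \qquad
A(s) = A_h + (A_t - A_h)\,s^{p},$$

with $s \in [0,1]$ the arc-length position (head at $s=0$), $f$ the TBF,
$\lambda$ the body wavelength, and amplitudes growing from head
($A_h$, default 0.02 BL) to tail ($A_t$, default 0.10 BL) with exponent
$p$ (default 2). The wave travels rearward at $V = f\lambda$.
Ground truth recorded with every dataset includes $V$ and the analytic
maximum curvature of the noiseless wave (closed-form derivatives
evaluated on a dense grid). Digitizing error is i.i.d. Gaussian jitter
per point. The default phase starts the tail-tip signal on an upward
zero crossing, the way manually digitized beat cycles conventionally
begin and end on a reversal through the midline.

Frame counts follow `round(frame_rate * n_cycles / f) + 1`, so a
1-cycle, 10-Hz sequence at 1000 fps has exactly 101 frames. The Nyquist
guard (`frame_rate > 2 f`) and the minimum 11 midline points (needed
for interior three-point curvature at 5% BL spacing) are enforced at
parameter construction.

## Station-keeping shoal

Shoal members hold noisy stations on a collinear template along the flow
axis; for $n$ fish at spacing $d$ the mean pairwise distance is
$d(n+1)/3$, so the template spacing is chosen to hit the target mean
separation exactly. Position switches are adjacent-rank transpositions
at Poisson times (rate `switch_rate_per_s`), each completed within one
sample step; the realized event count is recorded as truth. Real shoals
are two-dimensional and correlated in time — the collinear template is a
deliberate simplification that makes the separation target and the rank
order exactly controllable. Tests passing on it demonstrate estimator
correctness, not robustness to geometry the model does not contain.

## Oxygen trace

Rest (1 h) declines linearly at the resting rate; recovery
(&ge; 2 h) declines at

$$r(t) = r_{rest} + (r_{peak} - r_{rest})\,e^{-t/\tau},$$

the standard exponentially decaying excess post-exercise oxygen
consumption (EPOC) shape with $\tau$ = 15 min by default — the analysis
only requires a known, monotonically decaying instantaneous rate with
its maximum at recovery onset. Concentration is integrated exactly
between 60-s samples; if it would cross the 2 mg L^-1^ hypoxia floor
the chamber is re-aerated and the sample labeled `reset` so slope
fitting can exclude it. Measurement noise is Gaussian per sample.

## Study design

The default design mirrors the experimental layout: 10 larval, 9
juvenile and 10 adult shoals of 5 fish, alternating 32/28 °C treatments
with recorded acclimation temperatures carried per shoal, stage-specific
speed lists (larvae 1.5/2.6/3/4/5; juveniles 1.5/2/3/4/5; adults
1/1.5/2/3/4/5 BL s^-1^), 1000-fps midlines, 60-s oxygen sampling.
Injected effects are the study's headline pattern: TBF
$= a + b\,v$ per stage (15 + 3v, 8 + 2v, 2 + 1.2v Hz for
larva/juvenile/adult), head amplitudes 0.04/0.03/0.02 BL, wavelengths
0.70/0.95/1.10 BL, separation 3.6/2.4/1.2 BL, switch rates
0.10/0.15/0.20 s^-1^, and metabolic thermal ratios set so the true
resting Q~10~ is 1.96/9.98/2.19 and the true peak Q~10~ is
1.03/1.37/2.53. Between-shoal variability is lognormal with CV 6%,
between-fish 3%, midline jitter 0.003 BL, trajectory jitter 0.02 BL,
oxygen noise 0.02 mg L^-1^ — values a respirometry/videography lab
would consider clean but realistic. `effects = "null"` collapses all
cells to one population for type-I-error studies.

# Estimators

## Cycle detection and TBF

Beat cycles are delimited by every second zero crossing of the
mean-subtracted tail-tip signal (mean lateral position of the last five
midline points), after light zero-phase smoothing; crossings closer
than 3 samples are merged. A sequence boundary counts as a delimiting
crossing when the signal there is within 10% of its amplitude of zero:
a sequence spanning whole cycles generically contains $2n$ interior
crossings and would otherwise always lose one cycle. TBF is the frame
rate divided by the frames per cycle, averaged across cycles; frame
quantization keeps the error under $1/(\text{frames per cycle})$ per
cycle, and averaging across ≥2 cycles keeps it under 1% at the study's
frame rates. A non-oscillating sequence raises a dedicated
`shoalkin_no_cycle` condition, distinct from invalid input, and
contributes no kinematics.

## Amplitudes

The head (tail) signal is the mean lateral position of the first (last)
five points. The default amplitude estimator fits a sinusoid at the
cycle frequency by least squares and reports its amplitude, averaged
across cycles and normalized by BL. For sinusoidal oscillation this
*is* the maximum lateral excursion about the time mean (half
peak-to-peak), and it is essentially unbiased under digitizing jitter.
The naive alternative — the raw maximum |excursion|, available as
`method = "peak"` — takes a maximum over ~10^2^ noisy frames and is
therefore systematically inflated by noise on the extremes: at 0.005 BL
point jitter the expected inflation of a 0.02 BL head amplitude is
roughly +25%, which would swamp the signal. The head:tail ratio is
reported alongside both raw amplitudes (field usage of "head:tail
amplitude" is ambiguous between the ratio and the head amplitude in BL,
so both are emitted and the ratio is labeled as such); a zero tail
amplitude yields a missing ratio with a warning.

## Curvature

Local curvature is the inverse circumradius of the circle through three
body points, $\kappa = 4\,\text{area}/(abc)$, computed per mm and
scaled by BL; collinear points give 0, coincident points are an error.
Maximum body curvature scans every frame of the cycle and every
arc-length station, with flanking points at 5% BL (nearest midline
index, 10 points on a 200-point midline; ties toward the head). The
chord estimator underestimates smoothly varying curvature slightly and
cannot see the final 5% of the tail, so it is validated one-sidedly
against the analytic truth ($\kappa_{est} \le \kappa_{true}$, within
10%). Being a maximum over $\sim 10^4$ (frame, station) evaluations of
a second-difference quantity, it is the one metric that is genuinely
noise-sensitive: point jitter of $\sigma$ contributes curvature noise
of order $\sigma/h^2$ per evaluation ($h$ = 5% BL), which inflates the
reported maximum several-fold at 0.003 BL jitter. Midline digitizers
smooth their output upstream, which is where this belongs; within the
pipeline the inflation is common to all groups (it depends on the
jitter, not the wave), so within-speed comparisons remain meaningful
while the absolute value under jitter should be read as an upper
envelope.

## Wave speed and wavelength

The body wave is measured from the *phase propagation of the
local-curvature wave*. At every station in the posterior 50% of the
body (the near-straight head region carries no usable curvature
signal), the curvature time series is harmonically fit at the TBF; the
station-wise phase $\varphi(s)$ of a traveling wave satisfies
$\varphi(s) = -k s + \psi(s)$, where
$\psi = \arg[(A k^2 - A'') + 2 i A' k]$ is the phase lead contributed
by the growing amplitude envelope. This term matters: the curvature
wave is locally advected at $2\pi f/(k - \psi')$, not at $f\lambda$,
and simply tracking curvature crests under the default envelope
underestimates wave speed by 4–17% depending on wavelength — an
estimator bias, not noise. $\psi$ is therefore estimated from the
measured lateral-amplitude envelope and removed; the envelope and its
derivatives come from a degree-4 polynomial least-squares fit, because
pointwise finite differences amplify digitizing noise in $A''$ by
$\mathcal{O}(h^{-2}) \sim 10^3$ and were measured to corrupt the
wavelength by +6% ± 6% at 0.005 BL jitter (the polynomial fit:
−1.6% ± 0.8%). The wavenumber is the amplitude-weighted least-squares
slope of the corrected unwrapped phase, iterated once;
$V = 2\pi f / k$ and $\lambda = V/f$ exactly, by construction. Inputs
without a coherent curvature wave (rigid translation, straight bodies,
fewer than 8 usable stations) return missing values with a warning.

## Shoal metrics

Mean separation distance is the per-fish mean distance to the other
$n-1$ members, averaged over fish and frames and normalized by the
shoal-mean body length; it provably equals the unordered all-pairs mean
and is invariant to rigid transforms and relabeling (both asserted by
brute force in the tests). Position switches are streamwise rank
inversions: positions are resampled at 10 Hz (raw 1000-fps rank order is
jitter-dominated), projected on the flow axis, and each pair's order is
tracked by a Schmitt trigger with a 0.05 BL hysteresis band — an order
flip is counted only when the trailing fish leads by more than the
band. The trigger formulation makes the hysteresis monotonicity
property (more hysteresis, never more switches) exact. The rank-inversion
definition of a "switch" and the 10-Hz default are documented choices;
sensitivity to the resampling rate can be probed through the
`sample_hz` argument rather than assumed.

## Respirometry

The resting rate is the OLS slope magnitude over the final 30 min of
the 1-h rest phase (the first half-hour absorbs handling transients); a
rising-O~2~ window warns and clamps to 0, and r² is reported for QC.
The peak recovery rate slides a 10-min window (≥ 10 samples at 60-s
sampling) across the recovery phase and returns the maximal slope
magnitude, skipping any window containing a re-aeration reset. Because
the window averages a decaying instantaneous rate, the estimate is
biased low, never high, relative to the true onset rate — with
$\tau = 15$ min the first-window OLS slope of a 0.8→2.5 trace is
2.03 — so windowed peaks are conservative and comparisons across
temperature (which share the bias) remain meaningful, though the
recovered peak Q~10~ absorbs part of the resting-rate sensitivity.
Factorial MO~2~ is peak/rest with a guarded zero denominator. Q~10~ is
$(K_2/K_1)^{10/(T_2-T_1)}$ on stage-level cell means, using recorded
mean treatment temperatures when available (nominal labels otherwise).
Note that swapping the rates alone inverts Q~10~, while relabeling
rates and temperatures together is an identity — the tests assert both.

## Permutation ANOVA

F statistics come from sequential (Type I) sums of squares via a QR
decomposition computed once per design (term order: stage, temperature,
interaction — fixed and documented; with balanced cells Type I equals
Type III). Sums of squares below 10^-12^ of the total are floored so
noise-free designs report exact 0 or an infinite marker instead of
ratios of rounding error. One-way tests permute raw labels, enumerating
all distinct assignments exhaustively when there are at most 20,000
(e.g. 252 for two groups of five — p-values are then exact), otherwise
using `m` seeded random permutations with
$p = (\#\{F^* \ge F\} + 1)/(m+1)$. Two-way terms use the
Freedman–Lane scheme: permute the residuals of the reduced model
excluding the tested term (the other main effect for a main effect;
both main effects for the interaction), add back the reduced fit, and
recompute that term's sequential F from the full model. `m` is fixed
(default 4999) with an explicit seed — adaptive permutation counts are
reproducibility-hostile. Within-speed sweeps apply no multiple-testing
correction to the significance flags (matching the study's reporting),
but a Benjamini–Hochberg column is emitted alongside for transparency;
speeds where a tested factor has a single level, or any tested cell has
fewer than two shoals, are skipped with a logged reason.

# Numerical and design choices

* **Determinism.** Every stochastic component takes an explicit seed;
  child seeds are derived arithmetically (kept within 32-bit range), so
  a (design, seed) pair regenerates byte-identical data bundles and a
  (config, seed) pair reproduces every pipeline output hash-for-hash.
* **Coordinates** are stored in mm and normalized to BL at computation
  time only; per-BL outputs are invariant to co-scaling coordinates and
  BL, and all metrics are invariant to rigid transforms.
* **Degenerate inputs** have defined behavior throughout: no-cycle
  sequences (dedicated condition), zero tail amplitude (missing ratio,
  warning), no curvature wave (missing wave metrics, warning), empty
  Q~10~ cells (missing, warning), zero resting rate (missing factorial,
  warning), rank-deficient designs (error).
* **Problem sizes.** The validation suite runs the full 29-shoal
  design end-to-end once, parameter-recovery grids of 9 noiseless plus
  100 jittered midline sequences, 500-seed Poisson-recovery and
  1000-dataset type-I-error simulations — sizes chosen to give
  Monte-Carlo standard errors comfortably inside the asserted
  tolerances while keeping a laptop run in minutes.

# What passing tests do and do not show

The generator produces clean sinusoidal waves, stationary collinear
shoals, and exactly exponential EPOC decay. Recovery of its parameters
demonstrates that the estimators are correct and appropriately robust
to digitizing noise; it does not demonstrate robustness to burst-and-
coast swimming, body-shape change across ontogeny, two-dimensional
shoal geometry, background respiration, or activity in the respirometer
— all properties real data have and the model deliberately omits.
Applying the pipeline to real deposited data additionally requires
matching that study's (unreported) slope windows before quantitative
agreement of Q~10~ values can be expected; the provided-data mode and
the schema of the readers exist for exactly that use.
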
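---
title: "The dual-TR ghost: model, assembly schemes, and metrics"
author: "dualTRghost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual-TR ghost: model, assembly schemes, and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualTRghost)
```

## The artifact mechanism

Time-of-flight MR angiography of the lower extremities at 7 T needs venous
saturation pulses, but applying the saturation block before *every*
excitation makes cardiac-gated acquisitions too slow. Applying it before
every *second* excitation halves that cost — and makes the effective
repetition time alternate between a short interval TR1 (excitation to
saturation block) and a longer one TR2. In the spoiled gradient-echo steady
state the two alternating recovery intervals produce two different signal
amplitudes, so consecutive phase-encode lines are acquired with a
line-to-line modulation of period 2. A periodic modulation along ky aliases
into a replica of the object shifted by exactly half the field of view in
the phase-encode direction: a ghost, attenuated relative to the familiar
every-second-line-missing case because the weak signal is reduced, not
absent.

This package simulates that mechanism and the candidate countermeasures on
a synthetic phantom, entirely deterministically.

## Signal model

With perfect spoiling, the longitudinal magnetization before the two
excitations of the alternating cycle has a closed-form fixed point. For
flip angles $\theta_1$ (the excitation after the TR2 recovery) and
$\theta_2$, with $E_i = e^{-TR_i/T_1}$:

$$S_1 = M_0\,\frac{1 + E_2\left((1-E_1)\cos\theta_2 - 1\right)}
  {1 - \cos\theta_1\cos\theta_2\,E_1E_2}\;e^{-TE/T_2^*}\sin\theta_1,$$

and $S_2$ with the indices exchanged
(`steadyStateSignalsGeneral()`). Setting $\theta_1=\theta_2$ gives the
single-angle pair (`steadyStateSignals()`), and TR1 = TR2 collapses both to
the Ernst signal (`ernstSignal()`). The labels *strong* and *weak* are
derived — the signal after the longer recovery is the strong one — so they
do not flip when the two TRs are exchanged; the positional values `s1`,
`s2` are returned alongside.

Because the closed form is the package's core claim, it is cross-checked
against an independent oracle, `blochSteadyState()`, which iterates the
two-pulse cycle numerically (multiply by $\cos\alpha$ at each pulse, relax
toward $M_0$ over each interval) until it reaches a fixed point. The test
suite requires agreement below $10^{-10}$ relative over a grid of angle
pairs. The iteration's convergence is geometric with ratio
$\cos\theta_1\cos\theta_2 E_1E_2$, slowest at small angles, which is why
the default budget is generous (`max_cycles = 2e5`).

Assumptions worth keeping in mind: ideal spoiling (no residual transverse
coherence), no off-resonance or slice-profile effects, no magnetization
transfer from the saturation pulse, and real non-negative magnitude
signals ($\sin\theta \ge 0$ on $[0^\circ, 180^\circ]$).

## The synthetic phantom

`makeGradientFlipMap()` builds the standard object: a centered circle of
radius `radius_frac * n` inside which the flip angle runs linearly from 1°
to 90° along the readout axis, and exactly 0° outside. It emulates the one
feature of 7 T imaging that matters for this artifact — a transmit field
sweeping the local flip angle over a wide range — and nothing else: no
anatomy, no vessels or flow, no receive-coil weighting, no noise. Passing
tests therefore validate the artifact *mechanism* and the relative merits
of the correction schemes, not their performance on noisy in-vivo data
(where, for instance, the center-line correction also amplifies noise).

Defaults: N = 256 (keeps every run in the hundreds of milliseconds;
the acceptance checks are repeated at N = 320, the matrix of a typical
phantom measurement, to confirm the bounds are not geometry artifacts),
`radius_frac = 0.22` so the half-FOV ghost region is strictly disjoint
from the phantom (the constructor refuses radii at or above N/4), and the
gradient along the readout axis so each readout column carries one flip
angle and every metric curve bins exactly by column with no
interpolation. The flip angle is kept continuous rather than quantized to
whole degrees — the signal equations are smooth and quantization would add
artificial staircase edges.

`simulateImagePair()` evaluates the signal pair pixelwise. `M0` defaults
to 1 and cancels from every reported metric, which are all ratios.

## Fourier convention and the assembly schemes

`forwardKspace()`/`reconstructImage()` use the centered, unitary transform:
ky and kx run over $[-N/2, N/2-1]$ with DC at index 0, and Parseval's
identity holds exactly, so magnitude metrics do not depend on the
convention. Reconstruction returns the pixelwise magnitude, as in standard
MR practice.

Four assemblies model the acquisition variants; each records per line
whether it came from the weak-signal transform:

* **interleave** — even ky (including DC) from the strong image, odd ky
  from the weak one. This is the artifact-generating acquisition. The
  parity assignment gives the strong signal the contrast-determining
  center line, matching a sequence in which the doubly acquired center
  keeps the stronger acquisition; reversing the parity only shifts the
  ghost's sign pattern and changes no magnitude metric. For a homogeneous
  phantom the ghost-to-source ratio has the closed form
  $(S_1-S_2)/(S_1+S_2)$, which the tests verify to $10^{-10}$.
* **reorder** — weak lines moved to the outer ky half, strong lines fill
  the central half. The period-2 modulation disappears; what remains is a
  step in k-space amplitude at $\pm N/4$, i.e. a mild high-frequency
  attenuation of the *difference* image, visible as ringing.
  `inverted = TRUE` swaps the roles (a control that keeps the ringing but
  lowers the signal).
* **zero_fill** — strong central half, zeros outside: the classic
  truncation scenario whose Gibbs ringing bounds the reordering ringing
  from above.
* **strong_only / weak_only** — artifact-free references.

`acquisitionOrder()` generates the scanner-facing chronological ordering
for the reordering scheme: both blocks ascending, interleaved weak-first,
which preserves the strict alternation of the two effective TRs and
reproduces the characteristic prefix (−32, −16, −31, −15 for N = 64). One
subtlety is documented rather than hidden: with strict alternation and
ascending blocks the DC line lands at position N/2 + 2 — one TR pair past
the exact midpoint. Placing it exactly centrally would require two
consecutive same-TR acquisitions, which the saturation-every-second-TR
scheme cannot produce; "acquired in the middle" is therefore true to
within one TR pair, and the tests assert exactly that. The simulated
images are independent of this ordering because the steady state is
time-invariant.

## Center-line correction factor

The correction approach rescales every weak line by a factor estimated
from the k-space center line only (which a sequence can afford to acquire
twice, once per TR). `estimateCorrectionFactor()` offers three estimators:

* `dc_ratio` (default): the magnitude ratio of the two center lines' DC
  samples — equivalently the ratio of the two images' total signal.
* `l1_ratio`: ratio of the summed magnitudes of the two center lines.
* `masked_pointwise_mean`: mean pointwise ratio over samples above a
  relative magnitude threshold.

The default deserves a justification. On a sharp-edged numerical phantom
the high-spatial-frequency content of the center line is dominated by the
support edge, which both images share, so pointwise or L1-norm averages
are dragged toward 1 (about 0.98–1.00 under the standard conditions) and
the correction collapses to almost nothing. The DC sample isolates the
contrast-determining component; under the standard conditions it gives
0.930, which equals the signal-weighted mean of $S_2(\theta)/S_1(\theta)$
over the phantom. With that factor the corrected ghost curve behaves as
the mechanism predicts: it is nulled where
$S_2(\theta)/S_1(\theta)$ equals the factor — at about 40°, close to the
signal-weighted mean flip angle — falls below the uncorrected curve above
a crossover at $\sqrt{f}$-matching flip (about 29°), and lifts the
interior signal by $\tfrac12(1/f - 1) \approx 3.8\%$ at low flip angles.
For a homogeneous phantom all three estimators coincide and the exact
factor nulls the ghost completely (verified to $10^{-10}$).

## Flip-angle adaptation

`solveAdaptedFlip()` solves $S_1(\theta_1, \theta_2) = S_2$ for
$\theta_1 \in (0, \theta_2]$. The difference is negative as
$\theta_1 \to 0$ and non-negative at $\theta_1 = \theta_2$, so the root is
bracketed and handed to `uniroot` (tolerance $10^{-12}$ degrees; the
residual signal difference at the returned root is checked against a
$10^{-10} M_0$ budget and against an exhaustive 0.001° grid in the
tests). The resulting ratio $\theta_1/\theta_2$ is applied to the whole
flip map as a single multiplicative scale — the way a transmit-voltage
change acts physically. That global application is also why adaptation
fails on an inhomogeneous map: the condition $S_1 = S_2$ holds only at the
nominal angle (for 70°, the solved companion is 58.84°, scale 0.841), the
ghost is nulled only in the bins near it, and below a crossover around 47°
the adapted acquisition is actually *worse* than the uncorrected one. A
per-pixel application would null the artifact everywhere but corresponds
to no physically realizable excitation. Raising $\theta_2$ instead of
lowering $\theta_1$ would equalize the signals too, at higher RF power
deposition; it is not implemented.

## Metrics and their windows

All curve metrics bin by readout column (exact under the standard
geometry) and are invariant under global intensity scaling:

* `ghostRatioCurve()` — mean magnitude over the column's ghost pixels
  (mask shifted by N/2 with wraparound) over mean magnitude in the mask,
  in percent.
* `signalRatioCurve()` — column-mean ratio of two images inside the mask.
* `ringingAmplitudeCurve()` — half peak-to-peak range of
  image/reference − 1 per column, inside the mask eroded by 3 px by
  default. The erosion excludes the immediate edge overshoot so the value
  reflects interior oscillation.
* `oscillationVsMean()` — max |image − reference| over the mask eroded by
  1 px, normalized by the *mean* reference signal over the whole mask.

Two ringing normalizations coexist deliberately. The per-pixel relative
amplitude is the right scale for "how visible is the ripple on the local
signal", and with an edge-inclusive window (erosion 1 px) it reproduces
the classic truncation hierarchy: the zero-filled image rings at up to
about 5.7% (the Gibbs regime — the half peak-to-peak of the Dirichlet
partial sum, roughly (8.9% + 4.9%)/2 of the local step, independent of
flip angle), while reordering replaces the full signal step by the much
smaller strong–weak difference and stays near 0.05% at 15° and 1.6% at
90°. The mean-normalized oscillation answers a different question — "how
big is the ripple against the object's average brightness" — and is
reported alongside; its global maximum is dominated by the columns near
the Ernst angle (about 5°, where the local signal is several times the
phantom mean), so it is only meaningful per flip bin, and the summaries
state the window used.

`crossoverFlip()` locates the largest flip angle at which one curve stops
exceeding another, by linear interpolation between bins;
`estimateFlipMap()` inverts the signal ratio pixelwise with the AFI
approximation $\cos\theta = (rn-1)/(n-r)$, $r = S_\mathrm{weak}/S_\mathrm{strong}$,
$n = TR_2/TR_1$, which is excellent here (TR ≪ T1; the tests require
recovery within 0.5° for flip angles of 10° and above, and the observed
worst error is about 0.05°).

## The standard sweep

`runStandardSweep()` runs everything under the standard conditions
(TR1/TR2 = 4/7 ms, T1 = 1420 ms, T2* = 450 ms, TE = 3 ms, nominal
adaptation angle 70°) and reports nine reconstructions with their curves
and scalar summaries. Representative outcomes, all recomputed by the test
suite and the acceptance script rather than stored: the uncorrected ghost
grows monotonically to about 27% of the interior signal at 90°; reordering
suppresses it to at most 0.15% while tracking the strong-only image within
0.7%; the corrected interleave bottoms out near 40° and crosses the
uncorrected curve near 29°; adaptation at 70° keeps the ghost under 8.7%
below 70° with a crossover near 47°. Ghost-ratio curves for T1 of 700,
1420 and 2840 ms differ by well under 2 percentage points pointwise,
confirming that the artifact level depends on the TR ratio and flip angle
but hardly on T1 while TR ≪ T1.

Problem sizes were chosen for comfortable interactive use: the full
N = 256 sweep takes well under a second, the complete test suite a few
seconds, and the N = 320 robustness repeat adds about the same again.

## Known limitations

Only the steady state is modeled: approach-to-steady-state transients,
flow, pulsatility, cardiac gating, parallel imaging, multi-transmit mode
combination and noise are all outside scope, and several of them decide
whether a scheme is *usable* in vivo (reordering, for example, spreads the
central k-space lines over the whole acquisition and so becomes sensitive
to pulsatile flow — a property this simulation cannot show). The
correction factor is a single global scalar; for inhomogeneous objects the
true line-to-line ratio oscillates, and only a pointwise correction — which
would require acquiring everything twice — could do better.
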
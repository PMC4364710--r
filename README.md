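# dualTRghost

Deterministic simulation of the half-FOV ghost artifact produced by **two
alternating effective repetition times** in a saturated turbo-FLASH
(spoiled gradient-echo) sequence — and of the sequence variants proposed to
suppress it.

## The problem

Non-enhanced time-of-flight MR angiography of the lower extremities at 7 T
suppresses venous signal with saturation RF pulses. Applying the saturation
block before only every *second* excitation keeps cardiac-gated
acquisitions fast, but it makes the recovery interval alternate between a
short TR1 and a longer TR2. In the spoiled-GRE steady state the two
intervals yield two different signal amplitudes,

$$S_1 = M_0\,\frac{1 + E_2\big((1-E_1)\cos\theta - 1\big)}
  {1-\cos^2\theta\,E_1E_2}\,e^{-TE/T_2^*}\sin\theta,
  \qquad E_i = e^{-TR_i/T_1},$$

(and $S_2$ with TR1/TR2 exchanged), so every second phase-encode line is
slightly weaker. That period-2 modulation aliases into a ghost of the
object shifted by half the field of view along phase encode. The package
implements, for people working on sequence design and artifact analysis:

* the dual-TR steady-state signal model, its two-flip-angle generalization,
  and an independent Bloch fixed-point oracle;
* synthetic flip-angle phantoms (circular support, linear 1°–90° gradient)
  emulating the inhomogeneous 7 T transmit field;
* centered unitary FFTs and the k-space assembly variants: line
  interleaving (the artifact), center-line correction factor, phase-encode
  reordering (weak lines to the outer k-space), inverted reordering, zero
  filling;
* the flip-angle adaptation solver ($S_1 = S_2$ for $\theta_1$ given
  $\theta_2$) and AFI-style flip-angle map recovery;
* artifact metrics: ghost-to-source curves, interior signal ratios,
  ringing amplitudes, Gibbs-style oscillation, crossover angles.

Everything is pure computation on synthetic inputs; no scanner data and no
randomness anywhere.

## Worked example

```r
library(dualTRghost)

p <- SequenceParams()        # TR1/TR2 = 4/7 ms, T1 = 1420 ms, T2* = 450 ms, TE = 3 ms
s <- steadyStateSignals(70, p)
100 * (s$s_strong - s$s_weak) / (s$s_strong + s$s_weak)
#> 13.36    # ghost-to-source % for a homogeneous 70-degree object

solveAdaptedFlip(70, p)
#> FlipAdaptation: theta1(70 deg) = 58.8428 deg (scale 0.840611), |S1-S2| = 1.39e-17

res <- runStandardSweep(sweepConfig())
res
#> SweepResult: 256 x 256 grid, 9 variants, 2112 curve rows
#>   max ghost: interleave 26.62%, reorder 0.1532%
#>   correction factor 0.9301, adapted theta1(70) scale 0.8406
res$summaries$argmin_corrected_ghost
#> 40.36    # flip angle (deg) where the corrected ghost curve bottoms out
```

Reading: on the 1°–90° gradient phantom the uncorrected interleaved
acquisition ghosts at up to 26.6% of the interior signal, reordering
suppresses that to 0.15% (trading it for sub-percent interior ringing),
and the center-line correction factor (0.930) nulls the ghost only near
40°, the signal-weighted mean flip angle. `writeReport(res, "out")` writes
the curves as CSV and the summaries as JSON; a thin CLI over the same
functions lives at `inst/scripts/dualtr.R` (subcommands `sweep`,
`signals`, `adapt`, `order`, `afi`).

The methods vignette (`vignettes/dual-tr-ghost-model.Rmd`) documents the
model assumptions, the assembly schemes, the correction-factor estimator,
the metric windows, and known limitations.

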
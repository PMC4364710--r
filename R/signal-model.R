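# Closed-form steady-state signals for spoiled gradient-echo imaging with
# two alternating repetition intervals, the single-TR (Ernst) limit, an
# independent Bloch fixed-point iteration, and the AFI flip-angle inversion.

# Core evaluator shared by the one- and two-angle interfaces. Vectorized over
# the angles (recycled to a common length); returns both the positional
# signals (s1 = excitation following the TR2 recovery, s2 = following TR1)
# and the derived strong/weak labels (strong = after the longer recovery).
.dualTRSignals <- function(theta1_deg, theta2_deg, p) {
  stopifnot(is(p, "SequenceParams"))
  validObject(p)
  nl <- max(length(theta1_deg), length(theta2_deg))
  theta1_deg <- rep_len(theta1_deg, nl)
  theta2_deg <- rep_len(theta2_deg, nl)
  e1 <- exp(-p@tr1 / p@t1)
  e2 <- exp(-p@tr2 / p@t1)
  ete <- exp(-p@te / p@t2star)
  c1 <- cos(.deg2rad(theta1_deg))
  c2 <- cos(.deg2rad(theta2_deg))
  den <- 1 - c1 * c2 * e1 * e2
  s1 <- p@m0 * (1 + e2 * ((1 - e1) * c2 - 1)) / den * ete *
    sin(.deg2rad(theta1_deg))
  s2 <- p@m0 * (1 + e1 * ((1 - e2) * c1 - 1)) / den * ete *
    sin(.deg2rad(theta2_deg))
  if (p@tr2 >= p@tr1) {
    list(s_strong = s1, s_weak = s2, s1 = s1, s2 = s2)
  } else {
    list(s_strong = s2, s_weak = s1, s1 = s1, s2 = s2)
  }
}

#' Dual-TR spoiled gradient-echo steady-state signals
#'
#' Closed-form steady-state signal amplitudes of a perfectly spoiled
#' gradient-echo sequence whose repetition interval alternates between
#' `tr1_ms` and `tr2_ms` (both excitations with the same flip angle
#' `theta_deg`). The excitation that follows the *longer* recovery interval
#' yields the stronger signal; the line-to-line alternation between the two
#' values is what produces the half-FOV ghost when the lines are interleaved
#' in k-space.
#'
#' For a flip angle theta, with E_i = exp(-TR_i/T1):
#' \deqn{S_1 = M_0 \frac{1 + E_2((1-E_1)\cos\theta - 1)}
#'   {1 - \cos^2\theta\, E_1 E_2} e^{-TE/T_2^*} \sin\theta}
#' and S_2 with TR1 and TR2 exchanged in the numerator. `s1`/`s2` follow
#' this positional convention (S1 = excitation after the TR2 recovery);
#' `s_strong`/`s_weak` are the same two numbers labelled by the recovery
#' length, so they are invariant under exchanging the two TRs.
#'
#' @param theta_deg flip angle(s) in degrees, in \[0, 180\]. Values above 90
#'   degrees are accepted but outside the intended operating range of the
#'   sequence.
#' @param p a [SequenceParams-class] object.
#'
#' @return A list with numeric vectors `s_strong`, `s_weak`, `s1`, `s2`.
#' @examples
#' steadyStateSignals(90, SequenceParams())
#' @seealso [steadyStateSignalsGeneral()] for different flip angles per
#'   excitation, [blochSteadyState()] for the iterative oracle.
#' @export
steadyStateSignals <- function(theta_deg, p = SequenceParams()) {
  .checkAngles(theta_deg, "theta_deg")
  .dualTRSignals(theta_deg, theta_deg, p)
}

#' Generalized dual-TR signals with two flip angles
#'
#' Generalization of [steadyStateSignals()] to a different flip angle for
#' each of the two alternating excitations: `theta1_deg` for the excitation
#' following the TR2 recovery and `theta2_deg` for the one following TR1.
#' Setting the two angles equal recovers the single-angle formulas. This is
#' the model underlying flip-angle adaptation: the condition S1 = S2 can be
#' met by lowering theta1 below theta2 (see [solveAdaptedFlip()]).
#'
#' \deqn{S_1 = M_0 \frac{1 + E_2((1-E_1)\cos\theta_2 - 1)}
#'   {1 - \cos\theta_1 \cos\theta_2\, E_1 E_2} e^{-TE/T_2^*} \sin\theta_1}
#' and S2 with the indices exchanged.
#'
#' @param theta1_deg,theta2_deg flip angles in degrees, in \[0, 180\];
#'   recycled to a common length.
#' @inheritParams steadyStateSignals
#' @return A list with numeric vectors `s_strong`, `s_weak`, `s1`, `s2`.
#' @export
steadyStateSignalsGeneral <- function(theta1_deg, theta2_deg,
                                      p = SequenceParams()) {
  .checkAngles(theta1_deg, "theta1_deg")
  .checkAngles(theta2_deg, "theta2_deg")
  .dualTRSignals(theta1_deg, theta2_deg, p)
}

#' Bloch fixed-point oracle for the dual-TR steady state
#'
#' Independent numerical check of the closed-form signal model: iterates the
#' two-pulse cycle with perfect spoiling until the longitudinal magnetization
#' reaches a fixed point. After each excitation with angle alpha the
#' longitudinal magnetization is multiplied by cos(alpha); over the following
#' interval TR it relaxes toward M0 as Mz -> M0 + (Mz - M0) exp(-TR/T1).
#' Each returned signal is the Mz just before its pulse, times the sine of
#' the pulse angle, times exp(-TE/T2*). No closed-form expression is used
#' anywhere, so agreement with [steadyStateSignalsGeneral()] is a genuine
#' cross-validation.
#'
#' @param theta1_deg,theta2_deg scalar flip angles in degrees (theta1 is the
#'   pulse following the TR2 recovery, as in the closed form).
#' @inheritParams steadyStateSignals
#' @param tol relative tolerance on the per-cycle change of the pre-pulse
#'   magnetizations.
#' @param max_cycles iteration budget; exceeded budget is an error.
#' @return A list with `s_strong`, `s_weak`, `s1`, `s2` (scalars) and
#'   `cycles`, the number of cycles used.
#' @export
blochSteadyState <- function(theta1_deg, theta2_deg, p = SequenceParams(),
                             tol = 1e-13, max_cycles = 200000L) {
  .checkScalar(theta1_deg, "theta1_deg", 0, 180)
  .checkScalar(theta2_deg, "theta2_deg", 0, 180)
  .checkScalar(tol, "tol", 0, Inf, strict_lower = TRUE)
  stopifnot(is(p, "SequenceParams"))
  validObject(p)
  a1 <- .deg2rad(theta1_deg)
  a2 <- .deg2rad(theta2_deg)
  e1 <- exp(-p@tr1 / p@t1)
  e2 <- exp(-p@tr2 / p@t1)
  ete <- exp(-p@te / p@t2star)
  mz <- p@m0                 # pre-pulse-1 magnetization, initial guess
  mzb1_old <- Inf
  mzb2_old <- Inf
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    if (cycles > max_cycles)
      .stopf("Bloch iteration did not converge within %d cycles (tol = %g)",
             max_cycles, tol)
    mzb1 <- mz
    mz <- p@m0 + (mz * cos(a1) - p@m0) * e1   # pulse 1, relax over TR1
    mzb2 <- mz
    mz <- p@m0 + (mz * cos(a2) - p@m0) * e2   # pulse 2, relax over TR2
    ref <- max(abs(mzb1), abs(mzb2), p@m0 * 1e-12)
    if (abs(mzb1 - mzb1_old) <= tol * ref &&
        abs(mzb2 - mzb2_old) <= tol * ref) break
    mzb1_old <- mzb1
    mzb2_old <- mzb2
  }
  s1 <- mzb1 * sin(a1) * ete
  s2 <- mzb2 * sin(a2) * ete
  out <- if (p@tr2 >= p@tr1) list(s_strong = s1, s_weak = s2)
         else list(s_strong = s2, s_weak = s1)
  c(out, list(s1 = s1, s2 = s2, cycles = cycles))
}

#' Single-TR spoiled gradient-echo (Ernst) signal
#'
#' The classic spoiled-GRE steady-state signal
#' \eqn{M_0 (1-E)\sin\theta / (1 - E\cos\theta) \cdot e^{-TE/T_2^*}} with
#' \eqn{E = e^{-TR/T_1}}. Serves as the single-TR limit of the dual-TR
#' model: when TR1 = TR2 = `tr_ms`, both alternating signals collapse to
#' this value.
#'
#' @param theta_deg flip angle(s) in degrees.
#' @param tr_ms repetition time in ms.
#' @param p a [SequenceParams-class]; only `t1_ms`, `t2star_ms`, `te_ms` and
#'   `m0` are used.
#' @return Numeric vector of signal amplitudes.
#' @export
ernstSignal <- function(theta_deg, tr_ms, p = SequenceParams()) {
  .checkAngles(theta_deg, "theta_deg")
  .checkScalar(tr_ms, "tr_ms", 0, Inf, strict_lower = TRUE)
  stopifnot(is(p, "SequenceParams"))
  e <- exp(-tr_ms / p@t1)
  th <- .deg2rad(theta_deg)
  p@m0 * (1 - e) * sin(th) / (1 - e * cos(th)) * exp(-p@te / p@t2star)
}

#' Ernst angle for a given TR
#'
#' @inheritParams ernstSignal
#' @return The signal-maximizing flip angle `acos(exp(-TR/T1))` in degrees.
#' @export
ernstAngle <- function(tr_ms, p = SequenceParams()) {
  .checkScalar(tr_ms, "tr_ms", 0, Inf, strict_lower = TRUE)
  acos(exp(-tr_ms / p@t1)) * 180 / pi
}

#' AFI flip-angle inversion
#'
#' Recovers the local flip angle from the two dual-TR steady-state signals
#' using the actual flip angle imaging (AFI) approximation: with
#' r = s_weak / s_strong and n = tr2_ms / tr1_ms,
#' \deqn{\theta = \arccos\frac{rn - 1}{n - r},}
#' valid when both TRs are much shorter than T1. The argument is clamped to
#' \[-1, 1\] against rounding.
#'
#' @param s_strong,s_weak signal amplitudes (vectors recycled to a common
#'   length); `s_strong` is the signal after the longer recovery, so
#'   `s_weak <= s_strong` is required (up to rounding).
#' @param tr1_ms,tr2_ms the short and long repetition times; `tr2_ms` must
#'   exceed `tr1_ms`.
#' @return Flip angle(s) in degrees.
#' @examples
#' s <- steadyStateSignals(30, SequenceParams())
#' afiFlipAngle(s$s_strong, s$s_weak, 4, 7)
#' @export
afiFlipAngle <- function(s_strong, s_weak, tr1_ms, tr2_ms) {
  .checkScalar(tr1_ms, "tr1_ms", 0, Inf, strict_lower = TRUE)
  .checkScalar(tr2_ms, "tr2_ms", 0, Inf, strict_lower = TRUE)
  if (tr2_ms <= tr1_ms)
    .stopf("'tr2_ms' must exceed 'tr1_ms' (TR ratio n = tr2/tr1 must be > 1)")
  if (!is.numeric(s_strong) || !is.numeric(s_weak))
    .stopf("signals must be numeric")
  if (any(!is.finite(s_strong)) || any(!is.finite(s_weak)))
    .stopf("signals must be finite")
  if (any(s_strong <= 0))
    .stopf("'s_strong' must be strictly positive (undefined signal ratio)")
  if (any(s_weak < 0))
    .stopf("'s_weak' must be non-negative")
  r <- s_weak / s_strong
  if (any(r > 1 + 1e-9))
    .stopf("'s_weak' exceeds 's_strong': the AFI inversion requires r = s_weak/s_strong <= 1")
  r <- pmin(r, 1)
  n <- tr2_ms / tr1_ms
  arg <- pmin(1, pmax(-1, (r * n - 1) / (n - r)))
  acos(arg) * 180 / pi
}
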
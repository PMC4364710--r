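# Flip-angle adaptation: solve S1 = S2 for theta1 given theta2, and apply
# the resulting scale to a whole flip map as a transmit-voltage change would.

#' Solve the flip-angle adaptation condition S1 = S2
#'
#' For a fixed nominal angle `theta2_deg`, finds the companion angle theta1
#' in (0, theta2\] at which the two alternating steady-state signals are
#' equal, which precludes the ghost artifact at that flip angle. The signal
#' difference S1(theta1) - S2(theta1) is negative as theta1 -> 0 and
#' non-negative at theta1 = theta2 (the strong signal dominates at equal
#' angles), so the root is bracketed and refined with [stats::uniroot()].
#' If no sign change exists in the bracket (degenerate parameter sets), the
#' boundary minimizer is returned with `bracketed = FALSE`.
#'
#' Adaptation is only meaningful below 90 degrees and is negligible at small
#' angles, where the two signals are nearly equal anyway.
#'
#' @param theta2_deg nominal flip angle in degrees, in (0, 90\].
#' @param p a [SequenceParams-class].
#' @param tol root-finding tolerance on theta1 (degrees).
#' @return A [FlipAdaptation-class].
#' @examples
#' solveAdaptedFlip(70)
#' @export
solveAdaptedFlip <- function(theta2_deg, p = SequenceParams(), tol = 1e-12) {
  .checkScalar(theta2_deg, "theta2_deg", 0, 90, strict_lower = TRUE)
  .checkScalar(tol, "tol", 0, Inf, strict_lower = TRUE)
  stopifnot(is(p, "SequenceParams"))
  validObject(p)
  if (p@tr1 == p@tr2)   # symmetric TRs: signals are equal at equal angles
    return(new("FlipAdaptation", theta2 = theta2_deg, theta1 = theta2_deg,
               scale = 1, residual = 0, bracketed = TRUE))
  g <- function(th1) {
    s <- steadyStateSignalsGeneral(th1, theta2_deg, p)
    s$s1 - s$s2
  }
  lo <- min(1e-6, theta2_deg / 2)
  if (g(lo) >= 0 || g(theta2_deg) <= 0) {
    # no interior sign change: return whichever boundary has the smaller
    # absolute difference
    cand <- c(lo, theta2_deg)
    th1 <- cand[which.min(abs(vapply(cand, g, numeric(1))))]
    warning("no sign change of S1 - S2 in (0, theta2]; returning the boundary minimizer")
    return(new("FlipAdaptation", theta2 = theta2_deg, theta1 = th1,
               scale = th1 / theta2_deg, residual = abs(g(th1)),
               bracketed = FALSE))
  }
  root <- stats::uniroot(g, c(lo, theta2_deg), tol = tol)
  new("FlipAdaptation", theta2 = theta2_deg, theta1 = root$root,
      scale = root$root / theta2_deg, residual = abs(g(root$root)),
      bracketed = TRUE)
}

#' Image pair under flip-angle adaptation
#'
#' Solves the adaptation condition at the nominal angle and applies the
#' resulting ratio theta1/theta2 as a single multiplicative scale to the
#' whole flip map, then simulates the image pair. Global scaling is how a
#' transmit-voltage change acts physically, and it is also why adaptation
#' can null the artifact only at the one flip angle it was solved for: at
#' every other local flip angle the scaled pair of angles no longer
#' satisfies S1 = S2.
#'
#' @param fm a [FlipMap-class].
#' @param theta2_nominal_deg the flip angle the adaptation is solved for
#'   (degrees, in (0, 90\]).
#' @param p a [SequenceParams-class].
#' @return An [ImagePair-class] with `theta1Scale` set to the solved scale.
#' @seealso [solveAdaptedFlip()]
#' @export
adaptedImagePair <- function(fm, theta2_nominal_deg = 70,
                             p = SequenceParams()) {
  ad <- solveAdaptedFlip(theta2_nominal_deg, p)
  simulateImagePair(fm, p, theta1_scale = ad@scale)
}
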
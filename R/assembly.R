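# k-space assembly schemes: line interleaving (the artifact mechanism),
# phase-encode reordering, zero filling, the center-line correction factor,
# and the scanner-facing acquisition-order generator.

.checkSameShape <- function(k_strong, k_weak) {
  stopifnot(is(k_strong, "KSpaceGrid"), is(k_weak, "KSpaceGrid"))
  if (!identical(dim(k_strong@data), dim(k_weak@data)))
    .stopf("k-space grids must share dimensions (got %d and %d)",
           nrow(k_strong@data), nrow(k_weak@data))
  nrow(k_strong@data)
}

.newAssembly <- function(data, weak, scheme, factor = NA_real_) {
  new("KSpaceAssembly", kspace = new("KSpaceGrid", data = data),
      weakLines = weak, scheme = scheme, correctionFactor = factor)
}

#' Interleaved dual-TR k-space (the artifact-generating assembly)
#'
#' Models the standard acquisition with a saturation block every second TR:
#' phase-encode lines with even ky (including the DC line) are taken from
#' the strong-signal k-space and lines with odd ky from the weak-signal
#' k-space. The resulting line-to-line signal modulation of period 2 creates
#' a replica of the object shifted by half the field of view along phase
#' encode — the ghost artifact.
#'
#' @param k_strong,k_weak [KSpaceGrid-class] transforms of the
#'   strong-signal and weak-signal images.
#' @return A [KSpaceAssembly-class] with scheme `"interleave"`.
#' @export
assembleInterleaved <- function(k_strong, k_weak) {
  n <- .checkSameShape(k_strong, k_weak)
  ky <- kyIndex(n)
  weak <- ky %% 2L == 1L
  data <- k_strong@data
  data[weak, ] <- k_weak@data[weak, ]
  .newAssembly(data, weak, "interleave")
}

#' Reordered k-space: weak lines at the high spatial frequencies
#'
#' The reordering scheme acts like a low-pass filter on the signal
#' difference: the lines produced by the weaker signal are distributed
#' equally to the uppermost and lowermost ends of k-space
#' (ky in \[-N/2, -N/4-1\] and \[N/4, N/2-1\]), while the strong-signal
#' lines fill the contrast-determining central half. The period-2 modulation
#' disappears, suppressing the ghost at the cost of a ringing artifact from
#' the abrupt signal step at ky = +/- N/4. With `inverted = TRUE` the roles
#' are swapped (weak lines in the center), which keeps the ringing but also
#' lowers the image signal.
#'
#' @inheritParams assembleInterleaved
#' @param inverted place the weak lines in the center instead.
#' @return A [KSpaceAssembly-class] with scheme `"reorder"` or
#'   `"reorder_inverted"`.
#' @export
assembleReordered <- function(k_strong, k_weak, inverted = FALSE) {
  n <- .checkSameShape(k_strong, k_weak)
  ky <- kyIndex(n)
  outer <- ky < -n / 4 | ky >= n / 4
  weak <- if (inverted) !outer else outer
  data <- k_strong@data
  data[weak, ] <- k_weak@data[weak, ]
  .newAssembly(data, weak, if (inverted) "reorder_inverted" else "reorder")
}

#' Zero-filled k-space (Gibbs-ringing reference)
#'
#' Keeps the strong-signal lines in the central half of k-space (as in the
#' reordering scheme) but sets the outer half to zero instead of filling it
#' with the weak-signal lines. This is the classic truncation scenario whose
#' Gibbs ringing serves as the reference against which the much weaker
#' reordering ringing is compared.
#'
#' @param k_strong a [KSpaceGrid-class].
#' @return A [KSpaceAssembly-class] with scheme `"zero_fill"`.
#' @export
assembleZeroFilled <- function(k_strong) {
  stopifnot(is(k_strong, "KSpaceGrid"))
  n <- nrow(k_strong@data)
  ky <- kyIndex(n)
  outer <- ky < -n / 4 | ky >= n / 4
  data <- k_strong@data
  data[outer, ] <- 0 + 0i
  .newAssembly(data, rep(FALSE, n), "zero_fill")
}

#' Single-signal k-space (reference assemblies)
#'
#' Wraps a full k-space as a `"strong_only"` or `"weak_only"` assembly, the
#' artifact-free references against which the mixed assemblies are measured.
#'
#' @param k a [KSpaceGrid-class].
#' @param which `"strong"` or `"weak"` — which signal produced every line.
#' @return A [KSpaceAssembly-class].
#' @export
assembleSingle <- function(k, which = c("strong", "weak")) {
  stopifnot(is(k, "KSpaceGrid"))
  which <- match.arg(which)
  n <- nrow(k@data)
  .newAssembly(k@data, rep(which == "weak", n),
               if (which == "weak") "weak_only" else "strong_only")
}

#' Center-line correction factor
#'
#' Estimates the weak-to-strong signal ratio from the two k-space center
#' (ky = 0) lines, emulating a sequence that acquires the center line twice,
#' once with each effective TR. Three estimators are available:
#'
#' * `"dc_ratio"` (default): the magnitude ratio of the two lines' DC
#'   samples, which equals the ratio of the two images' total signal. This
#'   is the contrast-determining component of the center line, exact for a
#'   homogeneous phantom, and robust on sharp-edged numerical phantoms,
#'   where the center line's high spatial frequencies are dominated by the
#'   support edge (common to both images) rather than by the signal
#'   difference and therefore drag unweighted means toward 1.
#' * `"l1_ratio"`: the ratio of the summed magnitudes of the two center
#'   lines.
#' * `"masked_pointwise_mean"`: the mean pointwise magnitude ratio over
#'   samples where the strong line exceeds `threshold` times its maximum.
#'
#' @inheritParams assembleInterleaved
#' @param method estimator; see Details.
#' @param threshold relative magnitude threshold for the pointwise
#'   estimator.
#' @return The scalar factor (weak/strong); in (0, 1\] for unadapted pairs
#'   with TR2 > TR1.
#' @seealso [applyCorrection()]
#' @export
estimateCorrectionFactor <- function(k_strong, k_weak,
                                     method = c("dc_ratio", "l1_ratio",
                                                "masked_pointwise_mean"),
                                     threshold = 1e-6) {
  n <- .checkSameShape(k_strong, k_weak)
  method <- match.arg(method)
  dc <- n / 2 + 1
  s <- Mod(k_strong@data[dc, ])
  w <- Mod(k_weak@data[dc, ])
  if (sum(s) <= 0)
    .stopf("degenerate input: the strong-signal center line has zero magnitude")
  switch(method,
         dc_ratio = {
           if (s[dc] <= 0)
             .stopf("degenerate input: the strong-signal DC sample is zero")
           w[dc] / s[dc]
         },
         l1_ratio = sum(w) / sum(s),
         masked_pointwise_mean = {
           keep <- s > threshold * max(s)
           mean(w[keep] / s[keep])
         })
}

#' Apply the center-line correction to an assembly
#'
#' Multiplies every line that originated from the weaker signal by the
#' inverse of the correction factor, raising those lines to the level of the
#' strong signal. Works identically for the interleaved and reordered
#' assemblies; for a homogeneous object with the exact factor the artifact
#' is nulled completely.
#'
#' @param a a [KSpaceAssembly-class] with at least one weak line.
#' @param factor positive correction factor, usually from
#'   [estimateCorrectionFactor()].
#' @return The corrected [KSpaceAssembly-class] (factor recorded).
#' @export
applyCorrection <- function(a, factor) {
  stopifnot(is(a, "KSpaceAssembly"))
  .checkScalar(factor, "factor", 0, Inf, strict_lower = TRUE)
  if (!any(a@weakLines))
    .stopf("assembly '%s' has no weak lines to correct", a@scheme)
  data <- a@kspace@data
  data[a@weakLines, ] <- data[a@weakLines, ] / factor
  .newAssembly(data, a@weakLines, a@scheme, factor)
}

#' Scanner acquisition order for the reordering scheme
#'
#' Generates the chronological order in which the phase-encode lines are
#' acquired under the reordering scheme: the weak-signal block
#' (ky in \[-N/2, -N/4-1\] and \[N/4, N/2-1\]) and the strong-signal block
#' (ky in \[-N/4, N/4-1\]) are each traversed in ascending ky order and
#' interleaved weak-first, so the alternation of the two effective TRs is
#' strictly preserved while the k-space center (ky = 0) is still acquired
#' in the middle of the overall acquisition (position N/2 + 2, within one
#' TR pair of the exact midpoint; an exactly central DC line is
#' incompatible with strict TR alternation and ascending blocks). The
#' simulated images do not depend on this ordering — steady-state signals
#' are time-invariant — but the scanner implementation does.
#'
#' @param n number of phase-encode lines; must be divisible by 4.
#' @return Integer vector: a permutation of \[-N/2, N/2-1\].
#' @examples
#' head(acquisitionOrder(64), 4)  # -32 -16 -31 -15
#' which(acquisitionOrder(64) == 0)  # 34, one TR pair past the midpoint
#' @export
acquisitionOrder <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n != as.integer(n) ||
      n < 4L || n %% 4L != 0L)
    .stopf("'n' must be a positive integer divisible by 4")
  n <- as.integer(n)
  weak <- c(seq.int(-n / 2, -n / 4 - 1), seq.int(n / 4, n / 2 - 1))
  strong <- seq.int(-n / 4, n / 4 - 1)
  as.integer(rbind(weak, strong))
}

#' JSON-ready provenance record of an assembly
#'
#' @param a a [KSpaceAssembly-class].
#' @return A list (scheme, grid size, weak ky indices, correction factor)
#'   suitable for `jsonlite::toJSON()`.
#' @export
assemblyProvenance <- function(a) {
  stopifnot(is(a, "KSpaceAssembly"))
  n <- nrow(a@kspace@data)
  list(scheme = a@scheme, n = n,
       weak_ky = kyIndex(n)[a@weakLines],
       correction_factor = if (is.na(a@correctionFactor)) NULL
                           else a@correctionFactor)
}
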
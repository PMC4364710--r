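#' @import methods
NULL

# ---------------------------------------------------------------------------
# SequenceParams
# ---------------------------------------------------------------------------

#' Sequence timing and relaxation parameters
#'
#' Container for the constants shared by every steady-state signal
#' computation: the two alternating effective repetition times, the echo
#' time, the longitudinal and effective transverse relaxation times, and the
#' equilibrium magnetization. All times are in milliseconds; `m0` is in
#' arbitrary signal units and cancels out of every ratio metric.
#'
#' The defaults are the standard simulation conditions used throughout the
#' package: TR1 = 4 ms, TR2 = 7 ms, TE = 3 ms, T1 = 1420 ms (silicone oil
#' phantom), T2* = 450 ms, M0 = 1.
#'
#' @param tr1_ms,tr2_ms the two effective repetition times (ms). A saturation
#'   block preceding every second excitation makes the recovery interval
#'   alternate between these two values.
#' @param te_ms echo time (ms); must be shorter than both TRs.
#' @param t1_ms longitudinal relaxation time (ms).
#' @param t2star_ms effective transverse relaxation time (ms).
#' @param m0 equilibrium magnetization (arbitrary units).
#'
#' @return A `SequenceParams` object.
#' @examples
#' p <- SequenceParams()
#' tr1Ms(p)
#' @export
SequenceParams <- function(tr1_ms = 4, tr2_ms = 7, te_ms = 3,
                           t1_ms = 1420, t2star_ms = 450, m0 = 1) {
  new("SequenceParams",
      tr1 = as.numeric(tr1_ms), tr2 = as.numeric(tr2_ms),
      te = as.numeric(te_ms), t1 = as.numeric(t1_ms),
      t2star = as.numeric(t2star_ms), m0 = as.numeric(m0))
}

#' @rdname SequenceParams
#' @aliases SequenceParams-class
#' @exportClass SequenceParams
setClass("SequenceParams",
         representation(tr1 = "numeric", tr2 = "numeric", te = "numeric",
                        t1 = "numeric", t2star = "numeric", m0 = "numeric"))

setValidity("SequenceParams", function(object) {
  v <- c(tr1 = object@tr1, tr2 = object@tr2, te = object@te,
         t1 = object@t1, t2star = object@t2star, m0 = object@m0)
  if (any(lengths(list(object@tr1, object@tr2, object@te, object@t1,
                       object@t2star, object@m0)) != 1L))
    return("all parameters must be length-1 numerics")
  if (any(!is.finite(v)) || any(v <= 0))
    return(sprintf("all parameters must be finite and strictly positive (got %s)",
                   paste(sprintf("%s=%g", names(v), v), collapse = ", ")))
  if (object@te >= min(object@tr1, object@tr2))
    return("te_ms must be smaller than min(tr1_ms, tr2_ms)")
  TRUE
})

setMethod("show", "SequenceParams", function(object) {
  cat("SequenceParams\n")
  cat(sprintf("  TR1 = %g ms, TR2 = %g ms, TE = %g ms\n",
              object@tr1, object@tr2, object@te))
  cat(sprintf("  T1 = %g ms, T2* = %g ms, M0 = %g\n",
              object@t1, object@t2star, object@m0))
})

# ---------------------------------------------------------------------------
# FlipMap
# ---------------------------------------------------------------------------

#' Two-dimensional flip-angle map
#'
#' An N-by-N grid of excitation flip angles (degrees) with compact circular
#' support: values are strictly positive inside the support and exactly zero
#' outside. Rows are the phase-encode direction, columns the readout
#' direction. Constructed by [makeGradientFlipMap()], [makeUniformFlipMap()]
#' or [readFlipMap()].
#'
#' @slot grid numeric matrix of flip angles in degrees.
#' @slot radiusPx circle radius in pixels (`NA` for user-supplied maps).
#' @slot gradientAxis `"readout"`, `"phase_encode"`, `"none"` or `"user"`.
#' @slot thetaRange range of in-mask flip angles (degrees).
#'
#' @aliases FlipMap-class
#' @exportClass FlipMap
setClass("FlipMap",
         representation(grid = "matrix", radiusPx = "numeric",
                        gradientAxis = "character", thetaRange = "numeric"))

setValidity("FlipMap", function(object) {
  g <- object@grid
  if (!is.numeric(g) || nrow(g) != ncol(g))
    return("grid must be a square numeric matrix")
  n <- nrow(g)
  if (n %% 4L != 0L)
    return("grid size must be divisible by 4 (required by the reordering scheme)")
  if (any(!is.finite(g)) || any(g < 0))
    return("flip angles must be finite and non-negative")
  if (max(g) > 180)
    return("flip angles above 180 degrees are not supported")
  if (!any(g > 0))
    return("degenerate phantom: the support mask is empty")
  if (!is.na(object@radiusPx) && object@radiusPx >= n / 4)
    return("radius_px must be smaller than N/4 so the half-FOV ghost region is disjoint from the phantom")
  TRUE
})

setMethod("show", "FlipMap", function(object) {
  g <- object@grid
  cat(sprintf("FlipMap: %d x %d grid (rows = phase encode, cols = readout)\n",
              nrow(g), ncol(g)))
  cat(sprintf("  support: %d px (radius %s px), gradient axis: %s\n",
              sum(g > 0),
              ifelse(is.na(object@radiusPx), "?", format(object@radiusPx)),
              object@gradientAxis))
  cat(sprintf("  flip range inside mask: %.3g - %.3g deg\n",
              object@thetaRange[1], object@thetaRange[2]))
})

# ---------------------------------------------------------------------------
# ImagePair
# ---------------------------------------------------------------------------

#' Pair of pixelwise steady-state signal images
#'
#' The two images produced by evaluating the dual-TR steady-state signal
#' model over a [FlipMap-class]: `imgStrong` holds the signal of the
#' excitation that follows the longer recovery interval, `imgWeak` the other
#' one. When a flip-angle adaptation scale is applied (`theta1Scale != 1`),
#' the slot names keep referring to the recovery intervals, not to the
#' pointwise signal ordering (which adaptation deliberately changes).
#'
#' @slot imgStrong,imgWeak numeric matrices (arbitrary signal units).
#' @slot params the [SequenceParams-class] used.
#' @slot theta1Scale multiplicative scale applied to the flip angle of the
#'   long-recovery excitation (1 = plain dual-TR acquisition).
#'
#' @aliases ImagePair-class
#' @exportClass ImagePair
setClass("ImagePair",
         representation(imgStrong = "matrix", imgWeak = "matrix",
                        params = "SequenceParams", theta1Scale = "numeric"))

setValidity("ImagePair", function(object) {
  if (!identical(dim(object@imgStrong), dim(object@imgWeak)))
    return("the two images must share dimensions")
  if (any(!is.finite(object@imgStrong)) || any(!is.finite(object@imgWeak)))
    return("images must be finite")
  if (any(object@imgStrong < 0) || any(object@imgWeak < 0))
    return("steady-state magnitude images must be non-negative")
  TRUE
})

setMethod("show", "ImagePair", function(object) {
  cat(sprintf("ImagePair: %d x %d images\n",
              nrow(object@imgStrong), ncol(object@imgStrong)))
  cat(sprintf("  max strong = %.4g, max weak = %.4g, theta1 scale = %g\n",
              max(object@imgStrong), max(object@imgWeak), object@theta1Scale))
})

# ---------------------------------------------------------------------------
# KSpaceGrid
# ---------------------------------------------------------------------------

#' Centered k-space grid
#'
#' Complex N-by-N spatial-frequency grid in the centered, unitary transform
#' convention: the phase-encode index ky runs over \[-N/2, N/2-1\] along the
#' rows with DC (ky = 0) at row N/2 + 1, and likewise kx along the columns.
#' Unitarity makes Parseval's identity exact, so magnitude metrics are
#' convention-independent.
#'
#' @slot data complex matrix.
#'
#' @aliases KSpaceGrid-class
#' @exportClass KSpaceGrid
setClass("KSpaceGrid", representation(data = "matrix"))

setValidity("KSpaceGrid", function(object) {
  d <- object@data
  if (!is.complex(d)) return("k-space data must be complex")
  if (nrow(d) != ncol(d)) return("k-space grid must be square")
  if (nrow(d) %% 4L != 0L) return("grid size must be divisible by 4")
  TRUE
})

setMethod("show", "KSpaceGrid", function(object) {
  n <- nrow(object@data)
  cat(sprintf("KSpaceGrid: %d x %d, ky in [%d, %d], DC |value| = %.4g\n",
              n, n, -n / 2, n / 2 - 1, Mod(object@data[n / 2 + 1, n / 2 + 1])))
})

# ---------------------------------------------------------------------------
# KSpaceAssembly
# ---------------------------------------------------------------------------

.ASSEMBLY_SCHEMES <- c("interleave", "reorder", "reorder_inverted",
                       "zero_fill", "strong_only", "weak_only")

#' Assembled k-space with per-line provenance
#'
#' A combined k-space grid plus the bookkeeping of which excitation produced
#' each phase-encode line. Produced by the `assemble*` functions and modified
#' by [applyCorrection()].
#'
#' @slot kspace the combined [KSpaceGrid-class].
#' @slot weakLines logical flag per ky row (in ky order \[-N/2, N/2-1\])
#'   marking lines taken from the weak-signal k-space.
#' @slot scheme one of `"interleave"`, `"reorder"`, `"reorder_inverted"`,
#'   `"zero_fill"`, `"strong_only"`, `"weak_only"`.
#' @slot correctionFactor the center-line correction factor applied to the
#'   weak lines, or `NA` if none.
#'
#' @aliases KSpaceAssembly-class
#' @exportClass KSpaceAssembly
setClass("KSpaceAssembly",
         representation(kspace = "KSpaceGrid", weakLines = "logical",
                        scheme = "character", correctionFactor = "numeric"))

setValidity("KSpaceAssembly", function(object) {
  n <- nrow(object@kspace@data)
  if (length(object@weakLines) != n)
    return("weakLines must have one flag per ky row")
  if (!(object@scheme %in% .ASSEMBLY_SCHEMES))
    return(sprintf("unknown scheme '%s'", object@scheme))
  nw <- sum(object@weakLines)
  expected <- switch(object@scheme,
                     interleave = n / 2L, reorder = n / 2L,
                     reorder_inverted = n / 2L,
                     zero_fill = 0L, strong_only = 0L, weak_only = n)
  if (nw != expected)
    return(sprintf("scheme '%s' must flag %d weak lines, found %d",
                   object@scheme, expected, nw))
  # the contrast-determining DC line is held by the strong signal
  if (object@scheme %in% c("interleave", "reorder") &&
      object@weakLines[n / 2 + 1])
    return("the DC line (ky = 0) must come from the strong signal")
  TRUE
})

setMethod("show", "KSpaceAssembly", function(object) {
  n <- nrow(object@kspace@data)
  cat(sprintf("KSpaceAssembly: scheme '%s', %d x %d, %d weak lines%s\n",
              object@scheme, n, n, sum(object@weakLines),
              ifelse(is.na(object@correctionFactor), "",
                     sprintf(", correction factor %.6g",
                             object@correctionFactor))))
})

# ---------------------------------------------------------------------------
# FlipAdaptation
# ---------------------------------------------------------------------------

#' Result of the flip-angle adaptation solve
#'
#' For a nominal flip angle theta2, the solved companion angle theta1 that
#' equalizes the two alternating steady-state signals (S1 = S2), the
#' multiplicative scale theta1/theta2, and the residual signal difference at
#' the solution.
#'
#' @slot theta2 nominal (fixed) flip angle in degrees.
#' @slot theta1 solved flip angle in degrees.
#' @slot scale theta1 / theta2 (dimensionless; in (0, 1] when TR2 > TR1).
#' @slot residual |S1 - S2| at the solution (signal units).
#' @slot bracketed `TRUE` if a sign change was bracketed and refined;
#'   `FALSE` if the boundary minimizer was returned instead.
#'
#' @aliases FlipAdaptation-class
#' @exportClass FlipAdaptation
setClass("FlipAdaptation",
         representation(theta2 = "numeric", theta1 = "numeric",
                        scale = "numeric", residual = "numeric",
                        bracketed = "logical"))

setMethod("show", "FlipAdaptation", function(object) {
  cat(sprintf(
    "FlipAdaptation: theta1(%.4g deg) = %.6g deg (scale %.6g), |S1-S2| = %.3g%s\n",
    object@theta2, object@theta1, object@scale, object@residual,
    ifelse(object@bracketed, "", " [boundary minimizer, no sign change]")))
})
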
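# Synthetic flip-angle phantoms and the pixelwise simulated image pair.

.newFlipMap <- function(grid, radius_px, axis) {
  inmask <- grid[grid > 0]
  new("FlipMap", grid = grid, radiusPx = radius_px, gradientAxis = axis,
      thetaRange = if (length(inmask)) range(inmask) else c(NA_real_, NA_real_))
}

.circleGeometry <- function(n, radius_frac) {
  if (length(n) != 1L || !is.finite(n) || n != as.integer(n) || n < 8)
    .stopf("'n' must be a single integer >= 8")
  n <- as.integer(n)
  if (n %% 4L != 0L)
    .stopf("'n' must be divisible by 4 (required by the reordering scheme)")
  .checkScalar(radius_frac, "radius_frac", 0, Inf, strict_lower = TRUE)
  if (radius_frac >= 0.25)
    .stopf("'radius_frac' must be < 0.25 so the half-FOV ghost region is disjoint from the phantom")
  centre <- (n + 1) / 2            # symmetric pixel-centre coordinates
  radius <- radius_frac * n
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  mask <- (row - centre)^2 + (col - centre)^2 <= radius^2
  list(n = n, centre = centre, radius = radius, row = row, col = col,
       mask = mask)
}

#' Circular flip-angle phantom with a linear gradient
#'
#' Builds the standard synthetic phantom: a centered circle inside which the
#' excitation flip angle varies linearly along one axis from `theta_min_deg`
#' at one circle edge to `theta_max_deg` at the other, and is exactly zero
#' outside. This emulates the strongly inhomogeneous transmit (B1) field at
#' 7 T, where the local flip angle sweeps over a wide range across the
#' object. The flip angle is continuous (not quantized to whole degrees).
#'
#' The defaults — N = 256, radius 0.22 N, 1 to 90 degrees along the readout
#' axis — are the package's standard simulation geometry. With the gradient
#' along the readout axis every readout column carries a single flip angle,
#' so metric curves bin exactly by column.
#'
#' @param n grid size in pixels; must be divisible by 4.
#' @param radius_frac circle radius as a fraction of `n`; must be below 0.25
#'   so that the half-FOV ghost region cannot overlap the phantom.
#' @param theta_min_deg,theta_max_deg flip angles at the two circle edges.
#' @param gradient_axis `"readout"` (gradient across columns, the default)
#'   or `"phase_encode"` (across rows).
#' @return A [FlipMap-class].
#' @examples
#' fm <- makeGradientFlipMap(64, 0.2)
#' range(flipGrid(fm)[flipMask(fm)])
#' @export
makeGradientFlipMap <- function(n = 256L, radius_frac = 0.22,
                                theta_min_deg = 1, theta_max_deg = 90,
                                gradient_axis = c("readout", "phase_encode")) {
  gradient_axis <- match.arg(gradient_axis)
  .checkScalar(theta_min_deg, "theta_min_deg", 0, 180)
  .checkScalar(theta_max_deg, "theta_max_deg", 0, 180)
  if (theta_min_deg >= theta_max_deg)
    .stopf("'theta_min_deg' must be smaller than 'theta_max_deg'")
  g <- .circleGeometry(n, radius_frac)
  along <- if (gradient_axis == "readout") g$col else g$row
  tfrac <- (along - (g$centre - g$radius)) / (2 * g$radius)
  tfrac <- pmin(1, pmax(0, tfrac))
  theta <- theta_min_deg + (theta_max_deg - theta_min_deg) * tfrac
  grid <- ifelse(g$mask, theta, 0)
  .newFlipMap(grid, g$radius, gradient_axis)
}

#' Uniform circular flip-angle phantom
#'
#' Constant flip angle inside the centered circle, zero outside. Used for
#' closed-form checks: with a homogeneous excitation every artifact metric
#' has an exact analytic value.
#'
#' @inheritParams makeGradientFlipMap
#' @param theta_deg the constant flip angle (degrees); must be positive.
#' @return A [FlipMap-class].
#' @export
makeUniformFlipMap <- function(n = 256L, radius_frac = 0.22, theta_deg = 45) {
  .checkScalar(theta_deg, "theta_deg", 0, 180)
  if (theta_deg <= 0)
    .stopf("'theta_deg' must be positive (a zero flip angle gives a degenerate, empty phantom)")
  g <- .circleGeometry(n, radius_frac)
  grid <- ifelse(g$mask, theta_deg, 0)
  .newFlipMap(grid, g$radius, "none")
}

#' Simulate the dual-TR image pair from a flip map
#'
#' Evaluates the generalized steady-state signal model pixelwise over a flip
#' map: with theta2 equal to the map value and theta1 = `theta1_scale` times
#' theta2, the two alternating signals are computed at every pixel. The
#' default `theta1_scale = 1` reproduces the plain dual-TR acquisition; a
#' scale below 1 models a transmit-voltage reduction of the long-recovery
#' excitation, which is how flip-angle adaptation is applied physically
#' (see [adaptedImagePair()]).
#'
#' Pixels outside the support (flip angle 0) are exactly zero in both
#' images.
#'
#' @param fm a [FlipMap-class].
#' @param p a [SequenceParams-class].
#' @param theta1_scale dimensionless scale in (0, 2\]; the scaled angle must
#'   not exceed 180 degrees anywhere.
#' @return An [ImagePair-class].
#' @export
simulateImagePair <- function(fm, p = SequenceParams(), theta1_scale = 1) {
  stopifnot(is(fm, "FlipMap"))
  validObject(fm)
  .checkScalar(theta1_scale, "theta1_scale", 0, 2, strict_lower = TRUE)
  grid <- fm@grid
  if (max(grid) * theta1_scale > 180)
    .stopf("scaled flip angle exceeds 180 degrees (max %g * scale %g)",
           max(grid), theta1_scale)
  s <- steadyStateSignalsGeneral(theta1_scale * as.vector(grid),
                                 as.vector(grid), p)
  n <- nrow(grid)
  new("ImagePair",
      imgStrong = matrix(if (p@tr2 >= p@tr1) s$s1 else s$s2, n, n),
      imgWeak = matrix(if (p@tr2 >= p@tr1) s$s2 else s$s1, n, n),
      params = p, theta1Scale = theta1_scale)
}

#' Read / write flip maps as plain-text grids
#'
#' Flip maps are exchanged as whitespace-separated text grids, one image row
#' per line, values in degrees. `readFlipMap()` accepts user-supplied
#' phantoms; the grid must be square with size divisible by 4 and
#' non-negative values.
#'
#' @param path file path.
#' @return `readFlipMap()` returns a [FlipMap-class] (with unknown radius);
#'   `writeFlipMap()` returns `path` invisibly.
#' @export
readFlipMap <- function(path) {
  grid <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "double"
  .newFlipMap(grid, NA_real_, "user")
}

#' @rdname readFlipMap
#' @param fm a [FlipMap-class] to write.
#' @export
writeFlipMap <- function(fm, path) {
  stopifnot(is(fm, "FlipMap"))
  utils::write.table(fm@grid, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
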
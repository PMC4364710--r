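# Artifact quantification: ghost-to-source curves, signal-ratio curves,
# ringing amplitudes, oscillation-vs-mean, crossover finder, profiles, and
# AFI flip-angle map recovery.
#
# All curves are returned as data frames with columns flip_deg, value_pct,
# metric, variant — one row per readout column intersecting the phantom.
# Because the standard phantom's flip gradient runs along the readout axis,
# each column carries a single flip angle and the binning is exact.

.curveFrame <- function(flip, value, metric, variant) {
  ord <- order(flip)
  data.frame(flip_deg = flip[ord], value_pct = value[ord],
             metric = metric, variant = variant,
             stringsAsFactors = FALSE)
}

# mask shifted by half the field of view along phase encode (rows), with
# circular wraparound
.halfFOVShift <- function(mask) {
  n <- nrow(mask)
  idx <- ((seq_len(n) - 1 + n / 2) %% n) + 1
  mask[idx, , drop = FALSE]
}

#' Binary mask erosion
#'
#' Erodes a logical mask with a Euclidean disk of the given pixel radius
#' (a pixel survives only if every mask pixel within the disk is set).
#' Used to restrict ringing metrics to the phantom interior, away from the
#' edge overshoot.
#'
#' @param mask logical matrix.
#' @param radius_px non-negative integer erosion radius.
#' @return Logical matrix of the same shape.
#' @export
erodeMask <- function(mask, radius_px) {
  if (!is.matrix(mask) || !is.logical(mask))
    .stopf("'mask' must be a logical matrix")
  r <- as.integer(radius_px)
  if (r < 0) .stopf("'radius_px' must be non-negative")
  if (r == 0L) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  er <- mask
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy * dy + dx * dx > r * r || (dy == 0L && dx == 0L)) next
      sh <- matrix(FALSE, n, m)
      yi <- seq_len(n) + dy
      xi <- seq_len(m) + dx
      vy <- yi >= 1L & yi <= n
      vx <- xi >= 1L & xi <= m
      sh[which(vy), which(vx)] <- mask[yi[vy], xi[vx]]
      er <- er & sh
    }
  }
  er
}

.maskColumns <- function(mask) which(colSums(mask) > 0)

.columnFlip <- function(fm, mask, col) mean(fm@grid[mask[, col], col])

#' Ghost-to-source ratio curve
#'
#' For every readout column intersecting the phantom, the mean magnitude
#' over the column's ghost pixels (the support mask shifted by half the
#' field of view along phase encode) divided by the mean magnitude over the
#' column's phantom pixels, in percent, plotted against the column's flip
#' angle. This is the primary artifact metric: the ghost of an interleaved
#' dual-TR acquisition grows with the local flip angle because the signal
#' difference between the two excitations does.
#'
#' @param image reconstructed magnitude image (numeric matrix).
#' @param fm the [FlipMap-class] that generated the image (provides the
#'   support mask and the per-column flip angles).
#' @param variant label stored in the `variant` column.
#' @return A curve data frame (see package overview).
#' @export
ghostRatioCurve <- function(image, fm, variant = "") {
  stopifnot(is(fm, "FlipMap"))
  .checkSquareImage(image)
  mask <- flipMask(fm)
  if (!identical(dim(image), dim(mask)))
    .stopf("image and flip map must share dimensions")
  ghost <- .halfFOVShift(mask)
  if (any(ghost & mask))
    .stopf("geometry error: the half-FOV ghost region overlaps the phantom (radius must be < N/4)")
  cols <- .maskColumns(mask)
  flip <- vapply(cols, function(j) .columnFlip(fm, mask, j), numeric(1))
  value <- vapply(cols, function(j) {
    100 * mean(abs(image[ghost[, j], j])) / mean(abs(image[mask[, j], j]))
  }, numeric(1))
  .curveFrame(flip, value, "ghost_ratio", variant)
}

#' Phantom-interior signal-ratio curve
#'
#' Per readout column, 100 times the mean magnitude of `image_a` over the
#' column's phantom pixels divided by that of `image_b`, against flip
#' angle. Used to compare each correction variant's interior signal with
#' the artifact image or with the strong-signal-only reference.
#'
#' @param image_a,image_b magnitude images sharing the phantom geometry.
#' @inheritParams ghostRatioCurve
#' @return A curve data frame. Columns where `image_b` averages to zero are
#'   excluded with a warning.
#' @export
signalRatioCurve <- function(image_a, image_b, fm, variant = "") {
  stopifnot(is(fm, "FlipMap"))
  .checkSquareImage(image_a, "image_a")
  .checkSquareImage(image_b, "image_b")
  mask <- flipMask(fm)
  cols <- .maskColumns(mask)
  flip <- vapply(cols, function(j) .columnFlip(fm, mask, j), numeric(1))
  den <- vapply(cols, function(j) mean(abs(image_b[mask[, j], j])), numeric(1))
  num <- vapply(cols, function(j) mean(abs(image_a[mask[, j], j])), numeric(1))
  keep <- den > 0
  if (!all(keep))
    warning(sprintf("%d column(s) with zero denominator signal excluded",
                    sum(!keep)))
  .curveFrame(flip[keep], 100 * num[keep] / den[keep],
              "signal_ratio", variant)
}

#' Ringing amplitude curve
#'
#' Quantifies ringing in the phantom interior: per readout column of the
#' mask eroded by `erosion_px`, the pixelwise relative deviation
#' d = image/reference - 1 is computed and the half peak-to-peak range
#' 100 (max d - min d)/2 reported against flip angle. The erosion excludes
#' the edge overshoot so the value reflects interior oscillation.
#'
#' @param image magnitude image under test (e.g. the reordered
#'   reconstruction).
#' @param reference artifact-free reference (e.g. strong-signal-only).
#' @inheritParams ghostRatioCurve
#' @param erosion_px erosion radius in pixels (>= 1).
#' @return A curve data frame. Columns whose eroded support is empty are
#'   excluded.
#' @export
ringingAmplitudeCurve <- function(image, reference, fm, erosion_px = 3,
                                  variant = "") {
  stopifnot(is(fm, "FlipMap"))
  .checkSquareImage(image, "image")
  .checkSquareImage(reference, "reference")
  if (as.integer(erosion_px) < 1L)
    .stopf("'erosion_px' must be at least 1")
  mask <- flipMask(fm)
  er <- erodeMask(mask, erosion_px)
  cols <- .maskColumns(er)
  flip <- vapply(cols, function(j) .columnFlip(fm, er, j), numeric(1))
  value <- vapply(cols, function(j) {
    d <- abs(image[er[, j], j]) / abs(reference[er[, j], j]) - 1
    100 * (max(d) - min(d)) / 2
  }, numeric(1))
  .curveFrame(flip, value, "ringing_amplitude", variant)
}

#' Oscillation relative to the mean phantom signal
#'
#' The Gibbs-style oscillation measure: the maximum absolute deviation
#' |image - reference| over the eroded phantom interior, normalized by the
#' mean reference magnitude over the full mask, in percent. With
#' `flip_bin_deg` given, the maximum is restricted to the readout column
#' whose flip angle is nearest that value.
#'
#' @inheritParams ringingAmplitudeCurve
#' @param erosion_px erosion radius in pixels (>= 1; the default 1 keeps
#'   near-edge oscillation, matching the truncation-ringing comparison).
#' @param flip_bin_deg optional flip angle selecting a single column.
#' @return A single percentage value.
#' @export
oscillationVsMean <- function(image, reference, fm, erosion_px = 1,
                              flip_bin_deg = NULL) {
  stopifnot(is(fm, "FlipMap"))
  .checkSquareImage(image, "image")
  .checkSquareImage(reference, "reference")
  if (as.integer(erosion_px) < 1L)
    .stopf("'erosion_px' must be at least 1")
  mask <- flipMask(fm)
  er <- erodeMask(mask, erosion_px)
  if (!any(er)) .stopf("eroded mask is empty")
  if (!is.null(flip_bin_deg)) {
    .checkScalar(flip_bin_deg, "flip_bin_deg", 0, 180)
    cols <- .maskColumns(er)
    flip <- vapply(cols, function(j) .columnFlip(fm, er, j), numeric(1))
    j <- cols[which.min(abs(flip - flip_bin_deg))]
    sel <- matrix(FALSE, nrow(er), ncol(er))
    sel[, j] <- er[, j]
    er <- sel
  }
  100 * max(abs(image[er] - reference[er])) / mean(abs(reference[mask]))
}

#' Crossover flip angle between two curves
#'
#' Locates the largest flip angle at which `curve_a - curve_b` changes sign
#' from positive to non-positive, by linear interpolation between adjacent
#' samples. Operationalizes statements of the form "below X degrees the
#' corrected curve exceeds the uncorrected one".
#'
#' @param curve_a,curve_b curve data frames with identical `flip_deg`
#'   sampling.
#' @return The crossover flip angle in degrees, or `NA` if the sign pattern
#'   never changes from positive to non-positive.
#' @export
crossoverFlip <- function(curve_a, curve_b) {
  if (!all(c("flip_deg", "value_pct") %in% names(curve_a)) ||
      !all(c("flip_deg", "value_pct") %in% names(curve_b)))
    .stopf("inputs must be curve data frames with flip_deg and value_pct")
  if (nrow(curve_a) != nrow(curve_b) ||
      max(abs(curve_a$flip_deg - curve_b$flip_deg)) > 1e-9)
    .stopf("the two curves must share the same flip-angle sampling")
  f <- curve_a$flip_deg
  d <- curve_a$value_pct - curve_b$value_pct
  m <- length(d)
  idx <- which(d[-m] > 0 & d[-1] <= 0)
  if (length(idx) == 0L) return(NA_real_)
  i <- max(idx)
  f[i] + (f[i + 1] - f[i]) * d[i] / (d[i] - d[i + 1])
}

#' Extract a row or column profile
#'
#' @param image numeric matrix.
#' @param axis `"row"` (profile along a fixed phase-encode row) or
#'   `"column"`.
#' @param index 1-based row/column index.
#' @return Numeric vector of magnitudes.
#' @export
imageProfile <- function(image, axis = c("row", "column"), index) {
  axis <- match.arg(axis)
  if (!is.matrix(image)) .stopf("'image' must be a matrix")
  limit <- if (axis == "row") nrow(image) else ncol(image)
  if (length(index) != 1L || index < 1 || index > limit ||
      index != as.integer(index))
    .stopf("'index' must be an integer in [1, %d]", limit)
  if (axis == "row") abs(image[index, ]) else abs(image[, index])
}

#' Pixelwise AFI flip-angle map recovery
#'
#' Applies the AFI inversion ([afiFlipAngle()]) pixelwise over the phantom
#' support: wherever the strong image is positive, the local flip angle is
#' estimated from the signal ratio of the two images; outside it is zero.
#' Demonstrates that the same dual-TR signal difference that creates the
#' ghost also carries B1-mapping information.
#'
#' @param pair an [ImagePair-class] (its `SequenceParams` supply the TRs;
#'   the two TRs must differ).
#' @param p optional [SequenceParams-class] overriding the pair's.
#' @return A numeric matrix of flip angles in degrees (0 outside the
#'   support).
#' @export
estimateFlipMap <- function(pair, p = NULL) {
  stopifnot(is(pair, "ImagePair"))
  if (is.null(p)) p <- pair@params
  stopifnot(is(p, "SequenceParams"))
  if (p@tr1 == p@tr2)
    .stopf("AFI recovery requires two distinct TRs")
  tr_short <- min(p@tr1, p@tr2)
  tr_long <- max(p@tr1, p@tr2)
  s <- pair@imgStrong
  w <- pair@imgWeak
  est <- matrix(0, nrow(s), ncol(s))
  maskpx <- which(s > 0)
  est[maskpx] <- afiFlipAngle(s[maskpx], w[maskpx], tr_short, tr_long)
  est
}
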
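# Orchestration: the standard deterministic sweep over all assembly
# variants on the gradient phantom, plus report writing.

#' Configuration for the standard sweep
#'
#' Bundles and validates every knob of [runStandardSweep()]. The defaults
#' are the package's standard simulation conditions: a 256-pixel grid,
#' circle radius 0.22 N, flip gradient 1-90 degrees along the readout axis,
#' TR1/TR2 = 4/7 ms, T1 = 1420 ms, T2* = 450 ms, TE = 3 ms, adaptation
#' nominal angle 70 degrees, L1-ratio correction estimator, erosion margins
#' of 3 px (interior ringing) and 1 px (edge-inclusive oscillation).
#'
#' @param n grid size (divisible by 4).
#' @param radius_frac circle radius as a fraction of `n` (< 0.25).
#' @param theta_min_deg,theta_max_deg flip-angle range of the gradient.
#' @param gradient_axis `"readout"` or `"phase_encode"`.
#' @param params a [SequenceParams-class].
#' @param adapt_nominal_deg nominal angle for the flip-angle-adaptation
#'   variant.
#' @param correction_method correction-factor estimator
#'   (see [estimateCorrectionFactor()]).
#' @param erosion_ringing_px erosion for [ringingAmplitudeCurve()].
#' @param erosion_oscillation_px erosion for [oscillationVsMean()].
#' @return A `SweepConfig` (validated list).
#' @export
sweepConfig <- function(n = 256L, radius_frac = 0.22,
                        theta_min_deg = 1, theta_max_deg = 90,
                        gradient_axis = "readout",
                        params = SequenceParams(),
                        adapt_nominal_deg = 70,
                        correction_method = "dc_ratio",
                        erosion_ringing_px = 3L,
                        erosion_oscillation_px = 1L) {
  stopifnot(is(params, "SequenceParams"))
  validObject(params)
  # fail early: the phantom constructor re-validates the geometry
  fm <- makeGradientFlipMap(n, radius_frac, theta_min_deg, theta_max_deg,
                            gradient_axis)
  .checkScalar(adapt_nominal_deg, "adapt_nominal_deg", 0, 90,
               strict_lower = TRUE)
  correction_method <- match.arg(correction_method,
                                 c("dc_ratio", "l1_ratio",
                                   "masked_pointwise_mean"))
  structure(list(n = as.integer(n), radius_frac = radius_frac,
                 theta_min_deg = theta_min_deg,
                 theta_max_deg = theta_max_deg,
                 gradient_axis = gradient_axis, params = params,
                 adapt_nominal_deg = adapt_nominal_deg,
                 correction_method = correction_method,
                 erosion_ringing_px = as.integer(erosion_ringing_px),
                 erosion_oscillation_px = as.integer(erosion_oscillation_px)),
            class = "SweepConfig")
}

.curveAt <- function(curve, flip_deg) {
  curve$value_pct[which.min(abs(curve$flip_deg - flip_deg))]
}

.flipAtMin <- function(curve) curve$flip_deg[which.min(curve$value_pct)]

#' Run the standard artifact sweep
#'
#' The package's main computation: builds the gradient phantom, simulates
#' the dual-TR image pair, reconstructs all assembly variants
#' (`strong_only`, `weak_only`, `interleave` — the artifact image,
#' `interleave_corrected`, `adapted`, `reorder`, `reorder_corrected`,
#' `reorder_inverted`, `zero_fill`), and computes the full set of artifact
#' curves and scalar summaries. The pipeline contains no randomness:
#' identical configurations produce bit-identical results.
#'
#' Scalar summaries (all percentages unless noted):
#' \describe{
#'   \item{max_ghost_reorder}{maximum of the reordered ghost curve.}
#'   \item{ringing_reorder_15/45/90}{reordered-vs-strong ringing amplitude
#'     at the flip bin nearest 15/45/90 degrees.}
#'   \item{max_signal_dev_reorder}{max |signal ratio - 100| of reordered vs
#'     strong-only.}
#'   \item{zero_fill_oscillation_max}{maximum oscillation of the
#'     zero-filled image vs the mean phantom signal.}
#'   \item{zero_fill_ringing_max}{maximum edge-inclusive (1 px erosion)
#'     relative ringing amplitude of the zero-filled image — the Gibbs
#'     reference level.}
#'   \item{reorder_edge_ringing_15/90}{the reordered counterpart of the
#'     Gibbs reference at 15/90 degrees.}
#'   \item{reorder_oscillation_15/90}{same measure for the reordered image
#'     at 15/90 degrees.}
#'   \item{adapted_max_ghost_le_nominal}{max adapted ghost over bins at or
#'     below the nominal angle.}
#'   \item{crossover_adapted / crossover_corrected}{flip angle (degrees)
#'     below which the adapted / corrected ghost curve exceeds the
#'     uncorrected one.}
#'   \item{argmin_corrected_ghost}{flip bin (degrees) of the corrected
#'     ghost curve's minimum.}
#'   \item{corrected_gain_low_flip}{mean interior signal gain of the
#'     corrected over the artifact image for bins below 10 degrees.}
#'   \item{correction_factor}{the estimated center-line factor
#'     (dimensionless).}
#' }
#'
#' @param cfg a `SweepConfig` from [sweepConfig()].
#' @return A `SweepResult`: list with elements `curves` (one long data
#'   frame), `summaries` (named list of scalars), `images` (named list of
#'   reconstructions), `flip_map`, `adaptation`, `config`.
#' @examples
#' res <- runStandardSweep(sweepConfig(n = 64))
#' res$summaries$max_ghost_reorder
#' @export
runStandardSweep <- function(cfg = sweepConfig()) {
  if (!inherits(cfg, "SweepConfig"))
    .stopf("'cfg' must be created by sweepConfig()")
  p <- cfg$params
  fm <- makeGradientFlipMap(cfg$n, cfg$radius_frac, cfg$theta_min_deg,
                            cfg$theta_max_deg, cfg$gradient_axis)
  pair <- simulateImagePair(fm, p)
  kS <- forwardKspace(imgStrong(pair))
  kW <- forwardKspace(imgWeak(pair))
  factor <- estimateCorrectionFactor(kS, kW, method = cfg$correction_method)

  adaptation <- solveAdaptedFlip(cfg$adapt_nominal_deg, p)
  apair <- simulateImagePair(fm, p, theta1_scale = adaptation@scale)
  kA1 <- forwardKspace(imgStrong(apair))
  kA2 <- forwardKspace(imgWeak(apair))

  assemblies <- list(
    strong_only = assembleSingle(kS, "strong"),
    weak_only = assembleSingle(kW, "weak"),
    interleave = assembleInterleaved(kS, kW),
    interleave_corrected = applyCorrection(assembleInterleaved(kS, kW),
                                           factor),
    adapted = assembleInterleaved(kA1, kA2),
    reorder = assembleReordered(kS, kW),
    reorder_corrected = applyCorrection(assembleReordered(kS, kW), factor),
    reorder_inverted = assembleReordered(kS, kW, inverted = TRUE),
    zero_fill = assembleZeroFilled(kS))

  images <- lapply(assemblies, reconstructImage)

  ghost <- mapply(function(img, label) ghostRatioCurve(img, fm, label),
                  images, names(images), SIMPLIFY = FALSE)

  art <- images$interleave
  sig_vs_artifact <- list(
    adapted = signalRatioCurve(images$adapted, art, fm, "adapted"),
    interleave_corrected = signalRatioCurve(images$interleave_corrected,
                                            art, fm, "interleave_corrected"),
    reorder = signalRatioCurve(images$reorder, art, fm, "reorder"))
  art_vs_strong <- signalRatioCurve(art, images$strong_only, fm,
                                    "interleave")
  art_vs_weak <- signalRatioCurve(art, images$weak_only, fm, "interleave")
  reorder_vs_strong <- signalRatioCurve(images$reorder, images$strong_only,
                                        fm, "reorder")
  ringing <- list(
    reorder = ringingAmplitudeCurve(images$reorder, images$strong_only, fm,
                                    cfg$erosion_ringing_px, "reorder"),
    reorder_corrected = ringingAmplitudeCurve(images$reorder_corrected,
                                              images$strong_only, fm,
                                              cfg$erosion_ringing_px,
                                              "reorder_corrected"),
    # edge-inclusive amplitudes for the truncation (Gibbs) comparison
    zero_fill_edge = ringingAmplitudeCurve(images$zero_fill,
                                           images$strong_only, fm,
                                           cfg$erosion_oscillation_px,
                                           "zero_fill"),
    reorder_edge = ringingAmplitudeCurve(images$reorder,
                                         images$strong_only, fm,
                                         cfg$erosion_oscillation_px,
                                         "reorder_edge"))

  osc <- cfg$erosion_oscillation_px
  summaries <- list(
    max_ghost_interleave = max(ghost$interleave$value_pct),
    max_ghost_reorder = max(ghost$reorder$value_pct),
    ringing_reorder_15 = .curveAt(ringing$reorder, 15),
    ringing_reorder_45 = .curveAt(ringing$reorder, 45),
    ringing_reorder_90 = .curveAt(ringing$reorder, 90),
    max_signal_dev_reorder = max(abs(reorder_vs_strong$value_pct - 100)),
    zero_fill_oscillation_max = oscillationVsMean(images$zero_fill,
                                                  images$strong_only, fm,
                                                  osc),
    zero_fill_ringing_max = max(ringing$zero_fill_edge$value_pct),
    reorder_edge_ringing_15 = .curveAt(ringing$reorder_edge, 15),
    reorder_edge_ringing_90 = .curveAt(ringing$reorder_edge, 90),
    reorder_oscillation_15 = oscillationVsMean(images$reorder,
                                               images$strong_only, fm, osc,
                                               flip_bin_deg = 15),
    reorder_oscillation_90 = oscillationVsMean(images$reorder,
                                               images$strong_only, fm, osc,
                                               flip_bin_deg = 90),
    adapted_max_ghost_le_nominal = max(
      ghost$adapted$value_pct[ghost$adapted$flip_deg <=
                                cfg$adapt_nominal_deg]),
    crossover_adapted = crossoverFlip(ghost$adapted, ghost$interleave),
    crossover_corrected = crossoverFlip(ghost$interleave_corrected,
                                        ghost$interleave),
    argmin_corrected_ghost = .flipAtMin(ghost$interleave_corrected),
    corrected_gain_low_flip = {
      cur <- sig_vs_artifact$interleave_corrected
      mean(cur$value_pct[cur$flip_deg < 10] - 100)
    },
    correction_factor = factor)

  extra <- list(reorder_vs_strong = reorder_vs_strong,
                artifact_vs_strong_only = art_vs_strong,
                artifact_vs_weak_only = art_vs_weak)
  curves <- do.call(rbind, c(
    ghost,
    lapply(sig_vs_artifact, function(cv) {
      cv$metric <- "signal_vs_artifact"; cv
    }),
    list(artifact_vs_strong = within(art_vs_strong,
                                     metric <- "signal_vs_strong_only"),
         artifact_vs_weak = within(art_vs_weak,
                                   metric <- "signal_vs_weak_only"),
         reorder_vs_strong = within(reorder_vs_strong,
                                    metric <- "signal_vs_strong_only")),
    ringing))
  rownames(curves) <- NULL

  structure(list(curves = curves, summaries = summaries, images = images,
                 flip_map = fm, adaptation = adaptation, config = cfg),
            class = "SweepResult")
}

#' @export
print.SweepResult <- function(x, ...) {
  cat(sprintf("SweepResult: %d x %d grid, %d variants, %d curve rows\n",
              x$config$n, x$config$n, length(x$images), nrow(x$curves)))
  s <- x$summaries
  cat(sprintf("  max ghost: interleave %.2f%%, reorder %.4f%%\n",
              s$max_ghost_interleave, s$max_ghost_reorder))
  cat(sprintf("  correction factor %.4f, adapted theta1(%g) scale %.4f\n",
              s$correction_factor, x$config$adapt_nominal_deg,
              x$adaptation@scale))
  invisible(x)
}

#' Write a sweep report to disk
#'
#' Writes `curves.csv` (long format: variant, metric, flip_deg, value_pct)
#' and `summary.json` (all scalar summaries plus the configuration and the
#' metric window definitions). With `images = TRUE` each reconstruction is
#' additionally written as a plain-text PGM (P2) grayscale image.
#'
#' @param result a `SweepResult`.
#' @param out_dir output directory (created if missing).
#' @param images also write PGM renderings.
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(result, out_dir, images = FALSE) {
  if (!inherits(result, "SweepResult"))
    .stopf("'result' must be a SweepResult")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) .stopf("cannot create directory '%s'", out_dir)
  csv <- file.path(out_dir, "curves.csv")
  utils::write.csv(result$curves[, c("variant", "metric", "flip_deg",
                                     "value_pct")],
                   csv, row.names = FALSE)
  cfg <- result$config
  meta <- list(
    summaries = result$summaries,
    config = list(n = cfg$n, radius_frac = cfg$radius_frac,
                  theta_min_deg = cfg$theta_min_deg,
                  theta_max_deg = cfg$theta_max_deg,
                  gradient_axis = cfg$gradient_axis,
                  tr1_ms = cfg$params@tr1, tr2_ms = cfg$params@tr2,
                  te_ms = cfg$params@te, t1_ms = cfg$params@t1,
                  t2star_ms = cfg$params@t2star, m0 = cfg$params@m0,
                  adapt_nominal_deg = cfg$adapt_nominal_deg,
                  correction_method = cfg$correction_method,
                  erosion_ringing_px = cfg$erosion_ringing_px,
                  erosion_oscillation_px = cfg$erosion_oscillation_px),
    metric_windows = list(
      ghost_ratio = "per readout column: mean |image| over half-FOV-shifted mask / mean over mask, percent",
      ringing_amplitude = sprintf("per column of mask eroded by %d px: 100*(max-min)/2 of image/reference - 1",
                                  cfg$erosion_ringing_px),
      oscillation_vs_mean = sprintf("max |image-reference| over mask eroded by %d px / mean reference over full mask, percent",
                                    cfg$erosion_oscillation_px),
      signal_ratio = "per column: 100 * mean |image_a| / mean |image_b| over mask"))
  js <- file.path(out_dir, "summary.json")
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  paths <- c(csv, js)
  if (images) {
    for (nm in names(result$images)) {
      pth <- file.path(out_dir, paste0(nm, ".pgm"))
      writePGM(result$images[[nm]], pth)
      paths <- c(paths, pth)
    }
  }
  invisible(paths)
}

#' Write a matrix as a plain-text PGM (P2) image
#'
#' Intensities are scaled linearly to 0-255 over the matrix range.
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @export
writePGM <- function(mat, path) {
  if (!is.matrix(mat) || !is.numeric(mat)) .stopf("'mat' must be numeric")
  rng <- range(mat)
  scl <- if (diff(rng) > 0) (mat - rng[1]) / diff(rng) else mat * 0
  px <- matrix(as.integer(round(255 * scl)), nrow(mat), ncol(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(px), nrow(px)), "255"), con)
  utils::write.table(px, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
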
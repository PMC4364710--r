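# k-space assembly schemes, the correction factor, and the acquisition
# order.

test_that("identical inputs make every mixing scheme reproduce the strong image", {
  u <- uniformVariants(45)
  ref <- reconstructImage(u$kS)
  for (asm in list(assembleInterleaved(u$kS, u$kS),
                   assembleReordered(u$kS, u$kS),
                   assembleReordered(u$kS, u$kS, inverted = TRUE))) {
    expect_equal(reconstructImage(asm), ref, tolerance = 1e-13)
  }
})

test_that("interleaving bookkeeping: N/2 weak lines, DC held by the strong signal", {
  u <- uniformVariants(45)
  a <- assembleInterleaved(u$kS, u$kW)
  n <- gridSize(a)
  expect_identical(sum(weakLines(a)), n %/% 2L)
  expect_false(weakLines(a)[n / 2 + 1])
  expect_identical(weakLines(a), kyIndex(n) %% 2L == 1L)
})

test_that("uniform-phantom interleave ghost matches the closed form to 1e-10", {
  # interleaving two scaled copies of one image splits it into a main lobe
  # (S1+S2)/2 and a half-FOV replica (S1-S2)/2
  for (th in c(15, 45, 90)) {
    u <- uniformVariants(th)
    img <- reconstructImage(assembleInterleaved(u$kS, u$kW))
    curve <- ghostRatioCurve(img, u$fm)
    s <- steadyStateSignals(th)
    expected <- 100 * (s$s_strong - s$s_weak) / (s$s_strong + s$s_weak)
    expect_lt(max(abs(curve$value_pct - expected)), 1e-8)
    # interior mean equals the average of the two signals
    mask <- flipMask(u$fm)
    expect_equal(mean(img[mask]), (s$s_strong + s$s_weak) / 2,
                 tolerance = 1e-10)
  }
})

test_that("the gradient-phantom ghost sits half a FOV away along phase encode", {
  sw <- standardSweep()
  img <- sw$images$interleave
  fm <- sw$flip_map
  mask <- flipMask(fm)
  n <- nrow(mask)
  ghost <- mask[((seq_len(n) - 1 + n / 2) %% n) + 1, ]
  outside <- !(mask | ghost)
  expect_gt(mean(img[ghost]), 100 * mean(img[outside]))
})

test_that("reordering places the weak lines at the outer k-space ends", {
  u <- uniformVariants(45)
  a64 <- assembleReordered(forwardKspace(matrix(1, 64, 64)),
                           forwardKspace(matrix(2, 64, 64)))
  expect_identical(sort(kyIndex(64)[weakLines(a64)]),
                   c(-32:-17, 16:31))
  a <- assembleReordered(u$kS, u$kW)
  n <- gridSize(a)
  central <- which(kyIndex(n) >= -n / 4 & kyIndex(n) < n / 4)
  expect_identical(kspaceData(a)[central, ], kspaceData(u$kS)[central, ])
  inv <- assembleReordered(u$kS, u$kW, inverted = TRUE)
  expect_identical(weakLines(inv), !weakLines(a))
})

test_that("every assembled row comes verbatim from exactly one source grid", {
  u <- uniformVariants(30)
  for (a in list(assembleInterleaved(u$kS, u$kW),
                 assembleReordered(u$kS, u$kW))) {
    d <- kspaceData(a)
    for (i in seq_len(nrow(d))) {
      src <- if (weakLines(a)[i]) kspaceData(u$kW) else kspaceData(u$kS)
      expect_identical(d[i, ], src[i, ])
    }
  }
})

test_that("zero filling keeps the central half and can only remove energy", {
  u <- uniformVariants(45)
  a <- assembleZeroFilled(u$kS)
  n <- gridSize(a)
  ky <- kyIndex(n)
  expect_true(all(kspaceData(a)[ky < -n / 4 | ky >= n / 4, ] == 0))
  central <- which(ky >= -n / 4 & ky < n / 4)
  expect_identical(kspaceData(a)[central, ], kspaceData(u$kS)[central, ])
  expect_lte(sum(Mod(kspaceData(a))^2), sum(Mod(kspaceData(u$kS))^2))
})

test_that("truncating a 1-D boxcar reproduces the Dirichlet overshoot", {
  # independent 1-D oracle for the zero-fill ringing mechanism
  n <- 256
  f <- as.numeric(abs(seq_len(n) - (n + 1) / 2) <= n / 8)
  ks <- fft(f)
  keep <- c(1:(n / 4), (n - n / 4 + 2):n)   # central half in fft order
  ks[-keep] <- 0
  g <- Re(fft(ks, inverse = TRUE)) / n
  overshoot <- (max(g) - 1)
  expect_gt(overshoot, 0.07)
  expect_lt(overshoot, 0.11)
  # the 2-D pipeline shows the same overshoot on a uniform column
  u <- uniformVariants(45, n = 64)
  img <- reconstructImage(assembleZeroFilled(u$kS))
  mask <- flipMask(u$fm)
  s45 <- steadyStateSignals(45)$s_strong
  col <- which.max(colSums(mask))
  rel <- max(img[mask[, col], col]) / s45 - 1
  expect_gt(rel, 0.05)
  expect_lt(rel, 0.12)
})

test_that("the correction factor reduces to exact ratios on degenerate inputs", {
  u <- uniformVariants(45)
  for (m in c("dc_ratio", "l1_ratio", "masked_pointwise_mean")) {
    expect_equal(estimateCorrectionFactor(u$kS, u$kS, method = m), 1,
                 tolerance = 1e-12)
    # uniform phantom: every estimator sees two proportional center lines
    s <- steadyStateSignals(45)
    expect_equal(estimateCorrectionFactor(u$kS, u$kW, method = m),
                 s$s_weak / s$s_strong, tolerance = 1e-10)
  }
})

test_that("the gradient-phantom factor lies strictly between the extreme signal ratios", {
  sw <- standardSweep()
  s90 <- steadyStateSignals(90)
  f <- sw$summaries$correction_factor
  expect_gt(f, s90$s_weak / s90$s_strong)
  expect_lt(f, 1)
})

test_that("correcting with the exact factor nulls the uniform-phantom ghost", {
  u <- uniformVariants(45)
  s <- steadyStateSignals(45)
  a <- applyCorrection(assembleInterleaved(u$kS, u$kW),
                       s$s_weak / s$s_strong)
  curve <- ghostRatioCurve(reconstructImage(a), u$fm)
  expect_lt(max(curve$value_pct), 1e-8)
  # factor 1 must leave the assembly unchanged
  b <- assembleInterleaved(u$kS, u$kW)
  expect_identical(kspaceData(applyCorrection(b, 1)), kspaceData(b))
})

test_that("applyCorrection validates its inputs", {
  u <- uniformVariants(45)
  a <- assembleInterleaved(u$kS, u$kW)
  expect_error(applyCorrection(a, 0), "factor")
  expect_error(applyCorrection(assembleZeroFilled(u$kS), 0.9),
               "no weak lines")
})

test_that("the corrected gradient-phantom ghost curve has a single interior minimum", {
  sw <- standardSweep()
  cur <- sw$curves
  gc <- cur[cur$variant == "interleave_corrected" &
              cur$metric == "ghost_ratio", ]
  i <- which.min(gc$value_pct)
  expect_gt(i, 1)
  expect_lt(i, nrow(gc))
  # values fall monotonically toward the minimum and rise after it (allow
  # tiny numerical wiggle)
  expect_true(all(diff(gc$value_pct[seq_len(i)]) < 1e-6))
  expect_true(all(diff(gc$value_pct[i:nrow(gc)]) > -1e-6))
})

test_that("acquisition order alternates blocks with the center line near the middle", {
  ord <- acquisitionOrder(64)
  expect_identical(sort(ord), -32:31)           # a permutation
  expect_identical(ord[1:4], c(-32L, -16L, -31L, -15L))
  # DC within one TR pair of the exact midpoint
  expect_lte(abs(which(ord == 0L) - (64 + 1) / 2), 2)
  # strict weak/strong alternation (every odd acquisition is a weak line)
  for (n in c(8L, 64L, 128L)) {
    o <- acquisitionOrder(n)
    expect_identical(which(o == 0L), n %/% 2L + 2L)
    outer_block <- o[seq(1, n, by = 2)]
    expect_true(all(outer_block < -n / 4 | outer_block >= n / 4))
    inner_block <- o[seq(2, n, by = 2)]
    expect_true(all(inner_block >= -n / 4 & inner_block < n / 4))
  }
  expect_error(acquisitionOrder(10), "divisible by 4")
})

test_that("assembly provenance serializes to JSON and back", {
  u <- uniformVariants(45)
  a <- applyCorrection(assembleInterleaved(u$kS, u$kW), 0.9)
  prov <- assemblyProvenance(a)
  back <- jsonlite::fromJSON(jsonlite::toJSON(prov, auto_unbox = TRUE))
  expect_identical(back$scheme, "interleave")
  expect_identical(as.integer(back$weak_ky), kyIndex(64)[weakLines(a)])
  expect_equal(back$correction_factor, 0.9)
})
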
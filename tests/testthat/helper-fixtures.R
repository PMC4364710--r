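# Shared fixtures, built once per test run. Everything is deterministic, so
# caching is purely a speed concern.

.fixtures <- new.env(parent = emptyenv())

# the standard 256-pixel gradient-phantom sweep (default conditions)
standardSweep <- function() {
  if (is.null(.fixtures$sweep))
    .fixtures$sweep <- runStandardSweep(sweepConfig())
  .fixtures$sweep
}

# small uniform-phantom reconstruction set for closed-form checks
uniformVariants <- function(theta_deg, n = 64) {
  key <- sprintf("uniform_%g_%d", theta_deg, n)
  if (is.null(.fixtures[[key]])) {
    fm <- makeUniformFlipMap(n, 0.2, theta_deg)
    pair <- simulateImagePair(fm)
    kS <- forwardKspace(imgStrong(pair))
    kW <- forwardKspace(imgWeak(pair))
    .fixtures[[key]] <- list(fm = fm, pair = pair, kS = kS, kW = kW)
  }
  .fixtures[[key]]
}
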
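# Shared fixtures, all generated in code. The two-species deconvolved
# dataset is expensive enough to build once and reuse across test files.

PROTON <- 1.00728

# Noiseless spectrum with one Gaussian peak per charge state of each mass;
# areas[j] scales species j as a whole.
chargeSeriesSpectrum <- function(masses, zList, axis, fwhm = 2, areas = 1,
                                 adduct = PROTON) {
  if (!is.list(zList)) zList <- list(zList)
  areas <- rep_len(areas, length(masses))
  y <- numeric(length(axis))
  for (j in seq_along(masses)) {
    centers <- (masses[j] + zList[[j]] * adduct) / zList[[j]]
    for (c0 in centers)
      y <- y + areas[j] * stats::dnorm(axis, c0, fwhm / 2.35482)
  }
  MsiSpectrum(axis, y, domain = "mz")
}

smallDataset <- function(width = 2, height = 2, nPoints = 1000, seed = 42) {
  sim <- simulateMsiDataset(
    list(ProteoformSpec(mass = 60000, chargeCenter = 13, chargeSigma = 1.2,
                        zRange = c(11, 15), peakFWHM = 4,
                        pattern = "uniform", amplitude = 20)),
    NoiseSpec(baselineLevel = 0.1, gaussianSD = 0.05, seed = seed),
    width = width, height = height, axis = c(3500, 6000, nPoints))
  sim$dataset
}

.fixtures <- new.env(parent = emptyenv())

# 12 x 10 grid, two species with disjoint spatial patterns:
#   A: the 94,316 Da tetramer, charges 13-16, left half-plane;
#   C: a confounder whose 15+ channel coincides with where A's 18+ channel
#      would sit, right half-plane (the "different spatial pattern,
#      overlapping m/z" case).
twoSpeciesFixture <- function() {
  if (!is.null(.fixtures$two)) return(.fixtures$two)
  massA <- 94316
  mzA18 <- mzForCharge(massA, 18)
  massC <- massFromMz(mzA18, 15)
  sim <- simulateMsiDataset(
    list(
      ProteoformSpec(mass = massA, chargeCenter = 14.5, chargeSigma = 1.1,
                     zRange = c(13, 16), peakFWHM = 3,
                     pattern = "half_plane",
                     patternParams = list(side = "left"), amplitude = 100),
      ProteoformSpec(mass = massC, chargeCenter = 15, chargeSigma = 1.1,
                     zRange = c(13, 17), peakFWHM = 3,
                     pattern = "half_plane",
                     patternParams = list(side = "right"), amplitude = 100)),
    NoiseSpec(baselineLevel = 0.05, gaussianSD = 0.02, seed = 19),
    width = 12, height = 10, axis = c(4400, 7500, 1600))
  cfg <- DeconvConfig(zMin = 12, zMax = 20, massMin = 70000,
                      massMax = 100000, massBin = 20, nIter = 25,
                      peakFWHM = 3)
  res <- deconvolveDataset(sim$dataset, cfg)
  .fixtures$two <- list(sim = sim, cfg = cfg, res = res,
                        massA = massA, massC = massC)
  .fixtures$two
}

# one CKB-homodimer-like species on a small grid, deconvolved
ckbFixture <- function() {
  if (!is.null(.fixtures$ckb)) return(.fixtures$ckb)
  sim <- simulateMsiDataset(
    list(ProteoformSpec(mass = 85170, chargeCenter = 14.5, chargeSigma = 1,
                        zRange = c(13, 16), peakFWHM = 3, pattern = "disk",
                        amplitude = 50)),
    NoiseSpec(baselineLevel = 0, gaussianSD = 0, seed = 3),
    width = 6, height = 6, axis = c(5100, 6800, 1200))
  cfg <- DeconvConfig(zMin = 11, zMax = 19, massMin = 80000,
                      massMax = 90000, massBin = 10, nIter = 25,
                      peakFWHM = 3)
  res <- deconvolveDataset(sim$dataset, cfg)
  .fixtures$ckb <- list(sim = sim, cfg = cfg, res = res)
  .fixtures$ckb
}
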
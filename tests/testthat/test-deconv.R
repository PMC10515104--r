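cfgFor <- function(massMin, massMax, zMin, zMax, massBin = 10, nIter = 30,
                   peakFWHM = 2, ...) {
  DeconvConfig(zMin = zMin, zMax = zMax, massMin = massMin, massMax = massMax,
               massBin = massBin, nIter = nIter, peakFWHM = peakFWHM, ...)
}

test_that("preprocessing truncates, subtracts background, floors at zero", {
  ax <- seq(1000, 2000, by = 1)
  sp <- MsiSpectrum(ax, rep(3, length(ax)), "mz")
  # no-op config: identity
  cfg <- DeconvConfig(mzMin = 0, mzMax = 1e6, backgroundWidth = 0)
  expect_identical(axisValues(preprocessSpectrum(sp, cfg)), ax)
  expect_identical(intensityValues(preprocessSpectrum(sp, cfg)),
                   intensityValues(sp))
  # a flat spectrum minus its rolling minimum is zero
  cfgBg <- DeconvConfig(mzMin = 0, mzMax = 1e6, backgroundWidth = 20)
  expect_true(all(intensityValues(preprocessSpectrum(sp, cfgBg)) == 0))
  # window truncation
  cfgWin <- DeconvConfig(mzMin = 1200, mzMax = 1400)
  out <- preprocessSpectrum(sp, cfgWin)
  expect_true(all(axisValues(out) >= 1200 & axisValues(out) <= 1400))
  # a window excluding everything flags by emptiness, no exception
  cfgNone <- DeconvConfig(mzMin = 5000, mzMax = 6000)
  expect_length(axisValues(preprocessSpectrum(sp, cfgNone)), 0)
})

test_that("background subtraction keeps a peak on a sloped baseline", {
  ax <- seq(1000, 1200, by = 0.25)
  slope <- 0.004
  baseline <- slope * (ax - 1000)
  peak <- 10 * exp(-(ax - 1100)^2 / (2 * (2 / 2.35482)^2))
  sp <- MsiSpectrum(ax, baseline + peak, "mz")
  cfg <- DeconvConfig(mzMin = 0, mzMax = 1e6, backgroundWidth = 30)
  out <- preprocessSpectrum(sp, cfg)
  apex <- max(intensityValues(out))
  # a rolling minimum can overshoot by at most slope * half-window
  expect_lt(abs(apex - 10), slope * 15 + 1e-6)
  expect_lt(abs(apex - 10) / 10, 0.01)
})

test_that("a noiseless charge series deconvolves to its true mass", {
  # Gaussian peaks (FWHM 2 Th) at charges 13..17 of one species, equal areas
  M <- 85170
  ax <- seq(4700, 6800, by = 0.25)
  sp <- chargeSeriesSpectrum(M, list(13:17), ax, fwhm = 2)
  cfg <- cfgFor(80000, 90000, 10, 20)
  res <- deconvolveSpectrum(sp, cfg)
  pk <- peakPick(res$massSpectrum, 0.01, 50)
  main <- pk[which.max(pk$height), ]
  expect_lt(abs(main$mass - M), cfg@massBin)
  # largest spurious (harmonic) peak below 20% of the main peak
  others <- pk$height[pk$mass < main$mass - 50 | pk$mass > main$mass + 50]
  if (length(others)) expect_lt(max(others) / main$height, 0.20)
})

test_that("charge-assignment weights are normalized per signal point", {
  ax <- seq(4700, 6800, by = 0.5)
  sp <- chargeSeriesSpectrum(70000, list(11:14), ax, fwhm = 3)
  # zero out a stretch to exercise the empty-point rule
  y <- intensityValues(sp); y[1:100] <- 0
  sp <- MsiSpectrum(ax, y, "mz")
  res <- deconvolveSpectrum(sp, cfgFor(60000, 80000, 9, 16))
  rs <- rowSums(assignmentWeights(res$assignment))
  expect_true(all(abs(rs - 1) < 1e-9 | rs == 0))
  expect_true(all(rs[y == 0] == 0))
  expect_true(min(assignmentWeights(res$assignment)) >= 0)
})

test_that("intensity is conserved when no peak-width step is used", {
  ax <- seq(3000, 6000, by = 0.5)
  sp <- chargeSeriesSpectrum(60000, list(11:16), ax, fwhm = 4)
  # window covering every hypothesis mass: z in [10,20] over the full axis
  cfg <- cfgFor(10 * (3000 - 1.00728), 20 * 6000, 10, 20, peakFWHM = 0)
  res <- deconvolveSpectrum(sp, cfg)
  expect_lt(abs(sum(intensityValues(res$massSpectrum)) -
                sum(intensityValues(sp))) / sum(intensityValues(sp)),
            0.005)
})

test_that("all-zero and excluded-window inputs give all-zero output", {
  ax <- seq(4000, 5000, by = 1)
  zero <- MsiSpectrum(ax, numeric(length(ax)), "mz")
  cfg <- cfgFor(50000, 90000, 10, 20)
  expect_true(all(intensityValues(deconvolveSpectrum(zero, cfg)$massSpectrum) == 0))
  some <- chargeSeriesSpectrum(60000, list(12:14), ax, fwhm = 3)
  cfgOff <- cfgFor(1e6, 2e6, 10, 20)  # excludes every hypothesis
  expect_warning(res <- deconvolveSpectrum(some, cfgOff), regexp = "window")
  expect_true(all(intensityValues(res$massSpectrum) == 0))
})

test_that("random species are recovered within one mass bin", {
  # property: any mass, any contiguous charge run of >= 3 states
  withr::local_seed(424242)
  for (rep in seq_len(20)) {
    M <- runif(1, 30000, 80000)
    z0 <- sample(9:16, 1)
    zs <- z0:(z0 + sample(2:4, 1))
    centers <- mzForCharge(M, zs)
    ax <- seq(min(centers) - 60, max(centers) + 60, by = 0.4)
    sp <- chargeSeriesSpectrum(M, list(zs), ax, fwhm = 2)
    cfg <- cfgFor(M - 3000, M + 3000, max(1, z0 - 2), z0 + 6,
                  massBin = 10, nIter = 25)
    res <- deconvolveSpectrum(sp, cfg)
    pk <- peakPick(res$massSpectrum, 0.2, 100)
    expect_gt(nrow(pk), 0)
    apex <- pk$mass[which.max(pk$height)]
    expect_lt(abs(apex - M), cfg@massBin)
  }
})

test_that("two separated species keep their abundance ratio", {
  M1 <- 90000; M2 <- 91500; ratio <- 3
  ax <- seq(4400, 7600, by = 0.25)
  sp <- chargeSeriesSpectrum(c(M1, M2), list(13:16, 13:16), ax,
                             fwhm = 2, areas = c(ratio, 1))
  cfg <- cfgFor(85000, 95000, 11, 18, massBin = 10, nIter = 30)
  res <- deconvolveSpectrum(sp, cfg)
  pk <- peakPick(res$massSpectrum, 0.1, 500)
  pk <- pk[order(-pk$height), ][1:2, ]
  expect_lt(abs(sort(pk$mass)[1] - M1), 15)
  expect_lt(abs(sort(pk$mass)[2] - M2), 15)
  got <- max(pk$height) / min(pk$height)
  expect_lt(abs(got - ratio) / ratio, 0.15)
})

test_that("the engine is deterministic and per-pixel independent", {
  ds <- smallDataset(width = 2, height = 2, nPoints = 600, seed = 5)
  cfg <- cfgFor(50000, 70000, 10, 16, massBin = 20, nIter = 10, peakFWHM = 4)
  r1 <- deconvolveDataset(ds, cfg)
  r2 <- deconvolveDataset(ds, cfg)
  for (i in seq_len(4))
    expect_identical(intensityValues(r1$massSpectra[[i]]),
                     intensityValues(r2$massSpectra[[i]]))
  # permuting input pixels permutes outputs identically
  perm <- c(3L, 1L, 4L, 2L)
  dsPerm <- MsiDataset(spectra(ds)[perm], pixelCoords(ds)[perm, ],
                       domain = "mz", width = 2, height = 2)
  rp <- deconvolveDataset(dsPerm, cfg)
  for (k in seq_along(perm))
    expect_identical(intensityValues(rp$massSpectra[[k]]),
                     intensityValues(r1$massSpectra[[perm[k]]]))
  # dataset-summed spectrum is the pixel-wise sum, invariant to order
  expect_equal(intensityValues(rp$summed), intensityValues(r1$summed))
})

test_that("a dataset run is linear in pixel intensity", {
  ax <- seq(4200, 6200, by = 0.5)
  a <- chargeSeriesSpectrum(70000, list(12:15), ax, fwhm = 3)
  b <- MsiSpectrum(ax, 2 * intensityValues(a), "mz")
  ds <- MsiDataset(list(a, b), data.frame(x = 1:2, y = 1), domain = "mz",
                   width = 2, height = 1)
  cfg <- cfgFor(60000, 80000, 10, 17, nIter = 15, peakFWHM = 0)
  res <- deconvolveDataset(ds, cfg)
  expect_equal(intensityValues(res$massSpectra[[2]]),
               2 * intensityValues(res$massSpectra[[1]]), tolerance = 1e-12)
})

test_that("deconvolving a mass-domain input is refused", {
  fx <- ckbFixture()
  expect_error(deconvolveDataset(fx$res$dataset, fx$cfg),
               class = "msi_contract_error")
})

test_that("peak picking finds, refines and separates apexes", {
  grid <- seq(90000, 96000, by = 10)
  gauss <- function(m0, h, fw) h * exp(-4 * log(2) * (grid - m0)^2 / fw^2)
  # single peak centered on a grid point
  one <- MassSpectrum(grid, gauss(93000, 5, 200))
  pk1 <- peakPick(one, 0.1, 50)
  expect_equal(nrow(pk1), 1)
  expect_equal(pk1$mass, 93000, tolerance = 1e-6)
  # shoulder pair: 71 Da apart, FWHM 20 Da, heights 3:1
  grid2 <- seq(94000, 94600, by = 2)
  g2 <- function(m0, h) h * exp(-4 * log(2) * (grid2 - m0)^2 / 20^2)
  two <- MassSpectrum(grid2, g2(94316, 3) + g2(94387, 1))
  pk2 <- peakPick(two, 0.05, 30)
  expect_equal(nrow(pk2), 2)
  expect_lt(abs(abs(diff(pk2$mass)) - 71), 2)
  # all-zero spectrum: empty result
  expect_equal(nrow(peakPick(MassSpectrum(grid, numeric(length(grid))))), 0)
})
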
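#' @import methods
NULL

.DOMAINS <- c("mz", "mass")

#' Single-pixel spectrum
#'
#' One pixel's spectrum: an ascending axis (Th for the m/z domain, Da for
#' the mass domain) with non-negative intensities. A zero-length spectrum is
#' legal and marks a pixel whose analysis window removed every point.
#'
#' @slot axis numeric, strictly ascending axis values.
#' @slot intensity numeric, non-negative abundances (arbitrary units).
#' @slot domain `"mz"` or `"mass"`.
#'
#' @export
setClass("MsiSpectrum", representation(
  axis = "numeric",
  intensity = "numeric",
  domain = "character"
))

setValidity("MsiSpectrum", function(object) {
  msg <- character()
  if (length(object@domain) != 1L || !object@domain %in% .DOMAINS)
    msg <- c(msg, "domain must be one of 'mz', 'mass'")
  if (length(object@axis) != length(object@intensity))
    msg <- c(msg, "axis and intensity must have equal length")
  if (length(object@axis) > 1L && any(diff(object@axis) <= 0))
    msg <- c(msg, "axis must be strictly ascending")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param axis,intensity,domain see slots.
#' @rdname MsiSpectrum-class
#' @export
MsiSpectrum <- function(axis, intensity, domain = c("mz", "mass")) {
  domain <- match.arg(domain)
  new("MsiSpectrum", axis = as.numeric(axis),
      intensity = as.numeric(intensity), domain = domain)
}

#' MSI dataset: ordered pixel spectra plus coordinates
#'
#' The central container: a parallel collection of [MsiSpectrum] objects and
#' 1-based pixel coordinates (x = column, y = row, z = plane) on a
#' `width` x `height` grid. Pixels absent from the grid are simply missing
#' (never zero-filled); image extraction renders them as zero.
#'
#' @slot spectra list of [MsiSpectrum], one per pixel, acquisition order.
#' @slot coords data.frame with integer columns `x`, `y`, `z` (all >= 1).
#' @slot domain `"mz"` or `"mass"`, uniform across all spectra.
#' @slot width,height image dimensions in pixels.
#'
#' @export
setClass("MsiDataset", representation(
  spectra = "list",
  coords = "data.frame",
  domain = "character",
  width = "integer",
  height = "integer"
))

setValidity("MsiDataset", function(object) {
  msg <- character()
  if (length(object@domain) != 1L || !object@domain %in% .DOMAINS)
    msg <- c(msg, "domain must be one of 'mz', 'mass'")
  if (length(object@spectra) != nrow(object@coords))
    msg <- c(msg, "spectra and coords must be parallel (same length)")
  if (!all(c("x", "y", "z") %in% names(object@coords)))
    msg <- c(msg, "coords must have columns x, y, z")
  else {
    cc <- object@coords
    if (nrow(cc)) {
      if (any(cc$x < 1L) || any(cc$y < 1L) || any(cc$z < 1L))
        msg <- c(msg, "coordinates are 1-based: all must be >= 1")
      if (any(cc$x > object@width) || any(cc$y > object@height))
        msg <- c(msg, "coordinates must lie within (width, height)")
      if (anyDuplicated(cc[c("x", "y", "z")]))
        msg <- c(msg, "pixel coordinates must be unique")
    }
  }
  bad <- vapply(object@spectra, function(s)
    !is(s, "MsiSpectrum") || s@domain != object@domain, logical(1))
  if (any(bad))
    msg <- c(msg, "all spectra must be MsiSpectrum objects in the dataset domain")
  if (length(msg)) msg else TRUE
})

#' @param spectra,coords,domain,width,height see slots. `coords` may omit
#'   `z` (defaults to 1); `width`/`height` default to the coordinate maxima.
#' @rdname MsiDataset-class
#' @export
MsiDataset <- function(spectra, coords, domain = c("mz", "mass"),
                       width = NULL, height = NULL) {
  domain <- match.arg(domain)
  coords <- as.data.frame(coords)
  if (is.null(coords$z)) coords$z <- rep(1L, nrow(coords))
  coords$x <- as.integer(coords$x)
  coords$y <- as.integer(coords$y)
  coords$z <- as.integer(coords$z)
  if (is.null(width)) width <- max(coords$x, 0L)
  if (is.null(height)) height <- max(coords$y, 0L)
  new("MsiDataset", spectra = spectra,
      coords = coords[c("x", "y", "z")], domain = domain,
      width = as.integer(width), height = as.integer(height))
}

#' Deconvolution parameter set
#'
#' The single configuration applied to every pixel of a dataset run.
#' Defaults target native protein MSI: charges 5-30, a 10 Da output grid,
#' 50 iterations of the charge-assignment update and a +/- 1 charge
#' smoothness window.
#'
#' @slot zMin,zMax inclusive charge range (>= 1).
#' @slot adductMass Da added per charge; 1.00728 Da (a proton) by default.
#' @slot massMin,massMax output mass window (Da).
#' @slot massBin output grid spacing (Da).
#' @slot nIter iteration count (>= 1).
#' @slot chargeSmoothWidth +/- charge states in the smoothness filter.
#' @slot peakFWHM expected m/z peak full width at half maximum (Th);
#'   0 disables the Richardson-Lucy peak-width step.
#' @slot peakShape `"gaussian"` or `"lorentzian"`.
#' @slot backgroundWidth rolling-minimum background window (Th, 0 = off).
#' @slot mzMin,mzMax analysis window (Th).
#' @slot massSmoothSigma Gaussian smoothing of the output mass axis (Da,
#'   0 = off).
#'
#' @export
setClass("DeconvConfig", representation(
  zMin = "integer", zMax = "integer",
  adductMass = "numeric",
  massMin = "numeric", massMax = "numeric", massBin = "numeric",
  nIter = "integer",
  chargeSmoothWidth = "integer",
  peakFWHM = "numeric", peakShape = "character",
  backgroundWidth = "numeric",
  mzMin = "numeric", mzMax = "numeric",
  massSmoothSigma = "numeric"
))

setValidity("DeconvConfig", function(object) {
  msg <- character()
  if (object@zMin < 1L) msg <- c(msg, "z_min must be >= 1")
  if (object@zMin > object@zMax) msg <- c(msg, "z_min must be <= z_max")
  if (object@massMin >= object@massMax) msg <- c(msg, "mass_min must be < mass_max")
  if (object@massBin <= 0) msg <- c(msg, "mass_bin must be > 0")
  if (object@nIter < 1L) msg <- c(msg, "n_iter must be >= 1")
  if (object@chargeSmoothWidth < 0L) msg <- c(msg, "charge_smooth_width must be >= 0")
  if (object@peakFWHM < 0) msg <- c(msg, "peak_fwhm must be >= 0")
  if (!object@peakShape %in% c("gaussian", "lorentzian"))
    msg <- c(msg, "peak_shape must be 'gaussian' or 'lorentzian'")
  if (object@backgroundWidth < 0) msg <- c(msg, "background_width must be >= 0")
  if (object@mzMin >= object@mzMax) msg <- c(msg, "mz_min must be < mz_max")
  if (object@massSmoothSigma < 0) msg <- c(msg, "mass_smooth_sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param zMin,zMax,adductMass,massMin,massMax,massBin,nIter
#'   see slots.
#' @param chargeSmoothWidth,peakFWHM,peakShape,backgroundWidth see slots.
#' @param mzMin,mzMax,massSmoothSigma see slots.
#' @rdname DeconvConfig-class
#' @export
DeconvConfig <- function(zMin = 5L, zMax = 30L, adductMass = 1.00728,
                         massMin = 20000, massMax = 200000, massBin = 10,
                         nIter = 50L, chargeSmoothWidth = 1L,
                         peakFWHM = 2, peakShape = c("gaussian", "lorentzian"),
                         backgroundWidth = 0, mzMin = 0, mzMax = 1e5,
                         massSmoothSigma = 0) {
  peakShape <- match.arg(peakShape)
  new("DeconvConfig",
      zMin = as.integer(zMin), zMax = as.integer(zMax),
      adductMass = adductMass, massMin = massMin, massMax = massMax,
      massBin = massBin, nIter = as.integer(nIter),
      chargeSmoothWidth = as.integer(chargeSmoothWidth),
      peakFWHM = peakFWHM, peakShape = peakShape,
      backgroundWidth = backgroundWidth, mzMin = mzMin, mzMax = mzMax,
      massSmoothSigma = massSmoothSigma)
}

#' Deconvolved mass spectrum on a uniform grid
#'
#' @slot mass numeric, uniform grid from `mass_min` to `mass_max` in steps
#'   of `mass_bin` (Da).
#' @slot intensity numeric, non-negative.
#'
#' @export
setClass("MassSpectrum", representation(
  mass = "numeric",
  intensity = "numeric"
))

setValidity("MassSpectrum", function(object) {
  msg <- character()
  if (length(object@mass) != length(object@intensity))
    msg <- c(msg, "mass and intensity must have equal length")
  if (length(object@mass) > 2L) {
    d <- diff(object@mass)
    if (max(d) - min(d) > 1e-6 * max(d))
      msg <- c(msg, "mass grid must be uniform")
  }
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param mass,intensity see slots.
#' @rdname MassSpectrum-class
#' @export
MassSpectrum <- function(mass, intensity) {
  new("MassSpectrum", mass = as.numeric(mass), intensity = as.numeric(intensity))
}

#' Per-point charge assignment weights
#'
#' Posterior weight matrix of the charge-assignment iteration: `weights[i, k]`
#' is the probability that data point `i` carries charge `charges[k]`. Rows
#' of points with signal sum to 1; rows of empty points are all zero.
#'
#' @slot weights numeric matrix, points x charges, >= 0.
#' @slot charges integer vector of the charge states considered.
#'
#' @export
setClass("ChargeAssignment", representation(
  weights = "matrix",
  charges = "integer"
))

setValidity("ChargeAssignment", function(object) {
  msg <- character()
  if (ncol(object@weights) != length(object@charges))
    msg <- c(msg, "weights must have one column per charge")
  if (length(object@weights) && min(object@weights) < 0)
    msg <- c(msg, "weights must be >= 0")
  rs <- rowSums(object@weights)
  if (length(rs) && any(abs(rs - 1) > 1e-9 & abs(rs) > 1e-9))
    msg <- c(msg, "each row must sum to 0 or 1")
  if (length(msg)) msg else TRUE
})

#' 2-D intensity image extracted at an axis window
#'
#' `values` is indexed `[row, col]` = `[y, x]`; pixels absent from the source
#' dataset are zero. The window is the closed interval
#' `[center - halfWidth, center + halfWidth]`.
#'
#' @slot values numeric height x width matrix, >= 0.
#' @slot label free-text description of the extraction window.
#' @slot center,halfWidth extraction window (Th or Da).
#' @slot domain `"mz"` or `"mass"`.
#'
#' @export
setClass("IntensityImage", representation(
  values = "matrix",
  label = "character",
  center = "numeric",
  halfWidth = "numeric",
  domain = "character"
))

setValidity("IntensityImage", function(object) {
  msg <- character()
  if (length(object@values) && min(object@values) < 0)
    msg <- c(msg, "image values must be >= 0")
  if (!object@domain %in% .DOMAINS)
    msg <- c(msg, "domain must be one of 'mz', 'mass'")
  if (length(msg)) msg else TRUE
})

IntensityImage <- function(values, label = "", center = NA_real_,
                           halfWidth = NA_real_, domain = "mz") {
  new("IntensityImage", values = values, label = label,
      center = center, halfWidth = halfWidth, domain = domain)
}

#' Synthetic proteoform description
#'
#' One simulated species: its neutral mass, a Gaussian charge envelope
#' (discretised over `zRange` and renormalised), the m/z peak width, and a
#' spatial abundance pattern.
#'
#' @slot mass neutral mass (Da).
#' @slot chargeCenter,chargeSigma mean and width (in charges) of the
#'   Gaussian charge envelope.
#' @slot zRange integer length-2, inclusive charges simulated.
#' @slot peakFWHM m/z peak full width at half maximum (Th).
#' @slot pattern spatial abundance pattern: `"uniform"`, `"half_plane"`,
#'   `"disk"` or `"gradient"`.
#' @slot patternParams named list of pattern parameters (see
#'   [simulateMsiDataset()]).
#' @slot amplitude maximum per-pixel peak area (arbitrary units).
#'
#' @export
setClass("ProteoformSpec", representation(
  mass = "numeric",
  chargeCenter = "numeric",
  chargeSigma = "numeric",
  zRange = "integer",
  peakFWHM = "numeric",
  pattern = "character",
  patternParams = "list",
  amplitude = "numeric"
))

setValidity("ProteoformSpec", function(object) {
  msg <- character()
  if (object@mass <= 0) msg <- c(msg, "mass must be > 0")
  if (length(object@zRange) != 2L || object@zRange[1] > object@zRange[2] ||
      object@zRange[1] < 1L)
    msg <- c(msg, "zRange must be an increasing pair of charges >= 1")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (!object@pattern %in% c("uniform", "half_plane", "disk", "gradient"))
    msg <- c(msg, "unknown abundance pattern")
  if (object@peakFWHM <= 0) msg <- c(msg, "peakFWHM must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param mass,chargeCenter,chargeSigma,zRange,peakFWHM,pattern,patternParams,amplitude
#'   see slots.
#' @rdname ProteoformSpec-class
#' @export
ProteoformSpec <- function(mass, chargeCenter, chargeSigma = 1.5,
                           zRange = NULL, peakFWHM = 2,
                           pattern = c("uniform", "half_plane", "disk", "gradient"),
                           patternParams = list(), amplitude = 100) {
  pattern <- match.arg(pattern)
  if (is.null(zRange))
    zRange <- c(max(1, floor(chargeCenter - 2 * chargeSigma)),
                ceiling(chargeCenter + 2 * chargeSigma))
  new("ProteoformSpec", mass = mass, chargeCenter = chargeCenter,
      chargeSigma = chargeSigma, zRange = as.integer(zRange),
      peakFWHM = peakFWHM, pattern = pattern,
      patternParams = patternParams, amplitude = amplitude)
}

#' Synthetic noise description
#'
#' Additive Gaussian noise on a constant baseline, floored at zero. The seed
#' is mandatory so generated datasets are reproducible bit for bit.
#'
#' @slot baselineLevel additive constant.
#' @slot gaussianSD per-point Gaussian noise standard deviation.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("NoiseSpec", representation(
  baselineLevel = "numeric",
  gaussianSD = "numeric",
  seed = "integer"
))

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (object@baselineLevel < 0 || object@gaussianSD < 0)
    msg <- c(msg, "baselineLevel and gaussianSD must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' @param baselineLevel,gaussianSD,seed see slots.
#' @rdname NoiseSpec-class
#' @export
NoiseSpec <- function(baselineLevel = 0, gaussianSD = 0, seed) {
  new("NoiseSpec", baselineLevel = baselineLevel, gaussianSD = gaussianSD,
      seed = as.integer(seed))
}
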
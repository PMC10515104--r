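# Iterative Bayesian charge-state deconvolution of non-isotopically-resolved
# electrospray spectra, UniDec-family. Per data point i and charge z the
# hypothesis mass is M[i,z] = z*(x_i - adduct); a weight matrix W (points x
# charges) is refined by a charge-smoothness filter and, when a peak width
# is configured, a Richardson-Lucy peak-shape step; the weighted intensities
# are then binned onto a uniform mass grid.

#' Preprocess one pixel's m/z spectrum
#'
#' Truncates to the configured analysis window `[mz_min, mz_max]` and, when
#' `background_width > 0`, subtracts a centred rolling-minimum background of
#' that width (in Th), flooring at zero. A window that excludes every point
#' yields an empty (zero-length) spectrum rather than an error; empty pixels
#' deconvolve to all-zero output.
#'
#' @param spectrum an m/z-domain [MsiSpectrum].
#' @param config a [DeconvConfig].
#' @return an [MsiSpectrum].
#' @export
preprocessSpectrum <- function(spectrum, config) {
  stopifnot(is(spectrum, "MsiSpectrum"), is(config, "DeconvConfig"))
  if (spectrum@domain != "mz")
    stopContract("preprocessing expects an m/z-domain spectrum")
  keep <- spectrum@axis >= config@mzMin & spectrum@axis <= config@mzMax
  ax <- spectrum@axis[keep]
  y <- spectrum@intensity[keep]
  if (length(ax) && config@backgroundWidth > 0) {
    spacing <- if (length(ax) > 1L) stats::median(diff(ax)) else 1
    k <- max(1L, round(config@backgroundWidth / spacing))
    y <- pmax(y - rollingMin(y, k), 0)
  }
  MsiSpectrum(ax, pmax(y, 0), domain = "mz")
}

# Precomputed interpolation geometry for the charge-smoothness filter.
# For each charge z and neighbour z', the m/z where a species whose
# hypothesis mass comes from (x, z) would appear at z' is a fixed monotone
# map of the axis, so interpolation indices/weights are computed once.
chargeGeometry <- function(axis, config) {
  zs <- seq.int(config@zMin, config@zMax)
  nz <- length(zs)
  nx <- length(axis)
  w <- config@chargeSmoothWidth
  pairs <- list()
  counts <- integer(nz)
  for (zi in seq_len(nz)) {
    lo <- max(1L, zi - w); hi <- min(nz, zi + w)
    counts[zi] <- hi - lo + 1L
    for (zj in lo:hi) {
      u <- (zs[zi] * (axis - config@adductMass)) / zs[zj] + config@adductMass
      j1 <- findInterval(u, axis)
      bad <- j1 < 1L | u > axis[nx]
      j1c <- pmin(pmax(j1, 1L), nx)
      j2 <- pmin(j1c + 1L, nx)
      den <- axis[j2] - axis[j1c]
      t <- ifelse(den > 0, (u - axis[j1c]) / den, 0)
      w1 <- 1 - t; w2 <- t
      w1[bad] <- 0; w2[bad] <- 0
      pairs[[length(pairs) + 1L]] <- list(zi = zi, zj = zj, j1 = j1c,
                                          j2 = j2, w1 = w1, w2 = w2)
    }
  }
  # hypothesis masses and the in-window mask
  M <- outer(axis - config@adductMass, zs)
  inWin <- M >= config@massMin & M <= config@massMax
  list(zs = zs, nz = nz, nx = nx, pairs = pairs, counts = counts,
       M = M, inWin = inWin)
}

peakKernel <- function(config, spacing) {
  if (config@peakFWHM <= 0) return(NULL)
  if (config@peakShape == "gaussian") {
    sigmaPts <- max(config@peakFWHM / 2.35482 / spacing, 0.3)
    gaussKernel(sigmaPts)
  } else {
    lorentzKernel(max(config@peakFWHM / spacing, 0.5))
  }
}

massGrid <- function(config)
  seq(config@massMin, config@massMax, by = config@massBin)

# Bin weighted point intensities onto the uniform mass grid, splitting each
# contribution linearly between the two flanking bins (conserves intensity).
binToMassGrid <- function(masses, weights, config, grid) {
  nb <- length(grid)
  acc <- numeric(nb)
  ok <- weights > 0 & masses >= config@massMin & masses <= config@massMax
  if (!any(ok)) return(acc)
  m <- masses[ok]; wt <- weights[ok]
  p <- (m - config@massMin) / config@massBin
  k1 <- floor(p)
  f <- p - k1
  i1 <- as.integer(k1) + 1L
  i2 <- pmin(i1 + 1L, nb)
  idx <- c(i1, i2)
  val <- c(wt * (1 - f), wt * f)
  keep <- val > 0
  if (any(keep)) {
    s <- rowsum(val[keep], idx[keep])
    acc[as.integer(rownames(s))] <- s
  }
  acc
}

#' Deconvolve one spectrum to the mass domain
#'
#' The engine behind every pixel: iterative charge assignment with a
#' smoothness filter over neighbouring charge states, an optional
#' Richardson-Lucy peak-width step against the configured peak shape, and
#' linear-split binning onto the uniform mass grid. Deterministic: identical
#' input and configuration give bit-identical output.
#'
#' With `peak_fwhm = 0` and a mass window covering all charge hypotheses,
#' total intensity is conserved exactly by construction.
#'
#' @param spectrum a preprocessed m/z-domain [MsiSpectrum] (see
#'   [preprocessSpectrum()]).
#' @param config a [DeconvConfig].
#' @param geometry optional precomputed geometry (internal; lets a dataset
#'   run with a shared axis reuse one geometry for every pixel).
#' @return a list with elements `massSpectrum` ([MassSpectrum]) and
#'   `assignment` ([ChargeAssignment]).
#' @export
deconvolveSpectrum <- function(spectrum, config, geometry = NULL) {
  stopifnot(is(spectrum, "MsiSpectrum"), is(config, "DeconvConfig"))
  if (spectrum@domain != "mz")
    stopContract("deconvolution expects an m/z-domain spectrum")
  validObject(config)
  grid <- massGrid(config)
  zs <- seq.int(config@zMin, config@zMax)
  nx <- length(spectrum@axis)
  emptyOut <- function(W = matrix(0, nx, length(zs))) list(
    massSpectrum = MassSpectrum(grid, numeric(length(grid))),
    assignment = new("ChargeAssignment", weights = W, charges = as.integer(zs)))
  if (nx == 0L || all(spectrum@intensity == 0)) return(emptyOut())

  if (is.null(geometry)) geometry <- chargeGeometry(spectrum@axis, config)
  I <- spectrum@intensity
  nz <- geometry$nz

  # init: uniform over in-window charges, zero on empty points
  W <- matrix(0, nx, nz)
  W[geometry$inWin] <- 1
  W[I == 0, ] <- 0
  rs <- .rowSums(W, nx, nz)
  pos <- rs > 0
  if (!any(pos)) {
    msiWarn("mass window [%g, %g] excludes every charge hypothesis",
            config@massMin, config@massMax)
    return(emptyOut())
  }
  W[pos, ] <- W[pos, , drop = FALSE] / rs[pos]

  spacing <- if (nx > 1L) stats::median(diff(spectrum@axis)) else 1
  K <- peakKernel(config, spacing)
  B <- I  # Richardson-Lucy-corrected point intensities
  invCounts <- matrix(rep(1 / geometry$counts, each = nx), nx, nz)

  for (iter in seq_len(config@nIter)) {
    WI <- W * I
    S <- matrix(0, nx, nz)
    for (p in geometry$pairs) {
      V <- WI[, p$zj]
      S[, p$zi] <- S[, p$zi] + p$w1 * V[p$j1] + p$w2 * V[p$j2]
    }
    W <- W * S * invCounts
    rs <- .rowSums(W, nx, nz)
    pos <- rs > 0
    W[pos, ] <- W[pos, , drop = FALSE] / rs[pos]
    if (!is.null(K)) {
      R <- convolveSame(B, K)
      eps <- 1e-12 * max(R, 1e-300)
      ratio <- ifelse(R > eps, I / R, 0)
      B <- B * convolveSame(ratio, K)
      B[B < 0] <- 0
    }
  }

  contrib <- as.vector(W * B)
  intens <- binToMassGrid(as.vector(geometry$M), contrib, config, grid)
  if (config@massSmoothSigma > 0) {
    sigmaPts <- config@massSmoothSigma / config@massBin
    intens <- pmax(convolveSame(intens, gaussKernel(max(sigmaPts, 0.3))), 0)
  }
  list(massSpectrum = MassSpectrum(grid, intens),
       assignment = new("ChargeAssignment", weights = W,
                        charges = as.integer(zs)))
}

#' Deconvolve every pixel of a dataset
#'
#' Applies [preprocessSpectrum()] and [deconvolveSpectrum()] independently
#' to every pixel with the one shared configuration, onto one shared mass
#' grid. When all pixels share one m/z axis (continuous data) the
#' interpolation geometry is computed once and reused.
#'
#' @param dataset an m/z-domain [MsiDataset].
#' @param config a [DeconvConfig].
#' @param verbose log progress to stderr.
#' @return list with `dataset` (a mass-domain [MsiDataset] on the shared
#'   grid), `massSpectra` (list of [MassSpectrum]) and `summed` (the
#'   dataset-summed [MassSpectrum], the pixel-wise sum).
#' @export
deconvolveDataset <- function(dataset, config, verbose = FALSE) {
  stopifnot(is(dataset, "MsiDataset"), is(config, "DeconvConfig"))
  if (dataset@domain != "mz")
    stopContract("dataset is already in the mass domain")
  n <- length(dataset@spectra)
  pre <- lapply(dataset@spectra, preprocessSpectrum, config = config)

  ax0 <- pre[[1]]@axis
  shared <- length(ax0) > 0 && all(vapply(pre, function(s)
    length(s@axis) == length(ax0) && all(s@axis == ax0), logical(1)))
  geo <- if (shared) chargeGeometry(ax0, config) else NULL

  grid <- massGrid(config)
  summed <- numeric(length(grid))
  massSpectra <- vector("list", n)
  massSpecs <- vector("list", n)
  t0 <- Sys.time()
  for (i in seq_len(n)) {
    out <- deconvolveSpectrum(pre[[i]], config, geometry = geo)
    massSpectra[[i]] <- out$massSpectrum
    massSpecs[[i]] <- MsiSpectrum(grid, out$massSpectrum@intensity,
                                  domain = "mass")
    summed <- summed + out$massSpectrum@intensity
    if (verbose && (i %% 100L == 0L || i == n)) {
      rate <- i / max(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      1e-6)
      message(sprintf("deconvolved %d/%d pixels (%.1f spectra/s)", i, n, rate))
    }
  }
  massDataset <- MsiDataset(massSpecs, dataset@coords, domain = "mass",
                            width = dataset@width, height = dataset@height)
  list(dataset = massDataset, massSpectra = massSpectra,
       summed = MassSpectrum(grid, summed))
}

#' Deconvolve a store in place
#'
#' Reads the m/z-domain pixels from an HDF5 store, runs
#' [deconvolveDataset()], and attaches the per-pixel results, the summed
#' spectrum and the parameter set back onto the store.
#'
#' @param path an HDF5 store written by [toStore()].
#' @param config a [DeconvConfig].
#' @param verbose log progress.
#' @return invisibly, `path`.
#' @export
deconvolveStore <- function(path, config, verbose = FALSE) {
  dom <- readRootAttr(path, "domain")
  if (identical(as.character(dom), "mass"))
    stopContract("store %s already holds mass-domain data", path)
  dataset <- fromStore(path, domain = "mz")
  res <- deconvolveDataset(dataset, config, verbose = verbose)
  attachMassResults(path, res$massSpectra, config)
  invisible(path)
}

#' Pick peaks in a deconvolved mass spectrum
#'
#' Local maxima above a height threshold, separated by at least
#' `minSeparation`; each apex is refined by three-point parabolic
#' interpolation. When two candidate maxima tie in height, the lower mass
#' wins.
#'
#' @param ms a [MassSpectrum].
#' @param minHeightFraction keep maxima above this fraction of the global
#'   maximum.
#' @param minSeparation minimum distance between reported peaks (Da).
#' @return data.frame with columns `mass` (refined apex), `height` and
#'   `area` (integral between the flanking minima); empty when the spectrum
#'   has no signal.
#' @export
peakPick <- function(ms, minHeightFraction = 0.05, minSeparation = 0) {
  stopifnot(is(ms, "MassSpectrum"))
  y <- ms@intensity
  m <- ms@mass
  n <- length(y)
  empty <- data.frame(mass = numeric(0), height = numeric(0),
                      area = numeric(0))
  if (n < 3L || max(y) <= 0) return(empty)
  thr <- minHeightFraction * max(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  cand <- which(y >= left & y > right & y >= thr)
  if (!length(cand)) return(empty)
  # enforce separation: take candidates by descending height, lower mass
  # first on ties
  ord <- cand[order(-y[cand], m[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(m[i] - m[kept]) >= minSeparation))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  binw <- if (n > 1L) m[2] - m[1] else 1
  out <- lapply(kept, function(i) {
    apex <- m[i]
    if (i > 1L && i < n) {
      d <- y[i - 1] - 2 * y[i] + y[i + 1]
      if (d < 0) apex <- m[i] + 0.5 * (y[i - 1] - y[i + 1]) / d * binw
    }
    lo <- i; while (lo > 1L && y[lo - 1] < y[lo]) lo <- lo - 1L
    hi <- i; while (hi < n && y[hi + 1] < y[hi]) hi <- hi + 1L
    data.frame(mass = apex, height = y[i], area = sum(y[lo:hi]) * binw)
  })
  do.call(rbind, out)
}
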
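# Synthetic m/z-domain MSI generator: multi-charge Gaussian protein
# envelopes with spatial abundance patterns and seeded additive noise, plus
# the ground truth needed to validate the rest of the workflow.

patternMap <- function(pattern, params, width, height) {
  xg <- matrix(rep(seq_len(width), each = height), height, width)
  yg <- matrix(rep(seq_len(height), times = width), height, width)
  switch(pattern,
    uniform = matrix(1, height, width),
    half_plane = {
      side <- params$side %||% "left"
      frac <- params$frac %||% 0.5
      cut <- ceiling(width * frac)
      m <- (xg <= cut) * 1
      if (identical(side, "right")) m <- 1 - m
      m
    },
    disk = {
      cx <- params$cx %||% ((width + 1) / 2)
      cy <- params$cy %||% ((height + 1) / 2)
      r <- params$radius %||% (min(width, height) / 3)
      ((xg - cx)^2 + (yg - cy)^2 <= r^2) * 1
    },
    gradient = {
      along <- params$along %||% "x"
      if (identical(along, "y")) yg / height else xg / width
    },
    stopContract("unknown abundance pattern '%s'", pattern))
}

# unit-area Gaussian peak profile on the axis
gaussPeakProfile <- function(axis, center, fwhm) {
  sigma <- fwhm / 2.35482
  stats::dnorm(axis, mean = center, sd = sigma)
}

#' Generate a synthetic MSI dataset with known ground truth
#'
#' Each species contributes, at every pixel, Gaussian m/z peaks at
#' `mzForCharge(mass, z)` for each charge in its range, with peak areas
#' proportional to a discretised Gaussian charge envelope (renormalised over
#' the simulated charges) times the species' spatial abundance pattern.
#' Noise is additive Gaussian on a constant baseline, floored at zero, drawn
#' under the mandatory seed; the global RNG state is left untouched, and the
#' same inputs always produce a bit-identical dataset.
#'
#' Patterns: `uniform`; `half_plane` (params `side` = `"left"`/`"right"`,
#' `frac`); `disk` (params `cx`, `cy`, `radius`); `gradient` (param `along`
#' = `"x"`/`"y"`).
#'
#' @param specs list of [ProteoformSpec].
#' @param noise a [NoiseSpec].
#' @param width,height image dimensions in pixels.
#' @param axis numeric length 3: `c(mz_min, mz_max, n_points)`.
#' @param adductMass Da per charge.
#' @return list with `dataset` (an m/z-domain [MsiDataset], continuous
#'   axis) and `truth`, a list holding per-species `mass`, the per-pixel
#'   `abundance` map, and the per-charge `channels` (`z`, `mz`, envelope
#'   weight).
#' @export
simulateMsiDataset <- function(specs, noise, width, height, axis,
                               adductMass = 1.00728) {
  if (!length(specs)) stopContract("species list must be non-empty")
  stopifnot(all(vapply(specs, is, logical(1), "ProteoformSpec")),
            is(noise, "NoiseSpec"))
  if (length(axis) != 3L || axis[1] >= axis[2] || axis[3] < 2)
    stopContract("axis must be c(mz_min, mz_max, n_points)")
  ax <- seq(axis[1], axis[2], length.out = as.integer(axis[3]))

  truth <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    zs <- seq.int(sp@zRange[1], sp@zRange[2])
    centers <- mzForCharge(sp@mass, zs, adductMass)
    margin <- 2 * sp@peakFWHM
    bad <- centers < axis[1] + margin | centers > axis[2] - margin
    if (any(bad))
      stopContract("axis [%g, %g] too narrow for species of mass %g at charge %d (m/z %.2f)",
                   axis[1], axis[2], sp@mass, zs[which(bad)[1]],
                   centers[which(bad)[1]])
    env <- stats::dnorm(zs, sp@chargeCenter, sp@chargeSigma)
    env <- env / sum(env)
    truth[[k]] <- list(
      mass = sp@mass,
      abundance = patternMap(sp@pattern, sp@patternParams, width, height) *
        sp@amplitude,
      channels = data.frame(z = zs, mz = centers, weight = env))
  }

  # per-species template spectra (per unit abundance)
  templates <- lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    ch <- truth[[k]]$channels
    tmpl <- numeric(length(ax))
    for (j in seq_len(nrow(ch)))
      tmpl <- tmpl + ch$weight[j] * gaussPeakProfile(ax, ch$mz[j], sp@peakFWHM)
    tmpl
  })

  # seeded noise without disturbing the caller's RNG
  haveSeed <- exists(".Random.seed", envir = globalenv())
  if (haveSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (haveSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(noise@seed)

  n <- width * height
  xs <- rep(seq_len(width), times = height)
  ys <- rep(seq_len(height), each = width)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    y <- numeric(length(ax))
    for (k in seq_along(specs))
      y <- y + truth[[k]]$abundance[ys[i], xs[i]] * templates[[k]]
    y <- y + noise@baselineLevel
    if (noise@gaussianSD > 0)
      y <- y + stats::rnorm(length(ax), 0, noise@gaussianSD)
    spectra[[i]] <- MsiSpectrum(ax, pmax(y, 0), domain = "mz")
  }
  dataset <- MsiDataset(spectra, data.frame(x = xs, y = ys), domain = "mz",
                        width = width, height = height)
  list(dataset = dataset, truth = truth)
}
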
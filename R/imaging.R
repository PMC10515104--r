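# Ion / mass image extraction, composite images, cosine-similarity scoring
# of charge-state assignments, and raster rendering.

extractImage <- function(dataset, center, tol, wantDomain) {
  stopifnot(is(dataset, "MsiDataset"))
  if (dataset@domain != wantDomain)
    stopContract("%s image requested from a %s-domain dataset",
                 if (wantDomain == "mz") "ion" else "mass", dataset@domain)
  if (tol < 0) stopContract("tolerance must be >= 0")
  vals <- matrix(0, dataset@height, dataset@width)
  cc <- dataset@coords
  for (i in seq_along(dataset@spectra)) {
    s <- dataset@spectra[[i]]
    if (!length(s@axis)) next
    v <- if (tol == 0) {
      # point extraction: nearest axis point to the requested center
      s@intensity[which.min(abs(s@axis - center))]
    } else {
      sum(s@intensity[s@axis >= center - tol & s@axis <= center + tol])
    }
    vals[cc$y[i], cc$x[i]] <- v
  }
  unit <- if (wantDomain == "mz") "Th" else "Da"
  IntensityImage(vals,
                 label = sprintf("%.2f +/- %.2f %s", center, tol, unit),
                 center = center, halfWidth = tol, domain = wantDomain)
}

#' Extract an ion image
#'
#' Per pixel, the summed intensity over the closed m/z window
#' `[center - tol, center + tol]`; with `tol = 0`, the intensity of the
#' nearest axis point. Pixels absent from the dataset render as zero.
#'
#' @param dataset an m/z-domain [MsiDataset].
#' @param center window centre (Th).
#' @param tol window half-width (Th).
#' @return an [IntensityImage].
#' @export
ionImage <- function(dataset, center, tol)
  extractImage(dataset, center, tol, "mz")

#' Extract a mass image
#'
#' As [ionImage()] but on the deconvolved mass axis (window in Da), e.g.
#' a creatine-kinase-homodimer window of 85170 +/- 10 Da.
#'
#' @param dataset a mass-domain [MsiDataset] (see [deconvolveDataset()] or
#'   [fromStore()] with `domain = "mass"`).
#' @param center window centre (Da).
#' @param tol window half-width (Da).
#' @return an [IntensityImage].
#' @export
massImage <- function(dataset, center, tol)
  extractImage(dataset, center, tol, "mass")

#' Sum ion images into a composite image
#'
#' Pixel-wise sum of the given images (typically one ion image per charge
#' state of a proteoform); the label records the component windows.
#'
#' @param images list of [IntensityImage] with identical dimensions.
#' @return an [IntensityImage].
#' @export
compositeIonImage <- function(images) {
  if (!length(images)) stopContract("need at least one image")
  dims <- vapply(images, function(im) dim(im@values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopContract("images have mismatched dimensions")
  vals <- Reduce(`+`, lapply(images, function(im) im@values))
  IntensityImage(vals,
                 label = paste(vapply(images, function(im) im@label,
                                      character(1)), collapse = " + "),
                 domain = images[[1]]@domain)
}

cosineCore <- function(av, bv) {
  if (length(av) != length(bv))
    stopContract("images have mismatched dimensions")
  na <- sqrt(sum(av^2)); nb <- sqrt(sum(bv^2))
  if (na == 0 || nb == 0)
    stopContract("cosine similarity is undefined for an all-zero image")
  100 * sum(av * bv) / (na * nb)
}

#' @describeIn cosineSimilarity similarity of two images, optionally after
#'   excluding low-signal pixels: with `maskQuantile` set, pixels whose
#'   combined intensity falls below that quantile are dropped from both
#'   vectors before scoring (a mitigation for the inflation caused by empty
#'   glass-slide pixels, which are low and near-identical everywhere).
#' @param maskQuantile `NULL` (default: score all pixels, zeros included) or
#'   a quantile in \[0, 1).
#' @export
setMethod("cosineSimilarity", signature("IntensityImage", "IntensityImage"),
  function(a, b, maskQuantile = NULL) {
    av <- as.vector(a@values); bv <- as.vector(b@values)
    if (!is.null(maskQuantile)) {
      tot <- av + bv
      keep <- tot > stats::quantile(tot, maskQuantile)
      if (any(keep)) { av <- av[keep]; bv <- bv[keep] }
    }
    cosineCore(av, bv)
  })

#' @describeIn cosineSimilarity similarity of two bare numeric
#'   vectors/matrices.
#' @export
setMethod("cosineSimilarity", signature("numeric", "numeric"),
  function(a, b, ...) cosineCore(as.vector(a), as.vector(b)))

#' @export
setMethod("cosineSimilarity", signature("matrix", "matrix"),
  function(a, b, ...) cosineCore(as.vector(a), as.vector(b)))

#' Score a charge series against its mass image
#'
#' For a deconvolved mass peak, extracts the ion image of every listed
#' charge state at `mzForCharge(massPeak, z) +/- tolMz` and reports its
#' cosine similarity to the mass image at `massPeak +/- tolMass`. Channels
#' scoring below `cutoff` (default 80%) are flagged: ion images with a
#' different spatial distribution are likely not signals of the same
#' proteoform. The result also records the fraction of near-empty pixels
#' (pixels whose total m/z-domain signal is below 1% of the maximum pixel
#' total), because a high fraction of empty-substrate pixels inflates every
#' score toward 100%.
#'
#' @param massPeak deconvolved peak mass (Da).
#' @param datasetMz the m/z-domain [MsiDataset].
#' @param datasetMass the matching mass-domain [MsiDataset] (same grid of
#'   pixels).
#' @param charges integer vector of charge states to score.
#' @param tolMz,tolMass window half-widths (Th, Da).
#' @param cutoff flag threshold, percent.
#' @param adductMass Da per charge.
#' @param maskQuantile optional low-signal pixel mask, see
#'   [cosineSimilarity()].
#' @return data.frame with columns `z`, `mz`, `similarity`, `flagged`, and
#'   attributes `empty_pixel_fraction` and `cutoff`.
#' @export
chargeSeriesReport <- function(massPeak, datasetMz, datasetMass, charges,
                               tolMz = 2, tolMass = 10, cutoff = 80,
                               adductMass = 1.00728, maskQuantile = NULL) {
  if (!length(charges)) stopContract("charge list must be non-empty")
  mzC <- mzForCharge(massPeak, charges, adductMass)
  mImg <- massImage(datasetMass, massPeak, tolMass)
  sims <- vapply(seq_along(charges), function(k) {
    iImg <- ionImage(datasetMz, mzC[k], tolMz)
    cosineSimilarity(iImg, mImg, maskQuantile = maskQuantile)
  }, numeric(1))
  tic <- totalIonImage(datasetMz)@values
  emptyFrac <- mean(tic < 0.01 * max(tic))
  out <- data.frame(z = as.integer(charges), mz = mzC, similarity = sims,
                    flagged = sims < cutoff)
  attr(out, "empty_pixel_fraction") <- emptyFrac
  attr(out, "cutoff") <- cutoff
  out
}

#' Total-ion-current image
#'
#' @param dataset an [MsiDataset] in either domain.
#' @return an [IntensityImage] of per-pixel total intensity.
#' @export
totalIonImage <- function(dataset) {
  stopifnot(is(dataset, "MsiDataset"))
  vals <- matrix(0, dataset@height, dataset@width)
  cc <- dataset@coords
  for (i in seq_along(dataset@spectra))
    vals[cc$y[i], cc$x[i]] <- sum(dataset@spectra[[i]]@intensity)
  IntensityImage(vals, label = "total ion current", domain = dataset@domain)
}

#' Write a similarity report as tab-separated text
#'
#' Writes the table from [chargeSeriesReport()] with header comment lines
#' recording the flag cutoff and the near-empty pixel fraction.
#'
#' @param report a data.frame from [chargeSeriesReport()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSimilarityReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cutoff_percent: %g", attr(report, "cutoff")), con)
  writeLines(sprintf("# near_empty_pixel_fraction: %.4f",
                     attr(report, "empty_pixel_fraction")), con)
  utils::write.table(format(report, digits = 6), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render an image to a PNG with a numeric side-car
#'
#' Writes a lossless PNG (colormap applied per pixel) and a plain-text
#' tab-separated side-car `<path>.txt` holding the exact numeric grid, so
#' rendering is always reversible.
#'
#' @param image an [IntensityImage].
#' @param path output `.png` path.
#' @param colormap a palette name accepted by [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @param normalization `"max"` scales by the image maximum;
#'   `"linear"` treats values as already lying in \[0, 1\] and clips.
#' @return invisibly, list of the two paths.
#' @export
renderImage <- function(image, path, colormap = "viridis",
                        normalization = c("max", "linear")) {
  stopifnot(is(image, "IntensityImage"))
  normalization <- match.arg(normalization)
  v <- image@values
  u <- switch(normalization,
              max = if (max(v) > 0) v / max(v) else v,
              linear = pmin(pmax(v, 0), 1))
  pal <- grDevices::hcl.colors(256, colormap)
  idx <- pmin(pmax(as.integer(u * 255) + 1L, 1L), 256L)
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  arr <- array(0, dim = c(nrow(v), ncol(v), 3))
  arr[, , 1] <- matrix(rgb[1, ], nrow(v), ncol(v))
  arr[, , 2] <- matrix(rgb[2, ], nrow(v), ncol(v))
  arr[, , 3] <- matrix(rgb[3, ], nrow(v), ncol(v))
  png::writePNG(arr, path)
  sidecar <- paste0(path, ".txt")
  utils::write.table(v, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(png = path, sidecar = sidecar))
}
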
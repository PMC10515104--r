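#' Accessors
#'
#' Accessor generics for the package's data classes.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("axisValues", function(x) standardGeneric("axisValues"))

#' @rdname accessors
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname accessors
#' @export
setGeneric("spectrumDomain", function(x) standardGeneric("spectrumDomain"))

#' @rdname accessors
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname accessors
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname accessors
#' @export
setGeneric("imageDims", function(x) standardGeneric("imageDims"))

#' @rdname accessors
#' @export
setGeneric("pixelCount", function(x) standardGeneric("pixelCount"))

#' @rdname accessors
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))

#' @rdname accessors
#' @export
setGeneric("massValues", function(x) standardGeneric("massValues"))

#' @rdname accessors
#' @export
setGeneric("assignmentWeights", function(x) standardGeneric("assignmentWeights"))

#' @rdname accessors
#' @export
setGeneric("chargeStates", function(x) standardGeneric("chargeStates"))

#' Cosine similarity of two intensity images
#'
#' @param a,b two images (or bare numeric matrices/vectors) of identical
#'   dimensions.
#' @param ... method arguments, see [cosineSimilarity,IntensityImage,IntensityImage-method].
#' @return similarity as a percentage in \[0, 100\].
#' @export
setGeneric("cosineSimilarity", function(a, b, ...) standardGeneric("cosineSimilarity"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
setMethod("axisValues", "MsiSpectrum", function(x) x@axis)
#' @rdname accessors
setMethod("intensityValues", "MsiSpectrum", function(x) x@intensity)
#' @rdname accessors
setMethod("spectrumDomain", "MsiSpectrum", function(x) x@domain)
#' @rdname accessors
setMethod("spectrumDomain", "MsiDataset", function(x) x@domain)
#' @rdname accessors
setMethod("spectra", "MsiDataset", function(x) x@spectra)
#' @rdname accessors
setMethod("pixelCoords", "MsiDataset", function(x) x@coords)
#' @rdname accessors
setMethod("imageDims", "MsiDataset", function(x) c(width = x@width, height = x@height))
#' @rdname accessors
setMethod("pixelCount", "MsiDataset", function(x) length(x@spectra))
#' @rdname accessors
setMethod("massValues", "MassSpectrum", function(x) x@mass)
#' @rdname accessors
setMethod("intensityValues", "MassSpectrum", function(x) x@intensity)
#' @rdname accessors
setMethod("imageValues", "IntensityImage", function(x) x@values)
#' @rdname accessors
setMethod("imageDims", "IntensityImage",
          function(x) c(width = ncol(x@values), height = nrow(x@values)))
#' @rdname accessors
setMethod("assignmentWeights", "ChargeAssignment", function(x) x@weights)
#' @rdname accessors
setMethod("chargeStates", "ChargeAssignment", function(x) x@charges)

setMethod("show", "MsiSpectrum", function(object) {
  cat(sprintf("MsiSpectrum [%s domain], %d points", object@domain,
              length(object@axis)))
  if (length(object@axis))
    cat(sprintf(", axis %.2f..%.2f", min(object@axis), max(object@axis)))
  cat("\n")
})

setMethod("show", "MsiDataset", function(object) {
  cat(sprintf("MsiDataset [%s domain]: %d pixels on a %d x %d grid\n",
              object@domain, length(object@spectra), object@width,
              object@height))
})

setMethod("show", "MassSpectrum", function(object) {
  n <- length(object@mass)
  cat(sprintf("MassSpectrum: %d bins", n))
  if (n) cat(sprintf(", %.0f..%.0f Da, total intensity %.4g",
                     object@mass[1], object@mass[n], sum(object@intensity)))
  cat("\n")
})

setMethod("show", "IntensityImage", function(object) {
  cat(sprintf("IntensityImage [%s domain] %d x %d", object@domain,
              nrow(object@values), ncol(object@values)))
  if (nzchar(object@label)) cat(", window", object@label)
  else if (!is.na(object@center))
    cat(sprintf(", window %.2f +/- %.2f", object@center, object@halfWidth))
  cat("\n")
})

setMethod("show", "DeconvConfig", function(object) {
  cat(sprintf(paste0(
    "DeconvConfig: z %d..%d, adduct %.5f Da, mass %.0f..%.0f Da (bin %g Da),\n",
    "  %d iterations, charge smooth +/-%d, peak FWHM %g Th (%s),\n",
    "  m/z window %g..%g Th, background width %g Th, mass smooth sigma %g Da\n"),
    object@zMin, object@zMax, object@adductMass, object@massMin,
    object@massMax, object@massBin, object@nIter, object@chargeSmoothWidth,
    object@peakFWHM, object@peakShape, object@mzMin, object@mzMax,
    object@backgroundWidth, object@massSmoothSigma))
})

setMethod("show", "ChargeAssignment", function(object) {
  cat(sprintf("ChargeAssignment: %d points x charges %d..%d\n",
              nrow(object@weights), min(object@charges), max(object@charges)))
})
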
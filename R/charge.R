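#' Electrospray charge-state arithmetic
#'
#' A species of neutral mass M observed at charge z appears at
#' m/z = (M + z * adduct) / z, the standard positive-mode electrospray
#' relation with a proton adduct by default. `massFromMz()` is the exact
#' inverse: M = z * (m/z) - z * adduct.
#'
#' @param mass neutral mass (Da).
#' @param mz observed m/z (Th).
#' @param z charge state (integer >= 1).
#' @param adductMass mass added per charge (Da); defaults to a proton,
#'   1.00728 Da.
#' @return `mzForCharge()`: m/z in Th; `massFromMz()`: neutral mass in Da.
#'   Both vectorise over their arguments.
#'
#' @examples
#' mzForCharge(85170, 17)   # ~5011.01 Th
#' massFromMz(5011.007, 17) # ~85170 Da
#' @export
mzForCharge <- function(mass, z, adductMass = 1.00728) {
  if (any(z < 1)) stopContract("charge states must be >= 1")
  if (any(mass <= 0)) stopContract("mass must be > 0")
  (mass + z * adductMass) / z
}

#' @rdname mzForCharge
#' @export
massFromMz <- function(mz, z, adductMass = 1.00728) {
  if (any(z < 1)) stopContract("charge states must be >= 1")
  z * mz - z * adductMass
}

#' Proton-transfer charge-reduction product-ion series
#'
#' Given a precursor channel (m/z, charge), returns the m/z of each
#' charge-reduced product ion. Only the arithmetic of sequential proton
#' loss is modelled: a precursor of charge `Z` observed at m/z `x` yields,
#' at product charge `z`, m/z = (Z * x - (Z - z) * adduct) / z, so every
#' product channel maps back to exactly the precursor's neutral mass.
#'
#' @param precursorMz precursor m/z (Th).
#' @param precursorZ precursor charge.
#' @param productZ integer vector of product charges, each strictly below
#'   `precursorZ`.
#' @param adductMass Da per charge (default proton).
#' @return data.frame with columns `z` and `mz`.
#'
#' @examples
#' ptcrSeries(5011.007, 17, 13:16)
#' @export
ptcrSeries <- function(precursorMz, precursorZ, productZ,
                       adductMass = 1.00728) {
  if (!length(productZ)) stopContract("productZ must be non-empty")
  if (any(productZ >= precursorZ))
    stopContract("product charges must be strictly below the precursor charge")
  if (any(productZ < 1)) stopContract("product charges must be >= 1")
  mz <- (precursorZ * precursorMz - (precursorZ - productZ) * adductMass) /
    productZ
  data.frame(z = as.integer(productZ), mz = mz)
}
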
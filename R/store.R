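# HDF5 spectral container: the working format between imzML import and
# mass-domain export. Layout (documented in the README):
#   /                    attrs: domain, width, height, n_pixels
#   /spectrum_000000     one group per pixel, zero-padded, acquisition order
#       attrs: x, y, z   1-based pixel coordinates
#       raw              N x 2 table: column 1 axis, column 2 intensity
#       mass_intensity   per-pixel deconvolved intensities (after a run)
#   /mass_axis           shared deconvolved mass grid (after a run)
#   /mass_sum            dataset-summed deconvolved spectrum (after a run)
#   /                    attrs config_<key>: the single parameter set used

groupName <- function(i) sprintf("spectrum_%06d", i - 1L)

#' Convert a dataset to an HDF5 store
#'
#' Writes every pixel spectrum into one group of an HDF5 file, with its
#' 1-based x/y/z pixel coordinates as group attributes; groups are numbered
#' sequentially and zero-padded so lexical order equals acquisition order.
#'
#' @param dataset an [MsiDataset].
#' @param path output `.h5` path.
#' @param overwrite logical; an existing file is refused unless set.
#' @return invisibly, `path`.
#' @export
toStore <- function(dataset, path, overwrite = FALSE) {
  stopifnot(is(dataset, "MsiDataset"))
  if (file.exists(path) && !overwrite)
    stopContract("store %s exists; pass overwrite = TRUE to replace it", path)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(dataset@domain, fid, "domain")
  rhdf5::h5writeAttribute(dataset@width, fid, "width")
  rhdf5::h5writeAttribute(dataset@height, fid, "height")
  rhdf5::h5writeAttribute(length(dataset@spectra), fid, "n_pixels")
  cc <- dataset@coords
  for (i in seq_along(dataset@spectra)) {
    g <- groupName(i)
    gid <- rhdf5::H5Gcreate(fid, g)
    rhdf5::h5writeAttribute(cc$x[i], gid, "x")
    rhdf5::h5writeAttribute(cc$y[i], gid, "y")
    rhdf5::h5writeAttribute(cc$z[i], gid, "z")
    rhdf5::H5Gclose(gid)
    s <- dataset@spectra[[i]]
    rhdf5::h5write(cbind(s@axis, s@intensity), fid,
                   paste0(g, "/raw"), level = 0)
  }
  invisible(path)
}

storeGroups <- function(path) {
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  sort(ls$name[ls$otype == "H5I_GROUP" & grepl("^spectrum_", ls$name)])
}

readRootAttr <- function(path, name) {
  att <- rhdf5::h5readAttributes(path, "/")
  att[[name]]
}

#' Read a store back into a dataset
#'
#' @param path an HDF5 store written by [toStore()].
#' @param domain `"mz"` to read the raw imported spectra (the default), or
#'   `"mass"` to assemble the deconvolved per-pixel spectra attached by
#'   [attachMassResults()] into a mass-domain dataset.
#' @return an [MsiDataset].
#' @export
fromStore <- function(path, domain = c("mz", "mass")) {
  domain <- match.arg(domain)
  if (!file.exists(path)) stopIO("store not found: %s", path)
  root <- rhdf5::h5readAttributes(path, "/")
  for (k in c("domain", "width", "height"))
    if (is.null(root[[k]])) stopFormat("store lacks root attribute '%s'", k)
  groups <- storeGroups(path)
  if (!length(groups)) stopFormat("store contains no spectrum groups")
  if (domain == "mass") {
    ls <- rhdf5::h5ls(path, recursive = FALSE)
    if (!"mass_axis" %in% ls$name)
      stopContract("store has no deconvolved results; run the deconvolution first")
    massAxis <- as.numeric(rhdf5::h5read(path, "mass_axis"))
  }
  n <- length(groups)
  xs <- ys <- zs <- integer(n)
  spectra <- vector("list", n)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  for (i in seq_len(n)) {
    g <- groups[i]
    att <- rhdf5::h5readAttributes(fid, g)
    for (k in c("x", "y", "z"))
      if (is.null(att[[k]]))
        stopFormat("store group %s is missing coordinate attribute '%s'", g, k)
    xs[i] <- as.integer(att$x); ys[i] <- as.integer(att$y)
    zs[i] <- as.integer(att$z)
    if (domain == "mz") {
      tab <- rhdf5::h5read(fid, paste0(g, "/raw"))
      spectra[[i]] <- MsiSpectrum(tab[, 1], pmax(tab[, 2], 0), domain = "mz")
    } else {
      v <- as.numeric(rhdf5::h5read(fid, paste0(g, "/mass_intensity")))
      spectra[[i]] <- MsiSpectrum(massAxis, pmax(v, 0), domain = "mass")
    }
  }
  srcDomain <- if (domain == "mz") as.character(root$domain) else "mass"
  MsiDataset(spectra, data.frame(x = xs, y = ys, z = zs),
             domain = srcDomain,
             width = as.integer(root$width), height = as.integer(root$height))
}

#' Attach deconvolved mass results to a store
#'
#' Stores one deconvolved spectrum per pixel (all on one shared mass grid)
#' next to the raw m/z data, together with the dataset-summed spectrum and
#' the full parameter set used, so every mass image is traceable to one
#' configuration. Re-attaching replaces any previous results.
#'
#' @param path an HDF5 store written by [toStore()].
#' @param massSpectra list of [MassSpectrum], one per stored pixel, in
#'   store order, all sharing one grid.
#' @param config the [DeconvConfig] used to produce them.
#' @return invisibly, `path`.
#' @export
attachMassResults <- function(path, massSpectra, config) {
  stopifnot(is(config, "DeconvConfig"))
  if (!file.exists(path)) stopIO("store not found: %s", path)
  groups <- storeGroups(path)
  if (length(massSpectra) != length(groups))
    stopContract("store has %d pixels but %d mass spectra were supplied",
                 length(groups), length(massSpectra))
  grid <- massSpectra[[1]]@mass
  same <- vapply(massSpectra, function(m)
    length(m@mass) == length(grid) && all(m@mass == grid), logical(1))
  if (!all(same))
    stopContract("all mass spectra must share one mass grid")

  ls <- rhdf5::h5ls(path, recursive = TRUE)
  old <- gsub("^/+", "", paste(ls$group, ls$name, sep = "/"))
  for (d in c("mass_axis", "mass_sum"))
    if (d %in% old) rhdf5::h5delete(path, d)

  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  summed <- numeric(length(grid))
  for (i in seq_along(groups)) {
    ds <- paste0(groups[i], "/mass_intensity")
    if (ds %in% old) rhdf5::h5delete(fid, ds)
    rhdf5::h5write(massSpectra[[i]]@intensity, fid, ds, level = 0)
    summed <- summed + massSpectra[[i]]@intensity
  }
  rhdf5::h5write(grid, fid, "mass_axis", level = 0)
  rhdf5::h5write(summed, fid, "mass_sum", level = 0)
  for (k in names(.CONFIG_KEYS))
    rhdf5::h5writeAttribute(slot(config, .CONFIG_KEYS[[k]]), fid,
                            paste0("config_", k))
  invisible(path)
}

#' Read the dataset-summed deconvolved spectrum from a store
#'
#' @param path an HDF5 store holding deconvolved results.
#' @return a [MassSpectrum].
#' @export
summedMassSpectrum <- function(path) {
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  if (!all(c("mass_axis", "mass_sum") %in% ls$name))
    stopContract("store has no deconvolved results; run the deconvolution first")
  MassSpectrum(as.numeric(rhdf5::h5read(path, "mass_axis")),
               pmax(as.numeric(rhdf5::h5read(path, "mass_sum")), 0))
}

#' Parameter set recorded in a store
#'
#' @param path an HDF5 store holding deconvolved results.
#' @return the [DeconvConfig] recorded by [attachMassResults()].
#' @export
storedConfig <- function(path) {
  att <- rhdf5::h5readAttributes(path, "/")
  keys <- paste0("config_", names(.CONFIG_KEYS))
  if (!all(keys %in% names(att)))
    stopContract("store has no recorded deconvolution parameters")
  vals <- lapply(keys, function(k) {
    v <- att[[k]]
    if (is.array(v)) v <- as.vector(v)
    v
  })
  names(vals) <- names(.CONFIG_KEYS)
  configFromList(vals)
}
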
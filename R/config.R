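.CONFIG_KEYS <- c(
  z_min = "zMin", z_max = "zMax", adduct_mass = "adductMass",
  mass_min = "massMin", mass_max = "massMax", mass_bin = "massBin",
  n_iter = "nIter", charge_smooth_width = "chargeSmoothWidth",
  peak_fwhm = "peakFWHM", peak_shape = "peakShape",
  background_width = "backgroundWidth", mz_min = "mzMin", mz_max = "mzMax",
  mass_smooth_sigma = "massSmoothSigma"
)

#' Read and write deconvolution parameter files
#'
#' The configuration is a flat key-value YAML file using snake_case keys
#' (`z_min`, `z_max`, `adduct_mass`, `mass_min`, `mass_max`, `mass_bin`,
#' `n_iter`, `charge_smooth_width`, `peak_fwhm`, `peak_shape`,
#' `background_width`, `mz_min`, `mz_max`, `mass_smooth_sigma`). Keys left
#' out keep the [DeconvConfig()] defaults; unknown keys are an error naming
#' the key.
#'
#' @param path file path.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return `readDeconvConfig()`: a [DeconvConfig]. `writeDeconvConfig()`:
#'   the path, invisibly.
#' @export
readDeconvConfig <- function(path, overrides = list()) {
  if (!file.exists(path)) stopIO("config file not found: %s", path)
  vals <- tryCatch(yaml::read_yaml(path), error = function(e)
    stopConfig("cannot parse config file %s: %s", path, conditionMessage(e)))
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  configFromList(vals)
}

configFromList <- function(vals) {
  unknown <- setdiff(names(vals), names(.CONFIG_KEYS))
  if (length(unknown))
    stopConfig("unknown configuration key: %s", paste(unknown, collapse = ", "))
  args <- stats::setNames(vals, .CONFIG_KEYS[names(vals)])
  tryCatch(do.call(DeconvConfig, args), error = function(e)
    stopConfig("invalid configuration: %s", conditionMessage(e)))
}

configToList <- function(config) {
  out <- lapply(.CONFIG_KEYS, function(slotName) slot(config, slotName))
  names(out) <- names(.CONFIG_KEYS)
  out
}

#' @param config a [DeconvConfig].
#' @rdname readDeconvConfig
#' @export
writeDeconvConfig <- function(config, path) {
  stopifnot(is(config, "DeconvConfig"))
  yaml::write_yaml(configToList(config), path)
  invisible(path)
}

#' Read a synthetic-dataset description file
#'
#' Same flat YAML dialect as the deconvolution config: top-level keys
#' `width`, `height`, `axis` (list `mz_min`, `mz_max`, `n_points`),
#' `noise` (`baseline_level`, `gaussian_sd`, `seed`) and `species`, a list
#' of proteoform blocks (`mass`, `charge_center`, `charge_sigma`, `z_min`,
#' `z_max`, `peak_fwhm`, `pattern`, `amplitude`, plus optional pattern
#' parameters under `pattern_params`).
#'
#' @param path file path.
#' @return list with elements `specs` (list of [ProteoformSpec]), `noise`
#'   ([NoiseSpec]), `width`, `height`, `axis` (numeric length 3).
#' @export
readSynthSpec <- function(path) {
  if (!file.exists(path)) stopIO("synthetic spec file not found: %s", path)
  v <- tryCatch(yaml::read_yaml(path), error = function(e)
    stopConfig("cannot parse spec file %s: %s", path, conditionMessage(e)))
  need <- c("width", "height", "axis", "noise", "species")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stopConfig("synthetic spec missing key: %s", paste(miss, collapse = ", "))
  ax <- v$axis
  for (k in c("mz_min", "mz_max", "n_points"))
    if (is.null(ax[[k]])) stopConfig("synthetic spec axis missing key: %s", k)
  if (is.null(v$noise$seed)) stopConfig("synthetic spec noise block needs a seed")
  noise <- NoiseSpec(
    baselineLevel = v$noise$baseline_level %||% 0,
    gaussianSD = v$noise$gaussian_sd %||% 0,
    seed = v$noise$seed)
  specs <- lapply(v$species, function(sp) {
    if (is.null(sp$mass) || is.null(sp$charge_center))
      stopConfig("each species needs at least mass and charge_center")
    ProteoformSpec(
      mass = sp$mass, chargeCenter = sp$charge_center,
      chargeSigma = sp$charge_sigma %||% 1.5,
      zRange = if (!is.null(sp$z_min)) c(sp$z_min, sp$z_max) else NULL,
      peakFWHM = sp$peak_fwhm %||% 2,
      pattern = sp$pattern %||% "uniform",
      patternParams = sp$pattern_params %||% list(),
      amplitude = sp$amplitude %||% 100)
  })
  list(specs = specs, noise = noise, width = as.integer(v$width),
       height = as.integer(v$height),
       axis = c(ax$mz_min, ax$mz_max, ax$n_points))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
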
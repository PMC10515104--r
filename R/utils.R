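# Internal condition helpers. Error classes drive both user-facing messages
# and the CLI exit-code mapping (config/contract -> 2, format/io -> 3).

stopContract <- function(fmt, ..., call. = FALSE) {
  stop(structure(
    class = c("msi_contract_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stopFormat <- function(fmt, ..., call. = FALSE) {
  stop(structure(
    class = c("msi_format_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stopIO <- function(fmt, ...) {
  stop(structure(
    class = c("msi_io_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stopConfig <- function(fmt, ...) {
  stop(structure(
    class = c("msi_config_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' @keywords internal
msiWarn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Centred rolling minimum; window is clipped at the edges so a constant
# vector maps to itself.
rollingMin <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  k <- min(k, 2L * n - 1L)
  if (k %% 2L == 0L) k <- k + 1L
  half <- k %/% 2L
  xp <- c(rep(Inf, half), x, rep(Inf, half))
  do.call(pmin, lapply(seq_len(k), function(j) xp[j:(j + n - 1L)]))
}

# "Same"-length convolution with an odd, normalised kernel. Direct
# convolution: kernels here are short, so this beats FFT padding.
convolveSame <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1L) %/% 2L
  xp <- c(rep(0, half), x, rep(0, half))
  out <- stats::filter(xp, kernel, method = "convolution", sides = 2L)
  as.numeric(out[(half + 1L):(half + n)])
}

gaussKernel <- function(sigmaPts, halfWidth = ceiling(4 * sigmaPts)) {
  u <- seq(-halfWidth, halfWidth)
  k <- exp(-0.5 * (u / sigmaPts)^2)
  k / sum(k)
}

lorentzKernel <- function(fwhmPts, halfWidth = ceiling(8 * fwhmPts)) {
  u <- seq(-halfWidth, halfWidth)
  g <- fwhmPts / 2
  k <- g^2 / (u^2 + g^2)
  k / sum(k)
}

# UUID-v4-shaped identifier in pyimzml's braced format plus its raw 16 bytes.
# Derived from a content hash when `seed` is given so that writing the same
# dataset twice yields bit-identical files.
makeUUID <- function(seed = NULL) {
  if (is.null(seed)) {
    bytes <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  } else {
    bytes <- hexToRaw(digest::digest(seed, algo = "sha1"))[1:16]
  }
  bytes[7] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[7]), 0x0FL), 0x40L))
  bytes[9] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[9]), 0x3FL), 0x80L))
  hx <- toupper(paste(format(bytes), collapse = ""))
  str <- sprintf("{%s-%s-%s-%s-%s}",
    substr(hx, 1, 8), substr(hx, 9, 12), substr(hx, 13, 16),
    substr(hx, 17, 20), substr(hx, 21, 32))
  list(bytes = bytes, string = str)
}

hexToRaw <- function(s) {
  s <- gsub("[^0-9A-Fa-f]", "", s)
  as.raw(strtoi(substring(s, seq(1, nchar(s) - 1, 2), seq(2, nchar(s), 2)),
                base = 16L))
}
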
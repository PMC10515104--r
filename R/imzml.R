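# imzML 1.1 reader/writer: XML index (mzML vocabulary + imaging MS
# accessions) plus a paired .ibd binary file that starts with a 16-byte UUID.
# Little-endian IEEE floats only; "continuous" files share one m/z axis,
# "processed" files carry one axis per pixel.

.ACC <- c(
  continuous = "IMS:1000030", processed = "IMS:1000031",
  uuid = "IMS:1000080", sha1 = "IMS:1000091",
  externalData = "IMS:1000101", externalOffset = "IMS:1000102",
  externalArrayLength = "IMS:1000103", externalEncodedLength = "IMS:1000104",
  posX = "IMS:1000050", posY = "IMS:1000051", posZ = "IMS:1000052",
  maxX = "IMS:1000042", maxY = "IMS:1000043",
  mzArray = "MS:1000514", intensityArray = "MS:1000515",
  float32 = "MS:1000521", float64 = "MS:1000523",
  int32 = "MS:1000519", int64 = "MS:1000522",
  noCompression = "MS:1000576", zlib = "MS:1000574"
)

ibdPathFor <- function(path) {
  cand <- c(sub("\\.imzML$", ".ibd", path, ignore.case = TRUE),
            paste0(path, ".ibd"))
  hit <- cand[file.exists(cand)]
  if (length(hit)) hit[1] else cand[1]
}

#' Read an imzML file pair
#'
#' Parses the XML index and the paired `.ibd` binary file into an
#' [MsiDataset]. Both the continuous dialect (one shared axis referenced by
#' every pixel) and the processed dialect (per-pixel axes) are supported,
#' with 32- or 64-bit little-endian floats and no compression. Pixels not
#' listed in the file are absent from the dataset, never zero-filled.
#'
#' The binary file's leading 16-byte UUID and (when present) its SHA-1
#' checksum are verified against the XML. With `permissive = TRUE` a
#' mismatch is downgraded to a warning, which tolerates the dialect
#' irregularities some vendor converters produce.
#'
#' @param path path to the `.imzML` file; the `.ibd` companion is located
#'   next to it.
#' @param permissive logical; downgrade UUID/checksum mismatches to warnings.
#' @return an [MsiDataset]. The domain tag is `"mass"` when the file carries
#'   this package's `spectrum domain` annotation with value `mass`,
#'   otherwise `"mz"`.
#' @seealso [writeImzML()]
#' @export
readImzML <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stopIO("imzML file not found: %s", path)
  ibd <- ibdPathFor(path)
  if (!file.exists(ibd))
    stopIO("paired binary file not found (expected %s)", ibd)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stopFormat("malformed imzML XML in %s: %s", path, conditionMessage(e)))
  xml2::xml_ns_strip(doc)

  fileContent <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  if (inherits(fileContent, "xml_missing"))
    stopFormat("imzML is missing <fileContent>")
  fcAcc <- cvAccessions(fileContent)
  dialect <- if (.ACC[["continuous"]] %in% fcAcc) "continuous"
             else if (.ACC[["processed"]] %in% fcAcc) "processed"
             else if (permissive) "processed"
             else stopFormat("file declares neither the continuous nor the processed dialect")

  domain <- "mz"
  dom <- xml2::xml_find_first(fileContent, ".//userParam[@name='spectrum domain']")
  if (!inherits(dom, "xml_missing") &&
      identical(xml2::xml_attr(dom, "value"), "mass"))
    domain <- "mass"

  checkIbdIdentity(fileContent, ibd, permissive)

  groups <- resolveParamGroups(doc)

  w <- cvValueNum(doc, .ACC[["maxX"]])
  h <- cvValueNum(doc, .ACC[["maxY"]])

  specNodes <- xml2::xml_find_all(doc, ".//run/spectrumList/spectrum")
  if (!length(specNodes)) stopFormat("imzML lists no spectra")

  con <- file(ibd, open = "rb")
  on.exit(close(con))
  cache <- new.env(parent = emptyenv())

  n <- length(specNodes)
  xs <- ys <- zs <- integer(n)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    node <- specNodes[[i]]
    xs[i] <- specPos(node, .ACC[["posX"]], i, "x")
    ys[i] <- specPos(node, .ACC[["posY"]], i, "y")
    zval <- tryCatch(specPos(node, .ACC[["posZ"]], i, "z"),
                     error = function(e) 1L)
    zs[i] <- zval
    arrs <- readBinaryArrays(node, groups, con, cache)
    if (is.null(arrs$mz) || is.null(arrs$intensity))
      stopFormat("spectrum %d lacks an m/z or intensity array", i)
    spectra[[i]] <- MsiSpectrum(arrs$mz, pmax(arrs$intensity, 0),
                                domain = domain)
  }
  if (is.na(w)) w <- max(xs)
  if (is.na(h)) h <- max(ys)
  MsiDataset(spectra, data.frame(x = xs, y = ys, z = zs), domain = domain,
             width = w, height = h)
}

cvAccessions <- function(node)
  xml2::xml_attr(xml2::xml_find_all(node, ".//cvParam"), "accession")

cvValue <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) NA_character_ else xml2::xml_attr(p, "value")
}

cvValueNum <- function(node, accession) {
  v <- cvValue(node, accession)
  if (is.na(v)) NA_real_ else as.numeric(v)
}

specPos <- function(node, accession, i, what) {
  v <- cvValueNum(node, accession)
  if (is.na(v)) stopFormat("spectrum %d has no position %s", i, what)
  as.integer(v)
}

checkIbdIdentity <- function(fileContent, ibd, permissive) {
  report <- function(fmt, ...) {
    if (permissive) msiWarn(fmt, ...) else stopFormat(fmt, ...)
  }
  declared <- cvValue(fileContent, .ACC[["uuid"]])
  if (!is.na(declared)) {
    con <- file(ibd, open = "rb")
    head16 <- readBin(con, "raw", n = 16L)
    close(con)
    want <- hexToRaw(declared)
    if (length(want) != 16L || !identical(head16, want))
      report("UUID mismatch between %s and its XML index", ibd)
  }
  sha <- cvValue(fileContent, .ACC[["sha1"]])
  if (!is.na(sha) && nzchar(sha)) {
    got <- digest::digest(ibd, algo = "sha1", file = TRUE)
    if (tolower(got) != tolower(sha))
      report("SHA-1 checksum mismatch for %s", ibd)
  }
}

# Resolve referenceableParamGroup definitions into per-group storage traits.
resolveParamGroups <- function(doc) {
  nodes <- xml2::xml_find_all(doc, ".//referenceableParamGroupList/referenceableParamGroup")
  out <- list()
  for (g in nodes) {
    id <- xml2::xml_attr(g, "id")
    out[[id]] <- groupTraits(cvAccessions(g))
  }
  out
}

groupTraits <- function(acc) {
  if (.ACC[["zlib"]] %in% acc)
    stopFormat("compressed binary arrays are not supported (zlib declared)")
  if (any(c(.ACC[["int32"]], .ACC[["int64"]]) %in% acc))
    stopFormat("integer binary encodings are not supported")
  size <- if (.ACC[["float64"]] %in% acc) 8L
          else if (.ACC[["float32"]] %in% acc) 4L
          else NA_integer_
  kind <- if (.ACC[["mzArray"]] %in% acc) "mz"
          else if (.ACC[["intensityArray"]] %in% acc) "intensity"
          else NA_character_
  list(size = size, kind = kind)
}

readBinaryArrays <- function(specNode, groups, con, cache) {
  arrNodes <- xml2::xml_find_all(specNode, ".//binaryDataArrayList/binaryDataArray")
  res <- list(mz = NULL, intensity = NULL)
  for (a in arrNodes) {
    traits <- groupTraits(cvAccessions(a))
    ref <- xml2::xml_find_first(a, ".//referenceableParamGroupRef")
    if (!inherits(ref, "xml_missing")) {
      gt <- groups[[xml2::xml_attr(ref, "ref")]]
      if (!is.null(gt)) {
        if (is.na(traits$size)) traits$size <- gt$size
        if (is.na(traits$kind)) traits$kind <- gt$kind
      }
    }
    if (is.na(traits$kind)) next
    if (is.na(traits$size))
      stopFormat("binary array has no supported float encoding declared")
    offset <- cvValueNum(a, .ACC[["externalOffset"]])
    len <- cvValueNum(a, .ACC[["externalArrayLength"]])
    if (is.na(offset) || is.na(len))
      stopFormat("binary array lacks external offset/length accessions")
    key <- sprintf("%d@%d:%d", len, offset, traits$size)
    if (!is.null(cache[[key]])) {
      vals <- cache[[key]]
    } else {
      seek(con, where = offset, origin = "start")
      vals <- readBin(con, "double", n = len, size = traits$size,
                      endian = "little")
      cache[[key]] <- vals
    }
    res[[traits$kind]] <- vals
  }
  res
}

## ---------------------------------------------------------------------------

#' Write an imzML file pair
#'
#' Serialises an [MsiDataset] to a `.imzML`/`.ibd` pair readable by this
#' package and by third-party imzML consumers. Axis values are written as
#' 64-bit floats (charge arithmetic is sensitive to axis precision),
#' intensities as 32-bit floats. The dataset domain is recorded as a
#' `userParam` named `spectrum domain` on `<fileContent>`, so mass-domain
#' files re-read with `domain == "mass"`; readers that ignore the annotation
#' still see a structurally ordinary imzML file.
#'
#' @param dataset an [MsiDataset]; must be non-empty.
#' @param path output `.imzML` path; the `.ibd` file is written next to it.
#' @param dialect `"continuous"` (all spectra share one axis) or
#'   `"processed"` (per-pixel axes).
#' @param mzSize,intensitySize bytes per stored value (8 or 4).
#' @return invisibly, a list with the two file paths.
#' @export
writeImzML <- function(dataset, path, dialect = c("continuous", "processed"),
                       mzSize = 8L, intensitySize = 4L) {
  stopifnot(is(dataset, "MsiDataset"))
  dialect <- match.arg(dialect)
  if (!length(dataset@spectra))
    stopContract("refusing to write an empty dataset")
  sp <- dataset@spectra
  if (dialect == "continuous") {
    ax <- sp[[1]]@axis
    shared <- all(vapply(sp, function(s)
      length(s@axis) == length(ax) && all(s@axis == ax), logical(1)))
    if (!shared)
      stopContract(paste("continuous dialect requires a shared axis across",
                         "all spectra; resample first or use dialect =",
                         "'processed'"))
  }
  ibd <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd, path)) ibd <- paste0(path, ".ibd")

  uuid <- makeUUID(seed = list(dataset@coords,
                               lapply(sp, function(s) s@axis[1]),
                               dialect))
  con <- file(ibd, open = "wb")
  writeBin(uuid$bytes, con)
  offset <- 16
  n <- length(sp)
  writeArr <- function(v, size) {
    writeBin(as.numeric(v), con, size = size, endian = "little")
    nb <- length(v) * size
    off <- offset
    offset <<- offset + nb
    c(offset = off, length = length(v), encoded = nb)
  }
  mzRef <- vector("list", n)
  intRef <- vector("list", n)
  if (dialect == "continuous") {
    sharedRef <- writeArr(sp[[1]]@axis, mzSize)
    for (i in seq_len(n)) {
      mzRef[[i]] <- sharedRef
      intRef[[i]] <- writeArr(sp[[i]]@intensity, intensitySize)
    }
  } else {
    for (i in seq_len(n)) {
      mzRef[[i]] <- writeArr(sp[[i]]@axis, mzSize)
      intRef[[i]] <- writeArr(sp[[i]]@intensity, intensitySize)
    }
  }
  close(con)
  sha1 <- toupper(digest::digest(ibd, algo = "sha1", file = TRUE))

  xml <- imzmlXML(dataset, dialect, uuid$string, sha1, mzRef, intRef,
                  mzSize, intensitySize)
  writeLines(xml, path, useBytes = TRUE)
  invisible(list(imzml = path, ibd = ibd))
}

floatParam <- function(size) {
  if (size == 8L)
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>'
}

imzmlXML <- function(dataset, dialect, uuidStr, sha1, mzRef, intRef,
                     mzSize, intensitySize) {
  n <- length(dataset@spectra)
  dialectAcc <- if (dialect == "continuous") .ACC[["continuous"]] else .ACC[["processed"]]
  header <- c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" xsi:schemaLocation="http://psi.hupo.org/ms/mzml http://psidev.info/files/ms/mzML/xsd/mzML1.1.0_idx.xsd" version="1.1">',
    '  <cvList count="3">',
    '    <cv uri="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" id="MS" version="4.1.12"/>',
    '    <cv uri="http://purl.obolibrary.org/obo/uo.obo" fullName="Unit Ontology" id="UO" version="12:10:2011"/>',
    '    <cv uri="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo" fullName="Imaging MS Ontology" id="IMS" version="1.1.0"/>',
    '  </cvList>',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>',
    sprintf('      <cvParam cvRef="IMS" accession="%s" name="%s" value=""/>',
            dialectAcc, dialect),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>', uuidStr),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000091" name="ibd SHA-1" value="%s"/>', sha1),
    sprintf('      <userParam name="spectrum domain" value="%s"/>', dataset@domain),
    '    </fileContent>',
    '  </fileDescription>',
    '  <referenceableParamGroupList count="2">',
    '    <referenceableParamGroup id="mzArray">',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    paste0('      ', floatParam(mzSize)),
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '    <referenceableParamGroup id="intensityArray">',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    paste0('      ', floatParam(intensitySize)),
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '  </referenceableParamGroupList>',
    '  <softwareList count="1">',
    '    <software id="MsiDeconv" version="0.1.0">',
    '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="MsiDeconv"/>',
    '    </software>',
    '  </softwareList>',
    '  <scanSettingsList count="1">',
    '    <scanSettings id="scanSettings1">',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', dataset@width),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', dataset@height),
    '    </scanSettings>',
    '  </scanSettingsList>',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC1">',
    '    </instrumentConfiguration>',
    '  </instrumentConfigurationList>',
    '  <dataProcessingList count="1">',
    '    <dataProcessing id="MsiDeconvExport">',
    '      <processingMethod order="0" softwareRef="MsiDeconv">',
    '        <cvParam cvRef="MS" accession="MS:1000530" name="file format conversion" value=""/>',
    '      </processingMethod>',
    '    </dataProcessing>',
    '  </dataProcessingList>',
    sprintf('  <run defaultInstrumentConfigurationRef="IC1" id="%s">',
            sub("\\.imzML$", "", basename("run"), ignore.case = TRUE)),
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="MsiDeconvExport">', n)
  )

  cc <- dataset@coords
  specChunks <- vapply(seq_len(n), function(i) {
    paste(c(
      sprintf('      <spectrum defaultArrayLength="%d" id="spectrum=%d" index="%d">', mzRef[[i]][["length"]], i, i - 1L),
      '        <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
      '        <scanList count="1">',
      '          <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
      '          <scan instrumentConfigurationRef="IC1">',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>', cc$x[i]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>', cc$y[i]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000052" name="position z" value="%d"/>', cc$z[i]),
      '          </scan>',
      '        </scanList>',
      '        <binaryDataArrayList count="2">',
      '          <binaryDataArray encodedLength="0">',
      '            <referenceableParamGroupRef ref="mzArray"/>',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', mzRef[[i]][["length"]]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', mzRef[[i]][["encoded"]]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>', mzRef[[i]][["offset"]]),
      '            <binary/>',
      '          </binaryDataArray>',
      '          <binaryDataArray encodedLength="0">',
      '            <referenceableParamGroupRef ref="intensityArray"/>',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', intRef[[i]][["length"]]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', intRef[[i]][["encoded"]]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>', intRef[[i]][["offset"]]),
      '            <binary/>',
      '          </binaryDataArray>',
      '        </binaryDataArrayList>',
      '      </spectrum>'
    ), collapse = "\n")
  }, character(1))

  footer <- c('    </spectrumList>', '  </run>', '</mzML>')
  paste(c(header, specChunks, footer), collapse = "\n")
}
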
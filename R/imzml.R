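## imzML-dialect I/O for centroided MSI data.
##
## Only the "processed" storage mode (a separate m/z array per pixel) is
## supported, matching centroided acquisitions; continuous-mode files are
## rejected rather than silently converted. m/z values are stored as 64-bit
## floats (the 0.005 Da extraction windows need the precision), intensities
## as 32-bit floats. Pixel coordinates are 1-based in the file per the imzML
## convention and 0-based in memory.

## Most-abundant-isotope masses (Da). CODATA/IUPAC values.
.ISOTOPE_MASS <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  F = 18.99840322, Na = 22.9897692809, Mg = 23.985041697, Si = 27.9769265325,
  P = 30.97376163, S = 31.97207100, Cl = 34.96885268, K = 38.96370668,
  Ca = 39.96259098, Fe = 55.9349375, Zn = 63.9291422, Se = 79.9165213,
  Br = 78.9183371, I = 126.904473)

.ELECTRON_MASS <- 0.000548579909

#' Monoisotopic mass of an elemental formula
#'
#' Sums most-abundant-isotope masses over the formula. For a charged species
#' the electron mass is subtracted \code{charge} times and the result divided
#' by \code{abs(charge)}, i.e. the returned value is the m/z of the ion.
#'
#' @param formula elemental formula, e.g. \code{"C25H34O6"}. Element symbols
#'   with optional counts; no parentheses or isotope labels.
#' @param charge integer charge (0 for the neutral mass).
#' @return Mass (neutral) or m/z (charged), in Da.
#' @examples
#' monoisotopicMass("H2O")                     # 18.0106
#' monoisotopicMass("C34H32FeN4O4", charge = 1) # heme b cation, ~616.177
#' @export
monoisotopicMass <- function(formula, charge = 0) {
  stopifnot(length(formula) == 1L, is.character(formula))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula))
    stop("malformed elemental formula: '", formula, "'")
  parts <- regmatches(formula,
                      gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(sub("^[A-Z][a-z]?", "", parts))
  n[is.na(n)] <- 1L
  unknown <- setdiff(el, names(.ISOTOPE_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  mass <- sum(.ISOTOPE_MASS[el] * n)
  charge <- as.integer(charge)
  if (charge == 0L) return(mass)
  (mass - charge * .ELECTRON_MASS) / abs(charge)
}

## ---------------------------------------------------------------------------
## Writing
## ---------------------------------------------------------------------------

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Write an MSIDataset as an imzML file pair
#'
#' Emits a processed-mode, centroid imzML-dialect \code{.imzML}/\code{.ibd}
#' pair. The ibd UUID is derived from the MD5 of the binary payload, so
#' writing the same dataset twice produces byte-identical files.
#'
#' @param dataset a valid \linkS4class{MSIDataset}.
#' @param path output path; the \code{.imzML}/\code{.ibd} extensions are
#'   added (or replaced) as needed.
#' @return Invisibly, the path of the written \code{.imzML} file.
#' @seealso \code{\link{readImzML}}
#' @export
writeImzML <- function(dataset, path) {
  validObject(dataset)  # validation error before any file is written
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  xmlPath <- paste0(base, ".imzML"); ibdPath <- paste0(base, ".ibd")

  sp <- dataset@spectra
  n <- length(sp)
  lens <- vapply(sp, function(s) length(s$mz), integer(1))
  ## binary payload (without the leading UUID)
  payload <- file(ibdPath, "wb")
  on.exit(close(payload), add = TRUE)
  writeBin(raw(16L), payload)  # placeholder UUID
  pos <- 16
  mzOff <- intOff <- numeric(n)
  for (i in seq_len(n)) {
    mzOff[i] <- pos
    writeBin(as.double(sp[[i]]$mz), payload, size = 8, endian = "little")
    pos <- pos + 8 * lens[i]
    intOff[i] <- pos
    writeBin(as.double(sp[[i]]$intensity), payload, size = 4,
             endian = "little")
    pos <- pos + 4 * lens[i]
  }
  close(payload)
  on.exit(NULL)

  ## content-derived UUID: MD5 of the payload written above
  md5payload <- unname(tools::md5sum(ibdPath))
  uuidRaw <- as.raw(strtoi(substring(md5payload, seq(1, 31, 2),
                                     seq(2, 32, 2)), 16L))
  con <- file(ibdPath, "r+b")
  writeBin(uuidRaw, con)
  close(con)
  uuid <- paste0("{", substr(md5payload, 1, 8), "-",
                 substr(md5payload, 9, 12), "-", substr(md5payload, 13, 16),
                 "-", substr(md5payload, 17, 20), "-",
                 substr(md5payload, 21, 32), "}")
  ibdMd5 <- toupper(unname(tools::md5sum(ibdPath)))

  cv <- function(ref, acc, name, value = "")
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s" value="%s"/>',
            ref, acc, name, .xmlEscape(as.character(value)))

  head <- c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://ms-imaging.org/wp/wp-content/uploads/2009/08/imagingMS.obo"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    cv("MS", "MS:1000127", "centroid spectrum"),
    cv("IMS", "IMS:1000031", "processed"),
    cv("IMS", "IMS:1000080", "universally unique identifier", uuid),
    cv("IMS", "IMS:1000090", "ibd MD5", ibdMd5),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS", "MS:1000514", "m/z array"),
    cv("MS", "MS:1000523", "64-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cv("MS", "MS:1000515", "intensity array"),
    cv("MS", "MS:1000521", "32-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    sprintf('<softwareList count="1"><software id="msiSpatial" version="%s"/></softwareList>',
            as.character(utils::packageVersion("msiSpatial"))),
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    cv("IMS", "IMS:1000042", "max count of pixels x", dataset@gridDim[2L]),
    cv("IMS", "IMS:1000043", "max count of pixels y", dataset@gridDim[1L]),
    cv("IMS", "IMS:1000046", "pixel size (x)", dataset@pixelPitchUm),
    cv("IMS", "IMS:1000047", "pixel size y", dataset@pixelPitchUm),
    "</scanSettings></scanSettingsList>",
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export"><processingMethod order="1" softwareRef="msiSpatial">',
    cv("MS", "MS:1000544", "Conversion to mzML"),
    "</processingMethod></dataProcessing></dataProcessingList>",
    sprintf('<run id="%s" defaultInstrumentConfigurationRef="IC1">',
            .xmlEscape(dataset@sectionId)),
    sprintf('<userParam name="groupLabel" value="%s"/>',
            .xmlEscape(dataset@groupLabel)),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="export">', n))

  xs <- dataset@coords[, 1L] + 1L
  ys <- dataset@coords[, 2L] + 1L
  specChunks <- vapply(seq_len(n), function(i) paste0(
    sprintf('<spectrum id="Spectrum=%d" defaultArrayLength="%d" index="%d">',
            i, lens[i], i - 1L),
    cv("MS", "MS:1000127", "centroid spectrum"),
    cv("MS", "MS:1000130", "positive scan"),
    '<scanList count="1">', cv("MS", "MS:1000795", "no combination"),
    "<scan>",
    cv("IMS", "IMS:1000050", "position x", xs[i]),
    cv("IMS", "IMS:1000051", "position y", ys[i]),
    '<scanWindowList count="1"><scanWindow>',
    cv("MS", "MS:1000501", "scan window lower limit", dataset@mzRange[1L]),
    cv("MS", "MS:1000500", "scan window upper limit", dataset@mzRange[2L]),
    "</scanWindow></scanWindowList></scan></scanList>",
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="mzArray"/>',
    cv("IMS", "IMS:1000103", "external array length", lens[i]),
    cv("IMS", "IMS:1000104", "external encoded length", 8L * lens[i]),
    cv("IMS", "IMS:1000102", "external offset", mzOff[i]),
    "<binary/></binaryDataArray>",
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="intensityArray"/>',
    cv("IMS", "IMS:1000103", "external array length", lens[i]),
    cv("IMS", "IMS:1000104", "external encoded length", 4L * lens[i]),
    cv("IMS", "IMS:1000102", "external offset", intOff[i]),
    "<binary/></binaryDataArray>",
    "</binaryDataArrayList></spectrum>"), character(1))

  tail <- c("</spectrumList></run></mzML>")
  writeLines(c(head, specChunks, tail), xmlPath, useBytes = TRUE)
  invisible(xmlPath)
}

## ---------------------------------------------------------------------------
## Reading
## ---------------------------------------------------------------------------

## XPath helper: qualify element names with the document's default
## namespace prefix (libxml2 requires explicit prefixes; stripping
## namespaces instead is prohibitively slow on large spectrum lists).
.nsPath <- function(path, prefix) {
  if (!nzchar(prefix)) return(path)
  gsub("(^|/)([A-Za-z])", sprintf("\\1%s:\\2", prefix), path)
}

.cvValuesIn <- function(node, accession, prefix, ns) {
  nodes <- xml2::xml_find_all(
    node, .nsPath(sprintf(".//cvParam[@accession='%s']", accession), prefix),
    ns = ns)
  xml2::xml_attr(nodes, "value")
}

#' Read an imzML file pair into an MSIDataset
#'
#' Accepts processed-mode (per-pixel m/z array), centroid imzML files as
#' written by \code{\link{writeImzML}} or by standard converters. Continuous
#' (profile-raster) mode files are rejected.
#'
#' @param path path to the \code{.imzML} file (the \code{.ibd} pair must sit
#'   next to it).
#' @param checkChecksum verify the ibd MD5 recorded in the file (default
#'   TRUE; a mismatch is an error).
#' @return An \linkS4class{MSIDataset} with 0-based pixel coordinates.
#' @export
readImzML <- function(path, checkChecksum = TRUE) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  xmlPath <- paste0(base, ".imzML"); ibdPath <- paste0(base, ".ibd")
  if (!file.exists(xmlPath)) stop("no such imzML file: ", xmlPath)
  if (!file.exists(ibdPath)) stop("missing ibd pair for: ", xmlPath)

  doc <- xml2::read_xml(xmlPath)
  ns <- xml2::xml_ns(doc)
  prefix <- if ("d1" %in% names(ns)) "d1" else ""
  find1 <- function(node, path)
    xml2::xml_find_first(node, .nsPath(path, prefix), ns = ns)
  findAll <- function(node, path)
    xml2::xml_find_all(node, .nsPath(path, prefix), ns = ns)

  fileContent <- find1(doc, ".//fileDescription/fileContent")
  fcAccs <- xml2::xml_attr(findAll(fileContent, ".//cvParam"), "accession")
  if ("IMS:1000030" %in% fcAccs)
    stop("unsupported imzML mode: continuous (only processed/centroid files are read)")
  if (!"IMS:1000031" %in% fcAccs)
    stop("imzML file does not declare processed (centroid) mode")

  if (checkChecksum) {
    stored <- .cvValuesIn(fileContent, "IMS:1000090", prefix, ns)
    if (length(stored) == 1L) {
      actual <- toupper(unname(tools::md5sum(ibdPath)))
      if (!identical(toupper(stored), actual))
        stop("ibd MD5 checksum mismatch for ", ibdPath)
    }
  }

  ## which referenceable group is the m/z array, and its precision
  groups <- findAll(doc, ".//referenceableParamGroup")
  groupInfo <- lapply(groups, function(g) {
    acc <- xml2::xml_attr(findAll(g, ".//cvParam"), "accession")
    list(id = xml2::xml_attr(g, "id"),
         kind = if ("MS:1000514" %in% acc) "mz"
                else if ("MS:1000515" %in% acc) "intensity" else NA,
         bytes = if ("MS:1000523" %in% acc) 8L
                 else if ("MS:1000521" %in% acc) 4L else NA_integer_)
  })
  kinds <- vapply(groupInfo, `[[`, character(1), "kind")
  byId <- stats::setNames(groupInfo, vapply(groupInfo, `[[`, character(1), "id"))
  if (!all(c("mz", "intensity") %in% kinds))
    stop("malformed imzML index: missing m/z or intensity array definition")

  ## grid geometry
  scanSettings <- find1(doc, ".//scanSettings")
  ncolGrid <- as.integer(.cvValuesIn(scanSettings, "IMS:1000042", prefix, ns))
  nrowGrid <- as.integer(.cvValuesIn(scanSettings, "IMS:1000043", prefix, ns))
  pitch <- suppressWarnings(
    as.numeric(.cvValuesIn(scanSettings, "IMS:1000046", prefix, ns)))
  if (!length(pitch) || is.na(pitch)) pitch <- 400

  n <- length(findAll(doc, ".//spectrum"))
  ## one pass over every cvParam; per-spectrum items subset in document order
  allCv <- findAll(doc, "//cvParam")
  cvAcc <- xml2::xml_attr(allCv, "accession")
  cvVal <- xml2::xml_attr(allCv, "value")
  posx <- as.integer(cvVal[cvAcc == "IMS:1000050"])
  posy <- as.integer(cvVal[cvAcc == "IMS:1000051"])
  if (length(posx) != n || length(posy) != n || anyNA(posx) || anyNA(posy))
    stop("malformed imzML index: pixel positions do not match spectrum count")

  ## binary arrays, in document order: alternating per spectrum
  refs <- xml2::xml_attr(findAll(doc, "//referenceableParamGroupRef"), "ref")
  refs <- refs[refs %in% names(byId)]
  offs <- as.numeric(cvVal[cvAcc == "IMS:1000102"])
  alens <- as.integer(cvVal[cvAcc == "IMS:1000103"])
  if (length(refs) != 2L * n || length(offs) != 2L * n ||
      length(alens) != 2L * n)
    stop("malformed imzML index: incomplete binary array metadata")

  mzR <- as.numeric(c(cvVal[cvAcc == "MS:1000501"][1L],
                      cvVal[cvAcc == "MS:1000500"][1L]))

  con <- file(ibdPath, "rb")
  on.exit(close(con))
  readArr <- function(offset, len, bytes) {
    if (len == 0L) return(numeric(0))
    seek(con, where = offset, origin = "start")
    readBin(con, "double", n = len, size = bytes, endian = "little")
  }
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    j <- 2L * i - 1L
    kind1 <- byId[[refs[j]]]; kind2 <- byId[[refs[j + 1L]]]
    if (is.null(kind1) || is.null(kind2))
      stop("malformed imzML index: unknown array group reference '",
           refs[j], "'")
    arr1 <- readArr(offs[j], alens[j], kind1$bytes)
    arr2 <- readArr(offs[j + 1L], alens[j + 1L], kind2$bytes)
    if (kind1$kind == "mz") spectra[[i]] <- list(mz = arr1, intensity = arr2)
    else spectra[[i]] <- list(mz = arr2, intensity = arr1)
  }

  coords <- cbind(x = posx - 1L, y = posy - 1L)
  dup <- anyDuplicated(coords[, 1L] + ncolGrid * coords[, 2L])
  if (dup)
    stop(sprintf(
      "malformed imzML index: duplicate pixel coordinate at spectrum %d (x=%d, y=%d)",
      dup, posx[dup], posy[dup]))

  run <- find1(doc, ".//run")
  sectionId <- xml2::xml_attr(run, "id")
  gl <- xml2::xml_attr(
    find1(doc, ".//run/userParam[@name='groupLabel']"), "value")
  if (is.na(gl)) gl <- ""
  if (anyNA(mzR)) {
    allmz <- unlist(lapply(spectra, `[[`, "mz"))
    mzR <- if (length(allmz)) range(allmz) else c(0, 1)
  }

  MSIDataset(spectra = spectra, coords = coords,
             gridDim = c(nrowGrid, ncolGrid), pixelPitchUm = pitch,
             mzRange = mzR, sectionId = sectionId, groupLabel = gl)
}
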
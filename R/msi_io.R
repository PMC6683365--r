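# imzML 1.1 input/output.  Two files per dataset: an XML metadata file
# (.imzML) and a binary file (.ibd) holding the per-pixel m/z and intensity
# arrays, linked by a shared UUID.  m/z is stored as 64-bit float, intensity
# as 32-bit float, little-endian, no compression.  Both storage modes are
# supported: "continuous" (one m/z axis shared by every pixel) and
# "processed" (a private peak list per pixel).

IMZML_MZ_BYTES <- 8L
IMZML_INT_BYTES <- 4L

# random UUID without touching the caller's RNG stream
make_uuid_hex <- function() {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer((as.numeric(Sys.time()) * 1000 + Sys.getpid()) %% .Machine$integer.max))
  paste(sprintf("%02x", sample.int(256L, 16L, replace = TRUE) - 1L),
        collapse = "")
}

normalize_uuid <- function(x) tolower(gsub("[^0-9a-fA-F]", "", x))

uuid_to_bytes <- function(hex) {
  hex <- normalize_uuid(hex)
  as.raw(strtoi(substring(hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

ibd_path_for <- function(path) {
  sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
}

#' Write an MSI dataset as an imzML/ibd pair
#'
#' @param dataset an [msi_dataset()].
#' @param path output path ending in `.imzML`; the binary companion gets the
#'   same stem with extension `.ibd`.
#' @param mode `"processed"` (default; private peak list per pixel) or
#'   `"continuous"` (requires every pixel to share one m/z axis).
#' @return Invisibly, the paths of the two files written.
#' @export
write_imzml <- function(dataset, path, mode = c("processed", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "msi_dataset"))
  if (!grepl("\\.imzML$", path, ignore.case = TRUE)) {
    path <- paste0(path, ".imzML")
  }
  ibd_path <- ibd_path_for(path)
  n <- n_pixels(dataset)

  if (mode == "continuous") {
    ref <- dataset$mz[[1L]]
    same <- vapply(dataset$mz, function(m) {
      length(m) == length(ref) && all(m == ref)
    }, logical(1))
    if (!all(same)) {
      stop("continuous mode requires an identical m/z axis in every pixel; ",
           "pixel ", which(!same)[1L], " differs (use mode = \"processed\")")
    }
  }

  uuid <- make_uuid_hex()

  # binary layout: 16-byte UUID, then arrays; record each array's offset
  con <- file(ibd_path, "wb")
  ok <- FALSE
  on.exit(if (!ok) {close(con); unlink(ibd_path)}, add = TRUE)
  writeBin(uuid_to_bytes(uuid), con)
  offset <- 16
  mz_off <- numeric(n); mz_len <- integer(n)
  int_off <- numeric(n); int_len <- integer(n)
  if (mode == "continuous") {
    writeBin(as.double(dataset$mz[[1L]]), con, size = IMZML_MZ_BYTES,
             endian = "little")
    mz_off[] <- offset
    mz_len[] <- length(dataset$mz[[1L]])
    offset <- offset + length(dataset$mz[[1L]]) * IMZML_MZ_BYTES
    for (i in seq_len(n)) {
      v <- dataset$intensity[[i]]
      writeBin(as.double(v), con, size = IMZML_INT_BYTES, endian = "little")
      int_off[i] <- offset; int_len[i] <- length(v)
      offset <- offset + length(v) * IMZML_INT_BYTES
    }
  } else {
    for (i in seq_len(n)) {
      m <- dataset$mz[[i]]; v <- dataset$intensity[[i]]
      writeBin(as.double(m), con, size = IMZML_MZ_BYTES, endian = "little")
      mz_off[i] <- offset; mz_len[i] <- length(m)
      offset <- offset + length(m) * IMZML_MZ_BYTES
      writeBin(as.double(v), con, size = IMZML_INT_BYTES, endian = "little")
      int_off[i] <- offset; int_len[i] <- length(v)
      offset <- offset + length(v) * IMZML_INT_BYTES
    }
  }
  close(con)
  ok <- TRUE
  md5 <- unname(tools::md5sum(ibd_path))

  mode_cv <- if (mode == "continuous") {
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>'
  } else {
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>'
  }

  spectra <- vapply(seq_len(n), function(i) {
    paste0(
      '      <spectrum id="spectrum=', i, '" index="', i - 1L,
      '" defaultArrayLength="0">\n',
      '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      '        <scanList count="1">\n',
      '          <scan>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
      dataset$coords$x[i] + 1L, '"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
      dataset$coords$y[i] + 1L, '"/>\n',
      '          </scan>\n',
      '        </scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="mzArray"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', mz_len[i], '"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', mz_len[i] * IMZML_MZ_BYTES, '"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', format(mz_off[i], scientific = FALSE), '"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="intensityArray"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', int_len[i], '"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', int_len[i] * IMZML_INT_BYTES, '"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', format(int_off[i], scientific = FALSE), '"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '  <cvList count="3">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
    '    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription>\n',
    '    <fileContent>\n',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{', uuid, '}"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="', toupper(md5), '"/>\n',
    '      ', mode_cv, '\n',
    '    </fileContent>\n',
    '  </fileDescription>\n',
    '  <referenceableParamGroupList count="2">\n',
    '    <referenceableParamGroup id="mzArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="intensityArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '  </referenceableParamGroupList>\n',
    '  <softwareList count="1">\n',
    '    <software id="surfmsi" version="0.1.0"/>\n',
    '  </softwareList>\n',
    '  <scanSettingsList count="1">\n',
    '    <scanSettings id="scansettings1">\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="', dataset$grid_shape[2L], '"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="', dataset$grid_shape[1L], '"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="', dataset$pixel_pitch, '"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="', dataset$pixel_pitch, '"/>\n',
    '    </scanSettings>\n',
    '  </scanSettingsList>\n',
    '  <instrumentConfigurationList count="1">\n',
    '    <instrumentConfiguration id="IC1"/>\n',
    '  </instrumentConfigurationList>\n',
    '  <dataProcessingList count="1">\n',
    '    <dataProcessing id="dp1">\n',
    '      <processingMethod order="1" softwareRef="surfmsi">\n',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>\n',
    '      </processingMethod>\n',
    '    </dataProcessing>\n',
    '  </dataProcessingList>\n',
    '  <run id="', dataset$sample_id, '" defaultInstrumentConfigurationRef="IC1">\n',
    '    <spectrumList count="', n, '" defaultDataProcessingRef="dp1">\n',
    paste(spectra, collapse = "\n"), '\n',
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(c(imzml = path, ibd = ibd_path))
}

#' Read an imzML/ibd pair
#'
#' Validates the UUID linkage between the two files and, when present, the
#' MD5 checksum of the binary file.  Both continuous and processed modes
#' are supported.
#'
#' @param path path of the `.imzML` metadata file.
#' @param group group label to attach (`"treated"`, `"control"`,
#'   `"calibration"`); not stored in the standard, so supplied by the caller.
#' @param check_md5 verify the ibd checksum (default TRUE).
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path, group = "treated", check_md5 = TRUE) {
  if (!file.exists(path)) stop("imzML file not found: ", path)
  ibd_path <- ibd_path_for(path)
  if (!file.exists(ibd_path)) {
    stop("binary companion file not found: ", ibd_path)
  }
  doc <- xml2::read_xml(path)
  # keep the namespace intact (stripping it rewrites the whole tree and is
  # very slow on files with thousands of spectra); "q:" below stands for
  # the document's default namespace prefix, or nothing if there is none
  ns <- xml2::xml_ns(doc)
  pfx <- if ("d1" %in% names(ns)) "d1:" else ""
  q <- function(path) gsub("q:", pfx, path, fixed = TRUE)

  cv_value <- function(node, accession) {
    n <- xml2::xml_find_first(
      node, q(sprintf(".//q:cvParam[@accession='%s']", accession)), ns)
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
  }

  fc <- xml2::xml_find_first(doc, q(".//q:fileDescription/q:fileContent"), ns)
  uuid_xml <- cv_value(fc, "IMS:1000080")
  if (is.na(uuid_xml)) stop("imzML file carries no UUID (IMS:1000080)")
  md5_xml <- cv_value(fc, "IMS:1000090")
  if (is.na(md5_xml)) md5_xml <- cv_value(fc, "IMS:1000091")  # SHA-1 slot unused

  ibd_con <- file(ibd_path, "rb")
  on.exit(close(ibd_con), add = TRUE)
  uuid_ibd <- paste(sprintf("%02x", as.integer(readBin(ibd_con, "raw", 16L))),
                    collapse = "")
  if (normalize_uuid(uuid_xml) != uuid_ibd) {
    stop("UUID mismatch between imzML (", normalize_uuid(uuid_xml),
         ") and ibd (", uuid_ibd, ")")
  }
  if (check_md5 && !is.na(md5_xml) && nchar(md5_xml) == 32L) {
    md5_real <- unname(tools::md5sum(ibd_path))
    if (tolower(md5_xml) != tolower(md5_real)) {
      stop("ibd MD5 checksum mismatch: expected ", tolower(md5_xml),
           ", file has ", md5_real)
    }
  }

  ss <- xml2::xml_find_first(doc, q(".//q:scanSettings"), ns)
  cols <- as.integer(cv_value(ss, "IMS:1000042"))
  rows <- as.integer(cv_value(ss, "IMS:1000043"))
  pitch <- as.numeric(cv_value(ss, "IMS:1000046"))
  if (is.na(pitch)) pitch <- 350
  sample_id <- xml2::xml_attr(xml2::xml_find_first(doc, q(".//q:run"), ns), "id")
  if (is.na(sample_id)) sample_id <- "sample"

  specs <- xml2::xml_find_all(doc, q(".//q:spectrumList/q:spectrum"), ns)
  n <- length(specs)
  if (n == 0L) stop("imzML file contains no spectra")

  # vectorized parse in document order: one global XPath per field instead
  # of per-spectrum queries (orders of magnitude faster on large files)
  attr_num <- function(xpath) {
    as.numeric(xml2::xml_attr(xml2::xml_find_all(doc, q(xpath), ns), "value"))
  }
  spec_xp <- "/q:mzML/q:run/q:spectrumList/q:spectrum"
  scan_xp <- paste0(spec_xp, "/q:scanList/q:scan")
  xs <- attr_num(paste0(scan_xp, "/q:cvParam[@accession='IMS:1000050']"))
  ys <- attr_num(paste0(scan_xp, "/q:cvParam[@accession='IMS:1000051']"))
  if (length(xs) != n || length(ys) != n || anyNA(xs) || anyNA(ys)) {
    stop("missing pixel positions: expected one position x/y per spectrum")
  }
  xs <- as.integer(xs) - 1L; ys <- as.integer(ys) - 1L
  bda_xp <- paste0(spec_xp, "/q:binaryDataArrayList/q:binaryDataArray")
  refs <- xml2::xml_attr(
    xml2::xml_find_all(doc, q(paste0(bda_xp, "/q:referenceableParamGroupRef")), ns),
    "ref")
  lens <- attr_num(paste0(bda_xp, "/q:cvParam[@accession='IMS:1000103']"))
  offs <- attr_num(paste0(bda_xp, "/q:cvParam[@accession='IMS:1000102']"))
  if (length(refs) != 2L * n || length(lens) != 2L * n ||
      length(offs) != 2L * n || anyNA(lens) || anyNA(offs)) {
    stop("malformed binary array metadata: expected an m/z and an ",
         "intensity array with external offset/length per spectrum")
  }

  mz_list <- vector("list", n); int_list <- vector("list", n)
  for (i in seq_len(n)) {
    for (k in (2L * i - 1L):(2L * i)) {
      seek(ibd_con, where = offs[k], origin = "start")
      if (identical(refs[k], "mzArray")) {
        mz_list[[i]] <- readBin(ibd_con, "double", n = lens[k],
                                size = IMZML_MZ_BYTES, endian = "little")
      } else {
        int_list[[i]] <- readBin(ibd_con, "double", n = lens[k],
                                 size = IMZML_INT_BYTES, endian = "little")
      }
    }
    if (is.null(mz_list[[i]]) || is.null(int_list[[i]])) {
      stop("spectrum ", i, " (x=", xs[i], ", y=", ys[i],
           "): missing m/z or intensity array")
    }
    if (length(mz_list[[i]]) > 1L && any(diff(mz_list[[i]]) <= 0)) {
      stop("spectrum ", i, " (x=", xs[i], ", y=", ys[i],
           "): m/z values not strictly ascending")
    }
  }
  if (is.na(rows)) rows <- max(ys) + 1L
  if (is.na(cols)) cols <- max(xs) + 1L

  msi_dataset(data.frame(x = xs, y = ys), mz_list, int_list,
              grid_shape = c(rows, cols), pixel_pitch = pitch,
              sample_id = sample_id, group = group)
}

#' Extract a 2D ion image at a target m/z
#'
#' Sums, per pixel, the intensities of all peaks whose m/z lies within
#' `target_mz` plus or minus `tolerance` (the window is closed on both
#' sides, so a peak exactly at the boundary counts).  Pixels never acquired
#' are `NA`; acquired pixels with no peak in the window are 0.
#'
#' @param dataset an [msi_dataset()].
#' @param target_mz target m/z in Da (e.g. 3618 for the SP-C analog sodium
#'   adduct, 3886 for the protonated SP-B analog).
#' @param tolerance window half-width in Da; the default 1 Da gives a
#'   2 Da-wide window.
#' @return An [ion_image()].
#' @export
extract_ion_image <- function(dataset, target_mz, tolerance = 1) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (tolerance <= 0) stop("tolerance must be positive")
  if (target_mz < 1200 || target_mz > 4500) {
    warning("target m/z ", target_mz,
            " is outside the 1200-4500 acquisition range")
  }
  lo <- target_mz - tolerance
  hi <- target_mz + tolerance
  vals <- matrix(NA_real_, dataset$grid_shape[1L], dataset$grid_shape[2L])
  n <- n_pixels(dataset)
  v <- vapply(seq_len(n), function(i) {
    m <- dataset$mz[[i]]
    # peak lists are ascending: locate the window by binary search
    i0 <- findInterval(lo, m, left.open = TRUE) + 1L
    i1 <- findInterval(hi, m)
    if (i1 < i0) 0 else sum(dataset$intensity[[i]][i0:i1])
  }, numeric(1))
  vals[cbind(dataset$coords$y + 1L, dataset$coords$x + 1L)] <- v
  ion_image(vals, target_mz, tolerance,
            sample_id = dataset$sample_id, group = dataset$group)
}
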
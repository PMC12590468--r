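# Minimal mzML I/O.  Only what the pipeline needs: centroided MS1/MS2
# spectra with scan start times, MS2 precursor m/z, and base64-encoded
# 32/64-bit little-endian peak arrays, optionally zlib-compressed.

new_spectrum_series <- function(scans, source = NA_character_) {
  structure(list(scans = scans, source = source), class = "spectrum_series")
}

#' Build a spectrum series in memory
#'
#' @param scans List of scans, each a list with `rt` (min), `ms_level`
#'   (1 or 2), `precursor_mz` (`NA` for MS1), `mz` and `intensity`
#'   (equal-length numeric vectors).
#' @return A `spectrum_series`.
#' @export
spectrum_series <- function(scans) {
  rt <- vapply(scans, function(s) s$rt, numeric(1))
  if (is.unsorted(rt)) abort_validation("scan retention times must be nondecreasing")
  for (s in scans) {
    if (!s$ms_level %in% c(1L, 2L))
      abort_validation("ms_level must be 1 or 2")
    if (s$ms_level == 2L && !is_number(s$precursor_mz))
      abort_validation("MS2 scans must carry a precursor_mz")
    if (length(s$mz) != length(s$intensity) ||
        (length(s$intensity) && any(s$intensity < 0)))
      abort_validation("peak arrays must be equal length with intensities >= 0")
  }
  new_spectrum_series(scans)
}

#' @export
print.spectrum_series <- function(x, ...) {
  lv <- vapply(x$scans, function(s) s$ms_level, numeric(1))
  rt <- vapply(x$scans, function(s) s$rt, numeric(1))
  cat(sprintf("<spectrum_series> %d scans (%d MS1, %d MS2)%s\n",
              length(x$scans), sum(lv == 1), sum(lv == 2),
              if (length(rt)) sprintf(", rt %.3f..%.3f min", min(rt), max(rt))
              else ""))
  invisible(x)
}

#' @export
length.spectrum_series <- function(x) length(x$scans)

scan_rts <- function(series, ms_level = NULL) {
  sel <- scan_sel(series, ms_level)
  vapply(series$scans[sel], function(s) s$rt, numeric(1))
}

scan_sel <- function(series, ms_level = NULL) {
  if (is.null(ms_level)) return(seq_along(series$scans))
  which(vapply(series$scans, function(s) s$ms_level, numeric(1)) == ms_level)
}

#' Total ion current of the MS1 scans
#' @param series A `spectrum_series`.
#' @return Data.frame `rt`, `tic`.
#' @export
total_ion_current <- function(series) {
  sel <- scan_sel(series, 1L)
  data.frame(rt = vapply(series$scans[sel], function(s) s$rt, numeric(1)),
             tic = vapply(series$scans[sel], function(s) sum(s$intensity),
                          numeric(1)))
}

#' Read an mzML file
#'
#' Parses MS1 and MS2 spectra, converting scan start times to minutes
#' regardless of the file's unit attribute and retaining MS2 precursor m/z.
#' Spectra are assumed centroided; profile-mode files are read as-is with a
#' warning.
#'
#' @param path mzML file (plain or indexed).
#' @return A `spectrum_series`.
#' @export
read_mzml <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort_io("cannot read mzML file '%s'", as.character(path)[1])
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    abort_io("malformed mzML '%s': %s", path, conditionMessage(e)))
  spectra <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  profile_seen <- FALSE
  scans <- lapply(spectra, function(sp) {
    cv <- xml2::xml_find_all(sp, ".//*[local-name()='cvParam']")
    acc <- xml2::xml_attr(cv, "accession")
    val <- xml2::xml_attr(cv, "value")
    if ("MS:1000128" %in% acc) profile_seen <<- TRUE
    lev <- suppressWarnings(as.integer(val[match("MS:1000511", acc)]))
    if (is.na(lev)) lev <- 1L
    rt_i <- match("MS:1000016", acc)
    rt <- suppressWarnings(as.numeric(val[rt_i]))
    unit <- xml2::xml_attr(cv[rt_i], "unitName")
    if (!is.na(rt) && !is.na(unit) && grepl("second", unit)) rt <- rt / 60
    prec <- NA_real_
    if (lev >= 2L) {
      ion <- xml2::xml_find_first(
        sp, ".//*[local-name()='selectedIon']/*[local-name()='cvParam'][@accession='MS:1000744']")
      if (!inherits(ion, "xml_missing"))
        prec <- as.numeric(xml2::xml_attr(ion, "value"))
    }
    arrays <- decode_binary_arrays(sp)
    list(rt = rt, ms_level = lev, precursor_mz = prec,
         mz = arrays$mz, intensity = arrays$intensity)
  })
  if (profile_seen)
    warning("profile-mode spectra found; treating peaks as centroids",
            call. = FALSE)
  rt <- vapply(scans, function(s) s$rt, numeric(1))
  new_spectrum_series(scans[order(rt)], source = path)
}

decode_binary_arrays <- function(sp) {
  out <- list(mz = numeric(0), intensity = numeric(0))
  bdas <- xml2::xml_find_all(sp, ".//*[local-name()='binaryDataArray']")
  n_expect <- suppressWarnings(as.integer(xml2::xml_attr(sp, "defaultArrayLength")))
  for (bda in bdas) {
    cv <- xml2::xml_find_all(bda, "./*[local-name()='cvParam']")
    acc <- xml2::xml_attr(cv, "accession")
    kind <- if ("MS:1000514" %in% acc) "mz"
            else if ("MS:1000515" %in% acc) "intensity" else next
    size <- if ("MS:1000521" %in% acc) 4L else 8L
    zlib <- "MS:1000574" %in% acc
    b64 <- xml2::xml_text(
      xml2::xml_find_first(bda, "./*[local-name()='binary']"))
    raw <- base64enc::base64decode(gsub("[[:space:]]", "", b64))
    if (zlib && length(raw)) raw <- memDecompress(raw, type = "gzip")
    n <- length(raw) %/% size
    if (!is.na(n_expect) && n_expect >= 0 && n != n_expect && n_expect != 0)
      n <- min(n, n_expect)
    out[[kind]] <- readBin(raw, "double", n = n, size = size,
                           endian = "little")
  }
  out
}

encode_binary_array <- function(x, compress = FALSE) {
  if (!length(x)) return("")   # base64encode(raw(0)) yields character(0)
  raw <- writeBin(as.double(x), raw(), size = 8L, endian = "little")
  if (compress) raw <- memCompress(raw, type = "gzip")
  base64enc::base64encode(raw)
}

xml_num <- function(x) sprintf("%.12g", x)

#' Write a spectrum series to mzML
#'
#' Emits a minimal, structurally valid mzML 1.1 document: centroid spectra,
#' 64-bit little-endian peak arrays (optionally zlib-compressed), scan start
#' times in minutes and MS2 precursor m/z.
#'
#' @param series A `spectrum_series`.
#' @param path Output path.
#' @param compress Use zlib compression for the peak arrays (default
#'   `FALSE`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(series, path, compress = FALSE) {
  stopifnot(inherits(series, "spectrum_series"))
  con <- tryCatch(file(path, "w"), error = function(e)
    abort_io("cannot write mzML '%s'", path))
  on.exit(close(con))
  n <- length(series$scans)
  comp_cv <- if (compress)
    '<cvParam cvRef="MS" accession="MS:1000574" name="zlib compression"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>'
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
    '</fileContent></fileDescription>',
    '<run id="run">',
    sprintf('<spectrumList count="%d">', n)), con)
  for (i in seq_len(n)) {
    s <- series$scans[[i]]
    np <- length(s$mz)
    mzb <- encode_binary_array(s$mz, compress)
    inb <- encode_binary_array(s$intensity, compress)
    prec <- if (s$ms_level >= 2L && is_number(s$precursor_mz)) paste0(
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
      sprintf('<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%s"/>',
              xml_num(s$precursor_mz)),
      '</selectedIon></selectedIonList></precursor></precursorList>') else ""
    writeLines(c(
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
              i - 1L, i, np),
      sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
              as.integer(s$ms_level)),
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
      '<scanList count="1"><scan>',
      sprintf('<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%s" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>',
              xml_num(s$rt)),
      '</scan></scanList>',
      prec,
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(mzb)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      comp_cv,
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
      sprintf('<binary>%s</binary>', mzb),
      '</binaryDataArray>',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(inb)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      comp_cv,
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
      sprintf('<binary>%s</binary>', inb),
      '</binaryDataArray>',
      '</binaryDataArrayList>',
      '</spectrum>'), con)
  }
  writeLines(c('</spectrumList>', '</run>', '</mzML>'), con)
  invisible(path)
}
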
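# Containers and readers/writers for intact-run MS1 data and chromatograms.
#
# Two on-disk dialects are supported for spectra: mzML (MS1 scans, 64-bit
# float arrays, zlib or no compression) and a plain-text spectrum table
# (`rt_min,mz,intensity` CSV).  Chromatograms travel as `time_min,intensity`
# CSV.

#' Construct a spectrum set
#'
#' @param scans list of scans, each a list with `rt` (minutes), `mz`
#'   (ascending numeric vector) and `intensity` (same length).
#' @param metadata optional list (scan range, polarity, source path).
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(scans, metadata = list()) {
  rts <- vapply(scans, `[[`, numeric(1), "rt")
  if (is.unsorted(rts, strictly = TRUE))
    stop("scan retention times must be strictly increasing")
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    if (length(sc$mz) != length(sc$intensity))
      stop("scan ", i, ": mz/intensity length mismatch")
    if (is.unsorted(sc$mz)) {
      o <- order(sc$mz)
      scans[[i]]$mz <- sc$mz[o]
      scans[[i]]$intensity <- sc$intensity[o]
    }
  }
  structure(list(scans = scans, metadata = metadata), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  rts <- scan_times(x)
  cat(sprintf("spectrum set: %d MS1 scans, RT %.2f-%.2f min\n",
              length(x$scans), min(rts), max(rts)))
  invisible(x)
}

#' Scan retention times of a spectrum set
#' @param s a `spectrum_set`.
#' @return numeric vector, minutes.
#' @export
scan_times <- function(s) vapply(s$scans, `[[`, numeric(1), "rt")

#' Construct a chromatogram
#'
#' @param time numeric, minutes, increasing.
#' @param intensity numeric, same length.
#' @param channel label (e.g. `"FLR"` or an XIC target description).
#' @return object of class `chromatogram`.
#' @export
chromatogram <- function(time, intensity, channel = "FLR") {
  stopifnot(length(time) == length(intensity))
  if (is.unsorted(time)) stop("chromatogram time must be increasing")
  structure(list(channel = channel, time = as.numeric(time),
                 intensity = as.numeric(intensity)),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("chromatogram [%s]: %d points, %.2f-%.2f min\n",
              x$channel, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Read intact-run MS1 spectra
#'
#' @param path file path.
#' @param dialect `"mzML"` or `"csv-table"`; default guessed from the file
#'   extension.
#' @param rt_limits optional `c(lo, hi)` minutes; scans outside are kept
#'   but flagged in `metadata$out_of_limits`.
#' @return a [spectrum_set()].
#' @export
read_spectra <- function(path, dialect = NULL, rt_limits = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML"
               else "csv-table"
  dialect <- match.arg(dialect, c("mzML", "csv-table"))
  s <- if (dialect == "mzML") .read_mzml(path) else .read_spectrum_csv(path)
  s$metadata$source <- path
  if (!is.null(rt_limits)) {
    rts <- scan_times(s)
    s$metadata$rt_limits <- rt_limits
    s$metadata$out_of_limits <- which(rts < rt_limits[1] | rts > rt_limits[2])
  }
  s
}

.read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("rt_min", "mz", "intensity")
  if (!all(need %in% names(df)))
    stop("spectrum table must have columns rt_min,mz,intensity")
  scans <- lapply(split(df, df$rt_min), function(d)
    list(rt = d$rt_min[1], mz = d$mz, intensity = d$intensity))
  scans <- scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
  names(scans) <- NULL
  spectrum_set(scans)
}

#' Write spectra in the CSV spectrum-table dialect
#' @param s a `spectrum_set`.
#' @param path output path.
#' @export
write_spectrum_csv <- function(s, path) {
  # scans with no sticks cannot be represented in the table dialect and
  # are dropped; use mzML when empty scans must survive a round trip
  df <- do.call(rbind, lapply(s$scans, function(sc) {
    if (!length(sc$mz)) return(NULL)
    data.frame(rt_min = sc$rt, mz = sc$mz, intensity = sc$intensity)
  }))
  if (is.null(df)) stop("no non-empty scans to write")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an FLR or XIC chromatogram from CSV (`time_min,intensity`)
#' @param path CSV file.
#' @param channel channel label.
#' @return a [chromatogram()].
#' @export
read_chromatogram_csv <- function(path, channel = "FLR") {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "intensity") %in% names(df)))
    stop("chromatogram CSV must have columns time_min,intensity")
  chromatogram(df$time_min, df$intensity, channel = channel)
}

#' Write a chromatogram as CSV
#' @param c a `chromatogram`.
#' @param path output path.
#' @export
write_chromatogram_csv <- function(c, path) {
  utils::write.csv(data.frame(time_min = c$time, intensity = c$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

# ---- minimal mzML support -------------------------------------------------
# Reads MS1 spectra with 64-bit (or 32-bit) float arrays, no compression or
# zlib.  Scan start times are taken from cvParam MS:1000016 honouring the
# unit (minute/second).  Writing emits uncompressed 64-bit little-endian
# arrays, which is sufficient for fixtures and the simulator.

.decode_binary <- function(node, defaults = list()) {
  cv <- xml2::xml_find_all(node, ".//d1:cvParam | .//cvParam")
  acc <- xml2::xml_attr(cv, "accession")
  precision <- if ("MS:1000521" %in% acc) 4L else 8L
  zlib <- "MS:1000574" %in% acc
  b64 <- xml2::xml_text(
    xml2::xml_find_first(node, ".//d1:binary | .//binary"))
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (zlib) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, what = "double", size = precision,
          n = length(raw) %/% precision, endian = "little")
}

.read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  spectra <- xml2::xml_find_all(doc, "//d1:spectrum | //spectrum")
  if (!length(spectra)) stop("no spectra found in ", path)
  scans <- list()
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    cv <- xml2::xml_find_all(sp, "./d1:cvParam | ./cvParam")
    acc <- xml2::xml_attr(cv, "accession")
    lvl <- xml2::xml_attr(cv, "value")[acc == "MS:1000511"]
    if (length(lvl) && lvl != "1") next  # MS1 only
    rt_node <- xml2::xml_find_first(
      sp, ".//d1:cvParam[@accession='MS:1000016'] | .//cvParam[@accession='MS:1000016']")
    if (is.na(rt_node)) stop("scan ", i, ": no scan start time")
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    unit <- xml2::xml_attr(rt_node, "unitName")
    if (!is.na(unit) && grepl("second", unit)) rt <- rt / 60
    arrays <- xml2::xml_find_all(
      sp, ".//d1:binaryDataArray | .//binaryDataArray")
    mz <- intensity <- NULL
    for (arr in arrays) {
      a <- xml2::xml_attr(
        xml2::xml_find_all(arr, "./d1:cvParam | ./cvParam"), "accession")
      if ("MS:1000514" %in% a) mz <- .decode_binary(arr)
      if ("MS:1000515" %in% a) intensity <- .decode_binary(arr)
    }
    if (is.null(mz) || is.null(intensity))
      stop("scan ", i, ": missing m/z or intensity array")
    scans[[length(scans) + 1L]] <- list(rt = rt, mz = mz,
                                        intensity = intensity)
  }
  scans <- scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
  spectrum_set(scans)
}

.encode_binary <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

#' Write a spectrum set as minimal mzML
#'
#' Emits an mzML document with MS1 spectra, uncompressed 64-bit float
#' arrays and scan start times in minutes — enough for interchange with
#' standard readers; no chromatogram list or index is written.
#'
#' @param s a `spectrum_set`.
#' @param path output path.
#' @export
write_mzml <- function(s, path) {
  n <- length(s$scans)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('  <run id="run">')
  w('    <spectrumList count="%d">', n)
  for (i in seq_len(n)) {
    sc <- s$scans[[i]]
    w('      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      i - 1L, i, length(sc$mz))
    w('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>')
    w('        <scanList count="1"><scan>')
    w('          <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitName="minute"/>',
      sc$rt)
    w('        </scan></scanList>')
    w('        <binaryDataArrayList count="2">')
    for (which in c("mz", "int")) {
      vec <- if (which == "mz") sc$mz else sc$intensity
      acc <- if (which == "mz") "MS:1000514" else "MS:1000515"
      nm <- if (which == "mz") "m/z array" else "intensity array"
      b64 <- .encode_binary(vec)
      w('          <binaryDataArray encodedLength="%d">', nchar(b64))
      w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>')
      w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>')
      w('            <cvParam cvRef="MS" accession="%s" name="%s"/>', acc, nm)
      w('            <binary>%s</binary>', b64)
      w('          </binaryDataArray>')
    }
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}
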
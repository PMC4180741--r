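# Detector-frame and auxiliary-image I/O.
#
# Two on-disk dialects are supported natively: grayscale TIFF (8/16/32-bit)
# and EDF (ESRF data format: ASCII header padded to a 512-byte multiple,
# followed by a raw binary block). Header keys that carry the monitor and
# exposure vary by facility, so the accepted key lists are arguments.

.edfTypes <- list(
  UnsignedByte    = list(what = "integer", size = 1L, signed = FALSE),
  UnsignedShort   = list(what = "integer", size = 2L, signed = FALSE),
  UnsignedInteger = list(what = "integer", size = 4L, signed = TRUE),
  UnsignedLong    = list(what = "integer", size = 4L, signed = TRUE),
  SignedInteger   = list(what = "integer", size = 4L, signed = TRUE),
  FloatValue      = list(what = "double",  size = 4L, signed = TRUE),
  DoubleValue     = list(what = "double",  size = 8L, signed = TRUE)
)

.parseEdfHeader <- function(con) {
  # header: "{" ... "}" padded with whitespace to a multiple of 512 bytes
  raw <- readBin(con, "raw", 512L)
  if (length(raw) < 512L || rawToChar(raw[1]) != "{")
    stopIncompleteFile("not an EDF file or truncated header")
  txt <- rawToChar(raw)
  while (!grepl("}", txt, fixed = TRUE)) {
    more <- readBin(con, "raw", 512L)
    if (length(more) < 512L)
      stopIncompleteFile("EDF header not terminated (truncated file)")
    txt <- paste0(txt, rawToChar(more))
  }
  body <- sub("\\}.*$", "", sub("^\\s*\\{", "", txt))
  lines <- strsplit(body, "[;\n]")[[1]]
  lines <- trimws(lines[grepl("=", lines)])
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  kv
}

#' Read an EDF detector image
#'
#' @param path file path.
#' @param monitorKeys,exposureKeys header keys searched (first hit wins) for
#'   the monitor counts and exposure time.
#' @return list with `data` (matrix, rows = detector rows), `header` (named
#'   list), `monitor`, `exposure` (NA when the key is absent).
#' @export
readEDF <- function(path,
                    monitorKeys = c("Monitor", "monitor", "Intensity0",
                                    "mon", "mon1"),
                    exposureKeys = c("ExposureTime", "count_time",
                                     "exposure_time")) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .parseEdfHeader(con)
  for (k in c("Dim_1", "Dim_2", "DataType"))
    if (is.null(hdr[[k]])) stopIncompleteFile(
      sprintf("EDF header lacks required key '%s'", k))
  nc <- as.integer(hdr$Dim_1)   # fast axis = columns
  nr <- as.integer(hdr$Dim_2)
  ti <- .edfTypes[[hdr$DataType]]
  if (is.null(ti))
    stopUnknownFormat(sprintf("unsupported EDF DataType '%s'", hdr$DataType))
  endian <- if (identical(hdr$ByteOrder, "HighByteFirst")) "big" else "little"
  n <- nr * nc
  vals <- readBin(con, ti$what, n = n, size = ti$size,
                  signed = ti$signed, endian = endian)
  if (length(vals) < n)
    stopIncompleteFile(sprintf(
      "EDF data block truncated: expected %d values, read %d",
      n, length(vals)))
  firstKey <- function(keys) {
    for (k in keys) if (!is.null(hdr[[k]])) return(as.numeric(hdr[[k]]))
    NA_real_
  }
  list(data = matrix(as.numeric(vals), nrow = nr, ncol = nc, byrow = TRUE),
       header = hdr,
       monitor = firstKey(monitorKeys),
       exposure = firstKey(exposureKeys))
}

#' Write an EDF detector image
#'
#' Writes `UnsignedShort` for non-negative integer data within 16 bits,
#' `FloatValue` otherwise. Extra header entries (e.g. `Monitor`) are passed
#' via `header`.
#'
#' @param data numeric matrix (rows = detector rows).
#' @param path output file.
#' @param header named list of additional header key/value pairs.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(data, path, header = list()) {
  data <- as.matrix(data)
  isInt <- all(is.finite(data)) && all(data >= 0) && all(data < 65536) &&
    all(data == round(data))
  dtype <- if (isInt) "UnsignedShort" else "FloatValue"
  size <- if (isInt) 2L else 4L
  kv <- c(list(EDF_DataBlockID = "1.Image.Psd", Dim_1 = ncol(data),
               Dim_2 = nrow(data), DataType = dtype,
               ByteOrder = "LowByteFirst",
               Size = size * length(data), Image = 1),
          header)
  body <- paste0(vapply(names(kv), function(k)
    sprintf("%s = %s ;\n", k, as.character(kv[[k]])), character(1)),
    collapse = "")
  txt <- paste0("{\n", body, "}\n")
  pad <- 512L * ceiling(nchar(txt, type = "bytes") / 512L) -
    nchar(txt, type = "bytes")
  txt <- paste0(substr(txt, 1, nchar(txt) - 2),
                strrep(" ", pad), "}\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL)
  vals <- as.vector(t(data))   # row-major: fast axis = columns
  if (isInt) {
    writeBin(as.integer(vals), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Write a 16-bit grayscale TIFF of integer counts
#'
#' Counts must lie in [0, 65535]; the round trip through [readFrame()] is
#' bit-exact.
#' @param data non-negative integer matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFrameTIFF <- function(data, path) {
  data <- as.matrix(data)
  if (any(data < 0) || any(data > 65535) || any(data != round(data)))
    stop("TIFF output requires integer counts in [0, 65535]; use writeEDF")
  tiff::writeTIFF(data / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a detector frame
#'
#' Reads a grayscale TIFF or EDF image into a [Frame-class]. Integer
#' intensities are preserved bit-exactly. Header metadata (monitor counts,
#' exposure) is captured when present; missing values default to 1.0 with a
#' logged notice. Truncated files raise an "incomplete file" error
#' (condition class `saxspipe_incomplete_file`) rather than a silent
#' partial read — the online watcher relies on this.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tiff"` or `"edf"`.
#' @param scanPos optional named numeric of motor positions to attach.
#' @param monitorKeys,exposureKeys EDF header keys accepted for monitor /
#'   exposure (facility-dependent).
#' @return A [Frame-class] with Poisson `sigma = sqrt(max(counts, 1))`.
#' @export
readFrame <- function(path, format = c("auto", "tiff", "edf"),
                      scanPos = numeric(),
                      monitorKeys = c("Monitor", "monitor", "Intensity0",
                                      "mon", "mon1"),
                      exposureKeys = c("ExposureTime", "count_time",
                                       "exposure_time")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tif = , tiff = "tiff", edf = "edf",
                     stopUnknownFormat(sprintf(
                       "unknown image format '.%s' (%s)", ext, path)))
  }
  monitor <- NA_real_; exposure <- NA_real_
  if (format == "tiff") {
    img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) stopIncompleteFile(sprintf(
                      "unreadable or incomplete TIFF '%s': %s",
                      path, conditionMessage(e))))
    if (length(dim(img)) == 3) img <- img[, , 1]   # gray stored as 1 channel
    data <- matrix(as.numeric(img), nrow(img), ncol(img))
  } else {
    e <- readEDF(path, monitorKeys = monitorKeys,
                 exposureKeys = exposureKeys)
    data <- e$data; monitor <- e$monitor; exposure <- e$exposure
  }
  if (is.na(monitor)) {
    logMsg("debug", "no monitor in '%s'; defaulting to 1.0", basename(path))
    monitor <- 1
  }
  if (is.na(exposure)) exposure <- 1
  detectorFrame(data, monitor = monitor, exposure = exposure,
                scanPos = scanPos, sourcePath = path)
}

#' Read a mask image
#'
#' Nonzero pixels are excluded. Non-binary images are coerced
#' (nonzero -> excluded) with a logged warning.
#' @param path TIFF or EDF image of 0/nonzero values.
#' @return logical matrix, `TRUE` = excluded.
#' @export
readMask <- function(path) {
  fr <- readFrame(path)
  d <- frameData(fr)
  if (!all(d %in% c(0, 1))) {
    logMsg("warning", "mask '%s' is not binary; coercing nonzero -> excluded",
           basename(path))
  }
  d != 0
}

.fmtCell <- function(v) {
  if (is.null(v) || length(v) != 1 || (is.numeric(v) && !is.finite(v)))
    return(if (is.numeric(v) && length(v) == 1 && is.nan(v)) "NaN" else
           if (is.null(v) || is.na(v)) "NA" else format(v))
  if (is.numeric(v)) sprintf("%.12g", v) else as.character(v)
}

#' Write a Curve as tab-separated text
#' @param curve a [Curve-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path) {
  df <- as.data.frame(curve)
  cells <- vapply(seq_len(nrow(df)), function(i)
    paste(vapply(as.list(df[i, ]), .fmtCell, character(1)), collapse = "\t"),
    character(1))
  writeLines(c(paste(colnames(df), collapse = "\t"), cells), path)
  invisible(path)
}

#' Export a DataTable as spreadsheet-style text
#'
#' Writes one tab-separated text file with a header row of column names.
#' Scalar, text and image-ref cells are inlined (scalars at 12 significant
#' digits, so the round trip is loss-free at printed precision); curve cells
#' are written to one sidecar file per row and referenced by relative path.
#'
#' @param table a non-empty [DataTable-class].
#' @param path output file (sidecars are placed next to it).
#' @return `path`, invisibly.
#' @export
writeTable <- function(table, path) {
  stopifnot(is(table, "DataTable"))
  if (length(table@rows) == 0)
    stop("refusing to write an empty table")
  dir <- dirname(path)
  base <- tools::file_path_sans_ext(basename(path))
  cols <- names(table@colTypes)
  lines <- paste(cols, collapse = "\t")
  for (i in seq_along(table@rows)) {
    row <- table@rows[[i]]
    cells <- vapply(cols, function(nm) {
      v <- row[[nm]]
      if (table@colTypes[[nm]] == "curve") {
        if (is(v, "Curve")) {
          side <- sprintf("%s_%s_row%04d.dat", base,
                          gsub("[^A-Za-z0-9]+", "_", nm), i)
          writeCurve(v, file.path(dir, side))
          side
        } else "NA"
      } else .fmtCell(v)
    }, character(1))
    lines <- c(lines, paste(cells, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a scan-grid map
#'
#' Writes a value field on a scan grid in two text forms: an
#' `(x, y, value)` triplet list and a dense-grid matrix (rows = y, columns
#' = x, tab-separated, NaN for missing points).
#'
#' @param xs,ys grid coordinate vectors (ascending).
#' @param values matrix `length(ys) x length(xs)`.
#' @param path base path; writes `<path>.xyz` and `<path>.grid`.
#' @return character(2) of written paths, invisibly.
#' @export
writeMapGrid <- function(xs, ys, values, path) {
  stopifnot(nrow(values) == length(ys), ncol(values) == length(xs))
  tripletPath <- paste0(path, ".xyz")
  gridPath <- paste0(path, ".grid")
  trip <- c("x\ty\tvalue",
            unlist(lapply(seq_along(ys), function(i)
              vapply(seq_along(xs), function(j)
                sprintf("%.12g\t%.12g\t%s", xs[j], ys[i],
                        .fmtCell(values[i, j])), character(1)))))
  writeLines(trip, tripletPath)
  writeLines(apply(values, 1, function(r)
    paste(vapply(r, .fmtCell, character(1)), collapse = "\t")), gridPath)
  invisible(c(tripletPath, gridPath))
}
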
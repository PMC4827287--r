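# File formats: trace CSV, records CSV, image and metrics I/O. Dialects are
# strict (exact headers, locale-independent "." decimals) and parse errors
# name the offending line.

trace_cols <- c("time_s", "force_N", "displacement_um")
record_cols <- c("specimen_id", "group", "day", "modulus_18pct_MPa",
                 "coverage_pct", "mean_intensity", "dna_ng", "protein_ug",
                 "thickness_um", "diameter_mm")

read_table_strict <- function(path, required, numeric_cols) {
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    strip.white = TRUE),
    error = function(e)
      stop_quant("%s: malformed CSV at line 1 (%s)", path,
                 conditionMessage(e), class = "parse_error"))
  if (!all(required %in% names(raw)))
    stop_quant("%s: line 1: missing column(s) %s", path,
               paste(setdiff(required, names(raw)), collapse = ", "),
               class = "parse_error")
  if (nrow(raw) == 0L)
    stop_quant("%s: line 1: no data rows", path, class = "parse_error")
  for (col in intersect(numeric_cols, names(raw))) {
    txt <- raw[[col]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & txt != "" & txt != "NA" & is.na(num))
    if (length(bad) > 0L)
      stop_quant("%s: line %d: cannot parse '%s' in column %s", path,
                 bad[1L] + 1L, txt[bad[1L]], col, class = "parse_error")
    raw[[col]] <- num
  }
  raw
}

#' Read a cyclic compression trace from CSV
#'
#' Expects the columns `time_s, force_N, displacement_um` (header required,
#' `.` decimal separator, one specimen per file). Instrument sign
#' conventions are normalised to positive-compression: with
#' `force_sign = "auto"` the force is flipped when its largest excursion is
#' negative (Instron exports compression as negative), and a mostly
#' negative displacement channel is flipped likewise.
#'
#' @param path CSV path.
#' @param start_gap_um Platen gap at `displacement_um = 0` (needed for
#'   thickness detection).
#' @param force_sign `"auto"`, `"positive"` (already
#'   positive-in-compression) or `"negative"` (flip).
#' @param specimen_id Label; defaults to the file name.
#' @return A [cyclic_trace()].
#' @export
read_trace <- function(path, start_gap_um = NA_real_,
                       force_sign = c("auto", "positive", "negative"),
                       specimen_id = NULL) {
  force_sign <- match.arg(force_sign)
  tab <- read_table_strict(path, trace_cols, trace_cols)
  f <- tab$force_N
  d <- tab$displacement_um
  flip_f <- switch(force_sign,
                   positive = FALSE,
                   negative = TRUE,
                   auto = abs(min(f)) > abs(max(f)))
  if (flip_f) f <- -f
  if (stats::median(d) < 0) d <- -d
  cyclic_trace(tab$time_s, f, d,
               specimen_id = specimen_id %||%
                 tools::file_path_sans_ext(basename(path)),
               start_gap_um = start_gap_um)
}

# format numeric columns with 17 significant digits so write -> read round
# trips reproduce doubles bit-exactly, independent of locale
full_precision <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      txt <- sprintf("%.17g", df[[col]])
      txt[is.na(df[[col]])] <- NA
      df[[col]] <- txt
    }
  }
  df
}

#' Write a cyclic trace to CSV
#'
#' Numeric fields are written at full precision, so a write/read round trip
#' is lossless.
#'
#' @param trace A [cyclic_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cyclic_trace"))
  utils::write.csv(full_precision(trace$data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read construct records from CSV
#'
#' Dialect: `specimen_id, group, day, modulus_18pct_MPa, coverage_pct,
#' mean_intensity, dna_ng, protein_ug, thickness_um, diameter_mm`; missing
#' values blank. Extra columns are preserved.
#'
#' @param path CSV path.
#' @return Data frame of records.
#' @export
read_records <- function(path) {
  read_table_strict(path, c("specimen_id", "group", "day"),
                    setdiff(record_cols, c("specimen_id", "group")))
}

#' Write construct records to CSV
#'
#' @param records Data frame of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(full_precision(records), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write metrics or results to JSON
#'
#' Numbers are written at full precision (no rounding), scalars unboxed.
#'
#' @param x A result object or list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  if (!is.null(attr(x, "class"))) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path Image path.
#' @return Numeric array `H x W x 3` with values in `[0, 255]` (grayscale
#'   images are returned as `H x W`); any alpha channel is dropped.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop_quant("unsupported image format '%s'", ext,
                           class = "invalid_image"))
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L)
    img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an image as 8-bit PNG or TIFF
#'
#' @param image Array with values in `[0, 255]`.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
         stop_quant("unsupported image format '%s'", ext,
                    class = "invalid_image"))
  invisible(path)
}
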
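# Reading radiographs (DICOM / PNG / TIFF), landmark files and writing the
# measurement and comparison tables.

#' Read a radiograph from DICOM, PNG or TIFF
#'
#' DICOM files provide their own pixel spacing (the calibrated
#' `PixelSpacing` attribute is preferred over `ImagerPixelSpacing`); PNG and
#' TIFF carry no physical calibration, so `spacing_override` is required for
#' them.  DICOM `MONOCHROME1` images (inverted grey scale) are re-inverted
#' on read so that bone is always bright.  Anisotropic DICOM spacing is
#' accepted only if the two values differ by less than 1%.
#'
#' The reader supports uncompressed little-endian DICOM transfer syntaxes
#' (implicit and explicit VR) with 8- or 16-bit grayscale pixel data.
#'
#' @param path Path to a `.dcm`, `.png`, `.tif`/`.tiff` file (DICOM is also
#'   recognised by its magic bytes regardless of extension).
#' @param spacing_override Pixel spacing in millimetres; used for PNG/TIFF
#'   and as a fallback when a DICOM file carries no spacing attribute.
#' @return A [radiograph()].
#' @export
read_radiograph <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  is_dicom <- FALSE
  sz <- file.info(path)$size
  if (sz >= 132) {
    head <- readBin(path, "raw", 132L)
    if (rawToChar(head[129:132]) == "DICM") is_dicom <- TRUE
  }
  if (is_dicom || ext %in% c("dcm", "dicom")) {
    return(read_dicom_radiograph(path, spacing_override))
  }
  if (ext == "png") {
    px <- png::readPNG(path)
    bd <- png_bit_depth(path)
    px <- px * (2^bd - 1)  # undo readPNG's [0, 1] normalisation
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    storage.mode(px) <- "double"
  } else {
    stop(sprintf("unsupported image format: %s", path))
  }
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] > 1L)
      stop("colour images are not supported; provide a grayscale radiograph")
    px <- px[, , 1]
  }
  if (is.null(spacing_override))
    stop("pixel spacing unavailable for PNG/TIFF input; supply spacing_override (--pixel-spacing)")
  radiograph(px, spacing_override,
             case_id = tools::file_path_sans_ext(basename(path)))
}

# bit depth from the PNG IHDR chunk (byte 25 of the file)
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", 26L)
  as.integer(hdr[25])
}

# ---- minimal DICOM reader (uncompressed little-endian) ----------------------

dicom_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
dicom_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# parse a contiguous run of data elements; returns named list keyed
# "gggg,eeee" with raw values, plus bytes consumed
parse_dicom_elements <- function(raw, pos, end, explicit_vr, stop_after_group = NULL) {
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  out <- list()
  while (pos + 7 <= end) {
    group <- dicom_u16(raw, pos)
    elem <- dicom_u16(raw, pos + 2L)
    if (!is.null(stop_after_group) && group > stop_after_group) break
    pos <- pos + 4L
    vr <- NULL
    if (explicit_vr) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% long_vrs) {
        len <- dicom_u32(raw, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- dicom_u16(raw, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      len <- dicom_u32(raw, pos)
      pos <- pos + 4L
    }
    key <- sprintf("%04x,%04x", group, elem)
    if (len == 4294967295) {  # undefined length (sequence): skip items
      pos <- skip_dicom_undefined(raw, pos, end)
      next
    }
    if (identical(vr, "SQ")) { pos <- pos + len; next }
    if (len > 0) out[[key]] <- raw[pos:(pos + len - 1L)]
    else out[[key]] <- raw(0)
    pos <- pos + len
    if (key == "7fe0,0010") break
  }
  list(elements = out, pos = pos)
}

# skip an undefined-length sequence: scan for the sequence delimitation item
skip_dicom_undefined <- function(raw, pos, end) {
  depth <- 1L
  while (pos + 7 <= end && depth > 0L) {
    group <- dicom_u16(raw, pos)
    elem <- dicom_u16(raw, pos + 2L)
    len <- dicom_u32(raw, pos + 4L)
    pos <- pos + 8L
    if (group == 0xfffe && elem == 0xe0dd) { depth <- depth - 1L; next }
    if (group == 0xfffe && elem == 0xe000) {
      if (len == 4294967295) next else pos <- pos + len
      next
    }
    if (len == 4294967295) depth <- depth + 1L else pos <- pos + len
  }
  pos
}

dicom_string <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  v <- el[[key]]
  trimws(rawToChar(v[v != as.raw(0)]))
}
dicom_us <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  dicom_u16(el[[key]], 1L)
}

read_dicom_radiograph <- function(path, spacing_override = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  n <- length(raw)
  if (n < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("not a DICOM part-10 file: %s", path))
  # file meta group (0002) is always explicit VR little endian
  meta <- parse_dicom_elements(raw, 133L, n, explicit_vr = TRUE,
                               stop_after_group = 0x0002)
  ts <- dicom_string(meta$elements, "0002,0010")
  if (is.null(ts)) ts <- "1.2.840.10008.1.2.1"
  explicit <- ts == "1.2.840.10008.1.2.1"
  if (!explicit && ts != "1.2.840.10008.1.2")
    stop(sprintf("unsupported DICOM transfer syntax: %s (only uncompressed little endian)", ts))
  ds <- parse_dicom_elements(raw, meta$pos, n, explicit_vr = explicit)$elements

  rows <- dicom_us(ds, "0028,0010"); cols <- dicom_us(ds, "0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("DICOM file lacks Rows/Columns attributes")
  spp <- dicom_us(ds, "0028,0002")
  if (!is.null(spp) && spp != 1L)
    stop("colour (multi-sample) DICOM images are not supported")
  bits <- dicom_us(ds, "0028,0100")
  if (is.null(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L))
    stop(sprintf("unsupported BitsAllocated: %d", bits))
  signed <- identical(dicom_us(ds, "0028,0103"), 1L)
  photometric <- dicom_string(ds, "0028,0004")
  pd <- ds[["7fe0,0010"]]
  if (is.null(pd)) stop("DICOM file has no pixel data")
  npix <- as.numeric(rows) * as.numeric(cols)
  vals <- readBin(pd, "integer", n = npix, size = bits / 8L,
                  signed = if (bits == 8L) FALSE else signed,
                  endian = "little")
  if (bits == 16L && !signed) vals <- ifelse(vals < 0, vals + 65536, vals)
  if (length(vals) < npix) stop("DICOM pixel data truncated")
  px <- matrix(as.numeric(vals[seq_len(npix)]), nrow = rows, ncol = cols,
               byrow = TRUE)
  slope <- suppressWarnings(as.numeric(dicom_string(ds, "0028,1053")))
  intercept <- suppressWarnings(as.numeric(dicom_string(ds, "0028,1052")))
  if (length(slope) == 1 && is.finite(slope) &&
      length(intercept) == 1 && is.finite(intercept) &&
      (slope != 1 || intercept != 0)) {
    px <- px * slope + intercept
  }
  if (identical(photometric, "MONOCHROME1")) px <- max(px) - px
  if (min(px) < 0) px <- px - min(px)

  spacing <- parse_dicom_spacing(dicom_string(ds, "0028,0030"))  # calibrated
  if (is.null(spacing))
    spacing <- parse_dicom_spacing(dicom_string(ds, "0018,1164"))  # detector
  if (is.null(spacing)) spacing <- spacing_override
  if (is.null(spacing))
    stop("pixel spacing unavailable in DICOM header; supply spacing_override (--pixel-spacing)")
  radiograph(px, spacing,
             case_id = tools::file_path_sans_ext(basename(path)),
             meta = list(transfer_syntax = ts,
                         photometric = photometric,
                         bits_allocated = bits))
}

# "row\\col" decimal string -> scalar spacing; >1% anisotropy is an error
parse_dicom_spacing <- function(s) {
  if (is.null(s) || !nzchar(s)) return(NULL)
  v <- suppressWarnings(as.numeric(strsplit(s, "\\\\")[[1]]))
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NULL)
  if (length(v) >= 2 && abs(v[1] - v[2]) / mean(v[1:2]) >= 0.01)
    stop(sprintf("anisotropic pixel spacing (%g x %g mm) differs by >= 1%%; isotropy is assumed",
                 v[1], v[2]))
  mean(v[seq_len(min(2, length(v)))])
}

# ---- landmark and table IO --------------------------------------------------

#' Read a landmark file
#'
#' Reads manually placed landmarks for one or more cases from a CSV or JSON
#' file with fields `case_id`, `lunate_row`, `lunate_col`, `styloid_row`,
#' `styloid_col`, `finger_row`, `finger_col` (JSON: an array of objects with
#' those keys).
#'
#' @param path Path to the landmark file.
#' @return Named list mapping `case_id` to [landmark_set()] objects.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (tolower(tools::file_ext(path)) == "json") {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  need <- c("case_id", "lunate_row", "lunate_col", "styloid_row",
            "styloid_col", "finger_row", "finger_col")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop(sprintf("landmark file is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(df$case_id))
    stop(sprintf("duplicate case_id in landmark file: %s",
                 paste(unique(df$case_id[duplicated(df$case_id)]),
                       collapse = ", ")))
  out <- lapply(seq_len(nrow(df)), function(i) {
    landmark_set(
      lunate = c(df$lunate_row[i], df$lunate_col[i]),
      styloid = c(df$styloid_row[i], df$styloid_col[i]),
      finger = c(df$finger_row[i], df$finger_col[i]))
  })
  names(out) <- as.character(df$case_id)
  out
}

#' Write and read a measurement table
#'
#' The measurement table has one row per case with columns `case_id`,
#' `group`, then the 32 measurement names of [measurement_names()] in
#' canonical order.  Values round-trip through CSV at full double precision.
#'
#' @param table Data frame with columns `case_id`, `group` and the 32
#'   measurements (a `study_table` as produced by [run_study()], or any data
#'   frame with those columns).
#' @param path Output CSV path.
#' @return `write_measurements` returns `path` invisibly;
#'   `read_measurements` returns the table as a data frame.
#' @export
write_measurements <- function(table, path) {
  stopifnot(is.data.frame(table))
  need <- c("case_id", "group", measurement_names())
  missing <- setdiff(need, names(table))
  if (length(missing) > 0)
    stop(sprintf("measurement table is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  write.csv(table[, need, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("case_id", "group", measurement_names())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop(sprintf("measurement file is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  df
}
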
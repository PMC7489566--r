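# Build minimal DICOM part-10 byte streams in code, so the reader can be
# tested without any binary fixture on disk.

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dcm_pad_even <- function(v, pad = as.raw(0x20)) {
  if (length(v) %% 2L == 1L) c(v, pad) else v
}

# one data element, explicit VR little endian
dcm_elem <- function(group, elem, vr, value) {
  value <- dcm_pad_even(value, pad = if (vr == "UI") as.raw(0) else as.raw(0x20))
  hdr <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(hdr, as.raw(c(0, 0)), u32le(length(value)), value)
  } else {
    c(hdr, u16le(length(value)), value)
  }
}

dcm_str <- function(s) charToRaw(s)
dcm_us <- function(x) u16le(x)

# assemble a complete grayscale DICOM file; pixels is an integer matrix
# (rows x cols), written as 16-bit unsigned little endian, row-major
write_test_dicom <- function(path, pixels, spacing = "0.143\\0.143",
                             photometric = "MONOCHROME2",
                             spacing_tag = c(0x0028, 0x0030),
                             omit_spacing = FALSE) {
  stopifnot(is.matrix(pixels))
  pixel_raw <- writeBin(as.integer(t(pixels)), raw(), size = 2,
                        endian = "little")
  body <- c(
    dcm_elem(0x0008, 0x0060, "CS", dcm_str("CR")),
    dcm_elem(0x0028, 0x0002, "US", dcm_us(1)),
    dcm_elem(0x0028, 0x0004, "CS", dcm_str(photometric)),
    dcm_elem(0x0028, 0x0010, "US", dcm_us(nrow(pixels))),
    dcm_elem(0x0028, 0x0011, "US", dcm_us(ncol(pixels))),
    if (!omit_spacing)
      dcm_elem(spacing_tag[1], spacing_tag[2], "DS", dcm_str(spacing)),
    dcm_elem(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_elem(0x0028, 0x0101, "US", dcm_us(16)),
    dcm_elem(0x0028, 0x0102, "US", dcm_us(15)),
    dcm_elem(0x0028, 0x0103, "US", dcm_us(0)),
    dcm_elem(0x7fe0, 0x0010, "OW", pixel_raw))
  meta <- dcm_elem(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
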
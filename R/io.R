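#' Read a grayscale image file
#'
#' Supports PNG and TIFF (8- or 16-bit) and uncompressed single-frame
#' monochrome DICOM (explicit VR, little endian; see [read_dicom()]).
#' Multi-channel input is converted to a single channel by averaging the
#' channels (luminance average), with a warning.
#'
#' @param path image file; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`, `.dcm`/`.dicom`).
#' @return a [gray_image]; `n_levels` reflects the stored bit depth.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    img_from_array(a, path)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
    img_from_array(a, path)
  } else if (ext %in% c("dcm", "dicom")) {
    read_dicom(path)
  } else {
    stop("unsupported image format for: ", path)
  }
}

# readPNG/readTIFF return values in [0,1]; recover integer levels from
# the finest step present (8- vs 16-bit)
img_from_array <- function(a, path) {
  if (length(dim(a)) == 3L) {
    warning("multi-channel image ", path,
            ": converting to grayscale by channel average")
    a <- apply(a, c(1L, 2L), mean)
  }
  depth <- if (any(abs(a * 255 - round(a * 255)) > 1e-6)) 65535L else 255L
  gray_image(matrix(as.integer(round(a * depth)), nrow(a), ncol(a)),
             n_levels = depth + 1L)
}

#' Minimal DICOM reader (uncompressed monochrome)
#'
#' Parses single-frame grayscale DICOM files stored as explicit-VR
#' little-endian with native (uncompressed) pixel data — the layout used
#' by common mammography archives once decompressed.  Only the elements
#' needed to recover the pixel matrix are interpreted (rows, columns,
#' bits allocated, pixel representation, pixel data).
#'
#' @param path DICOM file path.
#' @return a [gray_image] with `n_levels = 2^bits_allocated`.
#' @export
read_dicom <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140L ||
      rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) u16(p) + 65536 * u16(p + 2L)
  rows <- cols <- bits <- signed <- NA_integer_
  pixdata <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      hdr <- 12L
    } else {
      len <- u16(pos + 6L)
      hdr <- 8L
    }
    body <- pos + hdr
    if (group == 0x0028) {
      if (elem == 0x0010) rows <- u16(body)
      if (elem == 0x0011) cols <- u16(body)
      if (elem == 0x0100) bits <- u16(body)
      if (elem == 0x0103) signed <- u16(body)
    }
    if (group == 0x7FE0 && elem == 0x0010) {
      pixdata <- raw[body:(body + len - 1L)]
      break
    }
    pos <- body + len
  }
  if (is.null(pixdata) || anyNA(c(rows, cols, bits)))
    stop("incomplete DICOM pixel metadata in: ", path)
  if (!bits %in% c(8L, 16L)) stop("unsupported bits allocated: ", bits)
  if (identical(signed, 1L)) stop("signed pixel data not supported")
  vals <- if (bits == 8L) as.integer(pixdata)
          else readBin(pixdata, "integer", n = rows * cols, size = 2L,
                       signed = FALSE, endian = "little")
  # DICOM pixel data is row-major (top row first)
  gray_image(matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
             n_levels = 2L^bits)
}

#' Minimal DICOM writer (fixture support)
#'
#' Writes an uncompressed explicit-VR little-endian monochrome DICOM
#' file containing just the elements [read_dicom()] consumes.  Intended
#' for building small paired test fixtures in code, not for clinical
#' interchange.
#'
#' @param image a [gray_image] with 256 or 65536 levels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(image, path) {
  image <- as_gray_image(image)
  bits <- if (image$n_levels <= 256L) 8L else 16L
  px <- t(image$pixels)            # row-major order on disk
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeChar("DICM", con, eos = NULL)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  elem_us <- function(group, elem, value) {
    w16(c(group, elem)); writeChar("US", con, eos = NULL); w16(2L)
    w16(value)
  }
  elem_us(0x0028, 0x0010, nrow(image$pixels))
  elem_us(0x0028, 0x0011, ncol(image$pixels))
  elem_us(0x0028, 0x0100, bits)
  elem_us(0x0028, 0x0103, 0L)      # unsigned
  n <- length(px)
  w16(c(0x7FE0, 0x0010)); writeChar("OW", con, eos = NULL); w16(0L)
  writeBin(as.integer(n * bits / 8L), con, size = 4L, endian = "little")
  if (bits == 8L) {
    writeBin(as.raw(as.vector(px)), con)
  } else {
    writeBin(as.integer(px), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Write a gray image as PNG
#'
#' @param image a [gray_image] with up to 65536 levels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  image <- as_gray_image(image)
  depth <- if (image$n_levels <= 256L) 255 else 65535
  png::writePNG(image$pixels / depth, path)
  invisible(path)
}
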
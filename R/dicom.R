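# Minimal DICOM support: single-frame grayscale, uncompressed, little
# endian (explicit or implicit VR).  No installed R package reads DICOM in
# this package's dependency footprint, and only this narrow profile is
# needed to ingest radiograph exports, so the parser is written here.

dicom_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

read_dicom_elements <- function(con, explicit) {
  elems <- list()
  repeat {
    hdr <- readBin(con, "raw", 4L)
    if (length(hdr) < 4L) break
    group <- readBin(hdr[1:2], "integer", size = 2, endian = "little", signed = FALSE)
    elem <- readBin(hdr[3:4], "integer", size = 2, endian = "little", signed = FALSE)
    if (explicit) {
      vr <- rawToChar(readBin(con, "raw", 2L))
      if (vr %in% dicom_long_vrs) {
        readBin(con, "raw", 2L)  # reserved
        len <- readBin(con, "integer", size = 4, endian = "little")
      } else {
        len <- readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
      }
    } else {
      vr <- "UN"
      len <- readBin(con, "integer", size = 4, endian = "little")
    }
    if (len < 0) stop("undefined-length DICOM element: unsupported", call. = FALSE)
    val <- readBin(con, "raw", len)
    key <- sprintf("%04X%04X", group, elem)
    elems[[key]] <- list(vr = vr, value = val)
    if (key == "7FE00010") break
    if (group >= 0x7FE0 && key != "7FE00010") break
  }
  elems
}

dicom_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

dicom_us <- function(el, default = NULL) {
  if (is.null(el)) return(default)
  readBin(el$value, "integer", size = 2, endian = "little", signed = FALSE)
}

dicom_num <- function(el, default = 0) {
  if (is.null(el)) return(default)
  v <- suppressWarnings(as.numeric(dicom_str(el)))
  if (is.na(v)) default else v
}

#' Read a DICOM radiograph, windowed and resized as 8-bit
#'
#' Supports single-frame grayscale DICOM with little-endian transfer syntax
#' (explicit or implicit VR), 8- or 16-bit unsigned pixels.  Rescale slope
#' and intercept are applied, MONOCHROME1 data are inverted, the result is
#' min-max windowed to 8-bit and bilinearly resized to `size` x `size`.
#'
#' @param path DICOM file path.
#' @param size output side length in pixels (default 512).
#' @return a `radiograph` (8-bit, `size` x `size`).
#' @export
read_dicom_as_png <- function(path, size = 512L) {
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, "raw", 132L)
  if (length(pre) == 132L && rawToChar(pre[129:132]) == "DICM") {
    meta <- read_meta_group(con)
    ts <- meta$transfer_syntax
  } else {
    close(con); con <- file(path, "rb")
    ts <- "1.2.840.10008.1.2.1"
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
  )
  elems <- read_dicom_elements(con, explicit)
  frames <- dicom_num(elems[["00280008"]], 1)
  samples <- dicom_us(elems[["00280002"]], 1L)
  if (frames > 1) stop("multi-frame DICOM: unsupported", call. = FALSE)
  if (samples != 1L) stop("color DICOM: unsupported", call. = FALSE)
  rows <- dicom_us(elems[["00280010"]])
  cols <- dicom_us(elems[["00280011"]])
  bits <- dicom_us(elems[["00280100"]], 16L)
  pixrep <- dicom_us(elems[["00280103"]], 0L)
  photometric <- dicom_str(elems[["00280004"]])
  if (is.null(photometric)) photometric <- "MONOCHROME2"
  slope <- dicom_num(elems[["00281053"]], 1)
  intercept <- dicom_num(elems[["00281052"]], 0)
  px <- elems[["7FE00010"]]
  if (is.null(rows) || is.null(cols) || is.null(px)) {
    stop("DICOM file lacks image dimensions or pixel data", call. = FALSE)
  }
  if (bits == 8L) {
    v <- as.integer(px$value[seq_len(rows * cols)])
  } else {
    v <- readBin(px$value, "integer", n = rows * cols, size = 2,
                 endian = "little", signed = pixrep == 1L)
    if (pixrep == 0L) v <- ifelse(v < 0, v + 65536, v)
  }
  m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  m <- m * slope + intercept
  if (startsWith(photometric, "MONOCHROME1")) m <- max(m) - m
  rng <- range(m)
  m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  out <- resize_bilinear(m, size, size)
  radiograph(round(clip01(out) * 255), bit_depth = 8L,
             source_id = basename(path))
}

read_meta_group <- function(con) {
  # File meta group is always explicit VR little endian.  Read its group
  # length, then the group body, and pull the transfer syntax out of it.
  hdr <- readBin(con, "raw", 8L)
  len0 <- readBin(hdr[7:8], "integer", size = 2, endian = "little", signed = FALSE)
  body_len <- readBin(readBin(con, "raw", len0), "integer", size = 4,
                      endian = "little")
  body <- readBin(con, "raw", body_len)
  bc <- rawConnection(body)
  on.exit(close(bc))
  elems <- read_dicom_elements(bc, explicit = TRUE)
  list(transfer_syntax = dicom_str(elems[["00020010"]]))
}

# Serialize a minimal explicit-VR little-endian DICOM file.  Used to build
# synthetic fixtures in tests and examples; not a general-purpose writer.
write_dicom_stub <- function(path, pixels, bits = 16L,
                             photometric = "MONOCHROME2",
                             slope = 1, intercept = 0) {
  pad_even <- function(s) if (nchar(s) %% 2L) paste0(s, " ") else s
  con <- file(path, "wb")
  on.exit(close(con))
  elem <- function(group, el, vr, value_raw) {
    writeBin(writeBin(as.integer(c(group, el)), raw(), size = 2,
                      endian = "little"), con)
    writeChar(vr, con, eos = NULL)
    if (vr %in% dicom_long_vrs) {
      writeBin(as.raw(c(0, 0)), con)
      writeBin(length(value_raw), con, size = 4, endian = "little")
    } else {
      writeBin(length(value_raw), con, size = 2, endian = "little")
    }
    writeBin(value_raw, con)
  }
  str_raw <- function(s) charToRaw(pad_even(s))
  us_raw <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  writeBin(raw(128L), con)
  writeChar("DICM", con, eos = NULL)
  ts <- "1.2.840.10008.1.2.1"
  # meta group: group length element then transfer syntax
  ts_raw <- str_raw(ts)
  meta_len <- 8L + length(ts_raw)
  elem(0x0002, 0x0000, "UL", writeBin(meta_len, raw(), size = 4, endian = "little"))
  elem(0x0002, 0x0010, "UI", ts_raw)
  elem(0x0028, 0x0002, "US", us_raw(1L))
  elem(0x0028, 0x0004, "CS", str_raw(photometric))
  elem(0x0028, 0x0008, "IS", str_raw("1"))
  elem(0x0028, 0x0010, "US", us_raw(nrow(pixels)))
  elem(0x0028, 0x0011, "US", us_raw(ncol(pixels)))
  elem(0x0028, 0x0100, "US", us_raw(bits))
  elem(0x0028, 0x0103, "US", us_raw(0L))
  elem(0x0028, 0x1052, "DS", str_raw(format(intercept)))
  elem(0x0028, 0x1053, "DS", str_raw(format(slope)))
  v <- as.integer(round(t(pixels)))   # row-major pixel order
  px <- if (bits == 8L) as.raw(v) else
    writeBin(v, raw(), size = 2, endian = "little")
  elem(0x7FE0, 0x0010, "OW", px)
  invisible(path)
}
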
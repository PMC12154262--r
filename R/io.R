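## Image and metadata I/O: 16-bit PNG + CSV as the reference fixture format,
## with a thin DICOM adapter (explicit VR little endian, monochrome) carrying
## the PixelSpacing tag.

## --- PNG helpers (matrices are [row, col]; EBImage images are x,y) ---------

## CRC-32 (polynomial 0xEDB88320), needed by the 16-bit PNG writer below
crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1L), -306674912L)   # 0xEDB88320
    else bitwShiftR(c, 1L)
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  v <- as.integer(bytes)
  for (b in v)
    crc <- bitwXor(crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  bitwXor(crc, -1L)
}

int_be <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(bitwShiftR(x, 24L), 255L), bitwAnd(bitwShiftR(x, 16L), 255L),
           bitwAnd(bitwShiftR(x, 8L), 255L), bitwAnd(x, 255L)))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_be(length(data)), body, int_be(crc32(body)))
}

## Writes a 16-bit grayscale PNG. The installed readers (png, EBImage) read
## 16-bit PNGs losslessly but only write 8 bits per sample, which would
## truncate CT dynamic range, so the encoder is implemented here: IHDR
## (bit depth 16, grayscale), one zlib-compressed IDAT with filter-0
## scanlines, IEND.
write_png16 <- function(mat, path) {
  v <- as.integer(round(pmin(pmax(mat, 0), 1) * 65535))
  h <- nrow(mat); w <- ncol(mat)
  vv <- matrix(v, h, w)
  samples <- rbind(as.vector(t(vv)) %/% 256L, as.vector(t(vv)) %% 256L)
  rows <- matrix(as.raw(samples), nrow = 2L * w)      # one column per scanline
  scan <- rbind(matrix(as.raw(0L), 1, h), rows)       # filter byte 0 per row
  idat <- memCompress(as.vector(scan), type = "gzip") # zlib stream
  ihdr <- c(int_be(w), int_be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
             png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
             png_chunk("IEND", raw(0))), con)
}

read_png_gray <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3) d <- d[, , 1]          # collapse replicated channels
  t(d)
}

write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path, type = "png", bits = 8L)
}

read_mask_png <- function(path) {
  m <- read_png_gray(path) > 0.5
  storage.mode(m) <- "integer"
  m
}

## --- series I/O ------------------------------------------------------------

#' Write a series of CT slices
#'
#' @param slices list of [ct_slice] objects.
#' @param dir output directory.
#' @param format `"png"` (16-bit PNG + `series.csv`) or `"dicom"`.
#' @return invisibly, the metadata data.frame (png) or file list (dicom).
#' @export
write_series <- function(slices, dir, format = c("png", "dicom")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "png") {
    meta <- do.call(rbind, lapply(slices, function(sl) {
      data.frame(subject_id = sl$subject_id, slice_index = sl$slice_index,
                 pixel_spacing_row_mm = sl$pixel_spacing[1],
                 pixel_spacing_col_mm = sl$pixel_spacing[2],
                 image_file = sprintf("%s_slice%03d.png", sl$subject_id, sl$slice_index),
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_along(slices))
      write_png16(slices[[i]]$pixels, file.path(dir, meta$image_file[i]))
    write.csv(meta, file.path(dir, "series.csv"), row.names = FALSE)
    invisible(meta)
  } else {
    files <- vapply(slices, function(sl)
      sprintf("%s_slice%03d.dcm", sl$subject_id, sl$slice_index), "")
    for (i in seq_along(slices))
      write_dicom_slice(slices[[i]], file.path(dir, files[i]))
    invisible(files)
  }
}

#' Load a series of CT slices
#'
#' PNG series are read through their `series.csv` (or `metadata.csv`) table;
#' DICOM series read every `*.dcm` file in the directory. Slices are sorted
#' by slice index within subject. 16-bit grayscale values are preserved
#' losslessly (as multiples of 1/65535 in `[0, 1]`).
#'
#' @param path directory containing the series.
#' @param format `"png"` or `"dicom"`.
#' @return list of [ct_slice] objects.
#' @export
load_series <- function(path, format = c("png", "dicom")) {
  format <- match.arg(format)
  if (format == "png") {
    csv <- file.path(path, "series.csv")
    if (!file.exists(csv)) csv <- file.path(path, "metadata.csv")
    if (!file.exists(csv))
      stop("no series.csv or metadata.csv found in ", path)
    meta <- read.csv(csv, stringsAsFactors = FALSE)
    if (!is.null(meta$pixel_spacing_mm) && is.null(meta$pixel_spacing_row_mm)) {
      meta$pixel_spacing_row_mm <- meta$pixel_spacing_mm
      meta$pixel_spacing_col_mm <- meta$pixel_spacing_mm
    }
    slices <- lapply(seq_len(nrow(meta)), function(i) {
      px <- read_png_gray(file.path(path, meta$image_file[i]))
      ct_slice(px, meta$subject_id[i], meta$slice_index[i],
               c(meta$pixel_spacing_row_mm[i], meta$pixel_spacing_col_mm[i]))
    })
  } else {
    files <- sort(list.files(path, pattern = "\\.dcm$", full.names = TRUE))
    if (length(files) == 0) stop("no .dcm files found in ", path)
    slices <- lapply(files, read_dicom_slice)
  }
  ord <- order(vapply(slices, function(s) s$subject_id, ""),
               vapply(slices, function(s) s$slice_index, 1L))
  slices <- slices[ord]
  check_series(slices)
  slices
}

check_series <- function(slices) {
  by_subj <- split(slices, vapply(slices, function(s) s$subject_id, ""))
  for (subj in by_subj) {
    idx <- vapply(subj, function(s) s$slice_index, 1L)
    if (anyDuplicated(idx))
      stop("duplicate slice_index within subject ", subj[[1]]$subject_id)
    sizes <- vapply(subj, function(s) paste(dim(s$pixels), collapse = "x"), "")
    if (length(unique(sizes)) > 1)
      stop("mixed image sizes within subject ", subj[[1]]$subject_id,
           ": ", paste(unique(sizes), collapse = ", "))
  }
  invisible(TRUE)
}

## --- polygon annotations ---------------------------------------------------

#' Rasterize an annotation polygon to a binary mask
#'
#' Scanline even-odd fill with the pixel-centre convention: a pixel is
#' foreground when its centre falls inside the polygon; centres lying exactly
#' on a left/top boundary are included, on a right/bottom boundary excluded,
#' so an axis-aligned square `(0,0)-(w,h)` covers exactly `w*h` pixels.
#'
#' @param vertices numeric matrix with columns `x`, `y` (0-based pixel
#'   coordinates), one row per vertex, in order.
#' @param size image side in pixels (scalar) or `c(rows, cols)`.
#' @return integer 0/1 matrix.
#' @export
polygon_to_mask <- function(vertices, size) {
  if (length(size) == 1) size <- c(size, size)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3)
    stop("polygon must have at least 3 vertices")
  xs <- vertices[, 1]; ys <- vertices[, 2]
  area2 <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys))
  if (area2 < .Machine$double.eps * 100)
    stop("degenerate polygon: zero area")
  n <- nrow(vertices)
  x1 <- xs; y1 <- ys
  x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
  mask <- matrix(0L, size[1], size[2])
  for (row in 0:(size[1] - 1)) {
    ## half-open edge rule avoids double counting at shared vertices
    hit <- (y1 <= row & y2 > row) | (y2 <= row & y1 > row)
    if (!any(hit)) next
    xc <- sort(x1[hit] + (row - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit]))
    for (i in seq(1, length(xc) - 1, by = 2)) {
      lo <- ceiling(xc[i]); hi <- ceiling(xc[i + 1]) - 1
      lo <- max(lo, 0); hi <- min(hi, size[2] - 1)
      if (lo <= hi) mask[row + 1, (lo:hi) + 1] <- 1L
    }
  }
  mask
}

## --- minimal DICOM (explicit VR little endian, MONOCHROME2, 16-bit) --------

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1)                       # even-length padding
    value_raw <- c(value_raw, as.raw(if (vr == "UI") 0L else 0x20))
  head <- c(dcm_uint16(group), dcm_uint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0, 0)), dcm_uint32(length(value_raw)), value_raw)
  else
    c(head, dcm_uint16(length(value_raw)), value_raw)
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))
dcm_us  <- function(group, elem, x) dcm_element(group, elem, "US", dcm_uint16(x))

#' Write one slice as a minimal DICOM file
#'
#' Explicit-VR little-endian, single-frame MONOCHROME2, 16 bits/pixel, with
#' PatientID, InstanceNumber, Rows/Columns and PixelSpacing populated.
#' Intended for I/O testing, not full DICOM conformance.
#'
#' @param slice a [ct_slice]; pixel values in `[0, 1]` are stored as uint16.
#' @param path output file.
#' @param omit_spacing drop the PixelSpacing tag (to exercise the reader's
#'   required-tag error path).
#' @export
write_dicom_slice <- function(slice, path, omit_spacing = FALSE) {
  px <- round(pmin(pmax(slice$pixels, 0), 1) * 65535)
  pixraw <- writeBin(as.integer(as.vector(t(px))), raw(), size = 2,
                     endian = "little")                   # row-major
  ts <- dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint32(length(ts))), ts)
  body <- c(dcm_str(0x0008, 0x0060, "CS", "CT"),
            dcm_str(0x0010, 0x0020, "LO", slice$subject_id),
            dcm_str(0x0020, 0x0013, "IS", as.character(slice$slice_index)),
            dcm_us(0x0028, 0x0002, 1L),
            dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
            dcm_us(0x0028, 0x0010, nrow(px)),
            dcm_us(0x0028, 0x0011, ncol(px)))
  if (!omit_spacing)
    body <- c(body, dcm_str(0x0028, 0x0030, "DS",
                            sprintf("%g\\%g", slice$pixel_spacing[1],
                                    slice$pixel_spacing[2])))
  body <- c(body,
            dcm_us(0x0028, 0x0100, 16L), dcm_us(0x0028, 0x0101, 16L),
            dcm_us(0x0028, 0x0102, 15L), dcm_us(0x0028, 0x0103, 0L),
            dcm_element(0x7FE0, 0x0010, "OW", pixraw))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
}

#' Read one slice from a minimal DICOM file
#'
#' Parses explicit-VR little-endian elements; a file without the PixelSpacing
#' tag (0028,0030) is a hard error naming the file, never a default value.
#'
#' @param path DICOM file.
#' @return a [ct_slice].
#' @export
read_dicom_slice <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  tags <- list()
  u16 <- function(i) readBin(bytes[i:(i + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(bytes[i:(i + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 7 <= length(bytes)) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupt DICOM not supported: ", path)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8); val_at <- pos + 12L
    } else {
      len <- u16(pos + 6); val_at <- pos + 8L
    }
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, raw = bytes[seq.int(val_at, length.out = len)])
    pos <- val_at + len
  }
  need <- function(key, what) {
    if (is.null(tags[[key]]))
      stop("DICOM file ", path, " lacks required tag (", key, ") ", what)
    tags[[key]]
  }
  as_str <- function(t) {
    r <- t$raw[t$raw != as.raw(0)]       # strip UI null padding
    sub(" +$", "", rawToChar(r))
  }
  rows <- u16_val(need("0028,0010", "Rows")$raw)
  cols <- u16_val(need("0028,0011", "Columns")$raw)
  spacing <- as.numeric(strsplit(as_str(need("0028,0030", "PixelSpacing")),
                                 "\\\\")[[1]])
  subj <- as_str(need("0010,0020", "PatientID"))
  idx <- as.integer(as_str(need("0020,0013", "InstanceNumber")))
  pixraw <- need("7FE0,0010", "PixelData")$raw
  vals <- readBin(pixraw, "integer", n = rows * cols, size = 2,
                  endian = "little", signed = FALSE)
  px <- matrix(vals / 65535, rows, cols, byrow = TRUE)
  ct_slice(px, subj, idx, spacing)
}

u16_val <- function(r) readBin(r, "integer", size = 2, endian = "little",
                               signed = FALSE)
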
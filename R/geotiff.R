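# Minimal GeoTIFF I/O: single-band, uncompressed, IEEE-float rasters with
# the two georeference tags GIS software reads (ModelPixelScale and
# ModelTiepoint) plus the conventional nodata tag. 64-bit samples make the
# write -> read round-trip bit-exact. Written because no geospatial raster
# I/O package is available; the format subset is the one produced here and
# by standard exporters of uncompressed float GeoTIFFs.

TAG_WIDTH <- 256L; TAG_LENGTH <- 257L; TAG_BITS <- 258L
TAG_COMPRESSION <- 259L; TAG_PHOTOMETRIC <- 262L; TAG_STRIP_OFFSETS <- 273L
TAG_SPP <- 277L; TAG_ROWS_PER_STRIP <- 278L; TAG_STRIP_BYTES <- 279L
TAG_PLANAR <- 284L; TAG_SAMPLE_FORMAT <- 339L
TAG_PIXEL_SCALE <- 33550L; TAG_TIEPOINT <- 33922L; TAG_NODATA <- 42113L

write_geotiff <- function(g, path) {
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  out <- t(v)                      # TIFF stores row-major, top row first
  out[is.na(out)] <- g$nodata
  data_bytes <- nr * nc * 8L
  ifd_offset <- 8L + data_bytes
  n_entries <- 14L
  after_ifd <- ifd_offset + 2L + n_entries * 12L + 4L
  off_scale <- after_ifd
  off_tie <- off_scale + 3L * 8L
  nodata_str <- c(charToRaw(sprintf("%.17g", g$nodata)), as.raw(0))
  off_nodata <- off_tie + 6L * 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  writeBin(as.vector(out), con, size = 8, endian = "little")
  writeBin(n_entries, con, size = 2, endian = "little")
  u16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
  entry <- function(tag, type, count, value, raw4 = NULL) {
    writeBin(u16(as.integer(tag)), con)
    writeBin(u16(as.integer(type)), con)
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (is.null(raw4)) writeBin(as.integer(value), con, size = 4,
                                endian = "little")
    else writeBin(raw4, con)
  }
  entry(TAG_WIDTH, 4L, 1L, nc)
  entry(TAG_LENGTH, 4L, 1L, nr)
  entry(TAG_BITS, 3L, 1L, raw4 = writeBin(c(64L, 0L), raw(), size = 2,
                                          endian = "little"))
  entry(TAG_COMPRESSION, 3L, 1L, raw4 = writeBin(c(1L, 0L), raw(), size = 2,
                                                 endian = "little"))
  entry(TAG_PHOTOMETRIC, 3L, 1L, raw4 = writeBin(c(1L, 0L), raw(), size = 2,
                                                 endian = "little"))
  entry(TAG_STRIP_OFFSETS, 4L, 1L, 8L)
  entry(TAG_SPP, 3L, 1L, raw4 = writeBin(c(1L, 0L), raw(), size = 2,
                                         endian = "little"))
  entry(TAG_ROWS_PER_STRIP, 4L, 1L, nr)
  entry(TAG_STRIP_BYTES, 4L, 1L, data_bytes)
  entry(TAG_PLANAR, 3L, 1L, raw4 = writeBin(c(1L, 0L), raw(), size = 2,
                                            endian = "little"))
  entry(TAG_SAMPLE_FORMAT, 3L, 1L, raw4 = writeBin(c(3L, 0L), raw(),
                                                   size = 2,
                                                   endian = "little"))
  entry(TAG_PIXEL_SCALE, 12L, 3L, off_scale)
  entry(TAG_TIEPOINT, 12L, 6L, off_tie)
  entry(TAG_NODATA, 2L, length(nodata_str), off_nodata)
  writeBin(0L, con, size = 4, endian = "little")  # no further IFD
  writeBin(c(g$cell_size, g$cell_size, 0), con, size = 8, endian = "little")
  # tiepoint: raster (0,0) pins the OUTER top-left corner
  writeBin(c(0, 0, 0, g$x_origin, g$y_origin, 0), con, size = 8,
           endian = "little")
  writeBin(nodata_str, con)
  invisible(path)
}

read_geotiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  rd_int <- function(off, size, endian) {
    readBin(raw[(off + 1):(off + size)], "integer", 1, size = size,
            signed = size >= 4, endian = endian)
  }
  magic <- rawToChar(raw[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big"
  else stop("not a TIFF file: ", path)
  if (rd_int(2, 2, endian) != 42L) stop("not a TIFF file: ", path)
  ifd <- rd_int(4, 4, endian)
  n <- rd_int(ifd, 2, endian)
  tags <- list()
  for (i in seq_len(n) - 1L) {
    e <- ifd + 2L + i * 12L
    tag <- rd_int(e, 2, endian)
    type <- rd_int(e + 2, 2, endian)
    count <- rd_int(e + 4, 4, endian)
    size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L,
              `12` = 8L)[as.character(type)]
    if (is.na(size)) next
    total <- size * count
    voff <- if (total <= 4) e + 8L else rd_int(e + 8, 4, endian)
    bytes <- raw[(voff + 1):(voff + total)]
    val <- switch(as.character(type),
                  `2` = rawToChar(bytes[bytes != as.raw(0)]),
                  `3` = readBin(bytes, "integer", count, size = 2,
                                signed = FALSE, endian = endian),
                  `4` = readBin(bytes, "integer", count, size = 4,
                                endian = endian),
                  `11` = readBin(bytes, "double", count, size = 4,
                                 endian = endian),
                  `12` = readBin(bytes, "double", count, size = 8,
                                 endian = endian),
                  readBin(bytes, "integer", count, size = 1, signed = FALSE,
                          endian = endian))
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("GeoTIFF tag ", tag, " missing in ", path)
    v
  }
  nc <- need(TAG_WIDTH); nr <- need(TAG_LENGTH)
  if (!is.null(tags[[as.character(TAG_COMPRESSION)]]) &&
        tags[[as.character(TAG_COMPRESSION)]] != 1L)
    stop("compressed TIFFs are not supported: ", path)
  bits <- need(TAG_BITS)[1]
  fmt <- tags[[as.character(TAG_SAMPLE_FORMAT)]]
  if (is.null(fmt)) fmt <- 1L
  if (!(bits %in% c(32L, 64L)) || fmt[1] != 3L)
    stop("only uncompressed IEEE-float TIFFs are supported (got ",
         bits, "-bit, sample format ", fmt[1], ")")
  offs <- need(TAG_STRIP_OFFSETS)
  cnts <- need(TAG_STRIP_BYTES)
  vals <- unlist(lapply(seq_along(offs), function(k)
    readBin(raw[(offs[k] + 1):(offs[k] + cnts[k])], "double",
            cnts[k] / (bits / 8), size = bits / 8, endian = endian)))
  if (length(vals) != nr * nc)
    stop("TIFF strip data does not match the declared dimensions")
  v <- t(matrix(vals, nc, nr))
  scale <- need(TAG_PIXEL_SCALE)
  tie <- need(TAG_TIEPOINT)
  if (abs(scale[1] - scale[2]) > 1e-9 * scale[1])
    stop("anisotropic pixels are not supported")
  nodata <- suppressWarnings(as.numeric(tags[[as.character(TAG_NODATA)]]))
  if (length(nodata) == 0 || is.na(nodata)) nodata <- -9999
  v[is.nan(v) | v == nodata] <- NA_real_
  # tiepoint maps raster (i, j) to model space; shift back to raster (0,0)
  lg_grid(v,
          x_origin = tie[4] - tie[1] * scale[1],
          y_origin = tie[5] + tie[2] * scale[2],
          cell_size = scale[1], nodata = nodata)
}
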
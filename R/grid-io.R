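## Raster data model and I/O (ESRI ASCII grid, minimal single-band GeoTIFF).
## All grids are treated as already projected to a planar equal-area /
## equidistant system; coordinates are metres, cells square, row 1 north.

#' Construct a GridLayer
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param xll,yll lower-left corner of the grid in metres.
#' @param cellSize cell size in metres.
#' @param mask optional logical nodata matrix (default: non-finite cells).
#' @param crsLabel free-text projection label.
#' @return a [GridLayer-class].
#' @export
newGrid <- function(values, xll = 0, yll = 0, cellSize,
                    mask = NULL, crsLabel = "projected-planar") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.finite(values)
  mask <- matrix(as.logical(mask), nrow(values), ncol(values))
  values[mask] <- NA_real_
  new("GridLayer", values = values, mask = mask, xll = as.numeric(xll),
      yll = as.numeric(yll), cellSize = as.numeric(cellSize),
      crsLabel = crsLabel)
}

#' @rdname newGrid
#' @param grid a [GridLayer-class].
#' @export
gridValues <- function(grid) grid@values

#' @rdname newGrid
#' @export
gridMask <- function(grid) grid@mask

#' @rdname newGrid
#' @export
cellAreaKm2 <- function(grid) {
  cs <- if (is(grid, "GridLayer")) grid@cellSize else grid@cellSize
  abs(cs * cs) / 1e6
}

#' Cell-centre coordinates of a grid
#'
#' @param grid a [GridLayer-class] (or any object carrying xll/yll/cellSize
#'   georeferencing and a values/suitable matrix).
#' @return list with vectors `x` (by column) and `y` (by row, row 1 = north),
#'   plus matrices `X`, `Y` of per-cell centres.
#' @export
cellCenters <- function(grid) {
  d <- gridDim(grid)
  cs <- grid@cellSize
  x <- grid@xll + (seq_len(d[2]) - 0.5) * cs
  y <- grid@yll + (d[1] - seq_len(d[1]) + 0.5) * cs
  list(x = x, y = y,
       X = matrix(x, d[1], d[2], byrow = TRUE),
       Y = matrix(y, d[1], d[2]))
}

gridDim <- function(grid) {
  if (is(grid, "GridLayer")) dim(grid@values)
  else if (is(grid, "BinaryMap")) dim(grid@suitable)
  else if (is(grid, "ChangeMap") ) dim(grid@classes)
  else if (is(grid, "LimitingFactorMap")) dim(grid@factorIndex)
  else stop("no grid dimensions for class ", class(grid))
}

## geometry equality within 1e-6 cell widths
sameGeometry <- function(a, b) {
  tol <- 1e-6 * a@cellSize
  all(gridDim(a) == gridDim(b)) &&
    abs(a@xll - b@xll) < tol && abs(a@yll - b@yll) < tol &&
    abs(a@cellSize - b@cellSize) < tol
}

#' Area of a cell mask
#'
#' Counts `TRUE` cells and multiplies by the per-cell area, the accounting
#' used for all range-area tables (equal-area projected grid).
#'
#' @param mask logical matrix or vector.
#' @param cellArea area of one cell in km^2.
#' @return area in km^2 (0 for an empty mask).
#' @export
areaOf <- function(mask, cellArea) {
  stopifnot(cellArea > 0)
  sum(mask, na.rm = TRUE) * cellArea
}

## ---- ESRI ASCII grid ----

readAsciiGrid <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, 1)
    if (!length(line)) stop("unexpected end of file in ", path)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    key <- toupper(parts[1])
    if (key %in% c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER",
                   "XLLCENTER", "YLLCENTER", "CELLSIZE", "NODATA_VALUE")) {
      hdr[[key]] <- as.numeric(parts[2])
    } else {
      seek(con, pos); break
    }
  }
  need <- c("NCOLS", "NROWS", "CELLSIZE")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid missing georeferencing header in ", path)
  nr <- hdr$NROWS; nc <- hdr$NCOLS
  vals <- scan(con, what = double(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nr, nc, byrow = TRUE)   # file rows run north -> south
  nodata <- hdr$NODATA_VALUE %||% -9999
  mask <- m == nodata
  m[mask] <- NA_real_
  xll <- hdr$XLLCORNER %||% (hdr$XLLCENTER - hdr$CELLSIZE / 2)
  yll <- hdr$YLLCORNER %||% (hdr$YLLCENTER - hdr$CELLSIZE / 2)
  newGrid(m, xll = xll, yll = yll, cellSize = hdr$CELLSIZE, mask = mask)
}

writeAsciiGrid <- function(grid, path, nodata = -9999) {
  v <- grid@values
  v[grid@mask] <- nodata
  hdr <- c(
    sprintf("NCOLS %d", ncol(v)),
    sprintf("NROWS %d", nrow(v)),
    sprintf("XLLCORNER %.10g", grid@xll),
    sprintf("YLLCORNER %.10g", grid@yll),
    sprintf("CELLSIZE %.10g", grid@cellSize),
    sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
}

## ---- minimal single-band GeoTIFF (float32/float64, uncompressed) ----

GEOTIFF_NODATA <- -3.4e38

tiffEntry <- function(tag, type, count, value) {
  list(tag = tag, type = type, count = count, value = value)
}

writeGeoTiff <- function(grid, path) {
  v <- grid@values
  v[grid@mask] <- GEOTIFF_NODATA
  nr <- nrow(v); nc <- ncol(v)
  con <- file(path, "wb"); on.exit(close(con))
  pix <- as.numeric(t(v))                 # row-major, row 1 first (north)
  nodataStr <- c(charToRaw(sprintf("%.6g", GEOTIFF_NODATA)), as.raw(0))
  pixScale <- c(grid@cellSize, grid@cellSize, 0)
  # tiepoint maps raster (0,0) (top-left corner) to model coordinates
  tiepoint <- c(0, 0, 0, grid@xll, grid@yll + nr * grid@cellSize, 0)
  entries <- list(
    tiffEntry(256L, 3L, 1L, nc),              # ImageWidth
    tiffEntry(257L, 3L, 1L, nr),              # ImageLength
    tiffEntry(258L, 3L, 1L, 32L),             # BitsPerSample
    tiffEntry(259L, 3L, 1L, 1L),              # Compression: none
    tiffEntry(262L, 3L, 1L, 1L),              # Photometric: BlackIsZero
    tiffEntry(273L, 4L, 1L, NA),              # StripOffsets (patched below)
    tiffEntry(277L, 3L, 1L, 1L),              # SamplesPerPixel
    tiffEntry(278L, 3L, 1L, nr),              # RowsPerStrip: single strip
    tiffEntry(279L, 4L, 1L, nr * nc * 4L),    # StripByteCounts
    tiffEntry(339L, 3L, 1L, 3L),              # SampleFormat: IEEE float
    tiffEntry(33550L, 12L, 3L, pixScale),     # ModelPixelScale
    tiffEntry(33922L, 12L, 6L, tiepoint),     # ModelTiepoint
    tiffEntry(42113L, 2L, length(nodataStr), nodataStr)  # GDAL_NODATA
  )
  # layout: header (8) | IFD | out-of-line values | pixel strip
  nE <- length(entries)
  ifdOffset <- 8L
  ifdSize <- 2L + nE * 12L + 4L
  valSize <- function(e) {
    bytes <- switch(as.character(e$type), "2" = 1L, "3" = 2L, "4" = 4L,
                    "12" = 8L) * e$count
    if (bytes > 4L) as.integer(ceiling(bytes / 2) * 2) else 0L
  }
  extra <- vapply(entries, valSize, integer(1))
  extraOff <- ifdOffset + ifdSize + c(0L, cumsum(extra))[seq_len(nE)]
  stripOffset <- ifdOffset + ifdSize + sum(extra)
  entries[[6]]$value <- stripOffset

  writeBin(c(charToRaw("II"), as.raw(c(42, 0))), con)          # little-endian
  writeBin(as.integer(ifdOffset), con, size = 4, endian = "little")
  writeBin(nE, con, size = 2, endian = "little")
  for (i in seq_len(nE)) {
    e <- entries[[i]]
    writeBin(as.integer(e$tag), con, size = 2, endian = "little")
    writeBin(as.integer(e$type), con, size = 2, endian = "little")
    writeBin(as.integer(e$count), con, size = 4, endian = "little")
    if (extra[i] > 0L) {
      writeBin(as.integer(extraOff[i]), con, size = 4, endian = "little")
    } else if (e$type == 3L) {
      writeBin(as.integer(e$value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(e$value), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")               # next IFD
  for (i in seq_len(nE)) {                                     # out-of-line
    e <- entries[[i]]
    if (extra[i] == 0L) next
    if (e$type == 12L) writeBin(e$value, con, size = 8, endian = "little")
    else if (e$type == 2L) {
      writeBin(e$value, con)
      if (length(e$value) %% 2) writeBin(as.raw(0), con)
    }
  }
  writeBin(pix, con, size = 4, endian = "little")
}

readGeoTiff <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  if (!order %in% c("II", "MM")) stop("not a TIFF file: ", path)
  le <- order == "II"
  getInt <- function(off, size) {
    readBin(raw[(off + 1):(off + size)], "integer", size = size,
            endian = if (le) "little" else "big",
            signed = size == 4)
  }
  getInts <- function(off, size, n) {
    readBin(raw[(off + 1):(off + size * n)], "integer", size = size, n = n,
            endian = if (le) "little" else "big", signed = size == 4)
  }
  getDoubles <- function(off, n) {
    readBin(raw[(off + 1):(off + 8 * n)], "double", size = 8, n = n,
            endian = if (le) "little" else "big")
  }
  ifd <- getInt(4, 4)
  nE <- getInt(ifd, 2)
  tags <- list()
  for (i in seq_len(nE)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- getInt(off, 2); typ <- getInt(off + 2, 2)
    cnt <- getInt(off + 4, 4)
    tb <- switch(as.character(typ), "1" = 1L, "2" = 1L, "3" = 2L, "4" = 4L,
                 "11" = 4L, "12" = 8L, stop("unsupported TIFF type ", typ))
    voff <- if (tb * cnt > 4) getInt(off + 8, 4) else off + 8
    val <- if (typ == 12L) getDoubles(voff, cnt)
    else if (typ == 2L) rawToChar(raw[(voff + 1):(voff + cnt)][
      raw[(voff + 1):(voff + cnt)] != as.raw(0)])
    else getInts(voff, tb, cnt)
    tags[[as.character(tag)]] <- val
  }
  need <- c("256", "257", "273", "279")
  if (!all(need %in% names(tags)))
    stop("TIFF missing required image tags in ", path)
  if (!all(c("33550", "33922") %in% names(tags)))
    stop("TIFF lacks georeferencing (ModelPixelScale/ModelTiepoint) in ", path)
  nc <- tags[["256"]]; nr <- tags[["257"]]
  bits <- (tags[["258"]] %||% 32L)[1]
  fmt <- (tags[["339"]] %||% 3L)[1]
  if ((tags[["259"]] %||% 1L)[1] != 1L) stop("compressed TIFF not supported")
  if (fmt != 3L || !bits %in% c(32L, 64L))
    stop("only float32/float64 sample format supported")
  offs <- tags[["273"]]; counts <- tags[["279"]]
  pix <- numeric(0)
  for (i in seq_along(offs)) {
    n <- counts[i] / (bits / 8)
    pix <- c(pix, readBin(raw[(offs[i] + 1):(offs[i] + counts[i])], "double",
                          size = bits / 8, n = n,
                          endian = if (le) "little" else "big"))
  }
  m <- matrix(pix, nr, nc, byrow = TRUE)
  nodata <- suppressWarnings(as.numeric(tags[["42113"]] %||% NA))
  mask <- if (is.finite(nodata)) {
    tolND <- max(abs(nodata) * 1e-6, 1e-30)
    abs(m - nodata) <= tolND
  } else matrix(FALSE, nr, nc)
  mask <- mask | !is.finite(m)
  scale <- tags[["33550"]]
  tie <- tags[["33922"]]
  cellSize <- scale[1]
  xll <- tie[4] - tie[1] * cellSize
  ytop <- tie[5] + tie[2] * scale[2]
  newGrid(m, xll = xll, yll = ytop - nr * scale[2], cellSize = cellSize,
          mask = mask)
}

#' Read / write a raster grid
#'
#' Supported formats: `ascii_grid` (ESRI ASCII: NCOLS/NROWS/XLLCORNER/
#' YLLCORNER/CELLSIZE/NODATA_value header) and `geotiff` (single band,
#' uncompressed float32, ModelPixelScale + ModelTiepoint + GDAL_NODATA
#' tags, written little-endian). When the file extension disagrees with
#' the `format` flag a warning is raised and the flag wins.
#'
#' @param path file path.
#' @param format `"ascii_grid"` or `"geotiff"`; default guessed from the
#'   extension (`.asc`/`.txt` vs `.tif`/`.tiff`).
#' @return [GridLayer-class] for `readGrid`; invisibly `path` for
#'   `writeGrid`.
#' @export
readGrid <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- resolveGridFormat(path, format)
  switch(format,
         ascii_grid = readAsciiGrid(path),
         geotiff = readGeoTiff(path))
}

#' @rdname readGrid
#' @param grid a [GridLayer-class] to write.
#' @export
writeGrid <- function(grid, path, format = NULL) {
  stopifnot(is(grid, "GridLayer"))
  format <- resolveGridFormat(path, format)
  switch(format,
         ascii_grid = writeAsciiGrid(grid, path),
         geotiff = writeGeoTiff(grid, path))
  invisible(path)
}

resolveGridFormat <- function(path, format) {
  ext <- tolower(tools::file_ext(path))
  guessed <- if (ext %in% c("tif", "tiff")) "geotiff" else "ascii_grid"
  if (is.null(format)) return(guessed)
  format <- match.arg(format, c("ascii_grid", "geotiff"))
  if (ext %in% c("tif", "tiff", "asc", "txt") && format != guessed)
    warning("file extension '", ext, "' does not match format '", format,
            "'; using the format flag")
  format
}
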
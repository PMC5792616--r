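#' Georeferenced single-band raster grid
#'
#' The common container for the elevation model and every terrain variable
#' derived from it. Values are stored row-major with row 1 the northernmost
#' row; the georeference is the *outer* corner of the top-left cell, so the
#' centre of cell \code{(r, c)} (1-based) sits at
#' \code{x_origin + (c - 0.5) * cell_size},
#' \code{y_origin - (r - 0.5) * cell_size}. Cell values represent cell
#' centres. Nodata cells are held as \code{NA} internally; the sentinel is
#' only used on disk.
#'
#' @param values numeric matrix (row 1 = north). \code{NA} marks nodata.
#' @param x_origin,y_origin coordinates (m) of the outer top-left corner.
#' @param cell_size cell edge length in metres (> 0).
#' @param nodata sentinel written to/read from disk for missing cells.
#' @param crs free-text label for the (projected, metric) coordinate frame.
#'   Carried as an opaque tag; the package never reprojects.
#' @return an object of class \code{lg_grid}.
#' @examples
#' g <- lg_grid(matrix(1:12, 3, 4), x_origin = 0, y_origin = 30, cell_size = 10)
#' dim(g$values)
#' @export
lg_grid <- function(values, x_origin, y_origin, cell_size,
                    nodata = -9999, crs = "local-meters") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.finite(x_origin), is.finite(y_origin),
            is.finite(cell_size), cell_size > 0,
            nrow(values) >= 1, ncol(values) >= 1)
  # mask any sentinel that slipped into the data
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, x_origin = x_origin, y_origin = y_origin,
         cell_size = cell_size, nodata = nodata, crs = crs),
    class = "lg_grid")
}

#' @export
print.lg_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<lg_grid> %d x %d cells @ %g m\n", nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  extent : x [%g, %g]  y [%g, %g]  (%s)\n",
              x$x_origin, x$x_origin + ncol(v) * x$cell_size,
              x$y_origin - nrow(v) * x$cell_size, x$y_origin, x$crs))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values : [%.6g, %.6g]  (%d nodata)\n",
                min(fin), max(fin), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.lg_grid <- function(x) dim(x$values)

grid_xmax <- function(g) g$x_origin + ncol(g$values) * g$cell_size
grid_ymin <- function(g) g$y_origin - nrow(g$values) * g$cell_size

#' Read a raster grid
#'
#' Supported formats: ESRI ASCII grid (text) and single-band uncompressed
#' IEEE-float GeoTIFF (the georeference is carried in the standard
#' ModelPixelScale/ModelTiepoint tags, nodata in the conventional nodata
#' tag).
#'
#' @param path file path.
#' @param format \code{"esri_ascii"} or \code{"geotiff"}; guessed from the
#'   file extension when missing.
#' @return an [lg_grid].
#' @export
read_grid <- function(path, format = c("auto", "esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
      "geotiff" else "esri_ascii"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         esri_ascii = read_esri_ascii(path),
         geotiff    = read_geotiff(path))
}

#' Write a raster grid
#'
#' ESRI ASCII values are printed with \code{\%.17g} and the GeoTIFF backend
#' stores 64-bit floats, so a write/read round-trip reproduces doubles
#' bit-exactly in both formats.
#'
#' @param g an [lg_grid].
#' @inheritParams read_grid
#' @return \code{path}, invisibly.
#' @export
write_grid <- function(g, path, format = c("auto", "esri_ascii", "geotiff")) {
  stopifnot(inherits(g, "lg_grid"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
      "geotiff" else "esri_ascii"
  }
  switch(format,
         esri_ascii = write_esri_ascii(g, path),
         geotiff    = write_geotiff(g, path))
  invisible(path)
}

read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("ESRI ASCII grid too short: ", path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2)
      stop("malformed ESRI ASCII header at line ", i, ": '", lines[i], "'")
    val <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(val))
      stop("non-numeric header value at line ", i, ": '", lines[i], "'")
    hdr[[tolower(tok[1])]] <- val
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII header missing ", paste(setdiff(need, names(hdr)), collapse = ", "))
  if (!("xllcorner" %in% names(hdr) && "yllcorner" %in% names(hdr)))
    stop("ESRI ASCII header missing xllcorner/yllcorner (xllcenter not supported)")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop("ESRI ASCII body has ", length(body), " data rows, header says nrows=", nr)
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != nc)
      stop("ESRI ASCII data row ", r, " (line ", i + r - 1, ") has ",
           length(row), " values, header says ncols=", nc)
    if (anyNA(row))
      stop("ESRI ASCII data row ", r, " contains non-numeric values")
    vals[r, ] <- row
  }
  vals[vals == nodata] <- NA_real_
  lg_grid(vals,
          x_origin = hdr$xllcorner,
          y_origin = hdr$yllcorner + nr * hdr$cellsize,
          cell_size = hdr$cellsize, nodata = nodata)
}

write_esri_ascii <- function(g, path) {
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", g$x_origin),
    sprintf("yllcorner %.17g", g$y_origin - nr * g$cell_size),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", g$nodata)), con)
  out <- v
  out[is.na(out)] <- g$nodata
  writeLines(apply(out, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
}

#' Map point coordinates to pixel indices
#'
#' Cells are half-open: a point on a shared edge belongs to the cell with the
#' larger row/column index, except on the grid's outer south/east edge, which
#' maps inward, so every in-bounds point has exactly one pixel.
#'
#' @param g an [lg_grid].
#' @param x,y numeric vectors of projected coordinates (m).
#' @return data frame with 1-based \code{row}, \code{col} and the linearised
#'   \code{pixel} index \code{(row - 1) * ncol + col}.
#' @export
pixel_id <- function(g, x, y) {
  stopifnot(inherits(g, "lg_grid"), length(x) == length(y))
  nr <- nrow(g$values); nc <- ncol(g$values); cs <- g$cell_size
  xmax <- grid_xmax(g); ymin <- grid_ymin(g)
  bad <- x < g$x_origin | x > xmax | y < ymin | y > g$y_origin
  if (any(bad))
    stop("point(s) outside grid bounds: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  col <- floor((x - g$x_origin) / cs) + 1L
  row <- floor((g$y_origin - y) / cs) + 1L
  col <- pmin(col, nc)  # outer max edge maps inward
  row <- pmin(row, nr)
  data.frame(row = as.integer(row), col = as.integer(col),
             pixel = as.integer((row - 1L) * nc + col))
}

#' Extract grid values at sample locations
#'
#' Returns the value of the containing cell (no interpolation). Samples that
#' fall on a nodata cell yield \code{NA} and are flagged, never dropped.
#'
#' @param g an [lg_grid].
#' @param samples a sample table (data frame with \code{x}, \code{y}; see
#'   [read_samples]).
#' @return numeric vector of per-sample values, with attribute
#'   \code{"missing"} giving the indices that hit nodata cells.
#' @export
extract_at <- function(g, samples) {
  px <- pixel_id(g, samples$x, samples$y)
  vals <- g$values[cbind(px$row, px$col)]
  miss <- which(is.na(vals))
  if (length(miss))
    warning(length(miss), " sample(s) fall on nodata cells")
  attr(vals, "missing") <- miss
  vals
}

#' Read a sample table
#'
#' CSV with header \code{id,x,y,alt,plot_id}: georeferenced individuals, the
#' field-measured altitude and the sampling-plot membership used as a
#' random-effect grouping.
#'
#' @param path CSV file path.
#' @return data frame with columns \code{id}, \code{x}, \code{y}, \code{alt},
#'   \code{plot_id}.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "alt", "plot_id")
  if (!all(need %in% names(df)))
    stop("sample table must have columns ", paste(need, collapse = ","))
  validate_samples(df[need])
}

validate_samples <- function(df) {
  df$id <- as.character(df$id)
  df$plot_id <- as.character(df$plot_id)
  if (anyDuplicated(df$id)) stop("duplicate sample ids")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite sample coordinates")
  if (any(!nzchar(df$plot_id))) stop("every individual needs a plot_id")
  df
}
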
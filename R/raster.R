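#' Georeferenced single-band raster
#'
#' Minimal in-memory raster used throughout the pipeline: a numeric matrix of
#' reflectance (or index) values plus an affine grid description. Row 1 of the
#' matrix is the northernmost (top) row; `xll`/`yll` give the coordinates of
#' the lower-left corner of the grid in scene-frame metres; y increases
#' northward (up).
#'
#' @param values numeric matrix, row 1 = top row.
#' @param xll,yll coordinates of the lower-left corner, metres.
#' @param cellsize pixel side length, metres.
#' @return an object of class `sc_raster`.
#' @export
sc_raster <- function(values, xll = 0, yll = 0, cellsize = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (cellsize <= 0) stop("`cellsize` must be positive")
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "sc_raster")
}

#' @export
print.sc_raster <- function(x, ...) {
  e <- raster_extent(x)
  cat(sprintf("<sc_raster> %d x %d pixels @ %g m, extent [%g,%g] x [%g,%g] m\n",
              nrow(x$values), ncol(x$values), x$cellsize,
              e["xmin"], e["xmax"], e["ymin"], e["ymax"]))
  invisible(x)
}

#' Raster extent
#'
#' @param r an `sc_raster`.
#' @return named numeric vector `xmin, ymin, xmax, ymax` in metres.
#' @export
raster_extent <- function(r) {
  c(xmin = r$xll, ymin = r$yll,
    xmax = r$xll + ncol(r$values) * r$cellsize,
    ymax = r$yll + nrow(r$values) * r$cellsize)
}

# Pixel (row, col) containing a point, half-open convention: a point on the
# max edge of the raster is outside. Vectorised over x/y. Returns a list with
# integer vectors row, col and a logical `inside`.
cell_of <- function(r, x, y) {
  col <- floor((x - r$xll) / r$cellsize) + 1L
  row_from_bottom <- floor((y - r$yll) / r$cellsize)
  row <- nrow(r$values) - row_from_bottom
  inside <- col >= 1L & col <= ncol(r$values) & row >= 1L & row <= nrow(r$values)
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

# Coordinates of the centre of pixel (row, col); vectorised.
cell_center <- function(r, row, col) {
  list(x = r$xll + (col - 0.5) * r$cellsize,
       y = r$yll + (nrow(r$values) - row + 0.5) * r$cellsize)
}

#' Look up raster values at point coordinates
#'
#' Nearest-neighbour lookup: each point is assigned the value of the pixel
#' containing it (half-open rule on the max edges).
#'
#' @param r an `sc_raster`.
#' @param x,y point coordinates, metres.
#' @return numeric vector of values.
#' @export
raster_value_at <- function(r, x, y) {
  cc <- cell_of(r, x, y)
  if (any(!cc$inside)) {
    i <- which(!cc$inside)[1]
    stop(sprintf("point (%g, %g) is outside the raster extent", x[i], y[i]))
  }
  r$values[cbind(cc$row, cc$col)]
}

#' Aggregate a raster by block means
#'
#' Produces a coarser raster whose every pixel is the mean of a `factor` x
#' `factor` block of the input; emulates the point-spread aggregation of a
#' multispectral sensor relative to the panchromatic grid.
#'
#' @param r an `sc_raster` whose dimensions are divisible by `factor`.
#' @param factor integer aggregation factor (default 4).
#' @return an `sc_raster` with `factor`-times larger pixels.
#' @export
block_mean <- function(r, factor = 4L) {
  v <- r$values
  if (nrow(v) %% factor != 0 || ncol(v) %% factor != 0)
    stop("raster dimensions must be divisible by the aggregation factor")
  nr <- nrow(v) %/% factor
  nc <- ncol(v) %/% factor
  # sum over column blocks, then row blocks
  rowgrp <- rep(seq_len(nr), each = factor)
  colgrp <- rep(seq_len(nc), each = factor)
  s <- rowsum(v, rowgrp, reorder = TRUE)           # nr x ncol
  s <- t(rowsum(t(s), colgrp, reorder = TRUE))     # nr x nc
  dimnames(s) <- NULL
  sc_raster(s / factor^2, xll = r$xll, yll = r$yll,
            cellsize = r$cellsize * factor)
}

#' Compute NDVI from red and NIR rasters
#'
#' Per pixel `(nir - red) / (nir + red)`; where the denominator is zero the
#' output is defined as 0.
#'
#' @param red,nir `sc_raster` objects sharing grid and extent.
#' @return an `sc_raster` of NDVI values in `[-1, 1]`.
#' @export
compute_ndvi <- function(red, nir) {
  if (!identical(dim(red$values), dim(nir$values)) ||
      red$cellsize != nir$cellsize ||
      red$xll != nir$xll || red$yll != nir$yll)
    stop("red and NIR rasters must share grid and extent")
  den <- nir$values + red$values
  num <- nir$values - red$values
  out <- ifelse(den == 0, 0, num / den)
  sc_raster(out, xll = red$xll, yll = red$yll, cellsize = red$cellsize)
}

#' Write a raster as ESRI ASCII grid
#'
#' Plain-text georeferenced raster format (`.asc`). Values are written at full
#' double precision so that write/read round-trips are lossless.
#'
#' @param r an `sc_raster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.17g", r$xll),
    sprintf("yllcorner %.17g", r$yll),
    sprintf("cellsize %.17g", r$cellsize),
    "NODATA_value -9999"
  ), con)
  apply_rows <- apply(r$values, 1, function(row)
    paste(sprintf("%.17g", row), collapse = " "))
  writeLines(apply_rows, con)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path path to a `.asc` file written by [write_asc()] or any
#'   conforming writer.
#' @return an `sc_raster`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: '%s'", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop(sprintf("malformed ASCII grid '%s': missing %s",
                                        path, k))
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows)
    stop(sprintf("malformed ASCII grid '%s': expected %d data rows, found %d",
                 path, hdr$nrows, length(body)))
  vals <- t(vapply(body, function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(v) != hdr$ncols)
      stop(sprintf("malformed ASCII grid '%s': row with %d values, expected %d",
                   path, length(v), hdr$ncols))
    v
  }, numeric(hdr$ncols), USE.NAMES = FALSE))
  if (hdr$ncols == 1L) vals <- matrix(as.numeric(vals), ncol = 1L)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals[vals == nodata] <- NA_real_
  sc_raster(vals, xll = hdr$xllcorner, yll = hdr$yllcorner,
            cellsize = hdr$cellsize)
}
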
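#' Build a fishnet grid over an extent
#'
#' Axis-aligned square-cell grid anchored at the extent origin. When the
#' extent is not an exact multiple of the cell size, the ragged last
#' row/column cells are retained with their true (smaller) area, so the cells
#' partition the extent exactly.
#'
#' @param extent named vector `xmin, ymin, xmax, ymax` (metres), e.g. from
#'   [raster_extent()].
#' @param cell_size_m cell side length, default 20 m (400 m2 cells).
#' @return an object of class `fishnet`: list with `origin`, `cell_size_m`,
#'   `n_rows`, `n_cols`, `extent`, and `cells` (data.frame: `cell_id`, `row`,
#'   `col`, `xmin`, `ymin`, `xmax`, `ymax`, `area_m2`, `count`).
#' @export
build_fishnet <- function(extent, cell_size_m = 20) {
  e <- as.list(extent)
  w <- e$xmax - e$xmin; h <- e$ymax - e$ymin
  if (w <= 0 || h <= 0) stop("extent must have positive width and height")
  if (cell_size_m <= 0) stop("cell_size_m must be positive")
  n_cols <- ceiling(w / cell_size_m - 1e-12)
  n_rows <- ceiling(h / cell_size_m - 1e-12)
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  xmin <- e$xmin + (g$col - 1) * cell_size_m
  ymin <- e$ymin + (g$row - 1) * cell_size_m
  xmax <- pmin(xmin + cell_size_m, e$xmax)
  ymax <- pmin(ymin + cell_size_m, e$ymax)
  cells <- data.frame(cell_id = seq_len(nrow(g)), row = g$row, col = g$col,
                      xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
                      area_m2 = (xmax - xmin) * (ymax - ymin),
                      count = NA_integer_)
  structure(list(origin = c(e$xmin, e$ymin), cell_size_m = cell_size_m,
                 n_rows = n_rows, n_cols = n_cols,
                 extent = c(xmin = e$xmin, ymin = e$ymin,
                            xmax = e$xmax, ymax = e$ymax),
                 cells = cells),
            class = "fishnet")
}

#' @export
print.fishnet <- function(x, ...) {
  cat(sprintf("<fishnet> %d x %d cells of %g m (%d cells)\n",
              x$n_rows, x$n_cols, x$cell_size_m, nrow(x$cells)))
  invisible(x)
}

#' Count points per fishnet cell
#'
#' Half-open binning by floor division on coordinates: each point belongs to
#' exactly one cell, so cell counts sum to the number of points.
#'
#' @param points an `lm_points` object (or data.frame with `x`, `y`).
#' @param fishnet a [build_fishnet()] grid covering all points.
#' @return the fishnet with its `cells$count` filled in.
#' @export
count_per_cell <- function(points, fishnet) {
  fn <- fishnet
  e <- fn$extent
  if (nrow(points) > 0) {
    out <- points$x < e["xmin"] | points$x >= e["xmax"] |
           points$y < e["ymin"] | points$y >= e["ymax"]
    if (any(out)) {
      i <- which(out)[1]
      stop(sprintf("point (%g, %g) lies outside the fishnet extent",
                   points$x[i], points$y[i]))
    }
  }
  col <- floor((points$x - e["xmin"]) / fn$cell_size_m) + 1L
  row <- floor((points$y - e["ymin"]) / fn$cell_size_m) + 1L
  id <- (row - 1L) * fn$n_cols + col
  cnt <- tabulate(id, nbins = fn$n_rows * fn$n_cols)
  # cells are ordered row-major with col fastest (expand.grid order)
  fn$cells$count <- cnt[(fn$cells$row - 1L) * fn$n_cols + fn$cells$col]
  fn
}

#' Predict stand density per fishnet cell and rasterize
#'
#' Applies a calibrated [fit_density_model()] per cell: the cell's point
#' count is scaled to a 400 m2 equivalent (ragged edge cells are
#' area-normalised rather than dropped), the model predicts trees per 400 m2,
#' negative predictions are floored at 0, and the result is converted to
#' trees/ha. Cells take the `"unclassified"` model unless a stratum label per
#' cell is supplied via `stratum_mask`.
#'
#' @param fishnet a fishnet with counts (see [count_per_cell()]).
#' @param models named list mapping stratum to `density_model`; must contain
#'   a model for every stratum that occurs.
#' @param stratum_mask optional character vector, one stratum label per cell
#'   (in `cells` order); default all `"unclassified"`.
#' @return list with `fishnet` (cells gain `n_prime_400`, `pred_per_plot`,
#'   `density_ha`, `stratum`) and `raster` (an [sc_raster] of trees/ha at the
#'   fishnet resolution).
#' @export
predict_density <- function(fishnet, models, stratum_mask = NULL) {
  fn <- fishnet
  cells <- fn$cells
  if (any(is.na(cells$count)))
    stop("fishnet has no counts; run count_per_cell() first")
  strat <- if (is.null(stratum_mask)) rep("unclassified", nrow(cells))
           else stratum_mask
  if (length(strat) != nrow(cells))
    stop("stratum_mask must have one label per cell")
  missing_models <- setdiff(unique(strat), names(models))
  if (length(missing_models))
    stop(sprintf("no model configured for stratum: %s",
                 paste(missing_models, collapse = ", ")))
  n400 <- cells$count * 400 / cells$area_m2
  pred <- numeric(nrow(cells))
  for (st in unique(strat)) {
    i <- strat == st
    pred[i] <- predict(models[[st]], n400[i])
  }
  pred <- pmax(pred, 0)
  cells$n_prime_400 <- n400
  cells$pred_per_plot <- pred
  cells$density_ha <- to_trees_per_ha(pred, 400)
  cells$stratum <- strat
  fn$cells <- cells

  # rasterize: matrix row 1 = top (max fishnet row)
  m <- matrix(NA_real_, fn$n_rows, fn$n_cols)
  m[cbind(fn$n_rows - cells$row + 1L, cells$col)] <- cells$density_ha
  r <- sc_raster(m, xll = fn$origin[1], yll = fn$origin[2],
                 cellsize = fn$cell_size_m)
  list(fishnet = fn, raster = r)
}

#' Write fishnet cells as GeoJSON polygons
#'
#' @param fishnet a fishnet (with or without predictions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fishnet_geojson <- function(fishnet, path) {
  cells <- fishnet$cells
  propcols <- setdiff(names(cells), c("xmin", "ymin", "xmax", "ymax"))
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    p <- cells[i, ]
    ring <- list(c(p$xmin, p$ymin), c(p$xmax, p$ymin),
                 c(p$xmax, p$ymax), c(p$xmin, p$ymax), c(p$xmin, p$ymin))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = as.list(p[propcols]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
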
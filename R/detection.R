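#' Spectral local-maximum (tree-top) detection
#'
#' Computes the moving-window maximum of the raster over a `w x w`
#' neighbourhood (clipped at the raster borders, no padding), subtracts it
#' from the original, and returns the pixels where the difference is zero --
#' the candidate crown-apex points. Connected components of equal-valued
#' zero-difference pixels (4-connectivity) are collapsed to a single point at
#' the component pixel nearest the component centroid (ties broken by
#' smallest row, then column), so one flat-topped crown yields one point.
#' Point coordinates are pixel centres in scene metres.
#'
#' @param raster an [sc_raster].
#' @param window_size odd integer >= 3, in pixels of this raster. The
#'   paper-faithful grid is `{3, 5, 7, 9, 11}`; other odd sizes are accepted.
#' @return an `lm_points` object: a data.frame with columns `x`, `y`,
#'   `value` (detection-band value) and `ndvi` (NA until
#'   [filter_by_ndvi()] annotates it), plus attributes `window_size`,
#'   `source_band`, `ndvi_threshold`.
#' @export
local_maxima <- function(raster, window_size) {
  stopifnot(inherits(raster, "sc_raster"))
  w <- window_size
  if (length(w) != 1 || w %% 2 != 1 || w < 3)
    stop("window_size must be an odd integer >= 3")
  v <- raster$values
  if (w > min(dim(v)))
    stop(sprintf("window_size %d exceeds the raster dimension %d",
                 w, min(dim(v))))
  mx <- moving_max(v, w)
  zero <- which(v == mx, arr.ind = TRUE)  # zero-difference pixels

  comp <- collapse_components(zero, v, nrow(v), ncol(v))
  cen <- cell_center(raster, comp$row, comp$col)
  pts <- data.frame(x = cen$x, y = cen$y,
                    value = v[cbind(comp$row, comp$col)],
                    ndvi = NA_real_)
  lm_points(pts, window_size = w, source_band = NA_character_,
            ndvi_threshold = NA_real_)
}

# Moving-window max over a w x w neighbourhood, clipped at borders.
# Separable: running max along rows, then along columns, each by +-h shifts.
moving_max <- function(v, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(v); nc <- ncol(v)
  m <- v
  for (s in seq_len(h)) {           # vertical shifts
    up <- rbind(v[-seq_len(s), , drop = FALSE],
                matrix(-Inf, s, nc))
    dn <- rbind(matrix(-Inf, s, nc),
                v[seq_len(nr - s), , drop = FALSE])
    m <- pmax(m, up, dn)
  }
  m2 <- m
  for (s in seq_len(h)) {           # horizontal shifts
    lf <- cbind(m[, -seq_len(s), drop = FALSE],
                matrix(-Inf, nr, s))
    rt <- cbind(matrix(-Inf, nr, s),
                m[, seq_len(nc - s), drop = FALSE])
    m2 <- pmax(m2, lf, rt)
  }
  m2
}

# Collapse 4-connected components of equal-valued zero-difference pixels to
# their centroid-nearest member pixel.
collapse_components <- function(zero, v, nr, nc) {
  if (nrow(zero) == 0)
    return(list(row = integer(0), col = integer(0)))
  idx <- (zero[, "col"] - 1L) * nr + zero[, "row"]  # linear indices
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)
  edges <- integer(0)
  # right neighbours (same row, col+1)
  r_ok <- zero[, "col"] < nc
  nb <- idx[r_ok] + nr
  keep <- pos[nb] > 0L & v[idx[r_ok]] == v[nb]
  if (any(keep)) edges <- c(edges, rbind(pos[idx[r_ok]][keep], pos[nb][keep]))
  # down neighbours (row+1, same col)
  d_ok <- zero[, "row"] < nr
  nb <- idx[d_ok] + 1L
  keep <- pos[nb] > 0L & v[idx[d_ok]] == v[nb]
  if (any(keep)) edges <- c(edges, rbind(pos[idx[d_ok]][keep], pos[nb][keep]))

  if (length(edges)) {
    g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(idx)
  }
  rows <- zero[, "row"]; cols <- zero[, "col"]
  sizes <- tabulate(memb)
  single <- sizes[memb] == 1L
  out_r <- rows[single]; out_c <- cols[single]
  if (any(!single)) {
    multi <- split(which(!single), memb[!single])
    for (grp in multi) {
      mr <- mean(rows[grp]); mc <- mean(cols[grp])
      d2 <- (rows[grp] - mr)^2 + (cols[grp] - mc)^2
      cand <- grp[d2 == min(d2)]
      cand <- cand[order(rows[cand], cols[cand])][1]
      out_r <- c(out_r, rows[cand]); out_c <- c(out_c, cols[cand])
    }
  }
  o <- order(out_c, out_r)
  list(row = out_r[o], col = out_c[o])
}

lm_points <- function(df, window_size, source_band, ndvi_threshold) {
  structure(df, class = c("lm_points", "data.frame"),
            window_size = window_size, source_band = source_band,
            ndvi_threshold = ndvi_threshold)
}

#' @export
print.lm_points <- function(x, ...) {
  cat(sprintf("<lm_points> %d points (band %s, window %s, NDVI threshold %s)\n",
              nrow(x), attr(x, "source_band"), attr(x, "window_size"),
              attr(x, "ndvi_threshold")))
  invisible(x)
}

#' Remove pseudo crown points by NDVI thresholding
#'
#' Annotates every detected point with the NDVI of the (coarser) NDVI-grid
#' pixel containing its coordinate (nearest-neighbour lookup across grids),
#' then drops points whose NDVI is below the threshold. Points over roads,
#' bare soil or standing dead trees have low NDVI and are removed this way.
#'
#' @param points an `lm_points` object.
#' @param ndvi an [sc_raster] of NDVI covering all point coordinates.
#' @param threshold numeric NDVI threshold in `[-1, 1]`, or `"none"` to only
#'   annotate without filtering.
#' @return the filtered, annotated `lm_points`.
#' @export
filter_by_ndvi <- function(points, ndvi, threshold) {
  stopifnot(inherits(points, "lm_points"), inherits(ndvi, "sc_raster"))
  if (nrow(points) > 0)
    points$ndvi <- raster_value_at(ndvi, points$x, points$y)
  if (identical(threshold, "none")) {
    attr(points, "ndvi_threshold") <- NA_real_
    return(points)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < -1 || threshold > 1)
    stop("threshold must be a number in [-1, 1] or \"none\"")
  keep <- points$ndvi >= threshold
  out <- points[keep, , drop = FALSE]
  lm_points(out, window_size = attr(points, "window_size"),
            source_band = attr(points, "source_band"),
            ndvi_threshold = threshold)
}

#' Detect tree-top points in a scene
#'
#' Composes [local_maxima()] on the selected detection band with
#' [compute_ndvi()] and [filter_by_ndvi()]. Window sizes are expressed in
#' pixels of the detection band, so a 3x3 window spans 1.8 m on the 0.6 m PAN
#' band but 7.2 m on the 2.4 m NIR band.
#'
#' @param scene an `sc_scene` (or any list with `pan`, `red`, `nir` rasters).
#' @param band `"PAN"` or `"NIR"`.
#' @param window_size odd integer >= 3, detection-band pixels.
#' @param ndvi_threshold numeric threshold or `"none"`.
#' @return an `lm_points` object with detection parameters recorded in its
#'   attributes.
#' @export
detect <- function(scene, band = c("PAN", "NIR"), window_size = 3,
                   ndvi_threshold = 0.1) {
  band <- match.arg(band)
  r <- if (band == "PAN") scene$pan else scene$nir
  pts <- local_maxima(r, window_size)
  attr(pts, "source_band") <- band
  ndvi <- compute_ndvi(scene$red, scene$nir)
  out <- filter_by_ndvi(pts, ndvi, ndvi_threshold)
  attr(out, "source_band") <- band
  out
}
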
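#' Count detected points inside a square sample plot
#'
#' Half-open inclusion: a point is inside when `xmin <= x < xmax` and
#' `ymin <= y < ymax`, so adjacent plots or fishnet cells never double-count
#' a point on a shared edge.
#'
#' @param points an `lm_points` object (or data.frame with `x`, `y`).
#' @param polygon named vector or list with `xmin, ymin, xmax, ymax` of an
#'   axis-aligned square plot, metres.
#' @return integer count.
#' @export
count_points_in_plot <- function(points, polygon) {
  p <- as.list(polygon)
  if (p$xmax <= p$xmin || p$ymax <= p$ymin)
    stop("degenerate plot polygon: zero or negative area")
  sum(points$x >= p$xmin & points$x < p$xmax &
      points$y >= p$ymin & points$y < p$ymax)
}

#' Classify a plot's stratum from its tree composition
#'
#' Pure-stand rule with a 70% cut: a plot is `"broadleaf"` when strictly more
#' than 70% of its trees are broadleaf, `"coniferous"` when strictly more
#' than 70% are coniferous, otherwise `"unclassified"`. (Every plot
#' additionally belongs to the unclassified pool when strata are analysed;
#' see [grid_search()].) The forest-inventory rule is defined on stock
#' volume; with no volumes available the tree-count fraction is used with the
#' same cut.
#'
#' @param trees data.frame of trees in the plot with a `stratum` column.
#' @return one of `"coniferous"`, `"broadleaf"`, `"unclassified"`.
#' @export
stratify_plot <- function(trees) {
  n <- nrow(trees)
  if (is.null(n) || n == 0) stop("cannot stratify an empty plot")
  fb <- mean(trees$stratum == "broadleaf")
  fc <- mean(trees$stratum == "coniferous")
  if (fb > 0.70) "broadleaf"
  else if (fc > 0.70) "coniferous"
  else "unclassified"
}

#' Convert a per-plot count to trees per hectare
#'
#' @param count tree (or point) count.
#' @param area_m2 plot area in square metres (400 for a 20 m square plot).
#' @return density in trees/ha: `count * 10000 / area_m2`.
#' @examples
#' to_trees_per_ha(27, 400)   # 675
#' to_trees_per_ha(110, 400)  # 2750
#' @export
to_trees_per_ha <- function(count, area_m2) {
  if (any(area_m2 <= 0)) stop("area_m2 must be positive")
  count * 10000 / area_m2
}

#' Build the plot observation table for one detection parameter combination
#'
#' Runs [detect()] once on the scene and counts surviving points inside every
#' sample plot, joining the detected count N' (the NSLMP) to the true count
#' NT from the scene's ground truth.
#'
#' @param scene an `sc_scene`.
#' @param band,window_size,ndvi_threshold detection parameters (see
#'   [detect()]).
#' @return data.frame with one row per plot: `plot_id`, `stratum`, `nt`,
#'   `n_prime`, `area_m2`.
#' @export
build_observation_table <- function(scene, band = "PAN", window_size = 3,
                                    ndvi_threshold = 0.1) {
  pts <- detect(scene, band, window_size, ndvi_threshold)
  observation_table(scene$plots, pts)
}

# Join an already-detected point set to the plot truth.
observation_table <- function(plots, pts) {
  n_prime <- vapply(seq_len(nrow(plots)), function(k)
    count_points_in_plot(pts, plots[k, c("xmin", "ymin", "xmax", "ymax")]),
    integer(1))
  data.frame(plot_id = plots$plot_id, stratum = plots$stratum,
             nt = plots$nt, n_prime = n_prime,
             area_m2 = (plots$xmax - plots$xmin) * (plots$ymax - plots$ymin),
             stringsAsFactors = FALSE)
}
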
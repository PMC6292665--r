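#' Write a scene to a directory
#'
#' Writes `pan.asc`, `red.asc`, `nir.asc` (ESRI ASCII grids), `trees.geojson`
#' (point features with `stratum`, `alive`, `crown_ns`, `crown_ew`,
#' `plot_id`), `plots.geojson` (square polygon features with `plot_id`,
#' `stratum`, `nt`), `plots.csv` (plot table) and `params.json`. The file set
#' round-trips losslessly through [read_scene()].
#'
#' @param scene an `sc_scene`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "sc_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_asc(scene$pan, file.path(dir, "pan.asc"))
  write_asc(scene$red, file.path(dir, "red.asc"))
  write_asc(scene$nir, file.path(dir, "nir.asc"))
  write_trees_geojson(scene$trees, file.path(dir, "trees.geojson"))
  write_plots_geojson(scene$plots, file.path(dir, "plots.geojson"))
  utils::write.csv(scene$plots[, c("plot_id", "stratum", "nt")],
                   file.path(dir, "plots.csv"), row.names = FALSE)
  pj <- scene$params; class(pj) <- NULL
  jsonlite::write_json(pj, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene from a directory written by [write_scene()]
#'
#' @param dir scene directory.
#' @return an `sc_scene`.
#' @export
read_scene <- function(dir) {
  for (f in c("pan.asc", "red.asc", "nir.asc", "trees.geojson",
              "plots.geojson", "params.json"))
    if (!file.exists(file.path(dir, f)))
      stop(sprintf("scene directory '%s' is missing '%s'", dir, f))
  pj <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  params <- scene_params(
    n_plots = pj$n_plots, stratum_mix = pj$stratum_mix,
    density_moments = pj$density_moments, conifer_crown = pj$conifer_crown,
    broadleaf_crown = pj$broadleaf_crown, plot_side_m = pj$plot_side_m,
    pan_pixel_m = pj$pan_pixel_m, ms_pixel_m = pj$ms_pixel_m,
    extent_m = pj$extent_m, noise_sd = pj$noise_sd,
    road_fraction = pj$road_fraction, dead_fraction = pj$dead_fraction,
    purity = pj$purity, min_separation_m = pj$min_separation_m,
    edge_margin_m = pj$edge_margin_m, seed = pj$seed)
  structure(list(
    pan = read_asc(file.path(dir, "pan.asc")),
    red = read_asc(file.path(dir, "red.asc")),
    nir = read_asc(file.path(dir, "nir.asc")),
    trees = read_trees_geojson(file.path(dir, "trees.geojson")),
    plots = read_plots_geojson(file.path(dir, "plots.geojson")),
    params = params), class = "sc_scene")
}

write_trees_geojson <- function(trees, path) {
  feats <- lapply(seq_len(nrow(trees)), function(i) {
    tr <- trees[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(tr$x, tr$y)),
         properties = list(stratum = tr$stratum,
                           alive = tr$alive,
                           crown_ns = tr$crown_ns,
                           crown_ew = tr$crown_ew,
                           plot_id = tr$plot_id))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_trees_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (length(fc$features) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      crown_ns = numeric(0), crown_ew = numeric(0),
                      stratum = character(0), alive = logical(0),
                      plot_id = integer(0), stringsAsFactors = FALSE))
  rows <- lapply(fc$features, function(f) {
    data.frame(x = f$geometry$coordinates[[1]],
               y = f$geometry$coordinates[[2]],
               crown_ns = f$properties$crown_ns,
               crown_ew = f$properties$crown_ew,
               stratum = f$properties$stratum,
               alive = f$properties$alive,
               plot_id = f$properties$plot_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_plots_geojson <- function(plots, path) {
  feats <- lapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    ring <- list(c(p$xmin, p$ymin), c(p$xmax, p$ymin),
                 c(p$xmax, p$ymax), c(p$xmin, p$ymax),
                 c(p$xmin, p$ymin))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(plot_id = p$plot_id, stratum = p$stratum,
                           nt = p$nt))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_plots_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (length(fc$features) == 0)
    return(data.frame(plot_id = integer(0), xmin = numeric(0),
                      ymin = numeric(0), xmax = numeric(0), ymax = numeric(0),
                      stratum = character(0), nt = integer(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(c) as.numeric(c[[1]]), numeric(1))
    ys <- vapply(ring, function(c) as.numeric(c[[2]]), numeric(1))
    data.frame(plot_id = f$properties$plot_id,
               xmin = min(xs), ymin = min(ys),
               xmax = max(xs), ymax = max(ys),
               stratum = f$properties$stratum,
               nt = as.integer(f$properties$nt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
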
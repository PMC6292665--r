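#' Synthetic scene parameters
#'
#' Bundles every knob of the synthetic forest-scene generator. Defaults
#' reproduce the statistical structure of the field campaign the pipeline is
#' designed for: 400 m2 square plots whose per-plot tree counts have mean 27,
#' SD 20, range 4-110 trees (i.e. mean 675, SD 500, range 100-2750 trees/ha);
#' conifer crown diameters mean 2.68 m (N-S) / 2.95 m (E-W), SD 0.96 m,
#' truncated to [1.38, 6.61] m; broadleaf crowns mean 3.63 / 3.79 m, SD
#' 1.52 m. Imagery is a 0.6 m panchromatic band plus 2.4 m red and NIR bands.
#'
#' Plots are placed on a 40 m slot lattice whose plot corners are multiples of
#' 20 m, so each plot coincides exactly with one cell of the default 20 m
#' fishnet; the extent is sized automatically (a multiple of the 2.4 m MS
#' pixel) when not supplied.
#'
#' @param n_plots number of square sample plots.
#' @param stratum_mix fraction of plots whose dominant species group is
#'   coniferous (the default 26/73 mirrors a 26-conifer / 45-broadleaf /
#'   73-plot design).
#' @param density_moments `c(mean, sd, min, max)` trees per plot; counts are
#'   drawn from a normal truncated to `[min, max]` and rounded.
#' @param conifer_crown `c(mean_ns, mean_ew, sd, min, max)` crown diameters, m.
#' @param broadleaf_crown `c(mean_ns, mean_ew, sd)` crown diameters, m
#'   (truncated to `[1, 9]` m).
#' @param plot_side_m plot side length, m (400 m2 default).
#' @param pan_pixel_m,ms_pixel_m pixel sizes of the PAN and multispectral
#'   grids; `ms_pixel_m` must be an exact integer multiple of `pan_pixel_m`.
#' @param extent_m scene side lengths `c(width, height)` in m, or `NULL` to
#'   size automatically from `n_plots`.
#' @param noise_sd standard deviation of i.i.d. Gaussian sensor noise added to
#'   every latent 0.6 m band (reflectance units).
#' @param road_fraction approximate fraction of the scene covered by bright,
#'   low-NDVI road strips (placed in the corridors between plots).
#' @param dead_fraction fraction of trees rendered as standing dead: bright in
#'   PAN but background-level NIR, so they yield pseudo crown points that NDVI
#'   filtering must remove.
#' @param purity probability that a tree inherits its plot's dominant stratum
#'   (the remainder belongs to the other species group).
#' @param min_separation_m minimum stem-to-stem distance enforced by rejection
#'   sampling.
#' @param edge_margin_m stems are inset from the plot boundary by this margin
#'   (one PAN pixel by default) so a crown apex pixel cannot fall outside its
#'   plot.
#' @param seed integer seed; every stochastic draw in the generator flows from
#'   it.
#' @return an object of class `scene_params` (a validated list).
#' @export
scene_params <- function(n_plots = 73,
                         stratum_mix = 26 / 73,
                         density_moments = c(mean = 27, sd = 20, min = 4, max = 110),
                         conifer_crown = c(mean_ns = 2.68, mean_ew = 2.95,
                                           sd = 0.96, min = 1.38, max = 6.61),
                         broadleaf_crown = c(mean_ns = 3.63, mean_ew = 3.79,
                                             sd = 1.52),
                         plot_side_m = 20,
                         pan_pixel_m = 0.6,
                         ms_pixel_m = 2.4,
                         extent_m = NULL,
                         noise_sd = 0.02,
                         road_fraction = 0.05,
                         dead_fraction = 0.03,
                         purity = 0.9,
                         min_separation_m = 1.2,
                         edge_margin_m = 0.6,
                         seed = 1L) {
  dm <- unname(density_moments)
  if (length(dm) != 4) stop("density_moments must be c(mean, sd, min, max)")
  if (!(dm[3] <= dm[1] && dm[1] <= dm[4]))
    stop("density_moments must satisfy min <= mean <= max")
  if (dm[3] < 1) stop("minimum per-plot count must be >= 1")
  ratio <- ms_pixel_m / pan_pixel_m
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("pan_pixel_m must divide ms_pixel_m exactly")
  if (n_plots < 1) stop("n_plots must be >= 1")
  if (stratum_mix < 0 || stratum_mix > 1) stop("stratum_mix must be in [0, 1]")

  slot <- 2 * plot_side_m         # plot + equal-width buffer corridor
  s <- ceiling(sqrt(n_plots))
  if (is.null(extent_m)) {
    side <- s * slot + plot_side_m + 4 * pan_pixel_m
    # round the side up to a common multiple of both pixel sizes
    side <- ceiling(side / ms_pixel_m) * ms_pixel_m
    extent_m <- c(side, side)
  }
  if (any(abs(extent_m - round(extent_m / ms_pixel_m) * ms_pixel_m) > 1e-6))
    stop("extent_m must be a multiple of ms_pixel_m")
  n_slots_x <- floor((extent_m[1] - plot_side_m) / slot)
  n_slots_y <- floor((extent_m[2] - plot_side_m) / slot)
  if (n_slots_x * n_slots_y < n_plots)
    stop(sprintf("extent %g x %g m has room for %d non-overlapping plots; %d requested",
                 extent_m[1], extent_m[2], n_slots_x * n_slots_y, n_plots))

  structure(list(
    n_plots = as.integer(n_plots), stratum_mix = stratum_mix,
    density_moments = dm, conifer_crown = unname(conifer_crown),
    broadleaf_crown = unname(broadleaf_crown),
    plot_side_m = plot_side_m, pan_pixel_m = pan_pixel_m,
    ms_pixel_m = ms_pixel_m, extent_m = unname(extent_m),
    noise_sd = noise_sd, road_fraction = road_fraction,
    dead_fraction = dead_fraction, purity = purity,
    min_separation_m = min_separation_m, edge_margin_m = edge_margin_m,
    seed = as.integer(seed)
  ), class = "scene_params")
}

# Exact truncated-normal sampler (inverse-CDF), vectorised.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate ground truth: trees and sample plots
#'
#' Draws plot locations, per-plot tree counts (truncated normal with the
#' configured moments, rounded and clipped to `[min, max]`), per-tree strata,
#' crown diameters (per-stratum truncated normals), live/dead flags, and stem
#' positions (uniform within the inset plot interior under a minimum-separation
#' rejection rule).
#'
#' @param params a [scene_params()] object.
#' @return list with elements `trees` (data.frame: `x, y, crown_ns, crown_ew,
#'   stratum, alive, plot_id`) and `plots` (data.frame: `plot_id, xmin, ymin,
#'   xmax, ymax, stratum, nt`). A plot's `stratum` is its realised composition
#'   class under the 70% pure-stand rule; `nt` counts live stems inside the
#'   polygon (half-open rule).
#' @export
generate_forest <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  p <- params
  slot <- 2 * p$plot_side_m
  n_slots_x <- floor((p$extent_m[1] - p$plot_side_m) / slot)
  n_slots_y <- floor((p$extent_m[2] - p$plot_side_m) / slot)
  slots <- expand.grid(i = seq_len(n_slots_x) - 1L, j = seq_len(n_slots_y) - 1L)
  pick <- sample(nrow(slots), p$n_plots)
  # plot corner at (side, side) offset into the slot -> corners are multiples
  # of plot_side_m, aligning every plot with one fishnet cell
  xmin <- slots$i[pick] * slot + p$plot_side_m
  ymin <- slots$j[pick] * slot + p$plot_side_m

  n_con <- round(p$stratum_mix * p$n_plots)
  dominant <- rep("broadleaf", p$n_plots)
  dominant[sample(p$n_plots, n_con)] <- "coniferous"

  dm <- p$density_moments
  counts <- rtruncnorm(p$n_plots, dm[1], dm[2], dm[3], dm[4])
  counts <- pmin(pmax(round(counts), dm[3]), dm[4])

  trees <- vector("list", p$n_plots)
  for (k in seq_len(p$n_plots)) {
    nk <- counts[k]
    pos <- place_stems(nk,
                       xmin[k] + p$edge_margin_m, xmin[k] + p$plot_side_m - p$edge_margin_m,
                       ymin[k] + p$edge_margin_m, ymin[k] + p$plot_side_m - p$edge_margin_m,
                       p$min_separation_m)
    strat <- ifelse(stats::runif(nk) < p$purity, dominant[k],
                    ifelse(dominant[k] == "coniferous", "broadleaf", "coniferous"))
    cc <- p$conifer_crown; bc <- p$broadleaf_crown
    is_con <- strat == "coniferous"
    crown_ns <- numeric(nk); crown_ew <- numeric(nk)
    crown_ns[is_con]  <- rtruncnorm(sum(is_con), cc[1], cc[3], cc[4], cc[5])
    crown_ew[is_con]  <- rtruncnorm(sum(is_con), cc[2], cc[3], cc[4], cc[5])
    crown_ns[!is_con] <- rtruncnorm(sum(!is_con), bc[1], bc[3], 1.0, 9.0)
    crown_ew[!is_con] <- rtruncnorm(sum(!is_con), bc[2], bc[3], 1.0, 9.0)
    trees[[k]] <- data.frame(
      x = pos$x, y = pos$y, crown_ns = crown_ns, crown_ew = crown_ew,
      stratum = strat, alive = stats::runif(nk) >= p$dead_fraction,
      plot_id = k, stringsAsFactors = FALSE)
  }
  trees <- do.call(rbind, trees)

  plots <- data.frame(
    plot_id = seq_len(p$n_plots),
    xmin = xmin, ymin = ymin,
    xmax = xmin + p$plot_side_m, ymax = ymin + p$plot_side_m,
    stringsAsFactors = FALSE)
  plots$stratum <- vapply(seq_len(p$n_plots), function(k) {
    tr <- trees[trees$plot_id == k & trees$alive, , drop = FALSE]
    if (nrow(tr) == 0) "unclassified" else stratify_plot(tr)
  }, character(1))
  plots$nt <- vapply(seq_len(p$n_plots), function(k) {
    tr <- trees[trees$plot_id == k & trees$alive, , drop = FALSE]
    sum(tr$x >= plots$xmin[k] & tr$x < plots$xmax[k] &
        tr$y >= plots$ymin[k] & tr$y < plots$ymax[k])
  }, integer(1))
  list(trees = trees, plots = plots)
}

# Uniform placement with a minimum-separation rejection rule. If the density
# is too high for the separation to be satisfiable the constraint is relaxed
# for the offending stem after `max_try` attempts (positions stay uniform).
place_stems <- function(n, xmin, xmax, ymin, ymax, min_sep, max_try = 200L) {
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_try)) {
      cx <- stats::runif(1, xmin, xmax)
      cy <- stats::runif(1, ymin, ymax)
      if (i == 1 || all((x[seq_len(i - 1)] - cx)^2 +
                        (y[seq_len(i - 1)] - cy)^2 >= min_sep^2)) {
        ok <- TRUE; break
      }
    }
    x[i] <- cx; y[i] <- cy
    if (!ok) next  # separation relaxed for this stem
  }
  list(x = x, y = y)
}

#' Render a synthetic scene to PAN / red / NIR rasters
#'
#' Conifer crowns are radially symmetric cosine-tapered brightness peaks (a
#' single strict maximum at the apex); broadleaf crowns are sums of 1-3 offset
#' Gaussian lobes with amplitude jitter, so a single crown can produce more
#' than one spectral local maximum. Live crowns are bright in NIR and dark in
#' red (NDVI around 0.8 at the apex); standing dead crowns keep their PAN
#' brightness but stay at background level in red and NIR (NDVI about 0).
#' Background soil and road strips have NDVI below 0.1. Gaussian noise of sd
#' `noise_sd` is added to every latent 0.6 m band; red and NIR are then
#' aggregated to the MS grid as 4x4 block means.
#'
#' @param trees,plots output of [generate_forest()].
#' @param params the same [scene_params()] object.
#' @return an object of class `sc_scene`: list with `pan`, `red`, `nir`
#'   ([sc_raster] objects), `trees`, `plots`, `params`.
#' @export
render_scene <- function(trees, plots, params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  set.seed(p$seed + 500009L)  # independent stream from generate_forest()
  if (nrow(trees) > 0 &&
      (any(trees$x < 0 | trees$x > p$extent_m[1]) ||
       any(trees$y < 0 | trees$y > p$extent_m[2])))
    stop("trees must lie within the scene extent")

  px <- p$pan_pixel_m
  nc <- round(p$extent_m[1] / px)
  nr <- round(p$extent_m[2] / px)

  # Soil background is spectrally flat (NDVI = 0) and dark relative to
  # canopy NIR, so that even the smallest crown (1.38 m) with its apex on an
  # MS pixel corner still lifts that pixel's NDVI above 0.1.
  bg_pan <- 0.10; bg_red <- 0.06; bg_nir <- 0.06
  pan <- matrix(bg_pan, nr, nc)
  red <- matrix(bg_red, nr, nc)
  nir <- matrix(bg_nir, nr, nc)

  # road strips in the corridors between plot slots (never through a plot)
  slot <- 2 * p$plot_side_m
  road_w <- 4
  n_corr <- floor(p$extent_m[2] / slot)
  n_roads <- min(n_corr, round(p$road_fraction * p$extent_m[2] / road_w))
  if (n_roads > 0 && n_corr > 0) {
    centers <- (sample(n_corr, n_roads) - 1L) * slot + p$plot_side_m / 2
    for (cy in centers) {
      rows <- row_range(nr, px, cy - road_w / 2, cy + road_w / 2)
      pan[rows, ] <- 0.30
      red[rows, ] <- 0.25
      nir[rows, ] <- 0.20
    }
  }

  # per-pixel-centre coordinates helper: col j centre x = (j-0.5)*px,
  # row i centre y = (nr-i+0.5)*px
  if (nrow(trees) > 0) for (i in seq_len(nrow(trees))) {
    tr <- trees[i, ]
    rx <- tr$crown_ew / 2; ry <- tr$crown_ns / 2
    cols <- seq(max(1L, floor((tr$x - rx) / px)),
                min(nc, ceiling((tr$x + rx) / px)))
    rows <- seq(max(1L, nr - ceiling((tr$y + ry) / px) + 1L),
                min(nr, nr - floor((tr$y - ry) / px)))
    if (!length(cols) || !length(rows)) next
    cxs <- (cols - 0.5) * px
    cys <- (nr - rows + 0.5) * px
    dx <- outer(rep(1, length(rows)), (cxs - tr$x) / rx)
    dy <- outer(cys - tr$y, rep(1, length(cols))) / ry
    rn <- sqrt(dx^2 + dy^2)
    if (tr$stratum == "coniferous") {
      f <- ifelse(rn < 1, cos(pi / 2 * rn)^2, 0)
    } else {
      nlobe <- sample(1:3, 1)
      f <- matrix(0, length(rows), length(cols))
      for (l in seq_len(nlobe)) {
        ox <- stats::runif(1, -0.4, 0.4); oy <- stats::runif(1, -0.4, 0.4)
        amp <- stats::runif(1, 0.6, 1.0)
        sig <- stats::runif(1, 0.25, 0.45)
        rl2 <- (dx - ox)^2 + (dy - oy)^2
        f <- pmax(f, amp * exp(-rl2 / (2 * sig^2)))
      }
      f[rn >= 1] <- 0
    }
    pan[rows, cols] <- pan[rows, cols] + 0.25 * f
    if (tr$alive) {
      nir[rows, cols] <- nir[rows, cols] + 0.80 * f
      red[rows, cols] <- pmax(red[rows, cols] - 0.05 * f, 0.01)
    }
  }

  if (p$noise_sd > 0) {
    pan <- pan + matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc)
    red <- red + matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc)
    nir <- nir + matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc)
  }

  fac <- as.integer(round(p$ms_pixel_m / p$pan_pixel_m))
  pan_r <- sc_raster(pan, 0, 0, px)
  red_r <- block_mean(sc_raster(red, 0, 0, px), fac)
  nir_r <- block_mean(sc_raster(nir, 0, 0, px), fac)

  structure(list(pan = pan_r, red = red_r, nir = nir_r,
                 trees = trees, plots = plots, params = p),
            class = "sc_scene")
}

# rows of the PAN matrix whose pixel centres fall in [y0, y1)
row_range <- function(nr, px, y0, y1) {
  ys <- (nr - seq_len(nr) + 0.5) * px
  which(ys >= y0 & ys < y1)
}

#' Generate and render a synthetic scene in one call
#'
#' @param params a [scene_params()] object.
#' @return an `sc_scene` (see [render_scene()]).
#' @export
simulate_scene <- function(params = scene_params()) {
  gt <- generate_forest(params)
  render_scene(gt$trees, gt$plots, params)
}

#' @export
print.sc_scene <- function(x, ...) {
  cat(sprintf("<sc_scene> %d trees in %d plots, extent %g x %g m, seed %d\n",
              nrow(x$trees), nrow(x$plots),
              x$params$extent_m[1], x$params$extent_m[2], x$params$seed))
  invisible(x)
}
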
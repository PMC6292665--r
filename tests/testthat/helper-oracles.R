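# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (per-pixel scans, explicit summations, direct
# normal-equations solves) so they never share code paths with the package.

# Exhaustive per-pixel local-maxima oracle with clipped windows. Returns a
# two-column matrix (row, col) of zero-difference pixels, sorted. Intended
# for rasters with all-distinct values (components are singletons).
oracle_local_maxima <- function(v, w) {
  h <- (w - 1) %/% 2
  nr <- nrow(v); nc <- ncol(v)
  hits <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    win <- v[max(1, i - h):min(nr, i + h), max(1, j - h):min(nc, j + h)]
    if (v[i, j] == max(win)) hits <- rbind(hits, c(i, j))
  }
  hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
}

# Convert lm_points coordinates back to (row, col) pixel indices of the
# source raster (points sit at pixel centres).
points_to_rc <- function(pts, raster) {
  cs <- raster$cellsize
  nr <- nrow(raster$values)
  col <- as.integer(round((pts$x - raster$xll) / cs + 0.5))
  row <- as.integer(nr - round((pts$y - raster$yll) / cs - 0.5))
  cbind(row, col)
}

# Mean of a normal(mean, sd) truncated to [lo, hi] (closed form).
oracle_truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / Z
}

# SD of the same truncated normal.
oracle_truncnorm_sd <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  m1 <- (dnorm(a) - dnorm(b)) / Z
  v <- 1 + (a * dnorm(a) - b * dnorm(b)) / Z - m1^2
  sd * sqrt(v)
}

# Direct-summation Pearson r (no calls into the package or to cor()).
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# OLS by explicit normal equations for nt ~ poly(n_prime, degree).
oracle_ols <- function(x, y, degree) {
  X <- cbind(1, x)
  if (degree == 2) X <- cbind(X, x^2)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# Brute-force LOOCV predictions via the normal-equations solver.
oracle_loocv_preds <- function(x, y, degree) {
  n <- length(x)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    b <- oracle_ols(x[-i], y[-i], degree)
    preds[i] <- if (degree == 1) b[1] + b[2] * x[i]
                else b[1] + b[2] * x[i] + b[3] * x[i]^2
  }
  preds
}

# Small scene parameter sets used across tests (kept tiny for speed).
small_params <- function(...) {
  scene_params(n_plots = 9, ...)
}

# Noise-free conifer-only scene with widely separated crowns: the regime in
# which detection must be exact (N' = NT in every plot).
separated_conifer_params <- function(seed = 1, n_plots = 9, k = 3) {
  scene_params(n_plots = n_plots, stratum_mix = 1, purity = 1,
               density_moments = c(k, 0, k, k),
               noise_sd = 0, road_fraction = 0, dead_fraction = 0,
               min_separation_m = 8, edge_margin_m = 1, seed = seed)
}
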
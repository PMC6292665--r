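#' Pearson correlation with a two-tailed t test
#'
#' Sample Pearson coefficient between `x` and `y`; significance from the
#' two-tailed t test with `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("undefined correlation: zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Build observation tables for a grid of detection parameter combinations
#'
#' Efficiently evaluates every band x window-size x NDVI-threshold
#' combination: the local-maxima pass and the NDVI annotation are computed
#' once per (band, window) and the thresholds are applied as filters of the
#' same annotated point set.
#'
#' @param scene an `sc_scene`.
#' @param bands character vector from `c("PAN", "NIR")`.
#' @param windows odd window sizes in detection-band pixels.
#' @param thresholds NDVI thresholds.
#' @return list of combinations, each a list with `band`, `window`,
#'   `threshold` and `table` (see [build_observation_table()]).
#' @export
detection_grid <- function(scene, bands = c("PAN", "NIR"),
                           windows = c(3, 5, 7, 9, 11),
                           thresholds = seq(0.1, 0.5, by = 0.1)) {
  ndvi <- compute_ndvi(scene$red, scene$nir)
  out <- list()
  for (band in bands) {
    r <- if (band == "PAN") scene$pan else scene$nir
    for (w in windows) {
      pts <- local_maxima(r, w)
      attr(pts, "source_band") <- band
      pts <- filter_by_ndvi(pts, ndvi, "none")  # annotate once
      for (th in thresholds) {
        keep <- pts[pts$ndvi >= th, , drop = FALSE]
        keep <- lm_points(keep, window_size = w, source_band = band,
                          ndvi_threshold = th)
        out[[length(out) + 1L]] <- list(
          band = band, window = w, threshold = th,
          table = observation_table(scene$plots, keep))
      }
    }
  }
  out
}

#' Grid search over detection parameter combinations by Pearson correlation
#'
#' For every combination and stratum, correlates the detected per-plot count
#' N' with the true count NT over the stratum's plots. The unclassified
#' stratum pools all plots; the pure strata use only plots classified to
#' them. The best combination per stratum is the one with maximal `r` among
#' significant cells (p < 0.05); when no cell is significant the maximal-r
#' cell is returned flagged non-significant. Cells ranked by `r`, not `|r|`:
#' the count-density relationship is physically positive.
#'
#' @param combos output of [detection_grid()] (or any list of combinations
#'   with per-plot observation tables).
#' @param strata strata to evaluate.
#' @param alpha significance level for the two-tailed t test.
#' @return list with `cells` (data.frame: band, window, threshold, stratum,
#'   n, r, p, significant) and `best` (named list per stratum: the best row,
#'   or `NULL` when every cell is degenerate).
#' @export
grid_search <- function(combos,
                        strata = c("coniferous", "broadleaf", "unclassified"),
                        alpha = 0.05) {
  rows <- list()
  for (cmb in combos) {
    tab <- cmb$table
    for (st in strata) {
      sub <- if (st == "unclassified") tab else tab[tab$stratum == st, ]
      n <- nrow(sub)
      if (n < 3) {
        warning(sprintf("stratum '%s' has %d plots (<3); skipped", st, n))
        next
      }
      cell <- list(band = cmb$band, window = cmb$window,
                   threshold = cmb$threshold, stratum = st, n = n,
                   r = NA_real_, p = NA_real_, significant = FALSE)
      if (stats::sd(sub$n_prime) > 0 && stats::sd(sub$nt) > 0) {
        pr <- pearson_r(sub$n_prime, sub$nt)
        cell$r <- pr$r; cell$p <- pr$p
        cell$significant <- pr$p < alpha
      }
      rows[[length(rows) + 1L]] <- cell
    }
  }
  cells <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    data.frame(band = character(0), window = numeric(0),
               threshold = numeric(0), stratum = character(0),
               n = integer(0), r = numeric(0), p = numeric(0),
               significant = logical(0))
  }
  best <- list()
  for (st in strata) {
    sub <- cells[cells$stratum == st & !is.na(cells$r), , drop = FALSE]
    if (nrow(sub) == 0) { best[st] <- list(NULL); next }  # explicit "none"
    sig <- sub[sub$significant, , drop = FALSE]
    pool <- if (nrow(sig) > 0) sig else sub
    best[[st]] <- pool[which.max(pool$r), , drop = FALSE]
  }
  list(cells = cells, best = best)
}

#' Fit a stand-density regression model
#'
#' Ordinary least squares of the true per-plot count NT on the detected count
#' N': `nt ~ n_prime` (linear) or `nt ~ n_prime + n_prime^2` (quadratic, the
#' "non-linear" form: a second-order polynomial, consistent with two model
#' degrees of freedom). Reports R2, RMSE = sqrt(SSE/n) in trees per plot, the
#' overall F statistic with its p-value and degrees of freedom, the
#' Shapiro-Wilk p of the residuals (advisory: the fit is reported
#' regardless), and leave-one-out cross-validation scores when `n >= 5`.
#'
#' @param obs observation table (see [build_observation_table()]) with
#'   columns `nt` and `n_prime`.
#' @param form `"quadratic"` (default) or `"linear"`.
#' @param stratum optional stratum label stored on the model.
#' @param cv compute LOOCV scores (default TRUE when `n >= 5`).
#' @return an object of class `density_model`.
#' @export
fit_density_model <- function(obs, form = c("quadratic", "linear"),
                              stratum = "unclassified", cv = TRUE) {
  form <- match.arg(form)
  n <- nrow(obs)
  k <- if (form == "linear") 1L else 2L
  if (n < k + 2) stop(sprintf("need at least %d observations for a %s fit",
                              k + 2, form))
  if (stats::sd(obs$n_prime) == 0)
    stop("singular fit: n_prime is constant")
  fit <- if (form == "linear") {
    stats::lm(nt ~ n_prime, data = obs)
  } else {
    stats::lm(nt ~ n_prime + I(n_prime^2), data = obs)
  }
  if (fit$rank < k + 1) stop("singular fit: rank-deficient design")
  sm <- summary(fit)
  res <- stats::residuals(fit)
  fstat <- sm$fstatistic
  shapiro_p <- if (n >= 3 && stats::sd(res) > 0)
    stats::shapiro.test(res)$p.value else NA_real_
  model <- structure(list(
    stratum = stratum, form = form,
    coefficients = unname(stats::coef(fit)),
    r_squared = sm$r.squared,
    rmse = sqrt(sum(res^2) / n),
    f_stat = unname(fstat[1]),
    p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
    dof = c(model = k, residual = n - k - 1L),
    shapiro_p = shapiro_p,
    n = n, r2_cv = NA_real_, rmse_cv = NA_real_,
    std_errors = unname(sm$coefficients[, "Std. Error"])
  ), class = "density_model")
  if (cv && n >= 5) {
    sc <- loocv(obs, form)
    model$r2_cv <- sc$r2_cv
    model$rmse_cv <- sc$rmse_cv
  }
  model
}

#' Predict per-plot tree counts from detected counts
#'
#' @param object a `density_model`.
#' @param n_prime vector of detected counts (per 400 m2 plot equivalent).
#' @param ... unused.
#' @return predicted NT per plot (not floored; mapping floors at 0).
#' @export
predict.density_model <- function(object, n_prime, ...) {
  b <- object$coefficients
  if (object$form == "linear") b[1] + b[2] * n_prime
  else b[1] + b[2] * n_prime + b[3] * n_prime^2
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model> %s %s: coef = (%s)\n  R2 = %.4f, RMSE = %.2f trees/plot, F = %.2f (df %d, %d), p = %.3g\n  Shapiro-Wilk p = %.3g, LOOCV r2_cv = %.4f, RMSEcv = %.2f\n",
              x$stratum, x$form,
              paste(sprintf("%.4g", x$coefficients), collapse = ", "),
              x$r_squared, x$rmse, x$f_stat, x$dof[1], x$dof[2], x$p_value,
              x$shapiro_p, x$r2_cv, x$rmse_cv))
  invisible(x)
}

#' Leave-one-out cross-validation of a density regression
#'
#' For each observation `i` the model is refit on the other `n - 1`
#' observations and used to predict observation `i`. Summaries:
#' `r2_cv = 1 - PRESS / SS_tot` and `rmse_cv = sqrt(PRESS / n)`.
#'
#' @param obs observation table with `nt` and `n_prime`; `n >= 5`.
#' @param form `"quadratic"` or `"linear"`.
#' @return list with `r2_cv`, `rmse_cv` and the vector of held-out
#'   `predictions`.
#' @export
loocv <- function(obs, form = c("quadratic", "linear")) {
  form <- match.arg(form)
  n <- nrow(obs)
  if (n < 5) stop("LOOCV requires at least 5 observations")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    train <- obs[-i, , drop = FALSE]
    fit <- tryCatch(
      fit_density_model(train, form, cv = FALSE),
      error = function(e)
        stop(sprintf("leave-one-out fit without observation %d failed: %s",
                     i, conditionMessage(e))))
    preds[i] <- predict(fit, obs$n_prime[i])
  }
  press <- sum((obs$nt - preds)^2)
  ss_tot <- sum((obs$nt - mean(obs$nt))^2)
  list(r2_cv = 1 - press / ss_tot, rmse_cv = sqrt(press / n),
       predictions = preds)
}
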
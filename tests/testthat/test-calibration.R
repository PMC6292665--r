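test_that("pearson_r handles exact linear relations and matches the oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(x, 2 * x + 1)$p, 0)
  set.seed(13)
  for (rep in 1:5) {
    a <- rnorm(20); b <- 0.5 * a + rnorm(20)
    pr <- pearson_r(a, b)
    expect_equal(pr$r, oracle_pearson(a, b), tolerance = 1e-12)
    # p agrees with the textbook two-tailed t transform
    t <- pr$r * sqrt(18 / (1 - pr$r^2))
    expect_equal(pr$p, 2 * pt(-abs(t), 18), tolerance = 1e-12)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("p-values shrink as |r| grows at fixed n", {
  set.seed(17)
  x <- rnorm(30)
  ps <- vapply(c(0.3, 0.8, 2, 5), function(b) {
    y <- b * x + rnorm(30, sd = 1)
    pearson_r(x, y)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

make_combo <- function(band, window, threshold, tab)
  list(band = band, window = window, threshold = threshold, table = tab)

test_that("grid search selects the exact-count combination with r = 1", {
  set.seed(23)
  nt <- rpois(12, 20) + 1
  tab_perfect <- data.frame(plot_id = 1:12, stratum = "coniferous",
                            nt = nt, n_prime = nt, area_m2 = 400)
  tab_noisy <- tab_perfect
  tab_noisy$n_prime <- nt + rpois(12, 6)
  gs <- grid_search(list(make_combo("PAN", 3, 0.3, tab_perfect),
                         make_combo("PAN", 5, 0.1, tab_noisy)),
                    strata = "coniferous")
  expect_equal(nrow(gs$cells), 2)
  b <- gs$best$coniferous
  expect_equal(b$window, 3)
  expect_equal(b$r, 1)
  expect_true(b$significant)
})

test_that("degenerate constant counts give NA cells and an explicit no-best", {
  tab <- data.frame(plot_id = 1:8, stratum = "broadleaf",
                    nt = c(3, 9, 4, 7, 5, 8, 6, 10), n_prime = 5,
                    area_m2 = 400)
  gs <- grid_search(list(make_combo("PAN", 3, 0.1, tab)),
                    strata = "broadleaf")
  expect_true(is.na(gs$cells$r))
  expect_null(gs$best$broadleaf)
  expect_warning(
    grid_search(list(make_combo("PAN", 3, 0.1, tab[1:2, ])),
                strata = "broadleaf"),
    "skipped")
})

test_that("the engineered noise-free combination wins the grid search", {
  # the 3x3 / NDVI 0.3 combination sees the true counts; every other
  # combination gets additive count noise -> selection must land on 3x3/0.3
  wins <- 0
  for (seed in 1:40) {
    set.seed(seed)
    nt <- pmax(round(rnorm(20, 27, 20)), 4)
    combos <- list()
    for (w in c(3, 5)) for (th in c(0.1, 0.3)) {
      n_prime <- if (w == 3 && th == 0.3) nt
                 else nt + rpois(20, 8) - rpois(20, 3)
      combos[[length(combos) + 1]] <- make_combo(
        "NIR", w, th, data.frame(plot_id = 1:20, stratum = "unclassified",
                                 nt = nt, n_prime = pmax(n_prime, 0),
                                 area_m2 = 400))
    }
    b <- grid_search(combos, strata = "unclassified")$best$unclassified
    if (b$window == 3 && b$threshold == 0.3) wins <- wins + 1
  }
  expect_gte(wins, 38)  # >= 95% of 40 seeds
})

test_that("exact polynomial data is recovered perfectly", {
  x <- c(1, 3, 5, 7, 9, 11)
  lin <- data.frame(nt = 2 + 3 * x, n_prime = x)
  # exact data: lm warns about an essentially perfect fit
  m <- suppressWarnings(fit_density_model(lin, "linear", cv = FALSE))
  expect_equal(m$coefficients, c(2, 3), tolerance = 1e-9)
  expect_equal(m$r_squared, 1)
  expect_equal(m$rmse, 0, tolerance = 1e-9)
  expect_equal(unname(m$dof), c(1, 4))

  quad <- data.frame(nt = 1 + 0 * x + 0.5 * x^2, n_prime = x)
  mq <- suppressWarnings(fit_density_model(quad, "quadratic", cv = FALSE))
  expect_equal(mq$coefficients, c(1, 0, 0.5), tolerance = 1e-9)
  expect_equal(unname(mq$dof), c(2, 3))
})

test_that("OLS coefficients match the normal-equations oracle", {
  set.seed(29)
  for (rep in 1:5) {
    x <- rpois(73, 25)
    y <- 5 + 1.2 * x + 0.01 * x^2 + rnorm(73, sd = 8)
    obs <- data.frame(nt = y, n_prime = x)
    for (form in c("linear", "quadratic")) {
      deg <- if (form == "linear") 1 else 2
      m <- fit_density_model(obs, form, cv = FALSE)
      expect_equal(m$coefficients, oracle_ols(x, y, deg), tolerance = 1e-8)
      # fit statistics agree with direct definitions
      pred <- predict(m, x)
      sse <- sum((y - pred)^2)
      expect_equal(m$rmse, sqrt(sse / 73), tolerance = 1e-10)
      expect_equal(m$r_squared, 1 - sse / sum((y - mean(y))^2),
                   tolerance = 1e-10)
    }
  }
  expect_error(fit_density_model(data.frame(nt = 1:5, n_prime = rep(2, 5)),
                                 "linear"), "singular")
})

test_that("R-squared of the linear fit equals squared Pearson r", {
  set.seed(31)
  x <- rpois(40, 15); y <- 3 + 2 * x + rnorm(40, sd = 5)
  m <- fit_density_model(data.frame(nt = y, n_prime = x), "linear", cv = FALSE)
  expect_equal(m$r_squared, pearson_r(x, y)$r^2, tolerance = 1e-12)
})

test_that("nested models: quadratic SSE never exceeds linear SSE", {
  set.seed(37)
  for (rep in 1:20) {
    x <- rpois(25, 20); y <- rnorm(25, 2 * x, 10)
    obs <- data.frame(nt = y, n_prime = x)
    sse <- vapply(c("linear", "quadratic"), function(f) {
      m <- fit_density_model(obs, f, cv = FALSE)
      sum((y - predict(m, x))^2)
    }, numeric(1))
    expect_lte(sse["quadratic"], sse["linear"] + 1e-8)
  }
})

test_that("LOOCV is exact on linear data and matches the refit oracle", {
  x <- c(2, 4, 6, 8, 10, 12)
  exact <- data.frame(nt = 1 + 2 * x, n_prime = x)
  sc <- suppressWarnings(loocv(exact, "linear"))  # perfect-fit lm warnings
  expect_equal(sc$r2_cv, 1, tolerance = 1e-9)
  expect_equal(sc$rmse_cv, 0, tolerance = 1e-9)

  set.seed(41)
  y <- 1 + 2 * x + rnorm(6, sd = 1)
  y[3] <- y[3] + 40  # gross outlier inflates held-out error beyond fit RMSE
  noisy <- data.frame(nt = y, n_prime = x)
  m <- fit_density_model(noisy, "linear", cv = TRUE)
  expect_gt(m$rmse_cv, m$rmse)

  obs <- data.frame(nt = rnorm(20, 50, 10), n_prime = rpois(20, 20))
  for (form in c("linear", "quadratic")) {
    deg <- if (form == "linear") 1 else 2
    got <- loocv(obs, form)$predictions
    expect_equal(got, oracle_loocv_preds(obs$n_prime, obs$nt, deg),
                 tolerance = 1e-8)
    # summary definitions: r2_cv = 1 - PRESS/SS_tot, rmse_cv = sqrt(PRESS/n)
    press <- sum((obs$nt - got)^2)
    expect_equal(loocv(obs, form)$r2_cv,
                 1 - press / sum((obs$nt - mean(obs$nt))^2))
  }
  expect_error(loocv(obs[1:4, ], "linear"), "at least 5")
})

test_that("Shapiro-Wilk p is attached and advisory", {
  set.seed(43)
  x <- rpois(30, 20); y <- 2 * x + rnorm(30, sd = 4)
  m <- fit_density_model(data.frame(nt = y, n_prime = x), "linear")
  expect_true(m$shapiro_p >= 0 && m$shapiro_p <= 1)
  res <- y - predict(m, x)
  expect_equal(m$shapiro_p, shapiro.test(res)$p.value, tolerance = 1e-10)
})
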
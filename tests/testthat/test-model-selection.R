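# Fit statistics (ANOVA R^2, Pillai's trace, Gaussian AIC) and the radius
# sweep / culling machinery.

test_that("per-variable R^2 equals hand-computed one-way ANOVA", {
  v <- matrix(c(0, 0, 1, 1), dimnames = list(NULL, "x"))
  expect_equal(unname(per_variable_r2(v, c(1, 1, 2, 2))), 1)

  v2 <- matrix(c(1, 2, 3, 4), dimnames = list(NULL, "x"))
  # SS_between = 4, SS_total = 5
  expect_equal(unname(per_variable_r2(v2, c(1, 1, 2, 2))), 0.8)

  expect_error(per_variable_r2(v2, c(1, 1, 1, 1)), ">= 2 clusters")
  expect_error(per_variable_r2(matrix(rep(1, 4), dimnames = list(NULL, "x")),
                               c(1, 1, 2, 2)), "zero total")

  # random labels explain almost nothing
  X <- withr::with_seed(21, matrix(rnorm(1500), ncol = 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  lab <- withr::with_seed(22, sample(1:3, 500, replace = TRUE))
  expect_lt(mean(per_variable_r2(X, lab)), 0.05)

  # standardization leaves R^2 unchanged
  Xz <- scale(X)
  expect_equal(per_variable_r2(X, lab), per_variable_r2(Xz, lab),
               tolerance = 1e-10)

  # unassigned days are excluded
  lab0 <- lab
  lab0[1:50] <- 0
  expect_equal(per_variable_r2(X, lab0),
               per_variable_r2(X[-(1:50), ], lab[-(1:50)]))
})

test_that("splitting a cluster never decreases any per-variable R^2", {
  X <- withr::with_seed(30, matrix(rnorm(900), ncol = 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  lab <- rep(1:2, each = 150)
  base <- per_variable_r2(X, lab)
  for (seed in 1:5) {
    split <- lab
    idx <- which(lab == 2)
    flip <- withr::with_seed(seed, sample(idx, 60))
    split[flip] <- 3
    expect_true(all(per_variable_r2(X, split) >= base - 1e-12))
  }
})

test_that("Pillai's trace matches stats::manova and its scalar identity", {
  # d = 1, k = 2: V equals the univariate R^2
  v <- matrix(c(1, 2, 3, 4, 10, 11, 12, 13), dimnames = list(NULL, "x"))
  lab <- rep(1:2, each = 4)
  expect_equal(pillai_trace(v, lab), unname(per_variable_r2(v, lab)),
               tolerance = 1e-12)

  # near-perfectly separated d = 2, k = 3 approaches min(d, k-1) = 2
  X <- withr::with_seed(31, matrix(rnorm(600, sd = 1e-3), ncol = 2)) +
    cbind(rep(c(0, 50, 100), each = 100), rep(c(0, 100, 0), each = 100))
  colnames(X) <- c("a", "b")
  lab3 <- rep(1:3, each = 100)
  expect_equal(pillai_trace(X, lab3), 2, tolerance = 1e-4)

  # enumerated instance against the independent MANOVA implementation
  X12 <- matrix(c(1, 2, 2, 3, 5, 6, 7, 5, 9, 9, 8, 10,
                  0, 1, 0, 2, 2, 3, 2, 4, 5, 4, 6, 5), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  lab12 <- rep(1:3, each = 4)
  ref <- summary(stats::manova(X12 ~ factor(lab12)),
                 test = "Pillai")$stats[1, "Pillai"]
  expect_equal(pillai_trace(X12, lab12), unname(ref), tolerance = 1e-10)

  # bounds on random instances
  for (seed in 1:5) {
    Xr <- withr::with_seed(40 + seed, matrix(rnorm(240), ncol = 3))
    colnames(Xr) <- c("a", "b", "c")
    labr <- withr::with_seed(50 + seed, sample(1:4, 80, replace = TRUE))
    V <- pillai_trace(Xr, labr)
    expect_gte(V, 0)
    expect_lte(V, min(3, length(unique(labr)) - 1) + 1e-12)
  }
})

test_that("Gaussian AIC matches its closed form and prefers true structure", {
  X <- withr::with_seed(60, matrix(rnorm(200), ncol = 2,
                                   dimnames = list(NULL, c("a", "b"))))
  lab1 <- rep(1, 100)
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / 100
  ll <- -0.5 * (100 * (2 * log(2 * pi) +
                         as.numeric(determinant(S)$modulus)) + 100 * 2)
  p <- 1 * (2 + 3)
  expect_equal(aic_score(X, lab1), -2 * ll + 2 * p, tolerance = 1e-8)

  # two well-separated clusters: k = 2 labels beat k = 1
  X2 <- rbind(X, sweep(X, 2, c(-20, -20)))
  lab2 <- rep(1:2, each = 100)
  expect_lt(aic_score(X2, lab2), aic_score(X2, rep(1, 200)))

  # tiny cluster falls back to pooled covariance instead of failing
  lab_tiny <- c(rep(1, 98), 2, 2)
  expect_silent(aic_score(X, lab_tiny))
})

test_that("radius sweep produces the model-fit table and flags extremes", {
  w <- make_weather_tbl(240, seed = 77)
  f <- fw_features(w, c("rh", "temp", "solar", "soil"))
  grid <- c(0.4, 0.8, 1.2, 6)
  sw <- sweep_radius(f, grid, ck = 20)
  expect_s3_class(sw, "fw_sweep")
  expect_equal(nrow(sw$stats), length(grid))
  expect_equal(sw$stats$r, grid)
  huge <- sw$stats[sw$stats$r == 6, ]
  expect_equal(huge$k, 1)
  expect_true(huge$flagged)
  ok <- sw$stats$k >= 2 & sw$stats$k <= 8
  expect_true(all(!sw$stats$flagged[ok]))
  expect_true(all(is.finite(sw$stats$mean_r2[ok])))
})

test_that("days-per-year culling drops models with fleeting clusters", {
  w <- make_weather_tbl(730, seed = 78)
  f <- fw_features(w, c("rh", "temp", "solar", "soil"))
  sw <- sweep_radius(f, c(0.5, 1.0, 8), ck = 10)
  culled <- cull_by_days_per_year(sw, min_days = 10)
  expect_true(all(culled$stats$min_days_per_year >= 10))
  expect_equal(nrow(culled$culling_log), nrow(sw$stats))
  # an impossible threshold empties the set with a warning
  expect_warning(empty <- cull_by_days_per_year(sw, min_days = 1e6),
                 "no candidate")
  expect_equal(nrow(empty$stats), 0)
})

test_that("leave-one-out subset screening counts subsets and finds wrenches", {
  cfg <- synth_config(n_years = 8, seed = 14)
  w <- generate_weather(cfg)
  grid <- seq(0.45, 1.0, length.out = 10)
  res <- screen_variable_subsets(w, c("rh", "temp", "solar", "soil", "wind"),
                                 ck = 50, r_grid = grid)
  expect_equal(nrow(res$subsets), 6) # full set + 5 leave-one-out
  expect_equal(nrow(res$wrench), 5)
  # wind is pure aseasonal noise: flagged as the wrench
  expect_true(res$wrench$is_wrench[res$wrench$variable == "wind"])
  expect_false(any(res$wrench$is_wrench[res$wrench$variable != "wind"]))

  # counting only: a 3-variable full set evaluates 4 subsets
  res3 <- screen_variable_subsets(w, c("rh", "temp", "soil"), ck = 30,
                                  r_grid = c(0.6, 0.9))
  expect_equal(nrow(res3$subsets), 4)
})
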
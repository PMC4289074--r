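# Canonical discriminant functions, the fire-weather plane, QDA
# classification and leave-one-out cross-validation.

make_class_features <- function(centers, n_per = 40, sd = 0.5, seed = 1) {
  k <- nrow(centers)
  d <- ncol(centers)
  X <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(rnorm(n_per * d, sd = sd), ncol = d) +
        matrix(centers[i, ], n_per, d, byrow = TRUE)
    }))
  })
  colnames(X) <- paste0("v", seq_len(d))
  list(features = features_from_matrix(X), labels = rep(seq_len(k),
                                                        each = n_per))
}

test_that("canonical functions carry the expected shares of variation", {
  # two separated spherical clusters in 2-D: a single informative axis
  cl <- make_class_features(rbind(c(0, 0), c(8, 0)))
  dm <- fw_discriminant(cl$features, cl$labels)
  expect_equal(length(dm$eigenvalues), 1)
  expect_equal(dm$pct_variance, 100)

  # three classes: shares sum to 100, axes uncorrelated, signs canonical
  cl3 <- make_class_features(rbind(c(0, 0, 0), c(5, 3, 0), c(0, 6, 2)),
                             seed = 3)
  dm3 <- fw_discriminant(cl3$features, cl3$labels)
  expect_equal(sum(dm3$pct_variance), 100, tolerance = 1e-9)
  sc <- dm3$scores
  expect_lt(abs(cor(sc$f1, sc$f2)), 1e-8)
  expect_true(all(dm3$struct_corr >= -1 & dm3$struct_corr <= 1))
  for (j in 1:2) {
    lead <- which.max(abs(dm3$struct_corr[, j]))
    expect_gt(dm3$struct_corr[lead, j], 0)
  }
  expect_true(all(dm3$f_stats$p_value < 0.01))

  # eigenvalue shares agree with the MASS::lda decomposition
  ld <- MASS::lda(feature_matrix(cl3$features), factor(cl3$labels))
  expect_equal(dm3$pct_variance, 100 * ld$svd^2 / sum(ld$svd^2),
               tolerance = 1e-6)
  # and eigenvalues agree up to the documented scaling
  n <- nrow(cl3$features)
  expect_equal(dm3$eigenvalues, ld$svd^2 * (3 - 1) / (n - 3),
               tolerance = 1e-6)
})

test_that("with one variable and two groups the analysis reduces to ANOVA", {
  X <- withr::with_seed(5, matrix(c(rnorm(30), rnorm(30, 2)), ncol = 1,
                                  dimnames = list(NULL, "v1")))
  f <- features_from_matrix(X)
  lab <- rep(1:2, each = 30)
  dm <- fw_discriminant(f, lab)
  r2 <- unname(per_variable_r2(feature_matrix(f), lab))
  # canonical correlation^2 = lambda / (1 + lambda) = R^2
  expect_equal(dm$eigenvalues / (1 + dm$eigenvalues), r2,
               tolerance = 1e-10)
})

test_that("projection reproduces training scores and respects the pipeline", {
  cl <- make_class_features(rbind(c(0, 0, 0), c(4, 2, 1), c(1, 5, 3)),
                            seed = 9)
  dm <- fw_discriminant(cl$features, cl$labels)
  pr <- fw_project(dm, cl$features)
  expect_equal(pr$f1, dm$scores$f1)
  expect_equal(pr$f2, dm$scores$f2)

  # a day equal to a class mean lands at the class centroid in the plane
  X <- feature_matrix(cl$features)
  mu <- colMeans(X[cl$labels == 2, , drop = FALSE])
  pr_mu <- fw_project(dm, matrix(mu, 1))
  cent <- c(mean(dm$scores$f1[cl$labels == 2]),
            mean(dm$scores$f2[cl$labels == 2]))
  expect_equal(unname(c(pr_mu$f1, pr_mu$f2)), cent, tolerance = 1e-8)

  bad <- cl$features
  attr(bad, "variables") <- c("x", "y", "z")
  expect_error(fw_project(dm, bad), "mismatch")
})

# helper: route raw points through the feature pipeline used by `f`
project_pts <- function(pts, f, raw = FALSE) {
  colnames(pts) <- feature_vars(f)
  if (raw) {
    df <- tibble::as_tibble(pts)
    return(df)
  }
  center <- attr(f, "center")
  scale <- attr(f, "scale")
  sweep(sweep(pts, 2, center[feature_vars(f)]), 2,
        scale[feature_vars(f)], "/")
}

test_that("QDA separates classes and honors class-specific covariance", {
  # identical covariances, means 10 SDs apart: no errors
  cl <- make_class_features(rbind(c(0, 0), c(10, 0)), sd = 1)
  dm <- fw_discriminant(cl$features, cl$labels)
  expect_equal(dm$misclassification, 0)

  # equal means, different covariances: far points go to the wide class
  X <- withr::with_seed(17, rbind(matrix(rnorm(400, sd = 0.5), ncol = 2),
                                  matrix(rnorm(400, sd = 3), ncol = 2)))
  colnames(X) <- c("v1", "v2")
  f <- features_from_matrix(X)
  lab <- rep(1:2, each = 200)
  dm2 <- fw_discriminant(f, lab)
  test_pts <- matrix(c(0, 0, 4, 4, -4, 4), ncol = 2, byrow = TRUE)
  # direct Gaussian-density oracle with the class MLE fits
  Z <- feature_matrix(f)
  dens <- sapply(1:2, function(cls) {
    sub <- Z[lab == cls, ]
    mu <- colMeans(sub)
    S <- crossprod(sweep(sub, 2, mu)) / nrow(sub)
    zt <- sweep(project_pts(test_pts, f), 2, mu)
    exp(-0.5 * rowSums(zt * t(solve(S, t(zt))))) / sqrt(det(S))
  })
  oracle_cls <- max.col(dens)
  got <- qda_classify(dm2, project_pts(test_pts, f, raw = TRUE))
  expect_equal(got$cluster, oracle_cls)

  # single observation per class: pooled fallback with a warning
  Xs <- matrix(c(0, 0.2, 5, 5, 4.8, 0, 1, 5, 6, 5.5), ncol = 2,
               dimnames = list(NULL, c("v1", "v2")))
  fs <- features_from_matrix(Xs)
  expect_warning(fw_discriminant(fs, c(1, 1, 2, 2, 2)), "pooled")
})

test_that("LOOCV tracks resubstitution and vanishes when seasons separate", {
  tight <- lapply(default_seasons(), function(s) {
    season_spec(s$name, s$doy_start, s$doy_end,
                temp = c(s$temp[1], s$temp[2] / 10),
                rh = c(s$rh[1], s$rh[2] / 10),
                solar = c(s$solar[1], s$solar[2] / 10),
                soil = c(s$soil[1], s$soil[2] / 10))
  })
  cfg <- synth_config(n_years = 3, seasons = tight, seed = 4,
                      transition_ramp_days = 0)
  w <- generate_weather(cfg)
  f <- fw_features(w)
  lab <- match(w$season, c("wet", "dry", "fire"))
  cv <- fw_loocv(f, lab)
  expect_equal(cv$rate, 0)
  expect_equal(cv$resubstitution, 0)
  expect_equal(sum(diag(cv$confusion)), nrow(f))
})
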
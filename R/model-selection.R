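# Candidate-model generation across the kernel radius, fit statistics
# (per-variable ANOVA R^2, Gaussian-mixture AIC, Pillai's trace) and the
# culling screens.

#' Default kernel-radius grid
#'
#' Forty log-spaced radii spanning 0.2 to 3.0 standardized units — wide
#' enough that the smallest radii over-fragment the data and the largest
#' merge it into a single cluster, so the sweep brackets the useful models.
#'
#' @param n Number of radii (default 40).
#' @param from,to Grid limits in standardized units.
#' @return Numeric vector of radii, increasing.
#' @export
default_radius_grid <- function(n = 40, from = 0.2, to = 3.0) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Per-variable one-way ANOVA R-squared
#'
#' For each variable, the share of total sum of squares explained by the
#' cluster factor: `R^2 = SS_between / SS_total`. Computed on whatever scale
#' `values` is supplied in; standardization leaves R^2 unchanged, so raw
#' (post-transform) and z-scored inputs agree. Unassigned days (label 0) are
#' excluded.
#'
#' @param values Numeric matrix (days x variables) with column names, or an
#'   [fw_features()] object (its post-transform raw scale is used).
#' @param labels Integer cluster labels (0 = unassigned).
#' @return Named numeric vector of R^2 values, one per variable.
#' @export
per_variable_r2 <- function(values, labels) {
  if (inherits(values, "fw_features")) values <- raw_matrix(values)
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  keep <- labels > 0
  values <- values[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    abort("per_variable_r2 requires >= 2 clusters")
  }
  f <- factor(labels)
  apply(values, 2, function(y) {
    ss_t <- sum((y - mean(y))^2)
    if (ss_t == 0) abort("zero total sum of squares for a variable")
    gm <- tapply(y, f, mean)
    ng <- tabulate(f)
    ss_b <- sum(ng * (gm - mean(y))^2)
    ss_b / ss_t
  })
}

#' Pillai's trace for a one-way MANOVA
#'
#' `V = tr(B (B + W)^-1)` from the between- (`B`) and within-group (`W`)
#' cross-product matrices of the (standardized) variables with cluster as
#' the factor. Bounded by `0 <= V <= min(d, k - 1)`.
#'
#' @param values Numeric matrix or [fw_features()] object (standardized
#'   scale is used).
#' @param labels Integer cluster labels (0 = unassigned, excluded).
#' @return Pillai's trace (scalar).
#' @export
pillai_trace <- function(values, labels) {
  if (inherits(values, "fw_features")) values <- feature_matrix(values)
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  keep <- labels > 0
  values <- values[keep, , drop = FALSE]
  labels <- labels[keep]
  k <- length(unique(labels))
  d <- ncol(values)
  n <- nrow(values)
  if (k < 2) abort("pillai_trace requires >= 2 clusters")
  if (n <= d + k) abort("pillai_trace requires n > d + k")
  bw <- between_within(values, labels)
  t_mat <- bw$B + bw$W
  ev <- tryCatch(solve(t_mat), error = function(e) {
    abort("singular total cross-product matrix in pillai_trace")
  })
  sum(diag(bw$B %*% ev))
}

# Between- and within-group cross-product matrices.
between_within <- function(values, labels) {
  f <- factor(labels)
  grand <- colMeans(values)
  centered <- sweep(values, 2, grand)
  total <- crossprod(centered)
  w <- matrix(0, ncol(values), ncol(values))
  for (lv in levels(f)) {
    sub <- values[f == lv, , drop = FALSE]
    w <- w + crossprod(sweep(sub, 2, colMeans(sub)))
  }
  list(B = total - w, W = w)
}

#' Gaussian-mixture AIC for a hard clustering
#'
#' `AIC = -2 log L + 2p` with `log L` the per-cluster multivariate-normal
#' log-likelihood at the cluster MLEs (full covariance per cluster) and
#' `p = k (d + d(d+1)/2)` free parameters. Clusters too small to estimate a
#' covariance (`n_c < d + 1`) fall back to the pooled covariance; singular
#' covariances are ridge-regularized by `1e-6 I` (with a warning).
#'
#' @param values Numeric matrix or [fw_features()] object (standardized).
#' @param labels Integer cluster labels (0 = unassigned, excluded).
#' @return AIC (scalar; lower is better).
#' @export
aic_score <- function(values, labels) {
  if (inherits(values, "fw_features")) values <- feature_matrix(values)
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  keep <- labels > 0
  values <- values[keep, , drop = FALSE]
  labels <- labels[keep]
  d <- ncol(values)
  f <- factor(labels)
  k <- nlevels(f)
  pooled <- NULL
  loglik <- 0
  for (lv in levels(f)) {
    sub <- values[f == lv, , drop = FALSE]
    n_c <- nrow(sub)
    mu <- colMeans(sub)
    if (n_c < d + 1) {
      if (is.null(pooled)) pooled <- pooled_mle_cov(values, f)
      sigma <- pooled
    } else {
      sigma <- crossprod(sweep(sub, 2, mu)) / n_c
    }
    ld <- determinant_safe(sigma)
    if (!ld$ok) {
      warn("singular cluster covariance in aic_score; ridge-regularized")
      sigma <- sigma + diag(1e-6, d)
      ld <- determinant_safe(sigma)
    }
    centered <- sweep(sub, 2, mu)
    quad <- sum(centered * t(solve(sigma, t(centered))))
    loglik <- loglik - 0.5 * (n_c * (d * log(2 * pi) + ld$logdet) + quad)
  }
  p <- k * (d + d * (d + 1) / 2)
  -2 * loglik + 2 * p
}

pooled_mle_cov <- function(values, f) {
  w <- matrix(0, ncol(values), ncol(values))
  for (lv in levels(f)) {
    sub <- values[f == lv, , drop = FALSE]
    w <- w + crossprod(sweep(sub, 2, colMeans(sub)))
  }
  w / nrow(values)
}

determinant_safe <- function(sigma) {
  ld <- determinant(sigma, logarithm = TRUE)
  ok <- is.finite(ld$modulus) && ld$sign > 0 &&
    rcond(sigma) > .Machine$double.eps
  list(ok = ok, logdet = as.numeric(ld$modulus))
}

#' Fit statistics for one cluster model
#'
#' @param features An [fw_features()] object.
#' @param model An `fw_cluster` model fitted on `features` (or a bare label
#'   vector).
#' @return A one-row tibble: `r`, `k`, `mean_r2`, `aic`, `pillai`,
#'   `min_days_per_year`, plus list columns `r2` (named per-variable R^2)
#'   and `days_per_year` (named mean days/year per cluster).
#' @export
fit_stats <- function(features, model) {
  labels <- if (inherits(model, "fw_cluster")) model$labels else model
  r2 <- per_variable_r2(features, labels)
  dpy <- days_per_year(feature_dates(features), labels)
  tibble(
    r = if (inherits(model, "fw_cluster")) model$r else NA_real_,
    k = length(unique(labels[labels > 0])),
    mean_r2 = mean(r2),
    aic = aic_score(features, labels),
    pillai = pillai_trace(features, labels),
    min_days_per_year = min(dpy),
    r2 = list(r2),
    days_per_year = list(dpy)
  )
}

# Mean days per year in each cluster (0 excluded).
days_per_year <- function(dates, labels) {
  stopifnot(length(dates) == length(labels))
  n_years <- length(unique(year(dates)))
  counts <- table(labels[labels > 0])
  setNames(as.numeric(counts) / n_years, names(counts))
}

#' Sweep the kernel radius to generate candidate models
#'
#' Runs [mode_cluster()] at every radius in the grid and computes fit
#' statistics for each resulting model. Models with fewer than 2 or more
#' than 8 clusters are flagged as outside the useful seasonal range (more
#' than 8 candidate seasons is taken as unlikely to be useful); their fit
#' statistics are `NA` where undefined. The `stats` table is the data behind
#' the radius-versus-mean-R^2 model-fit scatter.
#'
#' @param features An [fw_features()] object.
#' @param r_grid Positive increasing radii (default [default_radius_grid()]).
#' @param ck Minimum cluster size (default 50).
#' @return An object of class `fw_sweep`: list with `models` (list of
#'   `fw_cluster`) and `stats` (tibble: `r`, `k`, `mean_r2`, `aic`,
#'   `pillai`, `min_days_per_year`, `flagged`, `reason`, plus list columns).
#' @export
sweep_radius <- function(features, r_grid = default_radius_grid(), ck = 50) {
  stopifnot(length(r_grid) > 0, all(r_grid > 0), !is.unsorted(r_grid))
  models <- vector("list", length(r_grid))
  rows <- vector("list", length(r_grid))
  for (i in seq_along(r_grid)) {
    m <- mode_cluster(features, r_grid[i], ck)
    models[[i]] <- m
    flagged <- m$k < 2 || m$k > 8
    reason <- if (m$k < 2) "k < 2" else if (m$k > 8) "k > 8" else ""
    st <- tryCatch(fit_stats(features, m), error = function(e) NULL)
    if (is.null(st)) {
      dpy <- days_per_year(feature_dates(features), m$labels)
      st <- tibble(r = m$r, k = m$k, mean_r2 = NA_real_, aic = NA_real_,
                   pillai = NA_real_,
                   min_days_per_year = if (length(dpy)) min(dpy) else NA_real_,
                   r2 = list(NULL), days_per_year = list(dpy))
    }
    rows[[i]] <- mutate(st, flagged = flagged, reason = reason)
  }
  structure(list(models = models, stats = list_rbind(rows),
                 ck = ck, features_vars = feature_vars(features)),
            class = "fw_sweep")
}

#' @export
print.fw_sweep <- function(x, ...) {
  cat("<fw_sweep> ", length(x$models), " candidate models, CK = ", x$ck,
      ", variables: ", paste(x$features_vars, collapse = ", "), "\n",
      sep = "")
  print(select(x$stats, !where(is.list)))
  invisible(x)
}

#' @describeIn sweep_radius The per-radius statistics table.
#' @param x An `fw_sweep` object.
#' @param ... Unused.
#' @export
tidy.fw_sweep <- function(x, ...) x$stats

#' Cull candidate models by days per year
#'
#' Drops models in which any retained cluster averages fewer than `min_days`
#' days per year — such clusters are short-term weather changes, not
#' seasons.
#'
#' @param sweep An `fw_sweep`.
#' @param min_days Minimum mean days/year per cluster (default 10).
#' @return The filtered `fw_sweep`, with a `culling_log` tibble attached
#'   (`r`, `k`, `kept`, `reason`). Warns when nothing survives.
#' @export
cull_by_days_per_year <- function(sweep, min_days = 10) {
  stopifnot(inherits(sweep, "fw_sweep"), nrow(sweep$stats) > 0)
  keep <- sweep$stats$min_days_per_year >= min_days &
    !is.na(sweep$stats$min_days_per_year)
  log <- tibble(r = sweep$stats$r, k = sweep$stats$k, kept = keep,
                reason = if_else(keep, "",
                                 sprintf("cluster below %g days/yr",
                                         min_days)))
  out <- sweep
  out$models <- sweep$models[keep]
  out$stats <- sweep$stats[keep, ]
  out$culling_log <- log
  if (!any(keep)) warn("no candidate models survive the days-per-year cull")
  out
}

#' Screen variable subsets for wrench variables
#'
#' Sweeps the radius grid on the full variable set and on every
#' leave-one-out subset, recording each subset's best mean R^2 over models
#' with 2--8 clusters. A variable is flagged as a "wrench in the works" when
#' every subset containing it fits at least `delta` worse than the best
#' subset excluding it — i.e. its presence prevents well-fitting seasonal
#' models from emerging (wind speed plays this role in the motivating data).
#'
#' @param weather Weather tibble.
#' @param full_set Character vector of candidate variables (>= 3).
#' @param log_vars Variables to ln-transform where included.
#' @param ck Minimum cluster size.
#' @param r_grid Radius grid.
#' @param delta Mean-R^2 margin for the wrench verdict (default 0.05).
#' @return A list: `subsets` (tibble: `excluded` ("" for the full set),
#'   `variables`, `best_mean_r2`), `wrench` (tibble: `variable`,
#'   `is_wrench`, `best_with`, `best_without`).
#' @export
screen_variable_subsets <- function(weather, full_set,
                                    log_vars = intersect("soil", full_set),
                                    ck = 50,
                                    r_grid = default_radius_grid(),
                                    delta = 0.05) {
  stopifnot(length(full_set) >= 3)
  subsets <- c(list(full_set),
               lapply(full_set, function(v) setdiff(full_set, v)))
  excluded <- c("", full_set)
  best <- map_dbl(subsets, function(vars) {
    feats <- fw_features(weather, vars, intersect(log_vars, vars))
    sw <- sweep_radius(feats, r_grid, ck)
    ok <- sw$stats$k >= 2 & sw$stats$k <= 8 & !is.na(sw$stats$mean_r2)
    if (!any(ok)) return(NA_real_)
    max(sw$stats$mean_r2[ok])
  })
  subset_tbl <- tibble(excluded = excluded,
                       variables = map_chr(subsets, paste, collapse = "+"),
                       best_mean_r2 = best)
  wrench <- list_rbind(lapply(full_set, function(v) {
    has_v <- map_lgl_safe(subsets, function(s) v %in% s)
    bw <- suppressWarnings(max(best[has_v], na.rm = TRUE))
    bo <- suppressWarnings(max(best[!has_v], na.rm = TRUE))
    tibble(variable = v,
           best_with = bw, best_without = bo,
           is_wrench = is.finite(bw) && is.finite(bo) && bw <= bo - delta)
  }))
  list(subsets = subset_tbl, wrench = wrench)
}

map_lgl_safe <- function(x, f) vapply(x, f, logical(1))
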
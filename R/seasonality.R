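# Calendar characterization of cluster models: days/year, day-of-year
# histograms, circular predominance intervals, the seasonality screen,
# representative-model ranking, and season role labels.

#' Seasonal profile of a cluster model
#'
#' Characterizes each cluster as a calendar season: mean days per year,
#' 15-day day-of-year histogram (bins anchored at day 1; Feb 29 folded onto
#' day 59), circular predominance intervals (maximal day-of-year runs over
#' which the cluster is the across-years modal label) and consistency (the
#' minimum over years of the longest within-year run of consecutive days in
#' the cluster).
#'
#' @param model An `fw_cluster` (must carry dates) or an integer label
#'   vector.
#' @param dates Per-day dates aligned with the labels (defaults to the
#'   model's own dates).
#' @return An object of class `fw_season_profile`: list with tibbles
#'   `clusters` (`cluster`, `n_days`, `mean_days_per_year`, `consistency`),
#'   `histogram` (`cluster`, `bin`, `bin_start_doy`, `count`),
#'   `predominance` (`cluster`, `start_doy`, `end_doy`, `length`), the
#'   per-day-of-year `modal` labels, and `n_years`.
#' @export
season_profile <- function(model, dates = NULL) {
  labels <- if (inherits(model, "fw_cluster")) model$labels else model
  dates <- dates %||% (if (inherits(model, "fw_cluster")) model$date)
  if (is.null(dates)) abort("season_profile needs dates aligned to labels")
  stopifnot(length(dates) == length(labels))
  yrs <- year(dates)
  full_years <- as.integer(names(which(table(yrs) >= 360)))
  if (length(full_years) < 2) {
    abort("season_profile requires >= 2 full years of data")
  }
  doy <- doy_folded(dates)
  clusters <- sort(unique(labels[labels > 0]))
  n_years <- length(unique(yrs))

  cl_rows <- list_rbind(lapply(clusters, function(cl) {
    tibble(cluster = cl, n_days = sum(labels == cl),
           mean_days_per_year = sum(labels == cl) / n_years,
           consistency = consistency_days(dates, labels, cl, full_years))
  }))

  n_bins <- ceiling(366 / 15)
  hist_rows <- list_rbind(lapply(clusters, function(cl) {
    bins <- (doy[labels == cl] - 1) %/% 15 + 1
    tibble(cluster = cl, bin = seq_len(n_bins),
           bin_start_doy = (seq_len(n_bins) - 1) * 15 + 1,
           count = tabulate(bins, nbins = n_bins))
  }))

  modal <- modal_by_doy(doy, labels)
  pred <- predominance_intervals(modal)

  structure(list(clusters = cl_rows, histogram = hist_rows,
                 predominance = pred, modal = modal, n_years = n_years),
            class = "fw_season_profile")
}

# Longest run of calendar-consecutive days in cluster `cl`, minimized over
# the full years.
consistency_days <- function(dates, labels, cl, full_years) {
  runs <- vapply(full_years, function(y) {
    in_year <- year(dates) == y
    d <- dates[in_year]
    member <- labels[in_year] == cl
    if (!any(member)) return(0L)
    # runs broken either by non-membership or by a calendar gap
    idx <- which(member)
    breaks <- c(TRUE, diff(as.integer(d[idx])) != 1L)
    max(tabulate(cumsum(breaks)))
  }, integer(1))
  min(runs)
}

# Across-years modal cluster per day of year (1..365); ties to the lowest
# cluster id; NA where no labeled day exists.
modal_by_doy <- function(doy, labels) {
  vapply(1:365, function(d) {
    lab <- labels[doy == d & labels > 0]
    if (length(lab) == 0) return(NA_integer_)
    tab <- table(lab)
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
}

# Maximal circular runs of constant modal label.
predominance_intervals <- function(modal) {
  ok <- which(!is.na(modal))
  if (length(ok) == 0) {
    return(tibble(cluster = integer(), start_doy = integer(),
                  end_doy = integer(), length = integer()))
  }
  n <- 365L
  change <- which(vapply(seq_len(n), function(d) {
    prev <- if (d == 1L) n else d - 1L
    !identical(modal[d], modal[prev])
  }, logical(1)))
  if (length(change) == 0) {
    cl <- modal[1]
    return(tibble(cluster = cl, start_doy = 1L, end_doy = 365L,
                  length = sum(!is.na(modal))))
  }
  starts <- sort(change)
  rows <- lapply(seq_along(starts), function(i) {
    s <- starts[i]
    e <- (if (i < length(starts)) starts[i + 1] else starts[1] + n) - 1L
    len <- e - s + 1L
    e_doy <- ((e - 1L) %% n) + 1L
    tibble(cluster = modal[s], start_doy = s, end_doy = e_doy, length = len)
  })
  out <- list_rbind(rows)
  filter(out, !is.na(.data$cluster))
}

#' @export
print.fw_season_profile <- function(x, ...) {
  cat("<fw_season_profile> ", nrow(x$clusters), " clusters over ",
      x$n_years, " years\n", sep = "")
  print(x$clusters)
  invisible(x)
}

#' Seasonality screen
#'
#' A cluster qualifies as a season only if it recurs with at least
#' `min_days` consecutive days in every full year and predominates over
#' some day-of-year interval. A model passes when all its clusters qualify.
#'
#' @param profile An [season_profile()] result.
#' @param min_days Minimum within-year run length (default 10).
#' @return A list: `pass` (logical, model level) and `clusters` (tibble:
#'   `cluster`, `consistency`, `has_predominance`, `pass`, `reason`).
#' @export
screen_seasonal <- function(profile, min_days = 10) {
  stopifnot(inherits(profile, "fw_season_profile"))
  pred_cl <- unique(profile$predominance$cluster)
  det <- mutate(profile$clusters,
                has_predominance = .data$cluster %in% pred_cl,
                pass = .data$consistency >= min_days & .data$has_predominance,
                reason = case_when(
                  .data$consistency < min_days ~
                    sprintf("not consistent across years (min run %d < %g)",
                            .data$consistency, min_days),
                  !.data$has_predominance ~ "no predominance interval",
                  TRUE ~ ""))
  list(pass = all(det$pass), clusters = det)
}

#' Rank screened candidates and select the representative model
#'
#' Within the screened survivors, each model is ranked on each fit
#' statistic (mean R^2 descending, AIC ascending, Pillai's trace
#' descending); the representative model minimizes the mean rank, with ties
#' broken toward the smaller radius.
#'
#' @param stats A tibble with columns `r`, `mean_r2`, `aic`, `pillai` (one
#'   row per surviving model), e.g. the `stats` of a culled `fw_sweep`.
#' @return `rank_models()`: the tibble with `rank_r2`, `rank_aic`,
#'   `rank_pillai`, `mean_rank` appended and `selected` marking the winner.
#' @export
rank_models <- function(stats) {
  if (nrow(stats) == 0) abort("no surviving models to rank")
  out <- mutate(stats,
                rank_r2 = rank(-.data$mean_r2, ties.method = "average"),
                rank_aic = rank(.data$aic, ties.method = "average"),
                rank_pillai = rank(-.data$pillai, ties.method = "average"),
                mean_rank = (.data$rank_r2 + .data$rank_aic +
                               .data$rank_pillai) / 3)
  best <- with(out, order(mean_rank, r))[1]
  mutate(out, selected = dplyr::row_number() == best)
}

#' @describeIn rank_models Run the full screen-and-rank selection on a
#'   radius sweep: keeps models with 2--8 clusters, applies the
#'   days-per-year cull and the seasonality screen, ranks the survivors and
#'   returns the representative model.
#' @param sweep An `fw_sweep` from [sweep_radius()].
#' @param min_days Days-per-year and consistency threshold (default 10).
#' @return `select_representative()`: list with `model` (`fw_cluster`),
#'   `stats` (its one-row statistics), `profile`
#'   ([season_profile()] of the winner), `ranking` (the ranked table) and
#'   `screen_log`.
#' @export
select_representative <- function(sweep, min_days = 10) {
  stopifnot(inherits(sweep, "fw_sweep"))
  sweep <- cull_by_days_per_year(sweep, min_days)
  ok <- !sweep$stats$flagged & !is.na(sweep$stats$mean_r2)
  models <- sweep$models[ok]
  stats <- sweep$stats[ok, ]
  if (length(models) == 0) abort("no candidate models in the 2-8 cluster range")
  screened <- map_lgl_safe(models, function(m) {
    prof <- season_profile(m)
    screen_seasonal(prof, min_days)$pass
  })
  if (!any(screened)) abort("no candidate model passes the seasonality screen")
  ranking <- rank_models(stats[screened, ])
  winner <- which(ranking$selected)
  model <- models[screened][[winner]]
  list(model = model, stats = ranking[winner, ], profile =
         season_profile(model), ranking = ranking,
       screen_log = tibble(r = stats$r, k = stats$k, screened_pass = screened))
}

#' Assign wet/dry/fire roles to the clusters of a 3-season model
#'
#' The fire season is the cluster with both the highest mean solar
#' radiation and the lowest mean relative humidity; of the remaining two,
#' the wet season has the higher mean soil moisture and the dry season the
#' lower. Models with other than three clusters, or where the solar and
#' humidity criteria disagree, get all roles `"none"` (with a warning).
#'
#' @param model An `fw_cluster` (or label vector).
#' @param features The [fw_features()] the model was fitted on; must include
#'   `solar`, `rh` and `soil`.
#' @return Named character vector: cluster id -> role in
#'   `c("wet", "dry", "fire", "none")`.
#' @export
assign_roles <- function(model, features) {
  labels <- if (inherits(model, "fw_cluster")) model$labels else model
  clusters <- sort(unique(labels[labels > 0]))
  roles <- setNames(rep("none", length(clusters)), clusters)
  if (length(clusters) != 3) {
    return(roles)
  }
  vars <- feature_vars(features)
  if (!all(c("solar", "rh", "soil") %in% vars)) {
    warn("roles need solar, rh and soil among the feature variables")
    return(roles)
  }
  raw <- raw_matrix(features)
  keep <- labels > 0
  means <- aggregate(raw[keep, c("solar", "rh", "soil")],
                     list(cluster = labels[keep]), mean)
  fire_solar <- means$cluster[which.max(means$solar)]
  fire_rh <- means$cluster[which.min(means$rh)]
  if (fire_solar != fire_rh ||
      sum(means$solar == max(means$solar)) > 1) {
    warn("ambiguous fire-season cluster (solar and humidity disagree)")
    return(roles)
  }
  roles[as.character(fire_solar)] <- "fire"
  rest <- means[means$cluster != fire_solar, ]
  wet <- rest$cluster[which.max(rest$soil)]
  dry <- setdiff(rest$cluster, wet)
  roles[as.character(wet)] <- "wet"
  roles[as.character(dry)] <- "dry"
  roles
}
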
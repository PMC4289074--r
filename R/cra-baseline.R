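# Conventional two-season (wet/dry) reference model from cumulative
# rainfall anomalies.

#' Cumulative rainfall anomaly
#'
#' `A(d) = sum_{i <= d} (r_i - rbar)` within each rainfall year, where
#' `rbar` is the long-term mean daily rainfall over the whole series.
#' Rainfall years are anchored at the first day of `anchor_month` (default
#' October) so the wet season lies in the interior of the year and its
#' onset/end appear as the anomaly minimum/maximum rather than boundary
#' artifacts.
#'
#' @param weather Tibble with `date` and non-negative `rain` (cm/day).
#' @param anchor_month Month (1--12) starting each rainfall year.
#' @return A tibble: `date`, `rain`, `rain_year` (labelled by its starting
#'   calendar year), `anomaly`.
#' @export
cumulative_rainfall_anomaly <- function(weather, anchor_month = 10) {
  stopifnot(all(c("date", "rain") %in% names(weather)))
  if (any(weather$rain < 0, na.rm = TRUE)) abort("negative rainfall")
  weather <- arrange(weather, .data$date)
  rbar <- mean(weather$rain, na.rm = TRUE)
  m <- lubridate::month(weather$date)
  ry <- year(weather$date) - (m < anchor_month)
  if (length(unique(ry)) < 2) abort("need >= 2 rainfall years")
  out <- tibble(date = weather$date, rain = weather$rain, rain_year = ry)
  mutate(group_by(out, .data$rain_year),
         anomaly = cumsum(dplyr::coalesce(.data$rain, 0) - rbar)) |>
    ungroup()
}

#' Two-season reference model from cumulative rainfall anomalies
#'
#' Per rainfall year, the wet season runs from the day after the anomaly
#' minimum (onset) through the anomaly maximum (end); all other days are
#' dry. Years whose anomaly maximum does not follow the minimum (e.g. a
#' year with no real wet season) are flagged degenerate, labelled dry
#' throughout and excluded from the onset/duration means. Non-unique
#' extremes take the earliest day, with a warning.
#'
#' @param weather Tibble with `date` and `rain`.
#' @param anchor_month Rainfall-year anchor (default October).
#' @return An object of class `fw_cra`: list with `days` (tibble: `date`,
#'   `anomaly`, `label` in wet/dry), `years` (tibble: `rain_year`,
#'   `onset_date`, `end_date`, `onset_doy`, `duration`, `degenerate`),
#'   `mean_onset_doy` and `mean_duration` (over complete, non-degenerate
#'   years).
#' @export
cra_seasons <- function(weather, anchor_month = 10) {
  anom <- cumulative_rainfall_anomaly(weather, anchor_month)
  label <- rep("dry", nrow(anom))
  yr_rows <- list()
  for (ry in unique(anom$rain_year)) {
    idx <- which(anom$rain_year == ry)
    a <- anom$anomaly[idx]
    i_min <- which(a == min(a))
    i_max <- which(a == max(a))
    if (length(i_min) > 1 || length(i_max) > 1) {
      warn(sprintf("non-unique anomaly extreme in rainfall year %d; %s",
                   ry, "taking the earliest"))
    }
    i_min <- i_min[1]; i_max <- i_max[1]
    complete <- length(idx) >= 360
    degenerate <- i_max <= i_min + 1
    if (degenerate) {
      warn(sprintf("rainfall year %d has no interior wet season", ry))
    } else {
      wet_idx <- idx[(i_min + 1):i_max]
      label[wet_idx] <- "wet"
    }
    onset_date <- if (degenerate) as.Date(NA) else anom$date[idx[i_min + 1]]
    end_date <- if (degenerate) as.Date(NA) else anom$date[idx[i_max]]
    yr_rows[[as.character(ry)]] <- tibble(
      rain_year = ry, onset_date = onset_date, end_date = end_date,
      onset_doy = if (degenerate) NA_integer_ else
        doy_folded(onset_date),
      duration = if (degenerate) NA_real_ else
        as.numeric(end_date - onset_date) + 1,
      complete = complete, degenerate = degenerate)
  }
  years <- list_rbind(unname(yr_rows))
  usable <- filter(years, .data$complete, !.data$degenerate)
  structure(list(
    days = tibble(date = anom$date, anomaly = anom$anomaly, label = label),
    years = years,
    mean_onset_doy = mean(usable$onset_doy),
    mean_duration = mean(usable$duration)),
    class = "fw_cra")
}

#' @export
print.fw_cra <- function(x, ...) {
  cat("<fw_cra> mean wet-season onset doy ",
      round(x$mean_onset_doy, 1), ", mean duration ",
      round(x$mean_duration, 1), " days over ",
      sum(x$years$complete & !x$years$degenerate), " usable years\n",
      sep = "")
  invisible(x)
}

#' Reference fit of the CRA two-season model
#'
#' The mean per-variable ANOVA R^2 of the fire-weather variables with the
#' CRA wet/dry labels as the two-level factor — the benchmark every
#' clustering-derived seasonal model is compared against.
#'
#' @param features An [fw_features()] object.
#' @param cra An `fw_cra` from [cra_seasons()] (or a tibble with `date` and
#'   `label`).
#' @return A list: `mean_r2` and the named per-variable `r2`.
#' @export
reference_fit <- function(features, cra) {
  days <- if (inherits(cra, "fw_cra")) cra$days else cra
  stopifnot(all(c("date", "label") %in% names(days)))
  lab <- days$label[match(feature_dates(features), days$date)]
  if (anyNA(lab)) abort("CRA labels do not cover all feature dates")
  labels <- match(lab, c("wet", "dry"))
  r2 <- per_variable_r2(features, labels)
  list(mean_r2 = mean(r2), r2 = r2)
}
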
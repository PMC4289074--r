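# Synthetic daily weather and fire-record generator.
#
# Emulates the statistical structure the seasonal analysis assumes: three
# latent day-of-year seasons (wet, dry, fire) with season-specific means and
# SDs for each fire-weather variable, AR(1) day-to-day persistence,
# log-normal soil moisture (positively skewed on its natural scale),
# season-dependent rainfall for the cumulative-rainfall-anomaly baseline,
# and per-ignition-source fire events with season-dependent counts and
# log-normal burned areas.

#' Season specification for the synthetic generator
#'
#' One latent season: its circular day-of-year window and the per-variable
#' means and SDs of daily weather within it. Defaults for the three seasons
#' are supplied by [default_seasons()].
#'
#' @param name One of `"wet"`, `"dry"`, `"fire"`.
#' @param doy_start,doy_end Circular day-of-year window (inclusive start,
#'   inclusive end; the window may wrap past day 365).
#' @param temp,rh,solar,soil,wind Length-2 numeric `c(mean, sd)` for air
#'   temperature (deg C), relative humidity (%), solar radiation (mW m^-2),
#'   soil moisture (mm) and wind speed.
#' @param rain_rate Mean daily rainfall (cm/day) within the season.
#' @param rain_prob Probability a day in the season has nonzero rain.
#' @return A list of class `season_spec`.
#' @export
season_spec <- function(name, doy_start, doy_end, temp, rh, solar, soil,
                        wind = c(8, 3), rain_rate = 0.2, rain_prob = 0.35) {
  stopifnot(name %in% c("wet", "dry", "fire"),
            length(temp) == 2, length(rh) == 2, length(solar) == 2,
            length(soil) == 2, length(wind) == 2,
            temp[2] >= 0, rh[2] >= 0, solar[2] >= 0, soil[2] >= 0,
            wind[2] >= 0,
            soil[1] > 0, rain_rate >= 0, rain_prob >= 0, rain_prob <= 1)
  structure(list(name = name, doy_start = doy_start, doy_end = doy_end,
                 temp = temp, rh = rh, solar = solar, soil = soil,
                 wind = wind, rain_rate = rain_rate, rain_prob = rain_prob),
            class = "season_spec")
}

#' Default three-season specification
#'
#' The wet, dry and fire seasons with the per-season weather means and SDs
#' of the representative three-season model (temperature 24.9/18.1/24.2 deg
#' C, humidity 83/78/72%, solar 0.19/0.15/0.28 mW m^-2, soil 50.0/21.5/19.2
#' mm for wet/dry/fire) and predominance windows fire = days 98--173, wet =
#' 174--323, dry = 324--97 (circular partition of the year). Wind speed is
#' aseasonal by default (same mean and SD in all seasons) so that, as at the
#' real site, it carries no seasonal signal. Wet-season rainfall averages
#' 0.66 cm/day (89 cm over a 134-day wet season); dry and fire seasons are
#' drier and zero-inflated.
#'
#' @return A named list of three [season_spec()] objects.
#' @export
default_seasons <- function() {
  list(
    fire = season_spec("fire", 98, 173,
                       temp = c(24.2, 3.7), rh = c(72, 6),
                       solar = c(0.28, 0.03), soil = c(19.2, 11.5),
                       rain_rate = 0.20, rain_prob = 0.35),
    wet = season_spec("wet", 174, 323,
                      temp = c(24.9, 2.4), rh = c(83, 5),
                      solar = c(0.19, 0.05), soil = c(50.0, 34.2),
                      rain_rate = 0.66, rain_prob = 0.80),
    dry = season_spec("dry", 324, 97,
                      temp = c(18.1, 4.1), rh = c(78, 8),
                      solar = c(0.15, 0.05), soil = c(21.5, 16.3),
                      rain_rate = 0.15, rain_prob = 0.25)
  )
}

#' Default per-source, per-season fire regime parameters
#'
#' Expected fire counts per year and log-normal burned-area parameters for
#' each (ignition source, season) cell, derived from the 13-year fire-record
#' summary: counts (wet/dry/fire) of 13/3/43 lightning, 17/44/51 military
#' and 118/341/205 prescribed fires, with total areas 152/521/6093,
#' 1154/5853/11115 and 15269/69681/41129 ha respectively. Rates are counts /
#' 13 yr; `meanlog` matches the per-fire mean area given `sdlog` (1.5 for
#' the heavy-tailed lightning and military regimes, 1.0 for prescribed).
#'
#' @return A tibble with columns `source`, `season`, `rate`, `meanlog`,
#'   `sdlog`.
#' @export
default_fire_regime <- function() {
  counts <- c(13, 3, 43, 17, 44, 51, 118, 341, 205)
  areas <- c(152, 521, 6093, 1154, 5853, 11115, 15269, 69681, 41129)
  sdlog <- rep(c(1.5, 1.5, 1.0), each = 3)
  tibble(
    source = rep(c("lightning", "military", "prescribed"), each = 3),
    season = rep(c("wet", "dry", "fire"), times = 3),
    rate = counts / 13,
    meanlog = log(areas / counts) - sdlog^2 / 2,
    sdlog = sdlog
  )
}

#' Synthetic-generator configuration
#'
#' @param n_years Number of full calendar years (default 17).
#' @param start_year First calendar year (default 1993).
#' @param seasons Named list of [season_spec()]s (default [default_seasons()]).
#' @param ar1_rho Day-to-day AR(1) autocorrelation of each variable's
#'   residuals, in `[0, 1)` (default 0.7).
#' @param transition_sd_days SD (days) of the Gaussian per-year jitter of
#'   each season boundary (default 10).
#' @param transition_ramp_days Width (days) of the linear ramp over which
#'   the deterministic seasonal course crosses each season boundary
#'   (default 15); `0` or `1` gives hard season-mean steps.
#' @param calm_fraction Long-run fraction of days in the calm synoptic
#'   regime (default 0.75).
#' @param calm_scale Noise-SD multiplier on calm days, in (0, 1] (default
#'   0.5); disturbed-day inflation is derived so the stationary noise
#'   variance still matches the season SDs. `1` disables the regime
#'   structure (homoscedastic Gaussian noise).
#' @param p_leave_calm Daily probability of a calm spell ending (default
#'   0.08, i.e. mean calm spells of about 12 days).
#' @param seed RNG seed; required, no default.
#' @param fire_regime Per (source, season) rates and area parameters
#'   (default [default_fire_regime()]).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_years = 17, start_year = 1993,
                         seasons = default_seasons(), ar1_rho = 0.7,
                         transition_sd_days = 10, transition_ramp_days = 15,
                         calm_fraction = 0.75, calm_scale = 0.5,
                         p_leave_calm = 0.08, seed,
                         fire_regime = default_fire_regime()) {
  if (missing(seed) || is.null(seed)) {
    abort("synth_config() requires an explicit seed")
  }
  stopifnot(n_years >= 2, ar1_rho >= 0, ar1_rho < 1,
            transition_sd_days >= 0, transition_ramp_days >= 0,
            calm_fraction > 0, calm_fraction < 1,
            calm_scale > 0, calm_scale <= 1,
            p_leave_calm > 0, p_leave_calm < 1,
            all(fire_regime$rate >= 0))
  stopifnot(setequal(names(seasons), c("wet", "dry", "fire")))
  structure(list(n_years = n_years, start_year = start_year,
                 seasons = seasons, ar1_rho = ar1_rho,
                 transition_sd_days = transition_sd_days,
                 transition_ramp_days = transition_ramp_days,
                 calm_fraction = calm_fraction, calm_scale = calm_scale,
                 p_leave_calm = p_leave_calm, seed = seed,
                 fire_regime = fire_regime),
            class = "synth_config")
}

# Annual adjacency of the seasons (order of appearance through the year).
season_order <- c("fire", "wet", "dry")

# Smooth a per-day step series with a centered moving average of width
# `width` days: season interiors stay flat at the season level while each
# boundary becomes a linear ramp of that width (endpoints padded).
smooth_step <- function(x, width) {
  if (width <= 1) return(x)
  half <- floor(width / 2)
  width <- 2L * half + 1L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(padded, rep(1 / width, width),
                           sides = 2))[half + seq_along(x)]
}

# Per-day deterministic seasonal course of one variable: season-level steps
# smoothed into boundary ramps, with the step levels adjusted (fixed point)
# so the realized within-season means match the targets exactly.
seasonal_course <- function(labels, means, width) {
  m_eff <- means
  traj <- means[labels]
  for (it in 1:30) {
    traj <- smooth_step(m_eff[labels], width)
    realized <- tapply(traj, labels, mean)[names(means)]
    err <- means - realized
    if (max(abs(err)) < 1e-10) break
    m_eff <- m_eff + err
  }
  traj
}

# Log-scale seasonal course of soil moisture: linear recharge through the
# wet season to a peak at its end, rapid early-dry drawdown (exponential,
# time constant a quarter season) to a low that persists through the dry
# and fire seasons, and a slow linear rebound across the fire season to the
# wet onset. Level parameters solved (fixed point) so each season's mean of
# the course equals the target log-scale mean.
soil_course <- function(labels, meanlogs) {
  decay_mean <- 0.25 * (1 - exp(-4))
  a <- meanlogs[["fire"]]; b <- meanlogs[["wet"]]; clow <- meanlogs[["dry"]]
  for (it in 1:100) {
    b_new <- 2 * meanlogs[["wet"]] - a
    clow_new <- (meanlogs[["dry"]] - decay_mean * b_new) / (1 - decay_mean)
    a_new <- 2 * meanlogs[["fire"]] - clow_new
    if (max(abs(c(a_new - a, b_new - b, clow_new - clow))) < 1e-12) break
    a <- a_new; b <- b_new; clow <- clow_new
  }
  runs <- rle(labels)
  out <- numeric(length(labels))
  pos <- 0L
  for (j in seq_along(runs$lengths)) {
    s <- runs$values[j]
    len <- runs$lengths[j]
    t <- (seq_len(len) - 0.5) / len
    out[pos + seq_len(len)] <- switch(
      s,
      wet = a + (b - a) * t,
      dry = clow + (b - clow) * exp(-t / 0.25),
      fire = clow + (a - clow) * t)
    pos <- pos + len
  }
  out
}

# Markov regime sequence for synoptic activity: "calm" spells concentrated
# at the seasonal course and shorter "disturbed" (frontal/convective)
# spells with inflated variance. Returns the per-day noise scale factor,
# normalized so the stationary noise variance is 1.
regime_scales <- function(n, calm_fraction, calm_scale, p_leave_calm) {
  stopifnot(calm_fraction > 0, calm_fraction < 1,
            calm_scale > 0, calm_scale <= 1)
  disturbed_scale <-
    sqrt((1 - calm_fraction * calm_scale^2) / (1 - calm_fraction))
  p_leave_dist <- p_leave_calm * calm_fraction / (1 - calm_fraction)
  state <- logical(n) # TRUE = calm
  state[1] <- runif(1) < calm_fraction
  if (n > 1) {
    u <- runif(n - 1)
    for (t in 2:n) {
      state[t] <- if (state[t - 1]) u[t - 1] >= p_leave_calm
      else u[t - 1] < p_leave_dist
    }
  }
  ifelse(state, calm_scale, disturbed_scale)
}

# Latent season per day from per-year jittered boundaries. Boundaries are
# the nominal fire/wet/dry season starts; each is jittered independently per
# year, rounded to whole days, then ordered to keep the windows a partition.
latent_seasons <- function(dates, config) {
  s <- config$seasons
  nominal <- c(fire = s$fire$doy_start, wet = s$wet$doy_start,
               dry = s$dry$doy_start)
  yrs <- sort(unique(year(dates)))
  per_year <- lapply(yrs, function(y) {
    b <- round(nominal + rnorm(3, 0, config$transition_sd_days))
    b <- sort(pmax(2, pmin(365, b)))
    setNames(b, c("fire", "wet", "dry"))
  })
  names(per_year) <- as.character(yrs)
  doy <- doy_folded(dates)
  out <- character(length(dates))
  for (i in seq_along(dates)) {
    b <- per_year[[as.character(year(dates[i]))]]
    d <- doy[i]
    out[i] <- if (d >= b[["fire"]] && d < b[["wet"]]) "fire"
    else if (d >= b[["wet"]] && d < b[["dry"]]) "wet"
    else "dry"
  }
  out
}

# Log-normal parameters matching a target natural-scale mean and SD.
lnorm_params <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# AR(1) residual series with season-varying stationary SD.
ar1_series <- function(n, rho, sds) {
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sds[1])
  if (n > 1) {
    z <- rnorm(n - 1)
    fac <- sqrt(1 - rho^2)
    for (t in 2:n) e[t] <- rho * e[t - 1] + fac * sds[t] * z[t - 1]
  }
  e
}

#' Generate a synthetic daily weather series
#'
#' Draws daily weather for `n_years` full calendar years. Each day gets a
#' latent season from the (per-year jittered) day-of-year windows. Each
#' variable follows a deterministic seasonal course (season levels matched
#' to the configured season means, crossed by linear ramps of
#' `transition_ramp_days` at the boundaries) plus AR(1) noise whose
#' stationary variance completes the configured season SD; the noise is
#' modulated by a shared calm/disturbed synoptic regime, so calm spells sit
#' close to the seasonal course and disturbed spells carry the excursions.
#' Soil moisture is generated on the natural-log scale (season-wise
#' log-normal, so its natural scale is positively skewed); rainfall is a
#' zero-inflated gamma draw with season-dependent wet-day probability and
#' mean rate. The latent truth labels are returned in the `season` column.
#'
#' @param config A [synth_config()].
#' @return A tibble: `date`, `rh`, `temp`, `solar`, `wind`, `soil`, `rain`,
#'   `season` (latent truth).
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
                 as.Date(sprintf("%d-12-31",
                                 config$start_year + config$n_years - 1)),
                 by = "day")
    season <- latent_seasons(dates, config)
    s <- config$seasons
    n <- length(dates)
    scales <- if (config$calm_scale < 1) {
      regime_scales(n, config$calm_fraction, config$calm_scale,
                    config$p_leave_calm)
    } else {
      rep(1, n)
    }
    # seasonal course + regime-modulated AR(1) noise; the course carries
    # the boundary ramps, the noise completes the season SD
    gen_var <- function(means, sds) {
      traj <- seasonal_course(season, means, config$transition_ramp_days)
      vtraj <- tapply((traj - means[season])^2, season, mean)[names(means)]
      noise_sd <- sqrt(pmax(sds^2 - vtraj, (0.25 * sds)^2))
      traj + scales * ar1_series(n, config$ar1_rho, noise_sd[season])
    }
    season_field <- function(var, field) {
      vapply(season_order, function(nm) s[[nm]][[var]][field], numeric(1))
    }
    temp <- gen_var(season_field("temp", 1), season_field("temp", 2))
    rh <- pmin(100, pmax(1, gen_var(season_field("rh", 1),
                                    season_field("rh", 2))))
    solar <- pmax(0.001, gen_var(season_field("solar", 1),
                                 season_field("solar", 2)))
    # wind gets its own synoptic stream so that, when configured with equal
    # season means, it carries no signal shared with the other variables
    wind_scales <- if (config$calm_scale < 1) {
      regime_scales(n, config$calm_fraction, config$calm_scale,
                    config$p_leave_calm)
    } else {
      rep(1, n)
    }
    wind_traj <- seasonal_course(season, season_field("wind", 1),
                                 config$transition_ramp_days)
    wind_sd <- season_field("wind", 2)
    wind <- pmax(0.1, wind_traj +
                   wind_scales * ar1_series(n, config$ar1_rho,
                                            wind_sd[season]))
    ln_par <- vapply(season_order, function(nm) {
      lnorm_params(s[[nm]]$soil[1], s[[nm]]$soil[2])
    }, numeric(2))
    soil_traj <- soil_course(season, ln_par["meanlog", ])
    soil_vtraj <-
      tapply((soil_traj - ln_par["meanlog", season])^2, season,
             mean)[season_order]
    soil_noise <- sqrt(pmax(ln_par["sdlog", ]^2 - soil_vtraj,
                            (0.25 * ln_par["sdlog", ])^2))
    soil <- exp(soil_traj +
                  scales * ar1_series(n, config$ar1_rho,
                                      soil_noise[season]))
    rate <- vapply(season, function(nm) s[[nm]]$rain_rate, numeric(1))
    prob <- vapply(season, function(nm) s[[nm]]$rain_prob, numeric(1))
    shape <- 0.8
    wet_day <- rbinom(n, 1, prob) == 1
    rain <- numeric(n)
    if (any(wet_day)) {
      rain[wet_day] <- rgamma(sum(wet_day), shape = shape,
                              scale = rate[wet_day] / (prob[wet_day] * shape))
    }
    tibble(date = dates, rh = rh, temp = temp, solar = solar, wind = wind,
           soil = soil, rain = rain, season = season)
  })
}

#' Generate synthetic fire records
#'
#' Draws per-(source, season) fire counts as Poisson(rate x n_years), dates
#' uniformly over that season's days in the generated weather, and burned
#' areas from the configured log-normal distributions.
#'
#' @param config A [synth_config()].
#' @param weather A weather tibble from [generate_weather()] carrying the
#'   `season` truth column (or any tibble with `date` and `season`).
#' @return A tibble: `date`, `area_ha`, `source`, sorted by date. Empty (0
#'   rows) when all rates are zero.
#' @export
generate_fires <- function(config, weather) {
  stopifnot(inherits(config, "synth_config"),
            all(c("date", "season") %in% names(weather)))
  n_years <- length(unique(year(weather$date)))
  with_seed(config$seed + 1L, {
    rows <- lapply(seq_len(nrow(config$fire_regime)), function(i) {
      cell <- config$fire_regime[i, ]
      days <- weather$date[weather$season == cell$season]
      n_fires <- rpois(1, cell$rate * n_years)
      if (n_fires == 0 || length(days) == 0) return(NULL)
      tibble(date = sample(days, n_fires, replace = TRUE),
             area_ha = rlnorm(n_fires, cell$meanlog, cell$sdlog),
             source = cell$source)
    })
    rows <- purrr::compact(rows)
    if (length(rows) == 0) {
      return(tibble(date = as.Date(character()), area_ha = numeric(),
                    source = character()))
    }
    arrange(list_rbind(rows), .data$date)
  })
}
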
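# Calendar characterization, the seasonality screen, representative-model
# ranking and role assignment.

# Label vector over `years` full years: cluster 2 on days [from, to],
# cluster 1 elsewhere.
window_labels <- function(years, from, to) {
  dates <- seq(as.Date(sprintf("%d-01-01", 2001)),
               as.Date(sprintf("%d-12-31", 2000 + years)), by = "day")
  doy <- lubridate::yday(dates)
  leap <- lubridate::leap_year(dates)
  doy[leap & doy >= 60] <- doy[leap & doy >= 60] - 1L
  list(dates = dates, labels = ifelse(doy >= from & doy <= to, 2L, 1L))
}

test_that("season profile counts days, bins and predominance correctly", {
  wl <- window_labels(4, 98, 173)
  prof <- season_profile(wl$labels, wl$dates)
  cl2 <- prof$clusters[prof$clusters$cluster == 2, ]
  expect_equal(cl2$mean_days_per_year, 76)
  expect_equal(cl2$consistency, 76)
  # predominance intervals recover the construction windows exactly
  pred2 <- prof$predominance[prof$predominance$cluster == 2, ]
  expect_equal(pred2$start_doy, 98)
  expect_equal(pred2$end_doy, 173)
  # histogram: 25 bins, totals equal cluster day counts
  expect_equal(max(prof$histogram$bin), ceiling(366 / 15))
  tots <- tapply(prof$histogram$count, prof$histogram$cluster, sum)
  expect_equal(as.vector(tots[as.character(prof$clusters$cluster)]),
               prof$clusters$n_days)

  # alternating labels: consistency collapses to one day
  alt <- wl
  alt$labels <- rep(c(1L, 2L), length.out = length(wl$labels))
  prof_alt <- season_profile(alt$labels, alt$dates)
  expect_equal(max(prof_alt$clusters$consistency), 1)

  expect_error(season_profile(wl$labels[1:100], wl$dates[1:100]),
               "full years")
})

test_that("the seasonality screen enforces recurring 10-day seasons", {
  wl <- window_labels(4, 120, 210) # 91 contiguous days each year
  expect_true(screen_seasonal(season_profile(wl$labels, wl$dates))$pass)

  # a 9-day window fails the threshold
  wl9 <- window_labels(4, 100, 108)
  scr <- screen_seasonal(season_profile(wl9$labels, wl9$dates))
  expect_false(scr$pass)
  expect_match(scr$clusters$reason[scr$clusters$cluster == 2],
               "not consistent")

  # a cluster present in only some years fails
  wlx <- window_labels(4, 150, 200)
  yr <- lubridate::year(wlx$dates)
  wlx$labels[wlx$labels == 2 & yr > 2002] <- 1L
  scr2 <- screen_seasonal(season_profile(wlx$labels, wlx$dates))
  expect_false(scr2$pass)
})

test_that("ranking averages per-statistic ranks and breaks ties by radius", {
  stats <- tibble::tibble(
    r = c(0.5, 0.6, 0.7),
    mean_r2 = c(0.40, 0.35, 0.30),
    aic = c(100, 90, 120),
    pillai = c(1.2, 1.1, 1.4))
  rk <- rank_models(stats)
  # exhaustive recomputation of the mean ranks
  manual <- (rank(-stats$mean_r2) + rank(stats$aic) +
               rank(-stats$pillai)) / 3
  expect_equal(rk$mean_rank, manual)
  expect_equal(rk$r[rk$selected], stats$r[which.min(manual)])

  # dominance: best on all three wins
  dom <- tibble::tibble(r = c(0.5, 0.6), mean_r2 = c(0.5, 0.3),
                        aic = c(50, 80), pillai = c(1.5, 1.0))
  expect_equal(rank_models(dom)$r[rank_models(dom)$selected], 0.5)

  # single survivor is selected trivially
  one <- dom[1, ]
  expect_true(rank_models(one)$selected)

  # circular rankings: tie on mean rank broken toward smaller radius
  circ <- tibble::tibble(
    r = c(0.5, 0.6, 0.7),
    mean_r2 = c(0.40, 0.35, 0.30),
    aic = c(120, 90, 100),
    pillai = c(1.1, 1.0, 1.4))
  rkc <- rank_models(circ)
  expect_equal(length(unique(rkc$mean_rank)), 1)
  expect_equal(rkc$r[rkc$selected], 0.5)

  expect_error(rank_models(dom[0, ]), "no surviving")
})

test_that("role assignment recovers wet/dry/fire from weather structure", {
  cfg <- synth_config(n_years = 3, seed = 10)
  w <- generate_weather(cfg)
  f <- fw_features(w)
  truth_lab <- match(w$season, c("wet", "dry", "fire"))
  roles <- assign_roles(truth_lab, f)
  expect_equal(unname(roles[c("1", "2", "3")]), c("wet", "dry", "fire"))

  # k = 2 models get no roles
  expect_true(all(assign_roles(rep(1:2, length.out = nrow(f)), f) == "none"))

  # solar and humidity pointing at different clusters yields none + warning
  w2 <- w
  w2$solar <- ifelse(w2$season == "wet", 0.3, 0.1) +
    withr::with_seed(1, rnorm(nrow(w2), 0, 0.01))
  f2 <- fw_features(w2, c("rh", "temp", "solar", "soil"))
  expect_warning(r2 <- assign_roles(truth_lab, f2), "ambiguous")
  expect_true(all(r2 == "none"))
})

test_that("representative selection finds the seasonal model in a sweep", {
  cfg <- synth_config(n_years = 6, seed = 20)
  w <- generate_weather(cfg)
  f <- fw_features(w)
  sw <- sweep_radius(f, seq(0.5, 0.9, length.out = 8), ck = 50)
  sel <- select_representative(sw)
  expect_s3_class(sel$model, "fw_cluster")
  expect_gte(sel$model$k, 2)
  expect_lte(sel$model$k, 8)
  expect_true(sel$stats$r %in% sw$stats$r)
  # the winner minimizes the mean rank within the screened survivors
  expect_equal(min(sel$ranking$mean_rank),
               sel$ranking$mean_rank[sel$ranking$selected])
})
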
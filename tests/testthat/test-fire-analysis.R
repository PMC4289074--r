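# Fire-record ingestion, season attribution and the regime summaries.

table4_path <- function() {
  system.file("extdata", "table4_fires.csv", package = "fireseasons")
}
table3_path <- function() {
  system.file("extdata", "table3_summary.csv", package = "fireseasons")
}

test_that("fire records read, validate and reject malformed rows", {
  fires <- read_fire_records(table4_path())
  expect_equal(nrow(fires), 20)
  expect_setequal(unique(fires$source), c("lightning", "military"))
  expect_true(all(fires$area_ha > 0))
  expect_true(is.numeric(fires$cluster))

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,area_ha,source", "2001-05-01,10,arson"), path)
  expect_error(read_fire_records(path), "arson")
  writeLines(c("date,area_ha,source", "2001-05-01,-1,lightning"), path)
  expect_error(read_fire_records(path), "area")
  writeLines(c("date,area_ha,source", "someday,3,lightning"), path)
  expect_error(read_fire_records(path), "date")
})

test_that("season attribution joins the ignition day's context", {
  day_tab <- tibble::tibble(
    date = seq(as.Date("2001-01-01"), by = "day", length.out = 10),
    cluster = c(rep(1L, 5), rep(2L, 4), 0L),
    role = c(rep("dry", 5), rep("fire", 4), "none"),
    temp = 1:10, f1 = (1:10) / 10, f2 = -(1:10) / 10)
  fires <- tibble::tibble(date = day_tab$date[c(2, 7)],
                          area_ha = c(5, 50),
                          source = c("prescribed", "lightning"))
  joined <- attach_season(fires, day_tab)
  expect_equal(joined$role, c("dry", "fire"))
  expect_equal(joined$temp, c(2, 7))
  expect_equal(joined$f1, c(0.2, 0.7))

  expect_warning(
    attach_season(tibble::tibble(date = day_tab$date[10], area_ha = 1,
                                 source = "military"), day_tab),
    "unassigned")
  expect_error(
    attach_season(tibble::tibble(date = as.Date("1990-01-01"), area_ha = 1,
                                 source = "military"), day_tab),
    "outside")
})

test_that("the aggregate regime fixture reproduces the printed shares", {
  agg <- readr::read_csv(table3_path(), show_col_types = FALSE)
  s <- season_source_summary(agg)
  share <- function(src, sea, what) {
    s[[what]][s$source == src & s$season == sea]
  }
  expect_equal(share("lightning", "fire", "pct_fires"), 73)
  expect_equal(share("lightning", "wet", "pct_fires"), 22)
  expect_equal(share("lightning", "dry", "pct_fires"), 5)
  expect_equal(share("lightning", "fire", "pct_area"), 90)
  expect_equal(share("military", "fire", "pct_fires"), 46)
  expect_equal(share("military", "dry", "pct_fires"), 39)
  expect_equal(share("military", "wet", "pct_fires"), 15)
  expect_equal(share("military", "fire", "pct_area"), 61)
  expect_equal(share("prescribed", "dry", "pct_fires"), 51)
  expect_equal(share("prescribed", "dry", "pct_area"), 55)
  # shares sum to 100 +/- 1 within each source
  sums <- tapply(s$pct_fires, s$source, sum)
  expect_true(all(abs(sums - 100) <= 1))
})

test_that("summaries of raw joined records aggregate counts and areas", {
  fires <- tibble::tibble(
    date = as.Date("2001-06-01") + c(0, 1, 2, 40),
    area_ha = c(10, 30, 60, 100),
    source = c("lightning", "lightning", "lightning", "military"),
    role = c("fire", "fire", "wet", "dry"),
    temp = c(25, 26, 27, 20))
  s <- season_source_summary(fires)
  li_fire <- s[s$source == "lightning" & s$season == "fire", ]
  expect_equal(li_fire$n_fires, 2)
  expect_equal(li_fire$area_ha, 40)
  expect_equal(li_fire$temp_mean, 25.5)
  expect_equal(li_fire$temp_sd, sd(c(25, 26)))
  expect_equal(li_fire$pct_fires, 67)
  # a single fire owns 100% of its source
  expect_equal(s$pct_fires[s$source == "military"], 100)
  # exact totals per source
  expect_equal(sum(s$area_ha[s$source == "lightning"]), 100)
})

test_that("top-n ranking follows area with date tie-breaks", {
  fires <- read_fire_records(table4_path())
  top3 <- top_n_fires(fires, "lightning", 3)
  expect_equal(top3$area_ha, c(1914, 1652, 549))
  top_mil <- top_n_fires(fires, "military", 1)
  expect_equal(top_mil$area_ha, 2128)
  expect_equal(top_mil$date, as.Date("2006-05-04"))

  expect_equal(nrow(top_n_fires(fires, "prescribed", 5)), 0)
  expect_warning(all20 <- top_n_fires(fires, "lightning", 99), "only")
  expect_equal(nrow(all20), 10)
  # tie on area: earlier date first
  tied <- tibble::tibble(date = as.Date(c("2001-02-01", "2001-01-01")),
                         area_ha = c(7, 7), source = "lightning")
  expect_equal(top_n_fires(tied, "lightning", 2)$date,
               sort(tied$date))
  # top-10 never exceeds the source total
  expect_lte(sum(top_n_fires(fires, "military", 10)$area_ha),
             sum(fires$area_ha[fires$source == "military"]))
})

test_that("peak-mode overlay concentrates the largest lightning fires", {
  fires <- read_fire_records(table4_path())
  ov <- peak_mode_overlay(fires)
  li7 <- ov[ov$source == "lightning" & ov$cluster == 7, ]
  expect_equal(li7$n_fires, 5)
  expect_equal(attr(ov, "peak_mode"), 7)

  # printed aggregate pair: 4668 of 6766 ha in the peak cluster -> 69%
  pair <- readr::read_csv(
    system.file("extdata", "lightning_cluster_areas.csv",
                package = "fireseasons"), show_col_types = FALSE)
  ov2 <- peak_mode_overlay(pair)
  expect_equal(ov2$share_pct[ov2$cluster == "7"], 69)

  none <- fires[fires$source == "military", ]
  expect_warning(ovn <- peak_mode_overlay(none), "peak mode undefined")
  expect_true(is.na(attr(ovn, "peak_mode")))
})

test_that("bubble export scales disc radius with the square root of area", {
  fires <- tibble::tibble(date = as.Date("2001-01-01") + 0:2,
                          area_ha = c(0.0001, 4, 16),
                          source = "lightning", role = "fire",
                          f1 = 1:3, f2 = 3:1)
  b <- bubble_plot_export(fires)
  expect_equal(nrow(b), 3)
  expect_gt(b$radius[1], 0)
  expect_equal(b$radius[3] / b$radius[2], 2)
})
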
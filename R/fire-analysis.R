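# Fire-record ingestion, season attribution, regime summary tables, top-10
# rankings, peak-mode overlay and bubble-plot export.

fire_sources <- c("lightning", "military", "prescribed")

#' Read a fire-record table
#'
#' CSV with one row per fire: `date` (ignition date, ISO-8601 or m/d/Y),
#' `area_ha` (> 0) and `source` (lightning, military or prescribed). Extra
#' columns (e.g. a precomputed fine-model `cluster`) are kept.
#'
#' @param path CSV path.
#' @return A tibble of validated records sorted by date.
#' @export
read_fire_records <- function(path) {
  if (!file.exists(path)) abort(paste0("fire file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("date", "area_ha", "source")
  if (!all(needed %in% names(raw))) {
    abort(paste0("fire CSV must have columns ",
                 paste(needed, collapse = ", ")))
  }
  date <- as.Date(raw$date, tryFormats = c("%Y-%m-%d", "%m/%d/%Y"),
                  optional = TRUE)
  if (anyNA(date)) {
    abort(paste0("unparseable fire date at row ", which(is.na(date))[1]))
  }
  area <- suppressWarnings(as.numeric(gsub(",", "", raw$area_ha)))
  bad <- which(is.na(area) | area <= 0)
  if (length(bad) > 0) {
    abort(paste0("invalid area (must be > 0) at row ", bad[1]))
  }
  src <- raw$source
  bad <- which(!src %in% fire_sources)
  if (length(bad) > 0) {
    abort(paste0("unknown ignition source '", src[bad[1]], "' at row ",
                 bad[1]))
  }
  out <- tibble(date = date, area_ha = area, source = src)
  extra <- setdiff(names(raw), needed)
  for (v in extra) {
    num <- suppressWarnings(as.numeric(raw[[v]]))
    out[[v]] <- if (all(is.na(num) == is.na(raw[[v]]))) num else raw[[v]]
  }
  arrange(out, .data$date)
}

#' Per-day season table for joining fires onto
#'
#' Combines a cluster model, its season roles, the underlying weather and
#' (optionally) a fitted discriminant model into one per-day tibble:
#' `date`, `cluster`, `role`, the weather variables and fire-weather-plane
#' coordinates `f1`, `f2`.
#'
#' @param model `fw_cluster` with dates.
#' @param features The [fw_features()] it was fitted on.
#' @param roles Named roles from [assign_roles()] (optional).
#' @param dmodel [fw_discriminant()] fitted on the same model (optional).
#' @param weather Optional weather tibble for raw weather columns on the
#'   original scales.
#' @return A tibble keyed by `date`.
#' @export
season_day_table <- function(model, features, roles = NULL, dmodel = NULL,
                             weather = NULL) {
  stopifnot(inherits(model, "fw_cluster"), !is.null(model$date))
  out <- tibble(date = model$date, cluster = model$labels)
  if (!is.null(roles)) {
    out$role <- ifelse(out$cluster == 0, "none",
                       unname(roles[as.character(out$cluster)]))
    out$role[is.na(out$role)] <- "none"
  }
  if (!is.null(weather)) {
    out <- left_join(out, weather[c("date",
                                    intersect(fw_variables,
                                              names(weather)))],
                     by = "date")
  }
  if (!is.null(dmodel)) {
    out <- left_join(out, fw_project(dmodel, features), by = "date")
  }
  out
}

#' Attach season and weather context to fire records
#'
#' Joins each fire's ignition date onto the per-day season table: cluster,
#' season role, weather vector and fire-weather-plane coordinates. Fires on
#' unassigned days get role `"none"` (warning); fires outside the weather
#' span are an error.
#'
#' @param fires Fire tibble (see [read_fire_records()]).
#' @param day_table Per-day tibble from [season_day_table()] (any tibble
#'   keyed by `date` works).
#' @return The fire tibble with the joined columns.
#' @export
attach_season <- function(fires, day_table) {
  stopifnot("date" %in% names(day_table))
  missing <- setdiff(as.character(fires$date),
                     as.character(day_table$date))
  if (length(missing) > 0) {
    abort(paste0("fire date(s) outside the weather series: ",
                 paste(missing, collapse = ", ")))
  }
  out <- left_join(fires, day_table, by = "date",
                   suffix = c("", ".day"))
  if ("role" %in% names(out) && any(out$role == "none")) {
    warn(sprintf("%d fire(s) fall on unassigned days (role 'none')",
                 sum(out$role == "none")))
  }
  out
}

#' Fire-regime summary by ignition source and season
#'
#' Per (source, season role): number of fires, total burned area, mean and
#' sample SD of each weather variable on ignition days and of the (linear)
#' day of year, plus each source's integer-rounded percentage shares of
#' counts and area across seasons.
#'
#' @param fires Joined fire tibble carrying a `role` (or `season`) column;
#'   may be a pre-aggregated table with `n_fires` and `area_ha` per cell.
#' @return A tibble with one row per (source, season) cell, including
#'   `pct_fires` and `pct_area` shares within source.
#' @export
season_source_summary <- function(fires) {
  season_col <- if ("role" %in% names(fires)) "role" else "season"
  stopifnot(season_col %in% names(fires), "source" %in% names(fires))
  pre_aggregated <- "n_fires" %in% names(fires)
  if (pre_aggregated) {
    cells <- fires
    cells$season <- cells[[season_col]]
  } else {
    wvars <- intersect(fw_variables, names(fires))
    cells <- summarize(
      group_by(fires, source = .data$source, season = .data[[season_col]]),
      n_fires = dplyr::n(),
      area_ha = sum(.data$area_ha),
      across(all_of(wvars),
             list(mean = ~ mean(.x, na.rm = TRUE),
                  sd = ~ sd(.x, na.rm = TRUE))),
      doy_mean = mean(doy_folded(.data$date)),
      doy_sd = sd(doy_folded(.data$date)),
      .groups = "drop")
  }
  mutate(group_by(cells, .data$source),
         pct_fires = percent_shares(.data$n_fires),
         pct_area = percent_shares(.data$area_ha)) |>
    ungroup()
}

#' Largest fires of one ignition source
#'
#' The `n` largest fires by burned area, descending; ties broken by
#' earlier date. Warns and returns all records when fewer than `n` exist.
#'
#' @param fires Fire tibble (joined or raw).
#' @param source One of lightning, military, prescribed.
#' @param n Number of fires (default 10).
#' @return The ranked tibble with a `rank` column.
#' @export
top_n_fires <- function(fires, source, n = 10) {
  sub <- filter(fires, .data$source == !!source)
  if (nrow(sub) == 0) return(mutate(sub, rank = integer(0)))
  if (nrow(sub) < n) {
    warn(sprintf("only %d %s fires available (requested %d)",
                 nrow(sub), source, n))
    n <- nrow(sub)
  }
  sub <- arrange(sub, desc(.data$area_ha), .data$date)[seq_len(n), ]
  mutate(sub, rank = seq_len(n), .before = 1)
}

#' Peak-mode overlay of fires on a finer cluster model
#'
#' Tallies fires per (fine cluster, source): count, total area and share of
#' the source's area, and flags the "peak mode" — the fine cluster holding
#' the largest share of lightning-burned area. The fine labels come either
#' from a `cluster` column already on the fire records (e.g. printed
#' rankings) or from a day table of an 8-cluster model.
#'
#' @param fires Fire tibble; needs `cluster` or a `fine` day table.
#' @param fine Optional tibble with `date` and `cluster` supplying per-day
#'   fine-model labels.
#' @param total_area Optional named vector of per-source total areas to
#'   compute shares against (defaults to the totals present in `fires`) —
#'   useful when `fires` holds only the top-ranked subset of the record.
#' @return A tibble (`cluster`, `source`, `n_fires`, `area_ha`,
#'   `share_pct`) with attribute `"peak_mode"` (the peak cluster id);
#'   warns and returns `NA` peak when there are no lightning fires.
#' @export
peak_mode_overlay <- function(fires, fine = NULL, total_area = NULL) {
  if (!"cluster" %in% names(fires)) {
    if (is.null(fine)) abort("need fine-model labels: a 'cluster' column or `fine`")
    fires <- left_join(fires, fine[c("date", "cluster")], by = "date")
  }
  totals <- total_area %||% tapply(fires$area_ha, fires$source, sum)
  out <- summarize(group_by(fires, .data$cluster, .data$source),
                   n_fires = dplyr::n(), area_ha = sum(.data$area_ha),
                   .groups = "drop")
  out <- mutate(out,
                share_pct = round_half_away(
                  100 * .data$area_ha /
                    unname(totals[as.character(.data$source)])))
  li <- filter(out, .data$source == "lightning")
  if (nrow(li) == 0) {
    warn("no lightning fires; peak mode undefined")
    peak <- NA_integer_
  } else {
    peak <- li$cluster[which.max(li$area_ha)]
  }
  attr(out, "peak_mode") <- peak
  out
}

#' Export table for fire-weather-plane bubble plots
#'
#' One row per fire with plane coordinates, area, source and season; the
#' `radius` column scales with the square root of area so disc area is
#' proportional to burned area, floored at the radius of a 1-ha fire so
#' tiny fires stay visible.
#'
#' @param fires Joined fire tibble with `f1`, `f2`, `area_ha`.
#' @return A tibble: `f1`, `f2`, `area_ha`, `source`, `season`, `radius`.
#' @export
bubble_plot_export <- function(fires) {
  stopifnot(all(c("f1", "f2", "area_ha", "source") %in% names(fires)))
  season <- if ("role" %in% names(fires)) fires$role else
    if ("season" %in% names(fires)) fires$season else NA_character_
  tibble(f1 = fires$f1, f2 = fires$f2, area_ha = fires$area_ha,
         source = fires$source, season = season,
         radius = sqrt(pmax(fires$area_ha, 1)))
}
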
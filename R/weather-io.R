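# Reading daily weather tables and building the standardized feature matrix.

fw_variables <- c("rh", "temp", "solar", "wind", "soil", "rain")

#' Read a daily weather table
#'
#' Reads a CSV of daily fire-weather observations: relative humidity (`rh`,
#' %), air temperature (`temp`, deg C), solar radiation (`solar`, mW m^-2),
#' wind speed (`wind`), soil moisture at 30--60 cm depth (`soil`, mm) and
#' optionally daily rainfall (`rain`, cm). Dates must be ISO-8601, strictly
#' increasing and unique; soil moisture must be strictly positive wherever
#' present because downstream analysis log-transforms it.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   (`date`, `rh`, `temp`, `solar`, `wind`, `soil`, `rain`) to the column
#'   names used in the file, e.g. `c(date = "DATE", soil = "SM_30_60")`.
#'   Can also be the path to a YAML file holding such a mapping.
#' @return A tibble with a `Date` column `date` and the mapped numeric
#'   columns. Calendar gaps (missing days inside the span) are recorded in
#'   the `"gap_dates"` attribute.
#' @export
read_daily_weather <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("weather file not found: ", path))
  if (is.character(column_map) && length(column_map) == 1 &&
      file.exists(column_map)) {
    column_map <- unlist(yaml::read_yaml(column_map))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.null(column_map)) {
    present <- column_map[column_map %in% names(raw)]
    missing <- setdiff(column_map, names(raw))
    if (length(missing) > 0) {
      abort(paste0("mapped columns absent from file: ",
                   paste(missing, collapse = ", ")))
    }
    raw <- rename(raw, !!!setNames(present, names(present)))
  }
  if (!"date" %in% names(raw)) abort("no 'date' column after mapping")
  out <- validate_weather(parse_weather_columns(raw))
  out
}

parse_weather_columns <- function(raw) {
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(date)) {
    bad <- which(is.na(date))[1]
    abort(paste0("unparseable date at row ", bad, ": '", raw$date[bad], "'"))
  }
  out <- tibble(date = date)
  for (v in intersect(fw_variables, names(raw))) {
    cell <- raw[[v]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & cell != "" & is.na(num))
    if (length(bad) > 0) {
      abort(paste0("unparseable value in '", v, "' at row ", bad[1],
                   ": '", cell[bad[1]], "'"))
    }
    out[[v]] <- num
  }
  out
}

#' Validate a daily weather tibble
#'
#' Checks the invariants assumed downstream: unique strictly increasing
#' dates and strictly positive soil moisture. Records interior calendar gaps
#' in the `"gap_dates"` attribute.
#'
#' @param weather A tibble with a `date` column and weather columns.
#' @return The (sorted) tibble, invisibly validated.
#' @export
validate_weather <- function(weather) {
  stopifnot(is.data.frame(weather), "date" %in% names(weather))
  weather <- arrange(weather, .data$date)
  dup <- weather$date[duplicated(weather$date)]
  if (length(dup) > 0) {
    abort(paste0("duplicated date(s): ", paste(unique(dup), collapse = ", ")))
  }
  if ("soil" %in% names(weather)) {
    bad <- which(!is.na(weather$soil) & weather$soil <= 0)
    if (length(bad) > 0) {
      abort(paste0("non-positive soil moisture on ",
                   paste(weather$date[bad[1:min(3, length(bad))]],
                         collapse = ", "),
                   " (log transform requires soil > 0)"))
    }
  }
  full <- seq(min(weather$date), max(weather$date), by = "day")
  attr(weather, "gap_dates") <- as.Date(setdiff(full, weather$date),
                                        origin = "1970-01-01")
  weather
}

#' Write a daily weather table
#'
#' Inverse of [read_daily_weather()]: writes the canonical CSV layout with
#' full numeric precision so a read-back reproduces the values exactly.
#'
#' @param weather Weather tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_weather <- function(weather, path) {
  out <- mutate(weather,
                across(where(is.numeric), ~ format(.x, digits = 17)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-variable skewness report
#'
#' Sample skewness (adjusted Fisher--Pearson, i.e. the bias-corrected
#' `type = 2` estimator) for each requested variable, with a flag marking
#' strong asymmetry. Soil moisture on its natural scale is typically the
#' only strongly positively skewed fire-weather variable, which is why it
#' is log-transformed before clustering.
#'
#' @param weather Weather tibble.
#' @param variables Character vector of variable names (default: all weather
#'   variables present).
#' @param threshold Absolute-skewness flag threshold (default 1.0).
#' @return A tibble with columns `variable`, `n`, `skewness`, `flagged`.
#' @export
skewness_report <- function(weather, variables = NULL, threshold = 1.0) {
  variables <- variables %||% intersect(fw_variables, names(weather))
  stopifnot(all(variables %in% names(weather)))
  rows <- lapply(variables, function(v) {
    x <- weather[[v]][!is.na(weather[[v]])]
    if (length(x) < 3) abort(paste0("need >= 3 values to estimate skewness ('",
                                    v, "')"))
    if (sd(x) == 0) abort(paste0("skewness undefined for constant variable '",
                                 v, "'"))
    tibble(variable = v, n = length(x),
           skewness = e1071::skewness(x, type = 2))
  })
  mutate(list_rbind(rows), flagged = abs(.data$skewness) > threshold)
}

#' Build the transformed, standardized feature matrix
#'
#' Applies a natural-log transform to the requested variables (soil moisture
#' by default), drops days missing any selected variable, and z-standardizes
#' each column (sample SD, n-1) so every variable has equal weight in the
#' distance-based clustering. The post-transform, pre-standardization values
#' are retained for ANOVA and role assignment on interpretable scales.
#'
#' @param weather Weather tibble (see [read_daily_weather()]).
#' @param variables Variables to include, in the column order that all
#'   downstream eigen-decompositions will see. Default
#'   `c("rh", "temp", "solar", "soil")` — the four-variable set without wind
#'   speed.
#' @param log_vars Subset of `variables` to ln-transform (default `"soil"`,
#'   where it intersects `variables`).
#' @return An object of class `fw_features`: a tibble of `date` plus the
#'   standardized columns, carrying attributes `raw` (post-transform,
#'   pre-standardization tibble), `variables`, `log_vars`, `center`, `scale`
#'   and `dropped` (dates excluded for missingness).
#' @export
fw_features <- function(weather, variables = c("rh", "temp", "solar", "soil"),
                        log_vars = intersect("soil", variables)) {
  stopifnot(is.data.frame(weather), all(variables %in% names(weather)))
  if (!all(log_vars %in% variables)) {
    abort("log_vars must be a subset of variables")
  }
  weather <- validate_weather(weather)
  keep <- complete.cases(weather[variables])
  dropped <- weather$date[!keep]
  dat <- weather[keep, c("date", variables)]
  if (nrow(dat) == 0) abort("no complete rows left after missing-row removal")
  for (v in log_vars) {
    if (any(dat[[v]] <= 0)) {
      abort(paste0("variable '", v, "' must be strictly positive for log ",
                   "transform"))
    }
    dat[[v]] <- log(dat[[v]])
  }
  raw <- dat
  center <- vapply(dat[variables], mean, numeric(1))
  scale <- vapply(dat[variables], sd, numeric(1))
  zero <- variables[scale == 0 | !is.finite(scale)]
  if (length(zero) > 0) {
    abort(paste0("zero-variance variable(s): ", paste(zero, collapse = ", ")))
  }
  for (v in variables) dat[[v]] <- (dat[[v]] - center[[v]]) / scale[[v]]
  structure(dat,
            class = c("fw_features", class(tibble())),
            raw = raw, variables = variables, log_vars = log_vars,
            center = center, scale = scale, dropped = dropped)
}

#' @export
print.fw_features <- function(x, ...) {
  cat("<fw_features> ", nrow(x), " days x ", length(feature_vars(x)),
      " standardized variables (",
      paste(feature_vars(x), collapse = ", "), ")\n", sep = "")
  if (length(attr(x, "log_vars")) > 0) {
    cat("  ln-transformed: ", paste(attr(x, "log_vars"), collapse = ", "),
        "\n", sep = "")
  }
  NextMethod()
}

#' Accessors for feature objects
#'
#' `feature_matrix()` returns the standardized day-by-variable matrix,
#' `raw_matrix()` the post-transform pre-standardization matrix,
#' `feature_vars()` the ordered variable names and `feature_dates()` the
#' per-row dates.
#'
#' @param x An `fw_features` object.
#' @return A matrix, character vector or `Date` vector respectively.
#' @export
feature_matrix <- function(x) {
  stopifnot(inherits(x, "fw_features"))
  as.matrix(as.data.frame(x)[feature_vars(x)])
}

#' @rdname feature_matrix
#' @export
raw_matrix <- function(x) {
  stopifnot(inherits(x, "fw_features"))
  as.matrix(as.data.frame(attr(x, "raw"))[feature_vars(x)])
}

#' @rdname feature_matrix
#' @export
feature_vars <- function(x) attr(x, "variables")

#' @rdname feature_matrix
#' @export
feature_dates <- function(x) x$date

# Apply the transform + standardization of a fitted fw_features object to
# new weather rows (same variables, same centering), for projection.
apply_feature_pipeline <- function(features, weather) {
  vars <- feature_vars(features)
  if (!all(vars %in% names(weather))) {
    abort(paste0("new data lacks variable(s): ",
                 paste(setdiff(vars, names(weather)), collapse = ", ")))
  }
  dat <- weather[vars]
  for (v in attr(features, "log_vars")) dat[[v]] <- log(dat[[v]])
  center <- attr(features, "center"); scale <- attr(features, "scale")
  for (v in vars) dat[[v]] <- (dat[[v]] - center[[v]]) / scale[[v]]
  as.matrix(dat)
}
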
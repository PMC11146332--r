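#' Site metadata
#'
#' Describes the location a weather series belongs to. Latitude drives the
#' solar geometry of the radiation budget; elevation drives atmospheric
#' pressure and hence the psychrometric constant.
#'
#' @param name Site name.
#' @param latitude Decimal degrees, positive north. Must lie in [-90, 90].
#' @param elevation Metres above sea level (>= -430, the Dead Sea shore).
#' @return An object of class `site_meta`.
#' @examples
#' site_meta("Berubari", latitude = 26.38, elevation = 80)
#' @export
site_meta <- function(name, latitude, elevation) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(latitude) || length(latitude) != 1L ||
      latitude < -90 || latitude > 90) {
    stop("latitude must be a single value in [-90, 90]", call. = FALSE)
  }
  if (!is.numeric(elevation) || length(elevation) != 1L || elevation < -430) {
    stop("elevation must be a single value >= -430 m", call. = FALSE)
  }
  structure(list(name = name, latitude = as.numeric(latitude),
                 elevation = as.numeric(elevation)),
            class = "site_meta")
}

#' @export
print.site_meta <- function(x, ...) {
  cat(sprintf("<site_meta> %s (lat %.2f deg, elev %.0f m)\n",
              x$name, x$latitude, x$elevation))
  invisible(x)
}

# Canonical variable order; every input combination is a subset in this order.
WEATHER_VARS <- c("tmin", "tmax", "ws", "rh", "sr")

#' Daily weather series
#'
#' A data frame of daily weather records with a `site_meta` attribute.
#' Mandatory columns are `date` (class `Date`), `tmin` and `tmax` (deg C);
#' optional columns are `ws` (wind speed, m/s at 2 m), `rh` (relative
#' humidity, percent) and `sr` (solar radiation, MJ m-2 d-1). Rows are
#' sorted by date; dates are unique; `tmin <= tmax`; `rh` in [0, 100];
#' `ws` and `sr` non-negative.
#'
#' @param records Data frame with at least `date`, `tmin`, `tmax`.
#' @param site A [site_meta()] object.
#' @return An object of class `weather_series` (a data frame).
#' @export
weather_series <- function(records, site) {
  stopifnot(is.data.frame(records), inherits(site, "site_meta"))
  needed <- c("date", "tmin", "tmax")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[, intersect(c("date", WEATHER_VARS),
                                                names(records)), drop = FALSE]
  records$date <- as.Date(records$date)
  records <- records[order(records$date), , drop = FALSE]
  rownames(records) <- NULL
  out <- structure(records, site = site,
                   class = c("weather_series", "data.frame"))
  validate_weather_series(out)
  out
}

validate_weather_series <- function(x) {
  if (anyNA(x$date)) stop("undated records present", call. = FALSE)
  if (anyDuplicated(x$date)) stop("duplicate dates present", call. = FALSE)
  if (is.unsorted(x$date, strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  bad <- which(x$tmin > x$tmax)
  if (length(bad)) {
    stop("tmin > tmax at row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  if ("rh" %in% names(x) && any(x$rh < 0 | x$rh > 100, na.rm = TRUE)) {
    stop("rh outside [0, 100]", call. = FALSE)
  }
  if ("ws" %in% names(x) && any(x$ws < 0, na.rm = TRUE)) {
    stop("negative wind speed", call. = FALSE)
  }
  if ("sr" %in% names(x) && any(x$sr < 0, na.rm = TRUE)) {
    stop("negative solar radiation", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.weather_series <- function(x, ...) {
  s <- attr(x, "site")
  cat(sprintf("<weather_series> %d days, %s to %s, site %s\n",
              nrow(x), format(min(x$date)), format(max(x$date)), s$name))
  cat("variables:", paste(intersect(WEATHER_VARS, names(x)), collapse = ", "),
      "\n")
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Which weather variables a series carries
#' @param series A [weather_series()].
#' @return Character vector, a subset of `c("tmin","tmax","ws","rh","sr")`.
#' @export
available_variables <- function(series) {
  intersect(WEATHER_VARS, names(series))
}

# Column mapping of the CSV dialect
CSV_COLS <- c(date = "date", tmin = "tmin_c", tmax = "tmax_c",
              ws = "ws_ms", rh = "rh_pct", sr = "sr_mj_m2_d")

#' Read a daily weather CSV
#'
#' Reads the package's CSV dialect (header
#' `date,tmin_c,tmax_c,ws_ms,rh_pct,sr_mj_m2_d`, ISO-8601 dates). The
#' optional columns may be absent. Rows violating a record invariant
#' (unparseable date, `tmin > tmax`, `rh` outside [0, 100], negative `ws` or
#' `sr`) are rejected with a warning naming the row and the rule; valid rows
#' are kept. The number of rejected rows is attached as attribute
#' `n_rejected`.
#'
#' @param path Path to a CSV file.
#' @param site A [site_meta()] object.
#' @return A [weather_series()].
#' @export
read_weather_csv <- function(path, site) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- CSV_COLS[c("date", "tmin", "tmax")]
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("CSV lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  present <- CSV_COLS[CSV_COLS %in% names(raw)]
  df <- raw[, present, drop = FALSE]
  names(df) <- names(present)
  df$date <- as.Date(df$date, format = "%Y-%m-%d")

  reject <- rep(FALSE, nrow(df))
  note <- function(rows, rule) {
    rows <- which(rows & !reject)
    if (length(rows)) {
      warning(sprintf("rejected row(s) %s: %s",
                      paste(utils::head(rows, 10L), collapse = ", "), rule),
              call. = FALSE)
      reject[rows] <<- TRUE
    }
  }
  note(is.na(df$date), "malformed or missing date")
  note(is.na(df$tmin) | is.na(df$tmax), "missing temperature")
  note(!is.na(df$tmin) & !is.na(df$tmax) & df$tmin > df$tmax, "tmin > tmax")
  if ("rh" %in% names(df)) {
    note(!is.na(df$rh) & (df$rh < 0 | df$rh > 100), "rh outside [0, 100]")
  }
  if ("ws" %in% names(df)) note(!is.na(df$ws) & df$ws < 0, "negative ws")
  if ("sr" %in% names(df)) note(!is.na(df$sr) & df$sr < 0, "negative sr")

  out <- weather_series(df[!reject, , drop = FALSE], site)
  attr(out, "n_rejected") <- sum(reject)
  out
}

#' Write a daily weather CSV
#'
#' Inverse of [read_weather_csv()]; a write/read round trip reproduces the
#' series (site metadata is supplied by the reader, not stored in the file).
#'
#' @param series A [weather_series()].
#' @param path Output path.
#' @param extra Optional data frame of extra columns (e.g. an `et0_mm_d`
#'   column) appended verbatim.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(series, path, extra = NULL) {
  present <- CSV_COLS[names(CSV_COLS) %in% names(series)]
  df <- as.data.frame(series)[, names(present), drop = FALSE]
  names(df) <- present
  df$date <- format(df$date, "%Y-%m-%d")
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Chronological train/test split
#'
#' Splits a series into a leading training part of `floor(n * train_fraction)`
#' records and a trailing test part, preserving order — the split the model
#' evaluation protocol uses (70/30 by default, no shuffling).
#'
#' @param series A [weather_series()].
#' @param train_fraction Proportion in (0, 1); default 0.7.
#' @return A list with elements `train` and `test`, both `weather_series`.
#' @export
chronological_split <- function(series, train_fraction = 0.7) {
  stopifnot(inherits(series, "weather_series"))
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  n <- nrow(series)
  n_train <- floor(n * train_fraction)
  site <- attr(series, "site")
  list(
    train = weather_series(series[seq_len(n_train), , drop = FALSE], site),
    test = weather_series(series[setdiff(seq_len(n), seq_len(n_train)), ,
                                 drop = FALSE], site)
  )
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `g1 * sqrt(n(n-1))/(n-2)` with `g1 = m3 / m2^(3/2)` on central moments.
#' Returns `NA` for zero variance or `n < 3`.
#'
#' @param x Numeric vector.
#' @return Skewness coefficient, or `NA_real_`.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Dataset summary statistics
#'
#' Min, max, standard deviation, coefficient of variation (sd/mean) and
#' skewness for every weather variable present. The standard deviation is the
#' population form (divisor n); skewness is the adjusted Fisher-Pearson
#' sample coefficient. A zero mean yields `NA` for cv rather than infinity;
#' zero variance yields `NA` skewness.
#'
#' @param series A [weather_series()].
#' @return Data frame with columns `variable, min, max, sd, cv, sk`.
#' @export
summary_statistics <- function(series) {
  vars <- available_variables(series)
  rows <- lapply(vars, function(v) {
    x <- series[[v]]
    x <- x[!is.na(x)]
    if (length(x) < 3L) {
      stop("need >= 3 observations of ", v, call. = FALSE)
    }
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    cv <- if (m == 0) NA_real_ else s / m
    data.frame(variable = v, min = min(x), max = max(x), sd = s, cv = cv,
               sk = skewness(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Evaluate f with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, f) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  f()
}

#' Generate a synthetic daily weather series
#'
#' Emulates a humid subtropical daily record of the kind the estimator is
#' trained on: annual sinusoidal cycles with Gaussian noise for temperature
#' and humidity, a Weibull wind-speed distribution (positively skewed, as
#' observed in such records), and solar radiation as a seasonal clearness
#' fraction of the clear-sky ceiling [clear_sky_radiation()], so `sr <= Rso`
#' always holds. Identical `seed` and parameters reproduce the series
#' exactly.
#'
#' @param n_days Number of days (>= 1).
#' @param site A [site_meta()].
#' @param seed Integer seed.
#' @param start First date (default "2000-01-01").
#' @param params Optional list overriding generator settings: `tmax_mean`
#'   (28 degC), `tmax_amp` (4), `tmax_peak_doy` (140), `tmax_sd` (1.5),
#'   `drange_mean` (9), `drange_amp` (3), `drange_sd` (1), `rh_mean` (75),
#'   `rh_amp` (12), `rh_sd` (5), `ws_shape` (1.8), `ws_scale` (1.4),
#'   `clearness_base` (0.72), `clearness_wet_drop` (0.2),
#'   `clearness_sd` (0.08).
#' @return A [weather_series()] with all five variables.
#' @export
generate_synthetic_weather <- function(n_days, site, seed,
                                       start = as.Date("2000-01-01"),
                                       params = list()) {
  stopifnot(n_days >= 1, inherits(site, "site_meta"))
  p <- utils::modifyList(list(
    tmax_mean = 28, tmax_amp = 4, tmax_peak_doy = 140, tmax_sd = 1.5,
    drange_mean = 9, drange_amp = 3, drange_sd = 1,
    rh_mean = 75, rh_amp = 12, rh_sd = 5,
    ws_shape = 1.8, ws_scale = 1.4,
    clearness_base = 0.72, clearness_wet_drop = 0.2, clearness_sd = 0.08
  ), params)

  dates <- as.Date(start) + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  phase <- 2 * pi * (doy - p$tmax_peak_doy) / 365.25
  wetness <- (1 + sin(2 * pi * (doy - 100) / 365.25)) / 2  # ~1 in monsoon

  df <- with_seed(seed, function() {
    tmax <- p$tmax_mean + p$tmax_amp * cos(phase) +
      stats::rnorm(n_days, 0, p$tmax_sd)
    drange <- pmax(2, p$drange_mean - p$drange_amp * cos(phase) +
                     stats::rnorm(n_days, 0, p$drange_sd))
    tmin <- tmax - drange
    rh <- pmin(100, pmax(20, p$rh_mean + p$rh_amp * (wetness - 0.5) * 2 +
                           stats::rnorm(n_days, 0, p$rh_sd)))
    ws <- stats::rweibull(n_days, shape = p$ws_shape, scale = p$ws_scale)
    clearness <- pmin(1, pmax(0.25,
      p$clearness_base - p$clearness_wet_drop * wetness +
        stats::rnorm(n_days, 0, p$clearness_sd)))
    rso <- clear_sky_radiation(doy, site$latitude, site$elevation)
    data.frame(date = dates, tmin = tmin, tmax = tmax, ws = ws, rh = rh,
               sr = clearness * rso)
  })
  weather_series(df, site)
}
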
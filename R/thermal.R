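# Marine-heatwave detection against a fixed-baseline day-of-year climatology,
# and in-situ extreme-heat-day indicators with absolute temperature floors.
#
# Conventions (documented in the methods vignette):
#  - exceedance is strict (">") against the percentile threshold;
#  - the 23 degC sublethal floor and 25 degC lethal flag use ">=";
#  - percentiles are type-7 (linear interpolation between order statistics);
#  - climatology lives on a 365-day civil calendar, Feb 29 interpolated.

#' Construct a daily temperature series
#'
#' @param dates `Date` vector, strictly increasing by one day (contiguous).
#' @param temp_c Temperatures in degrees C; `NA` marks missing days.
#' @return Data frame of class `daily_temperature` with columns `date`,
#'   `temp_c`.
#' @export
daily_temperature <- function(dates, temp_c) {
  dates <- as.Date(dates)
  if (length(dates) == 0L) octopop_domain_error("empty temperature series")
  if (length(dates) != length(temp_c)) {
    octopop_domain_error("dates and temp_c must have equal length")
  }
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L)) {
    octopop_validation_error("dates must be contiguous, strictly increasing by one day")
  }
  if (any(is.infinite(temp_c), na.rm = TRUE)) {
    octopop_validation_error("temperatures must be finite where present")
  }
  structure(data.frame(date = dates, temp_c = as.numeric(temp_c)),
            class = c("daily_temperature", "data.frame"))
}

#' Reduce an hourly record to daily means
#'
#' Calendar-day arithmetic mean of all readings; days with fewer than
#' `min_readings` of the expected 24 are kept in the calendar but flagged
#' missing (`NA`), so they break marine-heatwave runs rather than
#' fabricating a mean from sparse data.
#'
#' @param timestamps `POSIXct` (or parseable) reading times.
#' @param temp_c Temperatures in degrees C.
#' @param min_readings Minimum readings per retained day. Default 20.
#' @return A [daily_temperature] spanning the record's full date range.
#' @export
daily_means <- function(timestamps, temp_c, min_readings = 20L) {
  if (length(timestamps) == 0L) octopop_domain_error("empty hourly input")
  ts <- as.POSIXct(timestamps, tz = "UTC")
  day <- as.Date(ts)
  agg_mean <- tapply(temp_c, day, mean)
  agg_n <- tapply(temp_c, day, length)
  all_days <- seq(min(day), max(day), by = "day")
  m <- agg_mean[as.character(all_days)]
  n <- agg_n[as.character(all_days)]
  m[is.na(n) | n < min_readings] <- NA_real_
  daily_temperature(all_days, as.numeric(m))
}

# Civil day-of-year on a 365-day calendar: in leap years, days after Feb 28
# shift back by one so that e.g. Mar 1 is always day 60. Feb 29 maps to 366.
civil_doy <- function(dates) {
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  leap <- (lt$year + 1900L) %% 4L == 0L &
    ((lt$year + 1900L) %% 100L != 0L | (lt$year + 1900L) %% 400L == 0L)
  feb29 <- leap & lt$mon == 1L & lt$mday == 29L
  doy[leap & doy > 59L] <- doy[leap & doy > 59L] - 1L
  doy[feb29] <- 366L
  doy
}

circular_ma <- function(x, width) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  idx <- outer(seq_len(n), -half:half, function(i, k) ((i - 1L + k) %% n) + 1L)
  rowMeans(matrix(x[idx], nrow = n))
}

#' Build a fixed-baseline day-of-year climatology
#'
#' For each civil day-of-year, pools every baseline-year observation within
#' `window_halfwidth_days` of it (wrapping over the year boundary), takes the
#' mean and the 90th-percentile threshold, then smooths both with a centred
#' circular moving average of `smoothing_days`. The Feb 29 entry is the mean
#' of the Feb 28 and Mar 1 entries. The baseline is fixed: data outside
#' `baseline_years` never enter the climatology, so appending new years
#' cannot change detection on old ones.
#'
#' @param series A [daily_temperature].
#' @param baseline_years Length-2 inclusive year range, e.g. `c(1982, 2011)`.
#' @param window_halfwidth_days Pooling half-window. Default 5.
#' @param smoothing_days Smoothing window (odd). Default 31.
#' @param percentile Threshold percentile. Default 0.9.
#' @param min_coverage Minimum fraction of baseline days with data. Default
#'   0.8.
#' @return Object of class `climatology`: data frame `doy` (1–366),
#'   `clim_mean`, `threshold`, plus attributes.
#' @export
build_climatology <- function(series, baseline_years,
                              window_halfwidth_days = 5L, smoothing_days = 31L,
                              percentile = 0.9, min_coverage = 0.8) {
  yrs <- as.integer(format(series$date, "%Y"))
  keep <- yrs >= baseline_years[1] & yrs <= baseline_years[2]
  base <- series[keep, , drop = FALSE]
  n_expected <- as.integer(as.Date(sprintf("%d-12-31", baseline_years[2])) -
                           as.Date(sprintf("%d-01-01", baseline_years[1]))) + 1L
  n_have <- sum(!is.na(base$temp_c))
  if (nrow(base) == 0L || n_have < min_coverage * n_expected) {
    octopop_stop(sprintf(
      "baseline %d-%d has %d of %d required daily values (coverage %.0f%% < %.0f%%)",
      baseline_years[1], baseline_years[2], n_have, n_expected,
      100 * n_have / max(n_expected, 1), 100 * min_coverage),
      "octopop_coverage_error")
  }
  doy <- civil_doy(base$date)
  ok <- !is.na(base$temp_c) & doy <= 365L  # Feb 29 obs join their neighbours via the window
  by_doy <- split(base$temp_c[ok], factor(doy[ok], levels = 1:365))
  hw <- window_halfwidth_days
  mu <- thr <- rep(NA_real_, 365)
  for (d in 1:365) {
    win <- ((d - 1L + (-hw:hw)) %% 365L) + 1L
    pool <- unlist(by_doy[win], use.names = FALSE)
    if (length(pool) == 0L) {
      octopop_stop(sprintf("no baseline data within the window of day-of-year %d", d),
                   "octopop_coverage_error")
    }
    mu[d] <- mean(pool)
    thr[d] <- stats::quantile(pool, percentile, names = FALSE, type = 7)
  }
  mu <- circular_ma(mu, smoothing_days)
  thr <- circular_ma(thr, smoothing_days)
  clim_mean <- c(mu, mean(mu[c(59, 60)]))
  threshold <- c(thr, mean(thr[c(59, 60)]))
  if (any(threshold < clim_mean)) {
    warning("climatology threshold below climatological mean on some days",
            call. = FALSE)
  }
  structure(data.frame(doy = 1:366, clim_mean = clim_mean, threshold = threshold),
            class = c("climatology", "data.frame"),
            baseline_years = as.integer(baseline_years), percentile = percentile)
}

#' Detect marine heatwave events
#'
#' A marine heatwave is a run of at least `min_duration` consecutive days
#' with temperature strictly above the day-of-year climatological threshold.
#' Two qualifying events separated by at most `max_gap` below-threshold days
#' are merged into one (the gap days are inside the event's span but are not
#' heatwave days). Missing days break runs.
#'
#' @param series A [daily_temperature].
#' @param climatology A [build_climatology()] result.
#' @param min_duration Minimum run length in days. Default 5.
#' @param max_gap Maximum below-threshold gap merged between events, in
#'   days. Default 2; set 0 to disable merging.
#' @return Object of class `mhw_events`: data frame with `start`, `end`,
#'   `duration` (span, days), `n_mhw_days` (above-threshold days),
#'   `max_exceedance_c`, `mean_exceedance_c`; attribute `mhw_dates` lists
#'   each event's above-threshold dates.
#' @export
detect_mhw_events <- function(series, climatology, min_duration = 5L,
                              max_gap = 2L) {
  thr <- climatology$threshold[civil_doy(series$date)]
  exc <- series$temp_c - thr
  hot <- !is.na(exc) & exc > 0
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs <- runs[runs$end - runs$start + 1L >= min_duration, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty_mhw_events())
  # merge qualifying runs separated by short, fully-observed gaps
  merged <- list(runs[1, ])
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      gap_idx <- (last$end + 1L):(runs$start[i] - 1L)
      gap <- runs$start[i] - last$end - 1L
      if (gap <= max_gap && !anyNA(series$temp_c[gap_idx])) {
        merged[[length(merged)]]$end <- runs$end[i]
      } else {
        merged[[length(merged) + 1L]] <- runs[i, ]
      }
    }
  }
  merged <- do.call(rbind, merged)
  mhw_dates <- lapply(seq_len(nrow(merged)), function(i) {
    idx <- merged$start[i]:merged$end[i]
    series$date[idx][hot[idx]]
  })
  ev <- data.frame(
    start = series$date[merged$start],
    end = series$date[merged$end],
    duration = merged$end - merged$start + 1L,
    n_mhw_days = vapply(mhw_dates, length, 0L),
    max_exceedance_c = vapply(seq_len(nrow(merged)), function(i) {
      idx <- merged$start[i]:merged$end[i]; max(exc[idx][hot[idx]])
    }, 0),
    mean_exceedance_c = vapply(seq_len(nrow(merged)), function(i) {
      idx <- merged$start[i]:merged$end[i]; mean(exc[idx][hot[idx]])
    }, 0))
  structure(ev, class = c("mhw_events", "data.frame"), mhw_dates = mhw_dates)
}

empty_mhw_events <- function() {
  structure(data.frame(start = as.Date(character()), end = as.Date(character()),
                       duration = integer(), n_mhw_days = integer(),
                       max_exceedance_c = numeric(), mean_exceedance_c = numeric()),
            class = c("mhw_events", "data.frame"), mhw_dates = list())
}

#' Marine-heatwave days per year
#'
#' Counts each event's above-threshold days whose calendar date falls in the
#' stated months (default the warm hydrological season, June–November,
#' "JJASON"), per year. An event spanning the window boundary contributes
#' only its in-window days; merged-gap days are never counted.
#'
#' @param events An `mhw_events` object.
#' @param months Integer months to count. Default `6:11`.
#' @param years Optional integer years to force into the output (with zero
#'   counts where no events occurred).
#' @return Named integer vector: year -> MHW day count.
#' @export
mhw_days_per_year <- function(events, months = 6:11, years = NULL) {
  days <- do.call(c, c(attr(events, "mhw_dates"), list(as.Date(character()))))
  days <- days[as.integer(format(days, "%m")) %in% months]
  yr <- as.integer(format(days, "%Y"))
  lev <- sort(unique(c(yr, as.integer(years))))
  counts <- table(factor(yr, levels = lev))
  stats::setNames(as.integer(counts), names(counts))
}

#' Extreme-heat-day indicator with absolute floors
#'
#' For in-situ records too short for a 30-year climatology, the indicator is
#' the number of days per year whose mean temperature strictly exceeds the
#' record's inter-annual 90th percentile (pooled over all daily values, all
#' calendar days — or the warm season only, see `season_months`) AND reaches
#' at least `min_temp_c` (sublethal floor). Years with any daily mean at or
#' above `lethal_temp_c` are flagged.
#'
#' @param series A [daily_temperature] with at least one full year of data.
#' @param min_temp_c Sublethal absolute floor, degC. Default 23.
#' @param lethal_temp_c Lethal flag threshold, degC. Default 25.
#' @param percentile Pooled percentile. Default 0.9.
#' @param season_months Optional integer months restricting BOTH the
#'   percentile pool and the counted days (e.g. `6:11`); `NULL` (default)
#'   pools all calendar days.
#' @return Data frame: `year`, `extreme_heat_days`, `lethal_day_flag`;
#'   attribute `threshold_c` carries the pooled percentile.
#' @export
extreme_heat_days <- function(series, min_temp_c = 23, lethal_temp_c = 25,
                              percentile = 0.9, season_months = NULL) {
  if (nrow(series) < 365L) {
    octopop_domain_error("extreme_heat_days needs at least one full year of daily data")
  }
  sel <- rep(TRUE, nrow(series))
  if (!is.null(season_months)) {
    sel <- as.integer(format(series$date, "%m")) %in% season_months
  }
  pool <- series$temp_c[sel & !is.na(series$temp_c)]
  thr <- stats::quantile(pool, percentile, names = FALSE, type = 7)
  yr <- as.integer(format(series$date, "%Y"))
  hit <- sel & !is.na(series$temp_c) & series$temp_c > thr & series$temp_c >= min_temp_c
  lethal <- !is.na(series$temp_c) & series$temp_c >= lethal_temp_c
  years <- sort(unique(yr))
  out <- data.frame(
    year = years,
    extreme_heat_days = as.integer(tapply(hit, yr, sum)[as.character(years)]),
    lethal_day_flag = as.logical(tapply(lethal, yr, any)[as.character(years)]))
  attr(out, "threshold_c") <- thr
  out
}
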
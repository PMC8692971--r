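# Climatology, MHW detection and extreme-heat-day indicators.

test_that("daily_means reduces hourly data and flags sparse days", {
  day1 <- as.POSIXct("2010-06-01 00:00", tz = "UTC") + 3600 * (0:23)
  day2 <- as.POSIXct("2010-06-02 00:00", tz = "UTC") + 3600 * (0:23)
  day3 <- as.POSIXct("2010-06-03 00:00", tz = "UTC") + 3600 * (0:9)  # 10 readings
  series <- daily_means(c(day1, day2, day3),
                        c(rep(20, 24), rep(c(19, 21), each = 12), rep(25, 10)))
  expect_equal(series$temp_c[1], 20)
  expect_equal(series$temp_c[2], 20)   # 12 h at 19, 12 h at 21
  expect_true(is.na(series$temp_c[3])) # coverage rule
  expect_error(daily_means(numeric(), numeric()), class = "octopop_domain_error")
})

test_that("daily_temperature enforces calendar contiguity", {
  d <- seq(as.Date("2010-01-01"), by = "day", length.out = 10)
  expect_s3_class(daily_temperature(d, rnorm(10, 18)), "daily_temperature")
  expect_error(daily_temperature(d[-3], rnorm(9, 18)),
               class = "octopop_validation_error")
})

test_that("climatology of a constant series is that constant", {
  clim <- build_climatology(flat_series(2000:2003), c(2000, 2003))
  expect_equal(clim$clim_mean, rep(18, 366))
  expect_equal(clim$threshold, rep(18, 366))
})

test_that("climatology tracks a noiseless sinusoid within the window bound", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2009-12-31"), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  temp <- 17 + 6 * cos(2 * pi * (doy - 227) / 365.25)
  clim <- build_climatology(daily_temperature(dates, temp), c(2000, 2009))
  # analytic bound: |d temp/d day| <= 6*2*pi/365.25 ~ 0.103 degC/day, so the
  # 90th percentile of a +/-5-day pool sits within ~0.5 degC of the centre
  # value, and 31-day smoothing attenuates amplitude by < 0.08 degC
  ref <- 17 + 6 * cos(2 * pi * (1:365 - 227) / 365.25)
  expect_lt(max(abs(clim$threshold[1:365] - ref)), 1.0)
  expect_gte(min(clim$threshold - clim$clim_mean), -1e-9)  # pct >= mean here
})

test_that("Feb 29 entry interpolates its neighbours; year order is irrelevant", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2007-12-31"), by = "day")
  set.seed(5)
  temp <- 17 + 5 * cos(2 * pi * (as.POSIXlt(dates)$yday) / 365.25) + rnorm(length(dates), 0, 0.2)
  clim <- build_climatology(daily_temperature(dates, temp), c(2000, 2007))
  expect_equal(clim$threshold[366], mean(clim$threshold[c(59, 60)]))
  expect_equal(clim$clim_mean[366], mean(clim$clim_mean[c(59, 60)]))
})

test_that("insufficient baseline coverage errors, naming the gap", {
  short <- flat_series(2000:2000)
  expect_error(build_climatology(short, c(2000, 2003)),
               "coverage", class = "octopop_coverage_error")
})

test_that("MHW detection honours strict exceedance, minimum duration and gaps", {
  base <- flat_series(2000:2004)
  clim <- build_climatology(base, c(2000, 2001))

  expect_equal(nrow(detect_mhw_events(base, clim)), 0)  # threshold = value, strict >

  one <- add_block(base, "2003-07-10", 6, 4)
  ev <- detect_mhw_events(one, clim)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 6L)
  expect_equal(ev$n_mhw_days, 6L)
  expect_equal(ev$max_exceedance_c, 4)

  short <- add_block(base, "2003-07-10", 4, 4)
  expect_equal(nrow(detect_mhw_events(short, clim)), 0)

  # two 5-day runs separated by a 2-day gap merge; gap days are not MHW days
  gap2 <- add_block(add_block(base, "2003-07-01", 5, 3), "2003-07-08", 5, 3)
  merged <- detect_mhw_events(gap2, clim, max_gap = 2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$duration, 12L)
  expect_equal(merged$n_mhw_days, 10L)
  split_ev <- detect_mhw_events(gap2, clim, max_gap = 0)
  expect_equal(nrow(split_ev), 2)

  # a missing day breaks a run
  broken <- add_block(base, "2003-07-10", 7, 4)
  broken$temp_c[match(as.Date("2003-07-13"), broken$date)] <- NA
  expect_equal(nrow(detect_mhw_events(broken, clim)), 0)

  # raising min_duration never increases the event count
  multi <- add_block(add_block(base, "2003-07-10", 6, 4), "2004-08-01", 9, 4)
  n_by_dur <- vapply(5:10, function(d) nrow(detect_mhw_events(multi, clim, min_duration = d)), 0L)
  expect_true(all(diff(n_by_dur) <= 0))
})

test_that("MHW day counts respect the season window and partition event days", {
  base <- flat_series(2000:2004)
  clim <- build_climatology(base, c(2000, 2001))

  july <- detect_mhw_events(add_block(base, "2003-07-05", 10, 4), clim)
  expect_equal(mhw_days_per_year(july), c("2003" = 10L))

  # event spanning 28 Nov - 7 Dec: only the 3 November days count in JJASON
  straddle <- detect_mhw_events(add_block(base, "2003-11-28", 10, 4), clim)
  expect_equal(mhw_days_per_year(straddle), c("2003" = 3L))
  expect_equal(unname(mhw_days_per_year(straddle, months = 1:12)), 10L)

  expect_equal(unname(mhw_days_per_year(detect_mhw_events(base, clim),
                                        years = 2000:2004)), rep(0L, 5))

  # partition: JJASON counts never exceed all-months counts
  multi <- detect_mhw_events(add_block(add_block(base, "2003-05-29", 8, 4),
                                       "2004-08-10", 6, 4), clim)
  all_m <- mhw_days_per_year(multi, months = 1:12)
  jjason <- mhw_days_per_year(multi, years = names(all_m))
  expect_equal(sum(all_m), sum(multi$n_mhw_days))
  expect_true(all(jjason <= all_m))
})

test_that("fixed baseline: appending years changes nothing upstream", {
  a <- add_block(flat_series(2000:2004), "2003-07-10", 6, 4)
  clim_a <- build_climatology(a, c(2000, 2001))
  # append two much warmer years
  ext_dates <- seq(as.Date("2000-01-01"), as.Date("2006-12-31"), by = "day")
  ext_temp <- c(a$temp_c, rep(24, length(ext_dates) - nrow(a)))
  b <- daily_temperature(ext_dates, ext_temp)
  clim_b <- build_climatology(b, c(2000, 2001))
  expect_equal(clim_b$threshold, clim_a$threshold)
  ev_a <- detect_mhw_events(a, clim_a)
  ev_b <- detect_mhw_events(b, clim_b)
  in_old <- ev_b[ev_b$end <= max(a$date), ]
  expect_equal(in_old$start, ev_a$start)
  expect_equal(in_old$n_mhw_days, ev_a$n_mhw_days)
})

test_that("extreme heat days need both the percentile and the 23 degC floor", {
  # hot tail below 23 degC: percentile exceedances but zero qualifying days
  dates <- seq(as.Date("2010-01-01"), as.Date("2012-12-31"), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  cool <- daily_temperature(dates, 15 + 5 * cos(2 * pi * (doy - 227) / 365.25))
  res <- extreme_heat_days(cool)
  expect_true(max(cool$temp_c) < 23)
  expect_equal(res$extreme_heat_days, rep(0L, 3))
  expect_false(any(res$lethal_day_flag))

  # constructed: exactly 12 days qualify in 2011, one lethal day in 2012
  warm <- 17 + 6 * cos(2 * pi * (doy - 227) / 365.25)
  warm[dates >= as.Date("2011-08-01") & dates <= as.Date("2011-08-12")] <- 24
  warm[dates == as.Date("2012-08-05")] <- 25.3
  ws <- daily_temperature(dates, warm)
  res2 <- extreme_heat_days(ws)
  thr <- attr(res2, "threshold_c")
  truth <- tapply(ws$temp_c > thr & ws$temp_c >= 23,
                  as.integer(format(dates, "%Y")), sum)
  expect_equal(res2$extreme_heat_days, as.integer(truth))
  expect_equal(res2$extreme_heat_days[res2$year == 2011],
               sum(ws$temp_c[format(dates, "%Y") == "2011"] > thr &
                   ws$temp_c[format(dates, "%Y") == "2011"] >= 23))
  expect_equal(res2$lethal_day_flag, c(FALSE, FALSE, TRUE))

  # uniform series: strict exceedance of its own percentile is impossible
  expect_equal(extreme_heat_days(flat_series(2010:2011, temp = 24))$extreme_heat_days,
               rep(0L, 2))

  # monotonicity: raising the floor never increases counts
  counts <- vapply(c(20, 22, 23, 24), function(m) {
    sum(extreme_heat_days(ws, min_temp_c = m)$extreme_heat_days)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})
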
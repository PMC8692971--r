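# Synthetic survey and temperature fixtures with known ground truth.
# All generators are pure functions of (parameters, seed); per-quadrat and
# per-colony streams are split from the scenario seed by stable hashing so
# adding a quadrat never reshuffles the draws of the others.

#' Population scenario for the survey simulator
#'
#' Describes an undisturbed population as sampled by the field protocol:
#' `n_quadrats` frames of `quadrat_area_m2` each, colony counts Poisson with
#' mean `initial_density_per_m2 * area`, heights i.i.d. log-normal
#' (right-skewed, strictly positive). Defaults emulate the red gorgonian
#' protocol: 30 quadrats of 0.25 m2 at 32 colonies per m2. With
#' `on_line` set, realised heights are rescaled so the population's mean
#' colony biomass sits exactly on the given self-thinning line at its
#' realised density.
#'
#' @param species Species id with a built-in config.
#' @param n_quadrats,quadrat_area_m2 Sampling design. Defaults 30 and 0.25.
#' @param initial_density_per_m2 Expected density. Default 32.
#' @param height_meanlog,height_sdlog Log-normal height parameters (log cm).
#'   Defaults log(15) and 0.45 (median 15 cm, matching a 10-20 cm modal
#'   class).
#' @param on_line Optional `selfthinning_line` to anchor mean colony biomass
#'   to.
#' @param seed Integer seed.
#' @return A `population_scenario`.
#' @export
population_scenario <- function(species = "paramuricea_clavata",
                                n_quadrats = 30L, quadrat_area_m2 = 0.25,
                                initial_density_per_m2 = 32,
                                height_meanlog = log(15), height_sdlog = 0.45,
                                on_line = NULL, seed = 1L) {
  if (n_quadrats < 1L || quadrat_area_m2 <= 0 || initial_density_per_m2 < 0) {
    octopop_domain_error("counts and areas must be positive")
  }
  if (!is.finite(height_meanlog) || !is.finite(height_sdlog) || height_sdlog < 0) {
    octopop_domain_error("height distribution parameters must be finite")
  }
  structure(list(species = species, n_quadrats = as.integer(n_quadrats),
                 quadrat_area_m2 = quadrat_area_m2,
                 initial_density_per_m2 = initial_density_per_m2,
                 height_meanlog = height_meanlog, height_sdlog = height_sdlog,
                 on_line = on_line, seed = as.integer(seed)),
            class = "population_scenario")
}

#' Default survey scenario for the red coral protocol
#'
#' 24 permanent quadrats of 0.04 m2 (0.20 m x 0.20 m; 0.96 m2 total), about
#' 67 colonies per m2, small colonies (median 4 cm).
#'
#' @param seed Integer seed.
#' @return A `population_scenario`.
#' @export
crubrum_scenario <- function(seed = 1L) {
  population_scenario(species = "corallium_rubrum", n_quadrats = 24L,
                      quadrat_area_m2 = 0.04, initial_density_per_m2 = 67,
                      height_meanlog = log(4), height_sdlog = 0.5, seed = seed)
}

#' Simulate an undisturbed population survey
#'
#' @param scenario A [population_scenario].
#' @param population_id,year Identity of the generated survey.
#' @return A [population_survey] with zero injury everywhere.
#' @export
simulate_population <- function(scenario, population_id = "sim_pop", year = 2003L) {
  quadrats <- data.frame(
    quadrat_id = sprintf("q%02d", seq_len(scenario$n_quadrats)),
    area_m2 = scenario$quadrat_area_m2, stringsAsFactors = FALSE)
  lambda <- scenario$initial_density_per_m2 * scenario$quadrat_area_m2
  cols <- lapply(seq_len(scenario$n_quadrats), function(i) {
    with_seed(split_seed(scenario$seed, i), {
      n <- stats::rpois(1, lambda)
      if (n == 0L) return(NULL)
      data.frame(quadrat_id = quadrats$quadrat_id[i],
                 colony_id = sprintf("q%02d_c%03d", i, seq_len(n)),
                 height_cm = stats::rlnorm(n, scenario$height_meanlog,
                                           scenario$height_sdlog),
                 injury_recent_pct = 0, injury_old_pct = 0,
                 status = "alive", stringsAsFactors = FALSE)
    })
  })
  colonies <- do.call(rbind, cols)
  if (is.null(colonies)) colonies <- empty_colony_table()
  survey <- population_survey(population_id, scenario$species, year, quadrats, colonies)
  if (!is.null(scenario$on_line) && nrow(colonies) > 0L) {
    cfg <- builtin_species_config(scenario$species)
    d <- density(survey)$mean
    target <- 10^line_predict(scenario$on_line, log10(d))
    cur <- mean(colony_biomass(colonies$height_cm, 0, cfg))
    s <- (target / cur)^(1 / cfg$allometric_b)
    survey$colonies$height_cm <- colonies$height_cm * s
  }
  survey
}

#' Disturbance event for the survey simulator
#'
#' Emulates a mass-mortality event: each colony dies outright (100% recent
#' injury, standing dead) with `total_mortality_prob`; survivors become
#' affected with a per-size-class probability and then draw a recent-injury
#' fraction from a Beta distribution. New recent injury adds to existing
#' injury, capped at 100%.
#'
#' @param year Event year (metadata).
#' @param total_mortality_prob Probability of whole-colony death. Default
#'   0.4 (the magnitude of a severe event).
#' @param injury_shape1,injury_shape2 Beta parameters for the recent-injury
#'   fraction among affected survivors. Defaults 2 and 2.
#' @param affected_prob_by_size Per-size-class probability of a surviving
#'   colony being affected, smallest class first; recycled. Default a
#'   size-increasing gradient `c(0.3, 0.45, 0.6, 0.7, 0.8)` (larger colonies
#'   are hit harder).
#' @param seed Integer seed.
#' @return A `disturbance_event`.
#' @export
disturbance_event <- function(year = 2003L, total_mortality_prob = 0.4,
                              injury_shape1 = 2, injury_shape2 = 2,
                              affected_prob_by_size = c(0.3, 0.45, 0.6, 0.7, 0.8),
                              seed = 1L) {
  probs <- c(total_mortality_prob, affected_prob_by_size)
  if (any(probs < 0) || any(probs > 1)) {
    octopop_domain_error("probabilities must lie in [0, 1]")
  }
  structure(list(year = as.integer(year),
                 total_mortality_prob = total_mortality_prob,
                 injury_shape1 = injury_shape1, injury_shape2 = injury_shape2,
                 affected_prob_by_size = affected_prob_by_size,
                 seed = as.integer(seed)),
            class = "disturbance_event")
}

#' Apply a disturbance event to a survey
#'
#' @param survey A [population_survey].
#' @param event A [disturbance_event].
#' @param config A [species_config] (for the size classes); defaults to the
#'   survey species' built-in.
#' @return The disturbed [population_survey], year set to `event$year`.
#' @export
apply_disturbance <- function(survey, event,
                              config = builtin_species_config(survey$species)) {
  col <- survey$colonies
  n <- nrow(col)
  if (n > 0L) {
    breaks <- c(0, config$size_bins_cm, Inf)
    cls <- as.integer(cut(col$height_cm, breaks, right = TRUE, include.lowest = TRUE))
    p_aff <- rep_len(event$affected_prob_by_size, length(breaks) - 1L)[cls]
    draws <- with_seed(event$seed, list(
      dies = stats::runif(n) < event$total_mortality_prob,
      affected = stats::runif(n) < p_aff,
      frac = stats::rbeta(n, event$injury_shape1, event$injury_shape2)))
    new_recent <- ifelse(draws$dies, 100,
                         ifelse(draws$affected, 100 * draws$frac, 0))
    # recent injury can only strike still-living surface
    room <- 100 - col$injury_recent_pct - col$injury_old_pct
    add <- pmin(new_recent, room)
    col$injury_recent_pct <- col$injury_recent_pct + ifelse(draws$dies, room, add)
    tot <- col$injury_recent_pct + col$injury_old_pct
    col$status <- ifelse(abs(tot - 100) <= 1e-9, "standing_dead", "alive")
  }
  population_survey(survey$population_id, survey$species, event$year,
                    survey$quadrats, col, depth_m = survey$depth_m)
}

#' Demographic dynamics parameters
#'
#' Annual processes applied by [step_dynamics()]: slow vertical growth
#' (field estimates are below 3 cm per year for these octocorals), gradual
#' conversion of recent injury to old (epibiont overgrowth), delayed
#' mortality of heavily injured colonies (biomass keeps eroding years after
#' an event), and Poisson recruitment of minimal-size colonies.
#'
#' @param annual_growth_cm Height increment per year, cm. Default 0.8.
#' @param recruitment_rate Recruits per m2 per year. Default 0.5.
#' @param delayed_mortality_prob Annual death probability for colonies with
#'   total injury above `injury_mortality_threshold_pct`. Default 0.1.
#' @param injury_mortality_threshold_pct Default 50.
#' @param epibiosis_conversion_rate Annual fraction of recent injury turning
#'   old. Default 0.5.
#' @param recruit_height_cm Height of new recruits, cm. Default 1.
#' @param seed Integer seed.
#' @return A `dynamics_params`.
#' @export
dynamics_params <- function(annual_growth_cm = 0.8, recruitment_rate = 0.5,
                            delayed_mortality_prob = 0.1,
                            injury_mortality_threshold_pct = 50,
                            epibiosis_conversion_rate = 0.5,
                            recruit_height_cm = 1, seed = 1L) {
  vals <- c(annual_growth_cm, recruitment_rate, delayed_mortality_prob,
            epibiosis_conversion_rate, recruit_height_cm)
  if (any(vals < 0)) octopop_domain_error("dynamics rates must be non-negative")
  if (delayed_mortality_prob > 1 || epibiosis_conversion_rate > 1) {
    octopop_domain_error("probabilities and rates must lie in [0, 1]")
  }
  structure(list(annual_growth_cm = annual_growth_cm,
                 recruitment_rate = recruitment_rate,
                 delayed_mortality_prob = delayed_mortality_prob,
                 injury_mortality_threshold_pct = injury_mortality_threshold_pct,
                 epibiosis_conversion_rate = epibiosis_conversion_rate,
                 recruit_height_cm = recruit_height_cm, seed = as.integer(seed)),
            class = "dynamics_params")
}

#' Step a population forward through yearly dynamics
#'
#' Each year, in order: living colonies grow; recent injury converts to old
#' at the epibiosis rate; colonies injured above the threshold die with the
#' delayed-mortality probability (dead colonies convert fully to old injury
#' and stand dead); Poisson recruits of minimal size appear per quadrat.
#'
#' @param survey Starting [population_survey].
#' @param params A [dynamics_params].
#' @param years Number of years to simulate (>= 1).
#' @return List of `years` [population_survey] objects (years
#'   `survey$year + 1, ...`).
#' @export
step_dynamics <- function(survey, params, years) {
  if (years < 1L) octopop_domain_error("years must be >= 1")
  out <- vector("list", years)
  cur <- survey
  for (t in seq_len(years)) {
    col <- cur$colonies
    yr_seed <- split_seed(params$seed, t)
    if (nrow(col) > 0L) {
      alive <- col$status == "alive"
      col$height_cm[alive] <- col$height_cm[alive] + params$annual_growth_cm
      conv <- col$injury_recent_pct * params$epibiosis_conversion_rate
      col$injury_recent_pct <- col$injury_recent_pct - conv
      col$injury_old_pct <- col$injury_old_pct + conv
      tot <- col$injury_recent_pct + col$injury_old_pct
      at_risk <- alive & tot > params$injury_mortality_threshold_pct
      dies <- rep(FALSE, nrow(col))
      if (any(at_risk)) {
        dies[at_risk] <- with_seed(split_seed(yr_seed, 1L),
                                   stats::runif(sum(at_risk)) < params$delayed_mortality_prob)
      }
      col$injury_old_pct[dies] <- 100 - col$injury_recent_pct[dies]
      tot <- col$injury_recent_pct + col$injury_old_pct
      col$status <- ifelse(abs(tot - 100) <= 1e-9, "standing_dead", "alive")
    }
    recruits <- lapply(seq_len(nrow(cur$quadrats)), function(i) {
      n <- with_seed(split_seed(yr_seed, 100L + i), stats::rpois(
        1, params$recruitment_rate * cur$quadrats$area_m2[i]))
      if (n == 0L) return(NULL)
      data.frame(quadrat_id = cur$quadrats$quadrat_id[i],
                 colony_id = sprintf("r%d_q%02d_%03d", t, i, seq_len(n)),
                 height_cm = params$recruit_height_cm,
                 injury_recent_pct = 0, injury_old_pct = 0,
                 status = "alive", stringsAsFactors = FALSE)
    })
    col <- rbind(col, do.call(rbind, recruits))
    if (is.null(col)) col <- empty_colony_table()
    cur <- population_survey(cur$population_id, cur$species, cur$year + 1L,
                             cur$quadrats, col, depth_m = cur$depth_m)
    out[[t]] <- cur
  }
  out
}

#' Simulate a daily temperature series with known anomalies
#'
#' Seasonal cosine plus AR(1) noise plus injected boxcar warm anomalies:
#' `T(t) = mean + amplitude * cos(2*pi*(doy - peak_doy)/365.25) + AR1 +
#' anomalies`. Every injected anomaly day is recorded in a ground-truth
#' ledger so detection can be scored exactly.
#'
#' @param start_year,end_year Inclusive calendar span (real leap years).
#' @param seasonal_mean,seasonal_amplitude degC. Defaults 17 and 6 (NW
#'   Mediterranean at ~20 m).
#' @param peak_doy Day-of-year of the seasonal maximum. Default 227
#'   (mid-August).
#' @param ar1_phi,noise_sd AR(1) noise parameters; `|phi| < 1`. Defaults 0.7
#'   and 0.3 degC.
#' @param anomalies Data frame with columns `start` (Date), `length_days`,
#'   `magnitude_c`; may be `NULL`. Overlapping anomalies are an error.
#' @param seed Integer seed.
#' @return List: `series` (a [daily_temperature]) and `ledger` (data frame
#'   `date`, `magnitude_c` of every injected anomaly day).
#' @export
simulate_temperature <- function(start_year, end_year, seasonal_mean = 17,
                                 seasonal_amplitude = 6, peak_doy = 227,
                                 ar1_phi = 0.7, noise_sd = 0.3,
                                 anomalies = NULL, seed = 1L) {
  if (abs(ar1_phi) >= 1) octopop_domain_error("|ar1_phi| must be < 1")
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", end_year)), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  seasonal <- seasonal_mean + seasonal_amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
  n <- length(dates)
  noise <- if (noise_sd > 0) {
    with_seed(seed, {
      innov_sd <- noise_sd * sqrt(1 - ar1_phi^2)  # stationary marginal sd = noise_sd
      as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), ar1_phi,
                               method = "recursive"))
    })
  } else rep(0, n)
  temp <- seasonal + noise
  ledger <- data.frame(date = as.Date(character()), magnitude_c = numeric())
  if (!is.null(anomalies) && nrow(anomalies) > 0L) {
    seen <- as.Date(character())
    for (i in seq_len(nrow(anomalies))) {
      a_days <- seq(as.Date(anomalies$start[i]), by = "day",
                    length.out = anomalies$length_days[i])
      if (any(a_days %in% seen)) octopop_domain_error("overlapping anomalies")
      seen <- c(seen, a_days)
      idx <- match(a_days, dates)
      if (anyNA(idx)) octopop_domain_error("anomaly extends outside the simulated span")
      temp[idx] <- temp[idx] + anomalies$magnitude_c[i]
      ledger <- rbind(ledger, data.frame(date = a_days,
                                         magnitude_c = anomalies$magnitude_c[i]))
    }
    ledger <- ledger[order(ledger$date), , drop = FALSE]
  }
  list(series = daily_temperature(dates, temp), ledger = ledger)
}
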
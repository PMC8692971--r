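# Fixtures are built in code: tiny surveys, temperature series and CSV files
# written to tempdir().

pclav <- builtin_species_config("paramuricea_clavata")
crub <- builtin_species_config("corallium_rubrum")

# survey with explicit colony heights/injuries spread over quadrats
make_survey <- function(heights, recent = 0, old = 0,
                        quadrat_of = NULL, n_quadrats = 2L, area = 0.25,
                        species = "paramuricea_clavata", year = 2004L,
                        population = "popA") {
  n <- length(heights)
  recent <- rep_len(recent, n)
  old <- rep_len(old, n)
  if (is.null(quadrat_of)) quadrat_of <- rep_len(seq_len(n_quadrats), n)
  quadrats <- data.frame(quadrat_id = paste0("q", seq_len(n_quadrats)),
                         area_m2 = area)
  colonies <- if (n > 0) {
    data.frame(quadrat_id = paste0("q", quadrat_of),
               colony_id = paste0("c", seq_len(n)),
               height_cm = heights,
               injury_recent_pct = recent, injury_old_pct = old,
               status = ifelse(recent + old >= 100, "standing_dead", "alive"))
  } else NULL
  population_survey(population, species, year, quadrats,
                    colonies %||% octopop:::empty_colony_table())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_survey_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# one well-formed survey file: 1 population, 2 quadrats, 3 colonies
basic_survey_rows <- function() {
  data.frame(
    population = "popA", species = "paramuricea_clavata", year = 2004,
    quadrat = c("q1", "q1", "q2"), area_m2 = 0.25,
    colony_id = c("c1", "c2", "c3"),
    height_cm = c(12, 25, 8),
    injury_recent_pct = c(0, 40, 100),
    injury_old_pct = c(0, 10, 0),
    status = c("alive", "alive", "standing_dead"))
}

# flat-baseline daily series over given years with optional added anomalies
flat_series <- function(years = 2000:2001, temp = 18) {
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[length(years)])), by = "day")
  daily_temperature(dates, rep(temp, length(dates)))
}

add_block <- function(series, start, len, delta) {
  idx <- match(seq(as.Date(start), by = "day", length.out = len), series$date)
  series$temp_c[idx] <- series$temp_c[idx] + delta
  daily_temperature(series$date, series$temp_c)
}
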
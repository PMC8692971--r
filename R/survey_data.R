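# Domain model, validation and I/O for colony-level quadrat surveys and
# species configuration.

SURVEY_REQUIRED_COLUMNS <- c("population", "species", "year", "quadrat",
                             "area_m2", "height_cm", "injury_recent_pct",
                             "injury_old_pct", "status")
COLONY_STATUSES <- c("alive", "standing_dead")

#' Construct a population survey
#'
#' A `population_survey` holds every quadrat of one population censused in one
#' year. Colonies live in a data frame with one row per colony; quadrats with
#' zero colonies are first-class records (they lower mean density) and appear
#' only in the quadrat table.
#'
#' @param population_id Population identifier.
#' @param species Species identifier, e.g. `"paramuricea_clavata"`.
#' @param year Integer census year.
#' @param quadrats Data frame with columns `quadrat_id`, `area_m2`.
#' @param colonies Data frame with columns `quadrat_id`, `colony_id`,
#'   `height_cm`, `injury_recent_pct`, `injury_old_pct`, `status`
#'   (`"alive"` or `"standing_dead"`). May have zero rows.
#' @param depth_m Optional depth metadata in metres.
#'
#' @details Colony invariants enforced: `height_cm > 0`; both injury
#'   percentages in \[0, 100\] with `recent + old <= 100`; a colony is
#'   `standing_dead` if and only if its total injury is 100%.
#'
#' @return An object of class `population_survey`.
#' @export
population_survey <- function(population_id, species, year, quadrats,
                              colonies = empty_colony_table(), depth_m = NA_real_) {
  quadrats <- as.data.frame(quadrats)
  colonies <- as.data.frame(colonies)
  if (nrow(quadrats) == 0L) {
    octopop_validation_error("a population survey needs at least one quadrat")
  }
  if (!all(c("quadrat_id", "area_m2") %in% names(quadrats))) {
    octopop_schema_error("quadrats must have columns quadrat_id, area_m2")
  }
  if (anyDuplicated(quadrats$quadrat_id)) {
    octopop_validation_error(sprintf(
      "duplicate quadrat_id in population '%s'", population_id))
  }
  if (any(!is.finite(quadrats$area_m2)) || any(quadrats$area_m2 <= 0)) {
    octopop_validation_error("quadrat area_m2 must be finite and > 0")
  }
  validate_colony_table(colonies)
  if (nrow(colonies) > 0L && !all(colonies$quadrat_id %in% quadrats$quadrat_id)) {
    octopop_validation_error("colony references a quadrat_id not in the quadrat table")
  }
  structure(
    list(population_id = as.character(population_id),
         species = as.character(species),
         year = as.integer(year),
         depth_m = as.numeric(depth_m),
         quadrats = quadrats[, c("quadrat_id", "area_m2")],
         colonies = colonies),
    class = "population_survey")
}

empty_colony_table <- function() {
  data.frame(quadrat_id = character(), colony_id = character(),
             height_cm = numeric(), injury_recent_pct = numeric(),
             injury_old_pct = numeric(), status = character(),
             stringsAsFactors = FALSE)
}

# Row-level colony invariants; `rows` (optional) carries original file row
# numbers so validation errors can cite them.
validate_colony_table <- function(colonies, rows = NULL) {
  need <- c("quadrat_id", "colony_id", "height_cm", "injury_recent_pct",
            "injury_old_pct", "status")
  miss <- setdiff(need, names(colonies))
  if (length(miss)) {
    octopop_schema_error(sprintf("colony table missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  }
  if (nrow(colonies) == 0L) return(invisible(colonies))
  if (is.null(rows)) rows <- seq_len(nrow(colonies))
  cite <- function(i, msg) {
    octopop_validation_error(sprintf("row %d: %s", rows[i], msg))
  }
  h <- colonies$height_cm
  ir <- colonies$injury_recent_pct
  io <- colonies$injury_old_pct
  st <- colonies$status
  bad <- which(!is.finite(h) | h <= 0)
  if (length(bad)) cite(bad[1], "height_cm must be > 0")
  bad <- which(!is.finite(ir) | ir < 0 | ir > 100 |
               !is.finite(io) | io < 0 | io > 100)
  if (length(bad)) cite(bad[1], "injury percentages must lie in [0, 100]")
  tot <- ir + io
  bad <- which(tot > 100 + 1e-9)
  if (length(bad)) {
    cite(bad[1], sprintf(
      "injury_recent_pct + injury_old_pct = %g exceeds the 100%% bound", tot[bad[1]]))
  }
  bad <- which(!st %in% COLONY_STATUSES)
  if (length(bad)) {
    cite(bad[1], sprintf("status must be one of: %s",
                         paste(COLONY_STATUSES, collapse = ", ")))
  }
  dead <- st == "standing_dead"
  full <- abs(tot - 100) <= 1e-9
  bad <- which(dead & !full)
  if (length(bad)) cite(bad[1], "standing_dead requires total injury = 100%")
  bad <- which(!dead & full)
  if (length(bad)) cite(bad[1], "total injury = 100% requires status standing_dead")
  for (q in unique(colonies$quadrat_id)) {
    ids <- colonies$colony_id[colonies$quadrat_id == q]
    if (anyDuplicated(ids)) {
      octopop_validation_error(sprintf("duplicate colony_id within quadrat '%s'", q))
    }
  }
  invisible(colonies)
}

#' @export
print.population_survey <- function(x, ...) {
  alive <- sum(x$colonies$status == "alive")
  cat(sprintf("<population_survey> %s (%s), %d\n", x$population_id, x$species, x$year))
  cat(sprintf("  %d quadrats (%.3g m2 total), %d colonies (%d alive)\n",
              nrow(x$quadrats), sum(x$quadrats$area_m2), nrow(x$colonies), alive))
  invisible(x)
}

#' Read colony-level quadrat surveys from CSV
#'
#' One colony per row; an empty quadrat is encoded as a row with status
#' `"absent"` and blank colony fields. Rows are grouped into one
#' [population_survey] per (population, year).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names (see Details) to the file's column names, e.g.
#'   `c(height_cm = "H")`. Unmapped columns are looked up by canonical name.
#'
#' @details Required columns: `population`, `species`, `year`, `quadrat`,
#'   `area_m2`, `height_cm`, `injury_recent_pct`, `injury_old_pct`, `status`.
#'   Optional: `colony_id` (generated from row numbers when absent),
#'   `depth_m`. Validation failures cite the offending file row.
#'
#' @return A list of [population_survey] objects, ordered by population then
#'   year.
#' @seealso [write_surveys()]
#' @export
read_surveys <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    octopop_stop(sprintf("file not found: %s", path), "octopop_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      from <- schema[[canon]]
      if (!from %in% names(raw)) {
        octopop_schema_error(sprintf(
          "schema maps '%s' to '%s', which is not a column of %s", canon, from, path))
      }
      names(raw)[names(raw) == from] <- canon
    }
  }
  miss <- setdiff(SURVEY_REQUIRED_COLUMNS, names(raw))
  if (length(miss)) {
    octopop_schema_error(sprintf("missing required column(s): %s",
                                 paste(miss, collapse = ", ")))
  }
  if (!"colony_id" %in% names(raw)) raw$colony_id <- paste0("c", seq_len(nrow(raw)))
  if (!"depth_m" %in% names(raw)) raw$depth_m <- NA
  num <- function(x) suppressWarnings(as.numeric(x))
  raw$year_n <- num(raw$year)
  raw$area_n <- num(raw$area_m2)
  if (any(is.na(raw$year_n)) || any(is.na(raw$area_n))) {
    octopop_validation_error(sprintf(
      "row %d: year and area_m2 must be numeric",
      which(is.na(raw$year_n) | is.na(raw$area_n))[1] + 1L))
  }

  key <- paste(raw$population, raw$year_n, sep = "\r")
  surveys <- lapply(split(seq_len(nrow(raw)), factor(key, unique(key))), function(idx) {
    g <- raw[idx, ]
    sp <- unique(g$species)
    if (length(sp) > 1L) {
      octopop_validation_error(sprintf(
        "population '%s' year %s mixes species: %s",
        g$population[1], g$year[1], paste(sp, collapse = ", ")))
    }
    quad <- unique(data.frame(quadrat_id = g$quadrat, area_m2 = g$area_n,
                              stringsAsFactors = FALSE))
    if (anyDuplicated(quad$quadrat_id)) {
      octopop_validation_error(sprintf(
        "quadrat '%s' listed with inconsistent areas",
        quad$quadrat_id[duplicated(quad$quadrat_id)][1]))
    }
    present <- g$status != "absent"
    cg <- g[present, , drop = FALSE]
    colonies <- data.frame(
      quadrat_id = cg$quadrat, colony_id = cg$colony_id,
      height_cm = num(cg$height_cm),
      injury_recent_pct = num(cg$injury_recent_pct),
      injury_old_pct = num(cg$injury_old_pct),
      status = cg$status, stringsAsFactors = FALSE)
    # +1: header row, so cited numbers match what the user sees in the file
    validate_colony_table(colonies, rows = idx[present] + 1L)
    population_survey(g$population[1], sp, g$year_n[1], quad, colonies,
                      depth_m = num(g$depth_m[1]))
  })
  names(surveys) <- NULL
  ord <- order(vapply(surveys, function(s) s$population_id, ""),
               vapply(surveys, function(s) s$year, 0L))
  surveys[ord]
}

#' Write surveys to CSV
#'
#' Inverse of [read_surveys()]: one colony per row, empty quadrats encoded as
#' `status = "absent"` rows with blank colony fields, so that
#' `read_surveys(write_surveys(x, f))` round-trips every numeric field.
#'
#' @param surveys A [population_survey] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(surveys, path) {
  if (inherits(surveys, "population_survey")) surveys <- list(surveys)
  rows <- lapply(surveys, function(s) {
    occupied <- s$quadrats$quadrat_id %in% s$colonies$quadrat_id
    area_of <- stats::setNames(s$quadrats$area_m2, s$quadrats$quadrat_id)
    col_rows <- if (nrow(s$colonies) > 0L) {
      data.frame(population = s$population_id, species = s$species,
                 year = s$year, depth_m = s$depth_m,
                 quadrat = s$colonies$quadrat_id,
                 area_m2 = unname(area_of[s$colonies$quadrat_id]),
                 colony_id = s$colonies$colony_id,
                 height_cm = s$colonies$height_cm,
                 injury_recent_pct = s$colonies$injury_recent_pct,
                 injury_old_pct = s$colonies$injury_old_pct,
                 status = s$colonies$status, stringsAsFactors = FALSE)
    } else NULL
    empty_rows <- if (any(!occupied)) {
      data.frame(population = s$population_id, species = s$species,
                 year = s$year, depth_m = s$depth_m,
                 quadrat = s$quadrats$quadrat_id[!occupied],
                 area_m2 = s$quadrats$area_m2[!occupied],
                 colony_id = "", height_cm = NA_real_,
                 injury_recent_pct = NA_real_, injury_old_pct = NA_real_,
                 status = "absent", stringsAsFactors = FALSE)
    } else NULL
    rbind(col_rows, empty_rows)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Species configuration
#'
#' Bundles the species-specific constants the indicators need: allometric
#' biomass coefficients (`biomass_g = a * height_cm^b`), ordered size-class
#' bin edges, the injury threshold above which a colony counts as "affected",
#' and the sublethal/lethal absolute temperature floors.
#'
#' @param species Species identifier.
#' @param allometric_a Scale coefficient (g per cm^b), > 0.
#' @param allometric_b Dimensionless allometric exponent, > 0.
#' @param size_bins_cm Strictly increasing interior bin edges starting after
#'   0; the last class is open-ended. E.g. `c(10, 20, 30, 40)` gives classes
#'   0–10, >10–20, >20–30, >30–40, >40 cm.
#' @param affected_threshold_pct Injury percentage above which (strictly) a
#'   colony is "affected". Default 10.
#' @param sublethal_temp_c,lethal_temp_c Absolute temperature floors in
#'   degrees C. Defaults 23 and 25.
#'
#' @return An object of class `species_config`.
#' @export
species_config <- function(species, allometric_a, allometric_b, size_bins_cm,
                           affected_threshold_pct = 10,
                           sublethal_temp_c = 23, lethal_temp_c = 25) {
  if (!is.numeric(allometric_a) || allometric_a <= 0 ||
      !is.numeric(allometric_b) || allometric_b <= 0) {
    octopop_domain_error("allometric coefficients must be > 0")
  }
  edges <- as.numeric(size_bins_cm)
  if (length(edges) < 1L || any(!is.finite(edges)) || any(edges <= 0) ||
      is.unsorted(edges, strictly = TRUE)) {
    octopop_domain_error("size_bins_cm must be strictly increasing positive edges")
  }
  if (affected_threshold_pct <= 0 || affected_threshold_pct >= 100) {
    octopop_domain_error("affected_threshold_pct must lie strictly in (0, 100)")
  }
  structure(
    list(species = as.character(species),
         allometric_a = as.numeric(allometric_a),
         allometric_b = as.numeric(allometric_b),
         size_bins_cm = edges,
         affected_threshold_pct = as.numeric(affected_threshold_pct),
         sublethal_temp_c = as.numeric(sublethal_temp_c),
         lethal_temp_c = as.numeric(lethal_temp_c)),
    class = "species_config")
}

#' @export
print.species_config <- function(x, ...) {
  cat(sprintf("<species_config> %s: biomass_g = %g * H^%g; bins %s cm; affected > %g%%\n",
              x$species, x$allometric_a, x$allometric_b,
              paste(x$size_bins_cm, collapse = ","), x$affected_threshold_pct))
  invisible(x)
}

#' Built-in species configurations
#'
#' Configurations for the two study species, loaded from the JSON shipped in
#' `inst/extdata/species_configs.json` (configs are data, not code: pass your
#' own file to [read_species_config()] to add species).
#'
#' *P. clavata*: biomass_g = 0.002 H^2.61, size classes 0-10, 10-20, 20-30,
#' 30-40 and above 40 cm (each class open on the left). *C. rubrum*:
#' biomass_g = 0.1535 H^1.9732, classes 0-3, 3-6, 6-9, 9-15 and above 15 cm.
#' Both use the 10% affected threshold and 23/25 degC floors.
#'
#' @param species `"paramuricea_clavata"` or `"corallium_rubrum"`.
#' @return A [species_config].
#' @export
builtin_species_config <- function(species) {
  path <- system.file("extdata", "species_configs.json", package = "octopop",
                      mustWork = TRUE)
  configs <- read_species_config(path)
  if (!species %in% names(configs)) {
    octopop_domain_error(sprintf(
      "unknown species '%s'; supported species: %s",
      species, paste(names(configs), collapse = ", ")))
  }
  configs[[species]]
}

#' Read species configurations from a JSON file
#'
#' @param path JSON file: an object keyed by species id, each entry holding
#'   the [species_config] fields.
#' @return Named list of [species_config] objects.
#' @export
read_species_config <- function(path) {
  if (!file.exists(path)) {
    octopop_stop(sprintf("species config not found: %s", path), "octopop_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(sp) {
    f <- raw[[sp]]
    species_config(sp, f$allometric_a, f$allometric_b, f$size_bins_cm,
                   affected_threshold_pct = f$affected_threshold_pct %||% 10,
                   sublethal_temp_c = f$sublethal_temp_c %||% 23,
                   lethal_temp_c = f$lethal_temp_c %||% 25)
  })
  stats::setNames(out, names(raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
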
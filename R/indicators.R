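# The five population parameters (affected %, mean injury, density, live
# biomass, size structure), baseline reconstruction from injury classes, and
# the Monte-Carlo exact size-structure comparison.

total_injury <- function(colonies) {
  colonies$injury_recent_pct + colonies$injury_old_pct
}

se_of <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Allometric live biomass of a colony
#'
#' Evaluates `a * height_cm^b` and corrects for partial mortality by the live
#' surface fraction, `(1 - injury_total_pct / 100)`. A healthy 1 cm colony
#' therefore weighs exactly `a` grams; a fully injured colony weighs 0.
#'
#' @param height_cm Colony height(s) in cm, > 0. Vectorised.
#' @param injury_total_pct Total injured surface percentage(s) in \[0, 100\].
#' @param config A [species_config].
#' @return Live biomass in grams, same length as the longer input.
#' @export
colony_biomass <- function(height_cm, injury_total_pct, config) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    octopop_domain_error("height_cm must be finite and > 0")
  }
  if (any(!is.finite(injury_total_pct)) ||
      any(injury_total_pct < 0) || any(injury_total_pct > 100)) {
    octopop_domain_error("injury_total_pct must lie in [0, 100]")
  }
  config$allometric_a * height_cm^config$allometric_b * (1 - injury_total_pct / 100)
}

#' Percentage of affected colonies
#'
#' Share of colonies whose injured surface strictly exceeds the species
#' threshold (default 10%). `injury_kind` selects which injury class is
#' tested: `"any"` uses recent + old, `"recent"` and `"old"` each class
#' alone.
#'
#' @param survey A [population_survey] with at least one colony.
#' @param config A [species_config].
#' @param injury_kind One of `"any"`, `"recent"`, `"old"`.
#' @return Percentage in \[0, 100\].
#' @export
pct_affected <- function(survey, config, injury_kind = c("any", "recent", "old")) {
  injury_kind <- match.arg(injury_kind)
  col <- survey$colonies
  if (nrow(col) == 0L) {
    octopop_empty_error("pct_affected is undefined for a population with no colonies")
  }
  inj <- switch(injury_kind,
                any = total_injury(col),
                recent = col$injury_recent_pct,
                old = col$injury_old_pct)
  100 * mean(inj > config$affected_threshold_pct)
}

#' Mean extent of injured tissue
#'
#' Arithmetic mean of total injury (recent + old) per colony, with standard
#' error across colonies. Standing-dead colonies carry 100% injury; whether
#' they enter the average is a reading choice, so both are exposed.
#'
#' @param survey A [population_survey].
#' @param include_standing_dead Include standing-dead colonies (at 100%
#'   injury) in the average? Default `TRUE`.
#' @return List with `mean`, `se` (NA when n < 2), `n`.
#' @export
mean_injury <- function(survey, include_standing_dead = TRUE) {
  col <- survey$colonies
  if (!include_standing_dead) col <- col[col$status == "alive", , drop = FALSE]
  if (nrow(col) == 0L) {
    octopop_empty_error("mean_injury: no colonies left after the inclusion filter")
  }
  inj <- total_injury(col)
  list(mean = mean(inj), se = se_of(inj), n = length(inj))
}

#' Population density
#'
#' Mean of per-quadrat densities of living colonies (colonies per m2), with
#' standard error across quadrats. Standing-dead colonies are excluded; empty
#' quadrats contribute zeros (they lower the mean).
#'
#' @param survey A [population_survey].
#' @return List with `mean`, `se`, `n` (number of quadrats), and
#'   `per_quadrat` (named vector of densities).
#' @export
density <- function(survey) {
  alive <- survey$colonies[survey$colonies$status == "alive", , drop = FALSE]
  counts <- table(factor(alive$quadrat_id, levels = survey$quadrats$quadrat_id))
  dens <- as.numeric(counts) / survey$quadrats$area_m2
  names(dens) <- survey$quadrats$quadrat_id
  list(mean = mean(dens), se = se_of(dens), n = length(dens), per_quadrat = dens)
}

#' Live population biomass per square metre
#'
#' Per quadrat, sums [colony_biomass()] over living colonies and divides by
#' quadrat area; returns the mean and standard error across quadrats.
#'
#' @param survey A [population_survey].
#' @param config A [species_config].
#' @return List with `mean`, `se`, `n`, `per_quadrat` (g per m2).
#' @export
population_biomass <- function(survey, config) {
  alive <- survey$colonies[survey$colonies$status == "alive", , drop = FALSE]
  per_col <- if (nrow(alive) > 0L) {
    colony_biomass(alive$height_cm, total_injury(alive), config)
  } else numeric()
  sums <- tapply(per_col, factor(alive$quadrat_id, levels = survey$quadrats$quadrat_id),
                 sum, default = 0)
  bm <- as.numeric(sums) / survey$quadrats$area_m2
  names(bm) <- survey$quadrats$quadrat_id
  list(mean = mean(bm), se = se_of(bm), n = length(bm), per_quadrat = bm)
}

size_class_labels <- function(edges) {
  lower <- c(0, edges)
  upper <- c(edges, Inf)
  ifelse(is.infinite(upper),
         sprintf(">%g", lower),
         ifelse(lower == 0, sprintf("0-%g", upper), sprintf(">%g-%g", lower, upper)))
}

#' Colony size structure
#'
#' Counts colonies per size class. The first class is closed, `[0, e1]`,
#' and every later class is left-open, `(e_i, e_{i+1}]`, with an open-ended
#' last class — a colony exactly on an edge belongs to the smaller class
#' ("from 0 to 10, greater than 10 to 20").
#'
#' @param survey A [population_survey] with at least one colony (after
#'   filtering).
#' @param config A [species_config] supplying `size_bins_cm`.
#' @param include_standing_dead Count standing-dead colonies? Default `FALSE`.
#' @return Named integer vector of counts, one per size class; sums to the
#'   number of included colonies.
#' @export
size_structure <- function(survey, config, include_standing_dead = FALSE) {
  col <- survey$colonies
  if (!include_standing_dead) col <- col[col$status == "alive", , drop = FALSE]
  if (nrow(col) == 0L) {
    octopop_empty_error("size_structure: no colonies after the inclusion filter")
  }
  breaks <- c(0, config$size_bins_cm, Inf)
  cls <- cut(col$height_cm, breaks = breaks, right = TRUE, include.lowest = TRUE,
             labels = size_class_labels(config$size_bins_cm))
  counts <- table(cls)
  stats::setNames(as.integer(counts), names(counts))
}

#' Reconstruct the pre-disturbance baseline of a survey
#'
#' Estimates each colony's state before a recent mortality event from its
#' injury classes: old injury (established epibiont overgrowth) is assumed to
#' predate the event and is kept; recent injury (denuded axis, fresh
#' epibiosis) is attributed to the event and reset to healthy tissue.
#' Colonies that were 100% recently injured come back alive and healthy;
#' colonies with 100% old injury stay standing dead. The operation is
#' idempotent.
#'
#' @param survey A [population_survey] distinguishing recent vs old injury.
#' @return A new [population_survey] for the same year set to the estimated
#'   baseline.
#' @export
reconstruct_baseline <- function(survey) {
  col <- survey$colonies
  if (nrow(col) > 0L) {
    col$injury_recent_pct <- 0
    col$status <- ifelse(abs(col$injury_old_pct - 100) <= 1e-9,
                         "standing_dead", "alive")
  }
  population_survey(survey$population_id, survey$species, survey$year,
                    survey$quadrats, col, depth_m = survey$depth_m)
}

#' Monte-Carlo exact test for a change in size structure
#'
#' Compares two size-class count vectors with an exact conditional test on
#' the 2 x k contingency table (the r x c generalisation of Fisher's exact
#' test). Tables with both margins fixed are sampled with the Patefield
#' algorithm; the p-value is the add-one-corrected share of sampled tables
#' whose conditional point probability is at most that of the observed
#' table:
#' `p = (1 + #\{P(table) <= P(observed)\}) / (n_montecarlo + 1)`.
#'
#' @param counts_a,counts_b Count vectors over identical size classes. If
#'   both are named, names must match.
#' @param n_montecarlo Number of sampled tables. Default 10000.
#' @param seed Integer seed; the estimate is deterministic given the seed.
#' @return List with `p_value`, `n_montecarlo`, `mc_se` (binomial standard
#'   error of the estimate).
#' @export
compare_size_structures <- function(counts_a, counts_b, n_montecarlo = 10000,
                                    seed = 1L) {
  if (length(counts_a) != length(counts_b)) {
    octopop_domain_error("count vectors must cover identical size classes")
  }
  if (!is.null(names(counts_a)) && !is.null(names(counts_b)) &&
      !identical(names(counts_a), names(counts_b))) {
    octopop_domain_error("count vectors must cover identical size classes (names differ)")
  }
  a <- as.numeric(counts_a); b <- as.numeric(counts_b)
  if (any(a < 0) || any(b < 0) || sum(a) < 1 || sum(b) < 1) {
    octopop_domain_error("counts must be non-negative with positive totals")
  }
  tab <- rbind(a, b)
  # conditional point log-probability given fixed margins is, up to a
  # constant shared by all tables, -sum(lgamma(n_ij + 1))
  logp <- function(m) -sum(lgamma(m + 1))
  obs <- logp(tab)
  hits <- with_seed(seed, {
    sims <- stats::r2dtable(n_montecarlo, rowSums(tab), colSums(tab))
    sum(vapply(sims, logp, 0) <= obs + 1e-7)
  })
  p <- (1 + hits) / (n_montecarlo + 1)
  list(p_value = p, n_montecarlo = n_montecarlo,
       mc_se = sqrt(p * (1 - p) / n_montecarlo))
}

#' Compute all five population parameters of a survey
#'
#' Convenience wrapper returning the full indicator set for one population
#' and year; [indicators_table()] flattens a list of these to the tidy CSV
#' schema.
#'
#' @param survey A [population_survey].
#' @param config A [species_config]; defaults to the built-in config of the
#'   survey's species.
#' @return An object of class `indicator_set`.
#' @export
compute_indicators <- function(survey, config = builtin_species_config(survey$species)) {
  has_colonies <- nrow(survey$colonies) > 0L
  has_alive <- any(survey$colonies$status == "alive")
  structure(
    list(population_id = survey$population_id, species = survey$species,
         year = survey$year, n_colonies = nrow(survey$colonies),
         pct_affected = if (has_colonies) pct_affected(survey, config) else NA_real_,
         pct_affected_recent = if (has_colonies) pct_affected(survey, config, "recent") else NA_real_,
         mean_injury = if (has_colonies) mean_injury(survey, TRUE) else NULL,
         mean_injury_alive = if (has_alive) mean_injury(survey, FALSE) else NULL,
         density = density(survey),
         biomass = population_biomass(survey, config),
         size_structure = if (has_alive) size_structure(survey, config) else NULL),
    class = "indicator_set")
}

#' @export
print.indicator_set <- function(x, ...) {
  cat(sprintf("<indicator_set> %s %d: affected %.1f%%, injury %.1f%%, density %.1f /m2, biomass %.1f g/m2\n",
              x$population_id, x$year, x$pct_affected,
              if (is.null(x$mean_injury)) NA else x$mean_injury$mean,
              x$density$mean, x$biomass$mean))
  invisible(x)
}

#' Tidy long-form indicator table
#'
#' @param indicator_sets List of objects from [compute_indicators()].
#' @return Data frame with columns population, year, indicator, value, se, n
#'   (size-structure rows use the class label as indicator
#'   `size_class:<label>` with count as value).
#' @export
indicators_table <- function(indicator_sets) {
  if (inherits(indicator_sets, "indicator_set")) indicator_sets <- list(indicator_sets)
  rows <- lapply(indicator_sets, function(x) {
    base <- data.frame(
      population = x$population_id, year = x$year,
      indicator = c("pct_affected", "pct_affected_recent", "mean_injury_pct",
                    "mean_injury_pct_alive", "density_per_m2", "biomass_g_per_m2"),
      value = c(x$pct_affected, x$pct_affected_recent,
                if (is.null(x$mean_injury)) NA_real_ else x$mean_injury$mean,
                if (is.null(x$mean_injury_alive)) NA_real_ else x$mean_injury_alive$mean,
                x$density$mean, x$biomass$mean),
      se = c(NA, NA,
             if (is.null(x$mean_injury)) NA_real_ else x$mean_injury$se,
             if (is.null(x$mean_injury_alive)) NA_real_ else x$mean_injury_alive$se,
             x$density$se, x$biomass$se),
      n = c(x$n_colonies, x$n_colonies,
            if (is.null(x$mean_injury)) NA_integer_ else x$mean_injury$n,
            if (is.null(x$mean_injury_alive)) NA_integer_ else x$mean_injury_alive$n,
            x$density$n, x$biomass$n),
      stringsAsFactors = FALSE)
    ss <- if (!is.null(x$size_structure)) {
      data.frame(population = x$population_id, year = x$year,
                 indicator = paste0("size_class:", names(x$size_structure)),
                 value = as.numeric(x$size_structure), se = NA_real_,
                 n = sum(x$size_structure), stringsAsFactors = FALSE)
    } else NULL
    rbind(base, ss)
  })
  do.call(rbind, rows)
}
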
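# The five population parameters, baseline reconstruction and the
# Monte-Carlo exact size-structure test.

test_that("colony_biomass matches the allometric equations and injury correction", {
  expect_equal(colony_biomass(1, 0, pclav), 0.002)
  expect_equal(colony_biomass(1, 0, crub), 0.1535)
  expect_equal(colony_biomass(37, 100, pclav), 0)
  expect_equal(colony_biomass(10, 50, pclav), 0.5 * 0.002 * 10^2.61)
  expect_error(colony_biomass(-1, 0, pclav), class = "octopop_domain_error")
  expect_error(colony_biomass(10, 101, pclav), class = "octopop_domain_error")
})

test_that("biomass is increasing in height and decreasing in injury", {
  set.seed(42)
  h <- sort(runif(50, 0.5, 80))
  inj <- sort(runif(50, 0, 100))
  for (cfg in list(pclav, crub)) {
    expect_true(all(diff(colony_biomass(h, 30, cfg)) > 0))
    expect_true(all(diff(colony_biomass(25, inj, cfg)) < 0))
  }
})

test_that("pct_affected uses a strict 10% threshold per injury kind", {
  s <- make_survey(heights = rep(20, 4), recent = c(5, 10, 10.1, 50))
  expect_equal(pct_affected(s, pclav), 50)  # 10 is not > 10
  expect_equal(pct_affected(s, pclav, "recent"), 50)
  expect_equal(pct_affected(s, pclav, "old"), 0)

  expect_equal(pct_affected(make_survey(rep(20, 3)), pclav), 0)
  all_dead <- make_survey(rep(20, 3), recent = 100)
  expect_equal(pct_affected(all_dead, pclav), 100)
  empty <- make_survey(numeric())
  expect_error(pct_affected(empty, pclav), class = "octopop_empty_error")

  # any-kind affected share dominates each single-kind share
  set.seed(7)
  for (i in 1:10) {
    r <- runif(20, 0, 60); o <- runif(20, 0, 40)
    s <- make_survey(rep(20, 20), recent = r, old = o)
    expect_gte(pct_affected(s, pclav),
               max(pct_affected(s, pclav, "recent"), pct_affected(s, pclav, "old")))
  }
})

test_that("mean_injury averages total injury with and without standing dead", {
  s <- make_survey(rep(20, 3), recent = c(0, 50, 100))
  expect_equal(mean_injury(s, include_standing_dead = TRUE)$mean, 50)
  expect_equal(mean_injury(s, include_standing_dead = FALSE)$mean, 25)
  one <- make_survey(20, recent = 20)
  mi <- mean_injury(one)
  expect_equal(mi$mean, 20)
  expect_true(is.na(mi$se))
  dead_only <- make_survey(rep(20, 2), recent = 100)
  expect_error(mean_injury(dead_only, include_standing_dead = FALSE),
               class = "octopop_empty_error")
})

test_that("density is the mean of per-quadrat densities, alive only", {
  s <- make_survey(rep(10, 15), quadrat_of = rep(c(1, 2), c(5, 10)))
  d <- density(s)
  expect_equal(d$mean, 30)          # (5/0.25 + 10/0.25)/2
  expect_equal(d$per_quadrat, c(q1 = 20, q2 = 40))

  # standing dead are excluded; empty survey gives 0
  sd_ <- make_survey(rep(10, 4), recent = c(0, 0, 100, 100),
                     quadrat_of = c(1, 1, 2, 2))
  expect_equal(density(sd_)$mean, mean(c(2 / 0.25, 0)))
  expect_equal(density(make_survey(numeric()))$mean, 0)

  # duplicating every quadrat keeps the mean, shrinks s.e. by sqrt(2)
  s1 <- make_survey(rep(10, 15), quadrat_of = rep(1:5, 3), n_quadrats = 5L)
  s2 <- make_survey(rep(10, 30), quadrat_of = rep(1:10, 3), n_quadrats = 10L)
  expect_equal(density(s2)$mean, density(s1)$mean)
  expect_equal(density(s2)$se, density(s1)$se / sqrt(2), tolerance = 1e-12)

  # scale invariance: same density at doubled area and count
  sa <- make_survey(rep(10, 6), quadrat_of = c(1, 1, 2, 2, 2, 2), area = 0.25)
  sb <- make_survey(rep(10, 12), quadrat_of = rep(c(1, 2), c(4, 8)), area = 0.5)
  expect_equal(density(sb)$mean, density(sa)$mean)
})

test_that("population_biomass averages per-quadrat live biomass per area", {
  s <- make_survey(1, n_quadrats = 1L)
  expect_equal(population_biomass(s, pclav)$mean, 0.002 / 0.25)
  expect_equal(population_biomass(make_survey(numeric()), pclav)$mean, 0)
  dead <- make_survey(c(10, 20), recent = 100)
  expect_equal(population_biomass(dead, pclav)$mean, 0)
})

test_that("size_structure bins with closed-left first class and open tail", {
  s <- make_survey(c(5, 15, 25, 35, 45))
  expect_equal(unname(size_structure(s, pclav)), rep(1L, 5))

  edge <- make_survey(c(10, 10.0001, 40, 41))
  ss <- size_structure(edge, pclav)
  expect_equal(ss[["0-10"]], 1L)    # exactly 10 belongs to the first class
  expect_equal(ss[[">10-20"]], 1L)
  expect_equal(ss[[">30-40"]], 1L)
  expect_equal(ss[[">40"]], 1L)

  cr <- make_survey(15, species = "corallium_rubrum", area = 0.04)
  expect_equal(size_structure(cr, crub)[[">9-15"]], 1L)

  # conservation: counts always sum to included colonies
  set.seed(11)
  for (i in 1:5) {
    h <- runif(40, 0.1, 60)
    s <- make_survey(h, n_quadrats = 4L)
    expect_equal(sum(size_structure(s, pclav)), 40L)
  }
})

test_that("reconstruct_baseline keeps old injury, clears recent, revives the recently killed", {
  s <- make_survey(c(20, 30, 25), recent = c(30, 100, 0), old = c(20, 0, 100))
  b <- reconstruct_baseline(s)
  expect_equal(b$colonies$injury_recent_pct, c(0, 0, 0))
  expect_equal(b$colonies$injury_old_pct, c(20, 0, 100))
  expect_equal(b$colonies$status, c("alive", "alive", "standing_dead"))

  # idempotent
  expect_identical(reconstruct_baseline(b), b)

  # baseline injury never exceeds post-event injury; baseline density >= post
  set.seed(13)
  for (i in 1:10) {
    r <- runif(25, 0, 70); o <- pmin(runif(25, 0, 50), 100 - r)
    s <- make_survey(rep(20, 25), recent = r, old = o, n_quadrats = 5L)
    b <- reconstruct_baseline(s)
    expect_lte(mean_injury(b)$mean, mean_injury(s)$mean)
    expect_gte(density(b)$mean, density(s)$mean)
  }
})

# closed-form Fisher 2x2: hypergeometric tail summed over tables whose point
# probability is at most the observed one
fisher_2x2_oracle <- function(tab) {
  k1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  probs <- stats::dhyper(0:min(k1, c1), c1, c2, k1)
  obs <- stats::dhyper(tab[1, 1], c1, c2, k1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("Monte-Carlo exact test behaves and matches the 2x2 oracle", {
  same <- compare_size_structures(c(10, 20, 5), c(10, 20, 5), 1e4, seed = 3)
  expect_gte(same$p_value, 0.99)

  extreme <- compare_size_structures(c(50, 0), c(0, 50), 1e4, seed = 3)
  expect_lte(extreme$p_value, 0.001)

  # determinism under seed
  expect_identical(compare_size_structures(c(8, 3, 9), c(2, 7, 4), 2000, seed = 9),
                   compare_size_structures(c(8, 3, 9), c(2, 7, 4), 2000, seed = 9))

  # 2x2 agreement with the closed-form hypergeometric within 3 MC s.e.
  tables <- list(rbind(c(8, 2), c(1, 5)), rbind(c(12, 7), c(5, 14)),
                 rbind(c(3, 9), c(10, 4)))
  for (tab in tables) {
    mc <- compare_size_structures(tab[1, ], tab[2, ], 2e4, seed = 17)
    expect_lt(abs(mc$p_value - fisher_2x2_oracle(tab)), 3 * mc$mc_se + 1e-4)
  }

  expect_error(compare_size_structures(c(1, 2), c(1, 2, 3)),
               class = "octopop_domain_error")
})

test_that("compute_indicators assembles the five parameters; table is tidy", {
  s <- make_survey(c(5, 15, 25, 40), recent = c(0, 20, 5, 100),
                   quadrat_of = c(1, 1, 2, 2))
  ind <- compute_indicators(s, pclav)
  expect_equal(ind$pct_affected, 50)     # 20 and 100 exceed 10
  expect_equal(ind$density$mean, mean(c(2, 1)) / 0.25)
  expect_equal(sum(ind$size_structure), 3L)  # alive only

  tab <- indicators_table(list(ind))
  expect_true(all(c("population", "year", "indicator", "value", "se", "n")
                  %in% names(tab)))
  expect_true(any(grepl("^size_class:", tab$indicator)))
  expect_equal(tab$value[tab$indicator == "density_per_m2"], ind$density$mean)
})
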
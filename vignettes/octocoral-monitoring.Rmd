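---
title: "Monitoring octocoral populations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring octocoral populations: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octopop)
```

`octopop` implements the quantitative core of long-term monitoring of
habitat-forming Mediterranean octocorals: demographic indicators from
colony-level quadrat surveys, baseline reconstruction from injury classes,
self-thinning trajectory analysis, and marine-heatwave statistics. This
vignette is the package's account of the science behind each piece: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic generator does and does not emulate,
and the numerical choices a careful user should know about.

## 1. The survey model

The observational unit is a **colony** inside a fixed-area **quadrat**:
maximum height in cm, the percentage of colony surface with **recent
injury** (denuded skeletal axis or fresh epibiosis) and with **old injury**
(established overgrowth by epibionts), and a status. Total injury is always
the sum of the two classes and cannot exceed 100%; a colony is
`standing_dead` exactly when its total injury is 100% — the skeleton is
still attached and countable. Colonies that detached entirely are simply
absent from the table: they are unobservable, which is why densities
reconstructed from later surveys carry a downward bias (see §3).

Two design choices deserve emphasis. First, **empty quadrats are data**: a
quadrat with zero colonies lowers the population's mean density, so the
reader preserves them (encoded as `status = "absent"` rows in the CSV).
Second, **species constants are configuration, not code**: the allometric
coefficients, size-class edges and thermal floors live in a JSON file
(`inst/extdata/species_configs.json`), so adding a species never means
editing functions.

## 2. The five indicators

* **Percentage of affected colonies** — share with injury strictly greater
  than the 10% threshold ("more than 10%" is a strict inequality; a colony
  at exactly 10% is unaffected). Computable for any injury class (`any`,
  `recent`, `old`).
* **Mean injury extent** — arithmetic mean of total injury per colony.
  Whether standing-dead colonies (100%) belong in the average is a genuine
  reading ambiguity in cumulative-injury time series, so both variants are
  computed and reported (`mean_injury_pct`, `mean_injury_pct_alive`).
* **Density** — the mean of *per-quadrat* densities of living colonies, not
  pooled count over pooled area. The distinction matters: with unequal
  occupancy the two differ, and the standard error is defined across
  quadrats. Duplicating every quadrat leaves the mean unchanged and shrinks
  the s.e. by √2 — a sampling identity the tests assert.
* **Live biomass per m²** — per quadrat, the sum of colony biomasses over
  living colonies divided by quadrat area, averaged across quadrats. Colony
  biomass is `a·H^b` corrected multiplicatively by the live surface
  fraction `(1 − injury/100)`. The multiplicative form is the simplest one
  consistent with "corrected for the proportion of injured surface": a
  colony 30% overgrown carries 70% of its allometric biomass.
* **Size structure** — counts over height classes. The first class is
  closed (`[0, e₁]`), later classes left-open (`(eᵢ, eᵢ₊₁]`), the last
  open-ended: a 10 cm red gorgonian belongs to the 0–10 class, not 10–20.

**Baseline reconstruction.** After a mortality event, the injury classes
date the damage: overgrowth by epibionts takes months to establish, so old
injury predates a recent event and recent injury is attributed to it. The
estimated pre-event state therefore keeps old injury, zeroes recent injury,
revives colonies whose injury was 100% recent, and keeps 100%-old colonies
standing dead. The operation is idempotent, can only decrease mean injury,
and can only increase living density — all property-tested. It cannot
credit colonies that detached before the first survey; reconstructed
baseline densities are accordingly conservative (biased low).

**Size-structure comparison.** Changes in size structure are tested with an
exact conditional test on the 2×k table of counts — the r×c generalisation
of Fisher's exact test. Rather than network enumeration, tables with both
margins fixed are sampled (Patefield's algorithm, `r2dtable`), and

p = (1 + #{tables with point probability ≤ observed}) / (n_montecarlo + 1).

The add-one correction keeps p > 0 and makes the estimator valid as a
p-value; given a seed the result is reproducible. The tests check agreement
with the closed-form 2×2 hypergeometric within three Monte-Carlo standard
errors, so the sampler is never its own oracle.

## 3. Self-thinning trajectories

Crowded, undisturbed populations of sessile organisms sit near a log–log
equilibrium between **mean individual biomass** and **density** with slope
≈ −3/2: further biomass growth requires density decay through competition.
The y-axis choice matters and is easy to get wrong: the −3/2 exponent
applies to *mean biomass per colony* versus density. Per-area biomass
B·D ∝ D^(−1/2) would thin at −1/2; `biomass_density_points()` therefore
defaults to per-colony mass and offers `mode = "per_area"` only for
exploration. Base-10 logarithms are used throughout (the convention of the
self-thinning literature); the base affects intercepts only.

The species line is fitted by OLS of log₁₀(B̄) on log₁₀(D) across
undisturbed reference populations. OLS-of-B-on-D is an assumption — the
regression could also be D-on-B or a major-axis fit, and published line
parameters rarely say which; a `method = "major_axis"` option exists for
sensitivity checks but is not the documented route. The fit reports slope,
intercept, R², the two-sided t-test p-value for the slope and the residual
standard error. No multiplicity correction is applied (one fit per
species).

A monitored population's yearly points are then mapped into the same plane.
The **signed vertical residual** (log₁₀ units) measures displacement below
or above the line; halving mean colony biomass at fixed density moves the
residual by exactly −log₁₀2 ≈ −0.301. The net movement of a series is
classified by comparing the first and last absolute residuals against a
tolerance: growth `> tol` is `"away-from-line"`, shrinkage `< −tol` is
`"toward-line"`, otherwise `"along-line"`. The default tolerance is the
fitted line's residual standard error — points within the scatter of the
reference populations cannot meaningfully be called displaced — with a
fallback of 0.1 log₁₀ units (≈ 26% in biomass) when the line carries no fit
diagnostics (theoretical or published lines). There is no field-standard
numeric criterion here; the choice is exposed as a parameter.

Because the reference dataset behind the red coral line is available only
as non-redistributable supplementary material, the package ships
`synthetic_crubrum_reference_points()`: 28 points **constructed** (residual
vector orthogonalised against the design and rescaled) so that OLS returns
slope −1.44 and R² 0.62 exactly. It is a labelled synthetic stand-in for
exercising the machinery at realistic size and diagnostics, not the
published data. Published lines (e.g. the red gorgonian slope −1.45) enter
the CLI as constants via `--slope`/`--intercept`.

## 4. Thermal statistics

Two indicators, two data regimes:

**Satellite-era MHW days.** A day-of-year climatology is built over a fixed
baseline (canonically 30 years, e.g. 1982–2011): for each civil day of
year, all baseline observations within a ±5-day window are pooled, the mean
and the 90th percentile computed, and both smoothed with a 31-day centred
circular moving average. These window defaults are the convention of the
standard MHW definition; the percentile (0.9) and the baseline period are
the scientifically load-bearing choices and all are parameters. A **marine
heatwave** is ≥ 5 consecutive days *strictly* warmer than the threshold;
two qualifying runs separated by ≤ 2 observed below-threshold days merge
into one event whose span includes the gap, but **gap days are never
counted as MHW days**. Missing days break runs — absence of data is not
absence of a heatwave's end. Yearly **JJASON MHW days** count each event's
above-threshold days falling in June–November.

The baseline is fixed by construction: appending later years can never
change the climatology, hence never re-score history (property-tested).

**In-situ extreme-heat days.** Multi-year logger records at depth are too
short for a percentile climatology, and for these species harm accrues at
absolute temperatures before the 5-day MHW criterion is met. The indicator
is therefore: days strictly above the record's pooled ("inter-annual") 90th
percentile **and** at ≥ 23 °C (the sublethal floor), counted per year;
years with any daily mean ≥ 25 °C (lethal floor) are flagged. "Inter-annual
90th percentile" is ambiguous between pooling all calendar days and pooling
the warm season only; the package pools all days by default and exposes
`season_months` for the other reading, asserting neither as canonical. The
percentile is applied to daily *means* (hourly records are reduced by
`daily_means()`, which flags days with fewer than 20 of 24 readings as
missing rather than averaging sparse data).

**Numerical conventions.** Strict `>` for percentile exceedance ("warmer
than"), `≥` for the absolute floors ("reaching"). Percentiles use linear
interpolation between order statistics (R type 7); percentile dialects move
thresholds by O(0.01 °C), which matters when comparing implementations.
Feb 29 gets the mean of the Feb 28 and Mar 1 climatology entries; leap-year
days after Feb 28 are shifted back one civil day so seasonal phase is
preserved.

One honest artefact to know about: on a *noiseless* seasonal cycle the
smoothed percentile threshold dips ~0.1 °C below the curve near the
seasonal peak (curvature bias of smoothing a deterministic signal), which
can flag spurious peak-season days. With realistic noise the 90th
percentile sits well above the mean and the effect vanishes. The tests
therefore assert exact anomaly recovery on a flat baseline and ledger
*completeness* (every injected day detected) on the seasonal one.

## 5. The synthetic world

The generator exists so every pipeline stage has ground truth. Its defaults
are a stated world, chosen once:

| Parameter | Default | Why |
|---|---|---|
| quadrats × area | 30 × 0.25 m² (red gorgonian); 24 × 0.04 m² (red coral) | the two field designs; the red coral design totals 0.96 m² |
| initial density | 32 /m² (gorgonian); 67 /m² (red coral) | healthy-population magnitudes for the two species |
| heights | log-normal, median 15 cm (sdlog 0.45) / 4 cm (sdlog 0.5) | right-skewed and positive; puts the gorgonian mode in the 10–20 cm class |
| event mortality | 0.4 | a severe event kills ≈ 40% of colonies |
| affected probability by size | 0.3 → 0.8 increasing | larger colonies are more affected |
| survivor injury | Beta(2, 2) | symmetric, mean 50%, full support |
| annual growth | 0.8 cm | well under the < 3 cm/yr ceiling for these species |
| recruitment | 0.5 /m²/yr | recruitment deficit: far below post-event losses |
| delayed mortality | 0.10/yr above 50% injury | losses continue years after the event |
| epibiosis conversion | 0.5/yr recent→old | overgrowth establishes within ~2 years |
| temperature | mean 17 °C, amplitude 6 °C, peak day 227, AR(1) φ = 0.7, σ = 0.3 °C | NW Mediterranean at ~20 m; red noise with ~3-day decorrelation |

Colony counts are Poisson per quadrat; each quadrat draws from its own
seed stream split deterministically from the scenario seed, so adding a
quadrat never reshuffles the others (tested). `on_line` scenarios rescale
realised heights by `(B_target/B̄)^{1/b}` so the population's mean colony
biomass lands exactly on a given self-thinning line at its realised
density — the anchor for trajectory ground truth.

What the generator does **not** emulate: spatial structure within quadrats,
size-dependent growth and fecundity, recruitment pulses, observer error in
height and injury estimation, and any mechanistic link between temperature
and mortality (disturbance events are imposed, not driven by the thermal
module). A green end-to-end test therefore establishes that the *pipeline*
recovers what was put in — not that the biology of a real collapse is
captured.

For the injection-recovery test of the thermal chain, note that AR(1) noise
legitimately produces exceedance runs of its own; ground truth for total
MHW days is therefore scored against a paired control run (same seed, no
injections) rather than against injected days alone.

## 6. Degenerate inputs and edge policies

* Empty population: indicator functions that average over colonies raise a
  typed error (`octopop_empty_error`) rather than returning 0 — a density
  of zero is data, an undefined mean is not.
* Single colony/quadrat: means are defined, standard errors reported `NA`.
* Two-point line fits: exact interpolation, R² = 1, with a warning; p-value
  undefined.
* Non-negative fitted self-thinning slope: warning, not an error (short
  noisy series can slope upward; the user should see it, not crash).
* All stochastic functions take an explicit integer seed, restore the
  caller's RNG state, and are bit-reproducible given (parameters, seed).

## 7. Known limitations

* Baseline reconstruction cannot see colonies that detached before the
  first post-event survey; reconstructed pre-event densities are lower
  bounds.
* The indicators treat quadrats as the independent sampling unit; no
  spatial autocorrelation between quadrats is modelled.
* Mixed-model inference on indicator time series (GLMMs) is out of scope;
  the package emits tidy tables that standard mixed-model tooling consumes.
* The MHW module detects events and counts days; it does not classify
  severity categories or interpolate between logger depths.
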
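---
title: "Methods: accounting for small-scale fisheries in national nutrient supply"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accounting for small-scale fisheries in national nutrient supply}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrisupply)
library(dplyr)
```

# The problem

Apparent consumption — production plus imports minus exports, after
correcting for non-food end uses and re-exports — is the standard
supply-side proxy for what a country eats when direct consumption surveys
are unavailable. This package applies that accounting to marine seafood,
keeps the catch *sector* (artisanal, subsistence, industrial, recreational,
mariculture, plus imports as a sixth source) attached to every tonne all the
way through, converts tonnage to supply of seven nutrients, and asks what
share of a coastal resident's nutrient supply comes from small-scale
fisheries (SSF), defined as the artisanal plus subsistence sectors.

The tracked nutrients are iron, zinc and calcium (mg per 100 g edible raw
muscle tissue), vitamin A (µg RAE), vitamin B12 (µg), DHA+EPA and protein
(g). The "assessed" set used for country means and classification is the six
without protein; protein is computed and reported but excluded from means,
since protein adequacy is driven by bulk staples while the motivating
question concerns micronutrients and fatty acids. The classification
nutrient set is nevertheless an argument (`nutrients =`) so protein can be
included if desired.

# Pipeline stages and their assumptions

**End-use filter.** Only commercial catch (artisanal and industrial) is
subject to discard and fishmeal/fish-oil removal; subsistence and
recreational catch is assumed entirely destined for domestic human
consumption, and mariculture entirely for human consumption. Unknown end-use
or sector labels are data errors, not silently dropped rows.

**Re-exports.** Countries acting as processing hubs would otherwise be
credited with consuming seafood that merely transits. Two routes are
combined per country × commodity: re-exports recorded as such in the trade
table, and *processed* re-exports inferred as
`max(0, exports − production)` from the food-balance production of the same
commodity — exports beyond what was produced domestically must have been
imported first. The total is capped at recorded exports, and is subtracted
from both imports and exports with a floor at zero. (An alternative rule —
netting recorded re-exports out of exports before the production gap is
computed — gives a smaller processed estimate; we use the plain
production–export difference, matching the operation's contract, with the
export cap preventing over-subtraction.)

**Freshwater crustaceans.** The analysis is marine-only, but crustacean
trade categories mix in freshwater species; a configurable fraction
(default 0.10) of crustacean-commodity exports is removed before export
subtraction.

**Export subtraction.** Adjusted exports of a commodity are allocated across
that commodity's (taxon, sector) production cells proportionally to
production tonnage, and subtracted. Artisanal production is part of the
exportable pool in the base case — the conservative choice, since treating
artisanal catch as retained can only raise SSF contributions — and the
sensitivity sweep (`sweep_artisanal_trade()`) runs both variants. Cells
driven negative are clamped at zero; surplus exports that could not be
allocated are reported, never discarded, so the mass balance
`retained + allocated = production` (pre-clamp) and
`allocated + surplus = exports` can be asserted to 1e-9 relative tolerance
on every run. Trade tonnages are nominally product weight; a per-commodity
conversion factor to live-weight equivalents is exposed
(`conversion_factors`, default 1 for every commodity) rather than hidden.

**Hierarchical nutrient matching.** Every taxon carries a commodity label,
so the fallback chain species → genus → family → order → class → commodity
is total: the match level is the first with at least one profile record,
and rank means are unweighted arithmetic means over non-missing values
(profile databases rarely report comparable sample sizes, so weighting is
not attempted). Two refinements matter in practice:

* *Per-field fallback.* If every record at the match level is missing one
  nutrient (or the edible fraction), that field alone falls through to the
  next level. This maximises use of the most specific data; the matched
  level is still reported per field (`<field>_level` columns).
* *Exact matching.* Names are compared after case-folding and whitespace
  collapse; no fuzzy matching, for reproducibility.

Import flows are resolved only to commodity category and are valued at the
commodity mean profile over all records carrying that label.

**Coastal population.** SSF catch is assumed consumed by the population
within a buffer of the coastline (or exported); everyone consumes the
national average of everything else. Cells are included by centroid
distance only — the simplest reproducible rule; areal weighting would
change strip populations by less than the grid discretisation error. Planar
mode uses exact point-to-segment Euclidean distance; geographic mode uses
great-circle point-to-segment distance via `geosphere::dist2Line`. The
headline buffer defaults to 50 km — the widest of the conventional 5–50 km
ladder, hence the most conservative (largest denominator, smallest
per-capita SSF supply) — and `sweep_buffer()` sweeps the ladder; there is
no single canonical choice, so the default is explicit and configurable.

**Contributions.** With per-capita daily supply `u_{c,s,n}` per country,
sector and nutrient, the SSF fraction is
`(u_artisanal + u_subsistence) / D` where `D` is the seafood sectors' sum
(scope `seafood`), plus non-seafood animal-sourced groups (beef, veal,
pork, dairy, poultry, sheep; scope `animal_sourced`), plus all non-seafood
groups (scope `all_foods`). The diet composition is that of a coastal
resident: SSF per coastal capita plus national averages for everything
else. Imports count as a seafood source-sector, which makes sector
contributions to the seafood scope sum exactly to one and preserves the
scope nesting `all_foods ≤ animal_sourced ≤ seafood`. For DHA+EPA the
non-seafood terms are forced to zero in every scope — seafood is treated as
its only dietary source — so its three fractions coincide. A zero
denominator yields a missing fraction, never zero.

**Classification.** Country means over the assessed nutrients are compared
against two rule families, both always emitted: percentile rules (strictly
above the interpolated percentile cutoff of the cross-country distribution,
default 0.70) and absolute rules (mean SSF contribution ≥ 0.15, mean
inadequate-intake prevalence ≥ 0.50, boundaries inclusive). Countries
without intake data keep missing vulnerability flags — "reliant,
vulnerability unknown" — and are excluded from the intake percentile
distribution rather than dropped from the output.

# Numerical choices

* **Percentile cutoff.** With sorted values $x_{(1)} \le \dots \le x_{(n)}$
  and $h = (n-1)p + 1$, the cutoff is
  $x_{(\lfloor h\rfloor)} + (h - \lfloor h\rfloor)\,(x_{(\lfloor
  h\rfloor+1)} - x_{(\lfloor h\rfloor)})$ — linear interpolation between
  order statistics, the common default convention. "Within the $p$-th and
  100th percentile" is implemented as *strictly above* the cutoff, which
  makes flag counts a weakly decreasing step function of $p$ and flags
  nobody at $p = 1$. At $p = 0$ the strict rule would exclude the minimum
  country (it equals its own cutoff), so $p = 0$ is special-cased to flag
  every country with data.
* **Means with gaps.** Country means are taken over the available assessed
  nutrients, with the number of missing fractions reported (`n_missing`);
  an all-missing country gets a missing mean.
* **Tolerances.** Mass-balance residuals and ground-truth recovery are
  asserted at 1e-9 relative tolerance; the arithmetic is exact up to
  floating-point rounding, so observed residuals sit near 1e-16 and the
  tolerance only absorbs summation-order effects.
* **Degenerate inputs.** Empty trade tables, countries without catch,
  zero-tonnage cells, commodities with exports but no production (pure
  surplus) and zero coastal populations (explicit error when SSF supply is
  positive, warning otherwise) are all defined behaviour with tests.

# The synthetic world

`generate_world()` draws a self-consistent miniature study system whose
expected outputs are bookkept analytically, so the pipeline can be checked
cell-for-cell. What it emulates, and how:

* **Geometry.** Each country is a planar rectangle whose western edge is
  its coastline; population cells sit at known x-distances, so coastal
  strip populations have closed forms (a uniform-density strip of width
  $d$ in a rectangle of width $W$ holds $d/W$ of the population). Country
  widths are set from the target coastal fraction
  (`coastal_fraction_range`) at the default 50 km buffer.
* **Catch.** Sector shares per country-species are symmetric
  Dirichlet-allocated (normalised unit-rate gamma draws); commercial catch
  is split across end uses with discard and fishmeal shares drawn from
  configurable ranges (defaults 5–20 % and 5–25 %).
* **Trade.** Exports are `export_intensity` (default 0.35) of exportable
  post-filter production plus re-exported imports; imports redistribute
  each commodity's world export pool. Of each re-export flow
  (`reexport_share`, default 0.15, of imports), half is recorded and half
  is only discoverable as a production–export gap — so both estimation
  routes are exercised by construction.
* **Profiles.** Concentrations are log-uniform within biologically
  plausible per-nutrient ranges (documented constants in the source),
  giving the heavy-tailed spread that stresses hierarchical averaging;
  15 % of individual values are missing so the per-field fallback is
  exercised. Species profiles are dropped at the species level and in
  whole genus/family/order blocks (`profile_missingness_by_rank`), pushing
  taxa to deeper fallback levels; one complete commodity-keyed record per
  category guarantees the terminal level. With the default missingness the
  class and commodity levels are not reached by domestic taxa — they are
  exercised by import flows and by crafted fixtures in the test suite.
* **Ground truth, twice.** `world$truth` is computed by vectorised base-R
  bookkeeping at generation time; `ground_truth_contributions()` recomputes
  everything with explicit record-by-record loops and its own brute-force
  matcher. Neither shares aggregation code with the dplyr pipeline, and the
  three routes are required to agree (truth vs oracle at floating-point
  accuracy on 50 seeds; pipeline vs truth within 1e-9 on the 50-world
  validation ensemble).

What it does **not** emulate: the real taxonomic catalogue (thousands of
taxa, synonymy, misspellings — name matching here is exact by
construction); realistic absolute magnitudes of catch or trade; bilateral
trade flows; geodesic coastlines with islands; intra-national heterogeneity
in diets. Passing the validation ensemble therefore demonstrates that the
accounting arithmetic, matching logic and classification rules are
implemented correctly — not that results on real extracts are insensitive
to name-matching quality, commodity concordances or population-raster
resolution, which are properties of the data.

# Validation problem sizes

The standard ensemble is 50 worlds of 20 countries × 100 taxa (seeds 1–50),
with smaller 4–6-country worlds for the loop-oracle cross-check and
property tests; these sizes give full coverage of every code path
(clamping, surplus, partial missingness, missing intake data) while keeping
the whole suite to a few minutes on one CPU. The matcher is additionally
checked against the brute-force scan on 1,000 randomised (taxon, lookup)
pairs with heavy value-missingness.

# Known limitations

* Nutrient retention under cooking/processing and non-muscle tissues are
  out of scope; concentrations refer to raw muscle.
* Bioavailability and within-country (age/sex, urban/rural) disaggregation
  are not modelled; the income pathway (fish sold to buy other food) is not
  modelled.
* Imports are valued at commodity-mean profiles, which flattens
  species-level variation in imported seafood.
* A single nominal year is assumed across catch, trade and population
  inputs.
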
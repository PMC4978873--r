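---
title: "Quantifying charcoal trade-offs in Mopane woodlands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying charcoal trade-offs in Mopane woodlands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mopane)
library(dplyr)
```

## The problem

Charcoal production in southern African Mopane woodlands removes large stems
of a few preferred hardwood species — above all *Colophospermum mopane* —
through selective harvest. The same woodlands supply firewood, construction
poles, wild foods, medicinal plants and thatching grass. `mopane` implements
an ecological production-function pipeline that turns plot inventories into
village-scale service availability estimates and asks, by counterfactual
simulation, how much of each service is traded off against charcoal: how much
was lost to past harvest, and how much would be lost if every suitable stem
were taken.

The pipeline has five stages, each usable on its own:

1. **Inventory** (`plot_metrics()`): per-plot structure from stem, quadrat
   and transect records.
2. **Typology** (`select_k()`, `assign_types()`): a woodland-type legend from
   compositional clustering.
3. **Production functions** (`plot_services()`, `village_totals()`):
   species-linked service availability, upscaled by land cover.
4. **Scenarios** (`apply_no_charcoal()`, `apply_total_charcoal()`,
   `run_scenarios()`): counterfactual harvest states with propagated
   uncertainty.
5. **Reporting** (`survey_percentages()`, `trend_concordance()`): survey
   summaries and concordance of model results with perceived trends.

Because the original field microdata are not deposited anywhere, the package
carries a first-class synthetic-data generator (`gen_dataset()`) that
emulates the study design; every stage is tested end to end against it.

## Inventory model

**DBH correction.** Diameters measured away from the standard 1.3 m point of
measurement are corrected with a linear taper,
$d(1.3) = d(h)\,(1 - \tau\,(1.3 - h))$, with $\tau$ = `r default_taper()`
per metre by default. The published correction function sits in
supplementary material we do not have; the linear form was chosen because it
is the simplest monotone model that is exactly invertible — the property the
scenario engine relies on, since stump reconstruction
(`reconstruct_stump_dbh()`) is the same formula applied to a stump
measurement. The rate is deliberately exposed as configuration and flagged
loudly here: all biomass numbers inherit it.

**Allometry.** Per-stem biomass is a power law $a\,\mathrm{DBH}^b$ (Mg C,
DBH in cm), defaulting to $a = 2.67\times10^{-5}$, $b = 2.58$ following the
Ryan et al. miombo allometry widely used for these woodlands. The
coefficients are configuration data (`default_allometry()`), never asserted
by tests — sites should substitute local values.

**Grass and dead wood.** Dry grass biomass is the quadrat mean of fresh mass
times dry fraction, scaled from g m⁻² to Mg ha⁻¹ (×0.01); recently burnt
plots are flagged and excluded from grass means rather than failing. Coarse
woody debris uses the line-intersect estimator: volume per hectare
$(\pi^2/8L)\sum d_i^2 \times 10^4$ over total transect length $L$ (80 m:
four 20 m transects), converted to carbon with a decay-class wood-density
table (0.58/0.45/0.30 Mg m⁻³) and carbon fraction 0.47
(`default_cwd_constants()`). Pieces below 3 cm diameter or 0.5 m length are
rejected at ingest.

**Diversity.** Richness counts live-stem species; evenness is Pielou's
$J = H/\ln S$ on per-species biomass shares, defined as 1 when $S \le 1$.
The source study reports only "evenness (index)"; Pielou on AGB shares is
our documented assumption, consistent with the biomass-based composition
used everywhere else.

Standing dead but uncut stems are excluded from live density, biomass and
all service availability; they only appear in necromass if fallen onto a
transect. The standard error of any mean over plots is the sample
SD/$\sqrt{n}$, and is *suppressed* (reported `NA`) when $n < 4$ — the small
samples make the estimate meaningless, matching the source study's practice.

## Woodland typology

Plots are described by their relative above-ground-biomass composition
(rows summing to 1). The legend comes from Bray–Curtis dissimilarity with
average-linkage clustering; the number of types is selected by running
k-means for $k = 2\ldots k_{max}$ (25 seeded restarts each) and maximising
the Calinski–Harabasz criterion
$\mathrm{CH}(k) = \frac{B/(k-1)}{W/(n-k)}$, ties broken toward smaller $k$.

One design choice deserves emphasis: **k-means runs on Hellinger-transformed
shares** (square roots of the compositions), not the raw rows. Per-stem
biomass is strongly right-skewed, so raw compositional rows form elongated
clusters in which a single large stem can dominate a plot's profile; on such
data the CH criterion reliably over-splits. The Hellinger transformation is
the standard remedy that makes Euclidean k-means appropriate for
compositional abundance data, and with it the criterion selects the correct
number of generator types with stable labels. `transform = "none"` restores
the raw behaviour for comparison. The Bray–Curtis/average-linkage dendrogram
is always computed on the raw shares and retained in the result for
inspection.

Clusters are named by greedy matching of each woodland type's indicator
species (highest mean share assigned first); plots with no live stems cannot
be clustered and fall back to their land-cover stratum, or `"other"`.

Plot samples are small per village, so production-function parameters are
pooled within chronosequence classes (*post-boom*, *boom*, *pre-boom*) by
`amalgamate()`: mean, SE (suppressed below $n=4$) and count per
(class, type). When a class has land cover of a type but no sampled plots at
all, the pipeline by default substitutes the class-pooled (study-wide)
parameters of that type — the same sample-size rationale taken one step
further; `fallback = FALSE` turns this into a hard, named error instead.

## Production functions and upscaling

Each tree service is a species set, a metric and a DBH band
(`gen_linkage_table()`, `default_dbh_bands()`):

| service      | metric       | DBH band (cm) |
|--------------|--------------|---------------|
| charcoal     | biomass      | ≥ 10          |
| firewood     | biomass      | 5–20          |
| construction | biomass      | 5–15          |
| food         | stem density | ≥ 5           |
| medicine     | stem density | ≥ 5           |

The bands are loud defaults: the species-use interviews named species, not
sizes. Only live, uncut stems provide a service. Grass-related services
cannot be tied to grass species, so maximum potential grass biomass is an
upper envelope of observed grass against stem density: a quantile fit at
$q$ = 0.9 (pinball loss minimised with Nelder–Mead from an OLS start;
`quantreg`-style machinery in one function), linear by default with an
exponential-decay alternative. Predictions are clamped at zero and, outside
the fitted density range, at the boundary value with an extrapolation flag —
the envelope is an interpolator, not a growth model.

Village landscapes are a 5 km circle (78.54 km² = 7 854 ha,
`village_area_ha()`). Landscape availability is area-weighted:
$V = \sum_t A f_t \mu_t$, with SE
$\sqrt{\sum_t (A f_t\,\mathrm{se}_t)^2}$ under independence, and 95% CIs as
$V \pm 1.96\,\mathrm{se}$. Types whose SE was suppressed contribute no error
term; the estimate is flagged `se_complete = FALSE` so undercoverage is
visible rather than silent.

## Scenarios

* **no charcoal** — every cut stem of a charcoal-linked species is restored
  as live, with DBH reconstructed from its stump through the taper model.
  Stumps without a recorded measurement height are skipped and counted.
* **total charcoal** — every live charcoal-species stem inside the charcoal
  band is felled (left as a 0.3 m stump whose diameter round-trips through
  reconstruction). Other species are untouched: selective harvest, not
  clear-felling.

Changes are recomputed through the full parameter pipeline (amalgamation →
upscaling) from the modified stem tables, holding the typology labels and
grass envelope at their current-state fits; percent change is
$100(V_{cf} - V_{cur})/V_{cur}$ with a first-order delta-method CI treating
the two estimates as independent. Independence is a fidelity choice (the two
states share plots, so it overstates variance); a Monte-Carlo estimator
(`method = "mc"`) is available behind a flag and the tests hold the two
within 5% of each other on 10⁵ draws. When the current estimate is zero the
percent change is undefined and only the absolute change is reported.

Structural guarantees, all under test: total-charcoal drives charcoal
availability to exactly −100% wherever it was positive; no tree service can
gain under total-charcoal or lose under no-charcoal; percent changes are
bounded below by −100; and restoring after total harvest equals restoring
alone (exactly, because the taper model is invertible) — which also equals
the current state on never-harvested plots. A subtlety worth recording: the
round trip does *not* return the current state on plots that already contain
historical stumps, because restoration revives those too; the equality holds
against the no-charcoal state.

## What the generator emulates — and what it does not

`gen_dataset()` draws seven villages (A–G) in three chronosequence classes
with 24 plots of 20 m radius each. Per woodland type it takes the observed
study conditions as parameters: stem densities (1764, 769, 639, 582, 103
stems ha⁻¹), biomass (31.7, 11.8, 12.8, 5.4, 7.31 Mg C ha⁻¹), grass (0.06,
0.66, 1.06, 0.79, 0.34 Mg ha⁻¹) and coarse woody debris (3.57, 0.90, 0.98,
0.72, 0.02 Mg C ha⁻¹) for Androstachys forest, Mopane, Combretum and Boscia
woodland and shrub Mopane respectively. Stem counts are Poisson about
density × area; diameters are lognormal, truncated at the 5 cm inventory
floor, with the meanlog *calibrated* (truncated-moment closed form +
`uniroot`) so that expected per-stem biomass × density reproduces the type's
biomass exactly under the default allometry. Species are drawn from per-type
pools dominated by the real indicator names (kept verbatim so typology
naming is testable) plus invented local names. A configurable share of
charcoal-suitable stems is already cut (defaults 0.35 post-boom, 0.15 boom,
0.05 and 0 pre-boom — the qualitative ordering of the chronosequence;
magnitudes are free parameters), with stump diameters generated by the
inverse taper so reconstruction is exact. Land-cover compositions are
invented to mirror the study landscape narrative (village A Boscia- and
shrub-heavy, B–C Mopane-heavy, D–G Combretum-heavy with Androstachys only in
the north). Survey counts are binomial with class-specific use
probabilities; perceived trends derive deterministically from the cut
fractions.

The type parameters describe the *intact* (pre-harvest) state; in villages
with cutting, observed live density and biomass sit below them by
construction. Parameter-recovery tests therefore run at zero cut fraction.

Passing tests on this generator show that the pipeline's arithmetic,
clustering, propagation and counterfactuals are correct under known truth.
They do not show that real Mopane woodlands satisfy the generator's
simplifications: no spatial structure or plot autocorrelation, no
species-specific size distributions or wood densities, no measurement error
in diameters or species identification, independent plots within villages,
and service magnitudes that follow our invented species-to-service overlap
rather than the (unavailable) field use table. Scenario percent changes on
synthetic data are therefore *structurally* comparable to the published
pattern (large post-boom no-charcoal gains, universal −100% charcoal under
total harvest, bounded firewood/construction losses) but not numerically.

## Numerical choices and problem sizes

* k-means: 25 restarts per k, `iter.max` 100, seeded; CH ties toward
  smaller k.
* Envelope fit: Nelder–Mead, `reltol` 1e-10, up to 5 000 evaluations, OLS
  initial values; all-zero grass returns a zero envelope with a warning.
* Calibration: `uniroot` on the truncated lognormal moment, tolerance 1e-10.
* Degenerate inputs: empty plots give zero density/biomass and evenness 1;
  Bray–Curtis on two all-zero vectors, non-positive diameters, and k-means
  on fewer than two distinct compositions are signalled errors, not NaNs.
* Test problem sizes: 200 plots/type for parameter recovery (checked at the
  family-wise 95% level across the 15 type × metric means, Bonferroni
  bound ≈ 2.97 SE per comparison), 30 plots/type for typology recovery,
  150 plots for envelope recovery, 10⁵ draws for Monte-Carlo CI oracles,
  and a full 168-plot study for the end-to-end run — sizes at which each
  check is decisive in a few seconds.

## Known limitations

The taper correction and allometry stand in for unavailable supplementary
functions and should be replaced with site-calibrated versions for real
analyses. DBH bands per service are assumptions. The grass envelope is an
upper bound driven only by stem density, and the source study itself notes
such potentials can be unrealistic for sparse low-grass types (shrub Mopane,
Boscia); treat grass results as indicative. The delta-method CI on percent
change assumes independence of current and counterfactual estimates, which
share plots. No regrowth, coppicing or temporal dynamics are modelled — the
scenarios are comparative statics, not forecasts.
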
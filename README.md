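# mopane

Ecosystem-service trade-offs of charcoal production in southern African
Mopane woodlands, as a tested, reusable R pipeline.

Charcoal in this region is made almost exclusively from a handful of
hardwood species — above all *Colophospermum mopane* — harvested selectively
from village woodlands that also supply firewood, construction poles, wild
food, medicinal plants and thatching grass. `mopane` quantifies those
trade-offs with the **ecological production-function** approach: plot
inventories → woodland typology → species-linked service availability →
village-scale totals with propagated uncertainty → counterfactual harvest
scenarios.

## The model in brief

* **Inventory.** Per-stem biomass is allometric, $AGB = a\,\mathrm{DBH}^b$
  (Mg C); off-height diameters are corrected with an invertible linear taper
  $d(1.3) = d(h)(1 - \tau(1.3-h))$; grass comes from dried quadrat samples;
  dead wood from line-intersect transects,
  $V = \frac{\pi^2}{8L}\sum d_i^2 \times 10^4$ m³ ha⁻¹.
* **Typology.** Plots are clustered on relative-biomass composition:
  Bray–Curtis / average-linkage for the legend, with the number of woodland
  types $k$ selected by maximising the Calinski–Harabasz criterion
  $\frac{B/(k-1)}{W/(n-k)}$ over seeded k-means partitions of the
  Hellinger-transformed shares.
* **Production functions.** Each service is a species set, a metric
  (biomass or stem density) and a DBH band; grass potential is an upper
  quantile envelope of grass biomass against stem density. Parameters are
  pooled within chronosequence classes (*post-boom*, *boom*, *pre-boom*),
  with SEs suppressed when $n < 4$ plots.
* **Upscaling.** Village availability over a 5 km sample circle (7 854 ha)
  is $V = \sum_t A f_t \mu_t$ with
  $\mathrm{se} = \sqrt{\sum_t (A f_t \mathrm{se}_t)^2}$ and 95% CIs.
* **Scenarios.** *no charcoal* restores every cut charcoal-species stump to
  a live stem (DBH reconstructed through the taper model); *total charcoal*
  fells every charcoal-suitable stem. Per-service percent changes carry
  delta-method CIs (Monte-Carlo alternative behind a flag).

Because the original field microdata are not deposited, the package includes
a seeded synthetic-data generator emulating the seven-village chronosequence
study design, used by the test suite to verify every stage against known
truth. The printed study tables (survey counts, plot bookkeeping, perceived
trends) ship as typed fixtures and are recomputed exactly.

## Worked example

```r
library(mopane)
library(dplyr)

report <- run_pipeline(synth_config(seed = 42))
report
#> <mopane_report>
#>   168 plots, typology k = 5, trend concordance 78%

glance(report$analysis$typology)
#>       k ch_max n_plots
#> 1     5   466.     168
```

The typology recovered five woodland types from the 168 synthetic plots.
Current charcoal availability per village (Mg C per landscape, ±95% CI):

```r
filter(report$analysis$estimates, service == "charcoal") |>
  select(village, value, se, ci_lo, ci_hi)
#>   village value   se ci_lo ci_hi
#> 1       A 19305 1111 17128 21482
#> 2       B 30417 1476 27524 33309
#> 3       C 30765 1443 27937 33592
#> 4       D 48745 1938 44946 52544
#> 5       E 48084 2018 44130 52039
#> 6       F 65349 2240 60959 69739
#> 7       G 61646 2212 57311 65981
```

Villages A–C (*post-boom*, long harvest histories) hold the least standing
charcoal stock. The *no charcoal* counterfactual asks how much larger the
stock would be had nothing been cut:

```r
filter(report$scenarios, service == "charcoal", scenario == "no_charcoal") |>
  select(village, pct_change, ci_lo, ci_hi)
#>   village pct_change ci_lo ci_hi
#> 1       A      62.76 40.33  85.2
#> 2       B      60.65 41.12  80.2
#> 3       C      62.00 42.37  81.6
#> 4       D      18.29  5.63  31.0
#> 5       E      18.54  5.17  31.9
#> 6       F       1.82 -7.78  11.4
#> 7       G       1.89 -8.11  11.9
```

Past harvest removed roughly 60% of the charcoal stock in post-boom
villages, ~18% in boom villages and almost nothing pre-boom — the
chronosequence gradient the generator encodes, recovered through the full
inventory → typology → upscaling chain. Under *total charcoal* the charcoal
service itself always changes by exactly −100%.

The printed household-survey table recomputes from its counts:

```r
survey_percentages(mabalane_survey()) |>
  filter(village == "(pooled)") |>
  select(service, users, sampled, pct_display)
#>   service      users sampled pct_display
#> 1 charcoal       183     260          70
#> 2 construction   159     260          61
#> 3 firewood       252     260          97
#> ...
```

`autoplot()` methods draw the standard figures: stacked availability by
woodland type, scenario percent changes with CIs, the grass envelope and the
CH selection curve. `tidy()`/`glance()` methods cover the fitted objects.
A thin CLI (`inst/cli/mopane-cli.R`) wraps `simulate`/`run`/`report` for
shell use.

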
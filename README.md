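# betashift

Spatio-temporal beta-diversity decomposition for community monitoring data.

## The problem

When a natural disturbance sweeps through an ecosystem — a crown-of-thorns
starfish outbreak collapsing live coral cover, a hurricane flattening reef
structure — the resident community (fish, invertebrates, microbes) can respond
in two very different ways that a single "total beta diversity" number
confounds:

* **replacement**: some species lose biomass while others gain it in the same
  amount, so composition turns over but total community biomass is stable
  (compensatory dynamics);
* **abundance difference**: species rise or fall together, so the change is a
  net gain or loss of total biomass (synchronous dynamics).

`betashift` implements the quantitative decomposition that separates the two,
applied through **both space and time** on replicated survey designs
(sites × time steps × transect replicates), and carries the full downstream
analysis chain: where and when composition was unusual, when each site shifted,
and which species drove the shift. The methods transfer directly to any
non-negative observations × species table (e.g. microbiome abundance tables).

## The statistics

For two observations with species quantity vectors, let `A` be the shared
quantity (`Σ_j min(y1j, y2j)`) and `B`, `C` each observation's surplus. The
package computes, for every pair:

```
d_BC  = (B + C) / (2A + B + C)          percentage difference (Bray-Curtis)
repl  = 2·min(B, C) / (2A + B + C)      replacement component
diff  = |B − C| / (2A + B + C)          abundance-difference component
```

with the exact identity `d_BC = repl + diff`. On top of these pairwise
matrices it provides:

* **BD_total / LCBD** — total community variance `SS_total/(N−1)` (bounded by
  0.5) and each observation's Local Contribution to Beta Diversity, from the
  diagonal of the Gower-centred dissimilarity matrix, with permutation tests;
* **stratified summaries** — per-site (temporal response) and per-time-step
  (spatial response) similarity/replacement/difference triplets for triangle
  plots, plus BD-scale component fractions;
* **trajectory models** — linear, quadratic (orthogonal polynomials) and
  4-parameter logistic fits `Y(t) = Y_b + (Y_a − Y_b)/(1 + e^{(T−t)/σ})` with
  AIC selection, for habitat covariates (live coral cover), total biomass and
  richness; BIC-penalised stepwise regression over time × site × season;
* **space-time tests** — two-way crossed multivariate ANOVA by RDA on PCoA
  coordinates of the square-root-embedded dissimilarities, with
  permutation-of-residuals tests per term;
* **shift location and attribution** — multivariate regression trees and
  per-site chronological clustering (pre-shift vs post-shift), indicator
  values (specificity × fidelity) with Holm-corrected permutation tests, and
  signed RDA species scores for joint selection of shift-driving species;
* **a synthetic generator** of disturbance-driven multi-site community time
  series (compensatory / synchronous / null regimes at a 13-site × 14-step ×
  3-replicate, 227-species survey scale) so the whole chain is testable
  without any field data.

## Worked example

```r
library(betashift)

# A full synthetic survey: 13 sites (9 NE + 4 W) x 14 time steps x 3 transects
pp <- preset_paper_scale(seed = 42)
pp$table
#> <community_table> 546 observations x 227 species
#>   sites: 13 | time steps: 14 | replicates per (site, time): 3

tt <- apply_transform(pp$table, "sqrt")
beta_div(tt, n_perm = 199, seed = 1)
#> <beta_div> N = 546 | SS_total = 107.5956 | BD_total = 0.1974
#>   LCBD: 55/546 significant at 0.05 (199 permutations)

# Temporal response per site: replacement dominates under compensatory dynamics
beta_strata(tt) |> dplyr::filter(scope == "spatial") |> head(3)
#>   group n_pairs mean_sim mean_repl mean_diff frac_repl
#> 1 r01       861    0.621     0.343    0.0359     0.905
#> 2 r02       861    0.628     0.346    0.0260     0.930
#> 3 r03       861    0.634     0.331    0.0352     0.904

# Habitat collapse: logistic fits with ~90% decline around the 2007 inflection
site_trajectories(pp$table$meta, "coral_cover") |> head(3)
#>   site  kind     r_squared decline_pct    T
#> 1 r01   logistic     0.982        88.5 2007.
#> 2 r02   logistic     0.964        94.2 2007.

# When did each site shift, and which species drove it?
sh <- site_shift_analysis(pp$table, n_perm = 199, seed = 2)
head(sh$shifts, 3)
#>   site  boundary r_squared p_value n_pre n_post
#> 1 r01      2007.     0.142   0.005    18     24
head(sh$species, 5)[, c("site", "species", "indval", "p_holm", "rda_score", "direction")]
#>   site  species indval p_holm rda_score direction
#> 1 r01   sp002    0.859 0.0227      4.40 increase
#> 2 r01   sp007    0.902 0.0227     -4.36 decrease
#> ...
```

Reading the output: `BD_total = 0.197` is the total compositional variance;
per site, mean pair similarity ~0.62 with `frac_repl ≈ 0.9` says most temporal
change is biomass replacement, not total-biomass fluctuation — the signature
of compensatory dynamics despite a ~90% habitat collapse. The chronological
split per site dates the compositional shift (here at the programmed 2006/2007
boundary, explaining ~14% of within-site variance), and the selected species
are exactly the generator's programmed drivers with their programmed
directions.

`run_pipeline(table, n_perm = 999, seed = 1, out_dir = "results/")` chains all
stages and writes `lcbd.csv`, `group_summaries.csv`, `trajectories.csv`,
`shifts.csv`, `shift_species.csv` and a `summary.json`. Figures:
`autoplot()` on a `beta_div` (LCBD bubble grid), `plot_triangle()`,
`plot_pcoa()`, `plot_shift_species()`.

## A note on SS_total

`SS_total` sums the *raw* percentage-difference values (lower triangle,
divided by N). Because the matrix of square-rooted dissimilarities is
Euclidean, the raw values are the squared embedded distances, which is what a
sum-of-squares decomposition requires; summing squared raw dissimilarities
instead would correspond to a different (non-embeddable) geometry.
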
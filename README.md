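# metacomnet

Delineating metacommunities from time series of habitat networks.

## What problem this solves

A metacommunity is a set of local species communities linked by dispersal.
Conservation planning at bioregional scale needs to know the *spatial
extents* of metacommunities, but delineating them is usually ad hoc. For
species of patchy habitats (the motivating case: odonates in wetland
landscapes), a habitat network gives an operational definition: patches are
nodes, two patches are linked when their edge-to-edge distance `d` is within
a dispersal threshold `theta`, and the connected components of the network —
groups of patches mutually reachable, possibly via stepping stones, with no
links leaving the group — are candidate metacommunities.

Because most such landscapes have lost habitat for a century or more,
today's communities may still reflect *historical* connectivity (an
extinction debt). `metacomnet` therefore builds candidate delineations from
habitat maps of **every available time step** (plus abiotic partitions such
as watersheds) and asks which candidate best separates species
beta-diversity:

- all pairs of current patches with occurrence data within a 15 km pairing
  limit form one shared universe; each pair carries its Jaccard
  dissimilarity `beta = 1 - |S_i ∩ S_j| / |S_i ∪ S_j|`;
- each candidate classes pairs *within* vs *between* metacommunities; the
  beta values are binarized *low*/*high* at the global median;
- agreement between the two binary labels is scored by accuracy, precision
  and Cohen's kappa `kappa = (p_o - p_e) / (1 - p_e)`, plus a Welch t-test
  on the raw within/between beta values;
- the candidate with the highest kappa (among those whose mean within-beta
  is below the between mean) wins.

A second, theory-side check correlates each metacommunity's gamma diversity
(pooled species richness) with its size — total area, patch count, and mean
inter-patch shortest-path distance ("network diameter").

A seeded synthetic generator (clustered, chain-shaped wetland landscapes
that only lose habitat; communities drawn from per-metacommunity species
pools with a plantable extinction-debt signal) makes the entire pipeline
testable without licensed survey data.

## Worked example

Simulate one extinction-debt study at the default conditions (two chains of
24 wetland patches degraded over 1899/1954/2010, communities seeded from the
1899 components) and score the three candidate delineations at a 500 m
dispersal threshold:

```r
library(metacomnet)
ev <- debt_experiment(seed = 1, regime = "historical")
tidy(ev)[, c("name", "n_within", "n_between", "kappa", "t_stat", "p_value", "best")]
#> # A tibble: 3 × 7
#>   name                  n_within n_between kappa t_stat  p_value best
#>   <chr>                    <int>     <int> <dbl>  <dbl>    <dbl> <lgl>
#> 1 network_1899_theta500      441       237 0.446 -16.7  3.98e-51 TRUE
#> 2 network_1954_theta500      330       312 0.368 -11.3  4.57e-27 FALSE
#> 3 network_2010_theta500      203       439 0.196  -6.14 1.64e- 9 FALSE
glance(ev)
#> # A tibble: 1 × 4
#>   n_delineations beta_threshold best_name             best_kappa
#>            <int>          <dbl> <chr>                      <dbl>
#> 1              3          0.739 network_1899_theta500      0.446
```

Read: the pair universe holds 678 patch pairs, binarized at the median
Jaccard dissimilarity 0.739. Grouping current patches by the **1899**
network separates low from high beta-diversity far better than chance
(kappa 0.446) and better than the 1954 or current (2010) grouping; all
three pass the direction check (within-pairs more similar than
between-pairs, strongly negative t). The communities were seeded from the
1899 components, so the evaluation recovers the planted historical signal —
run `regime = "current"` and the 2010 network wins instead.

`autoplot(ev)` plots the metrics per candidate; `plot_beta_pairs()` draws
the within/between box plots; `plot_patch_map()` maps a patch layer with
metacommunity hulls. For file-based work, `write_fixture_dataset()` emits a
miniature dataset (ASCII-grid masks, `occurrences.csv`, watershed GeoJSON,
YAML config) and `run_pipeline()` runs harmonize → label → networks (all
time steps × thresholds) → delineations → evaluation → gamma correlations,
writing CSV/GeoJSON outputs and a reproducibility manifest. A thin wrapper
for shell use is in `inst/scripts/run_pipeline.R`.

The methods vignette (`vignettes/metacommunity-delineation.Rmd`) documents
the model, every tunable parameter, the generator's design and its limits.

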
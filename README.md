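# soilbeta

Community-assembly analysis of soil microbial β-diversity.

Soil bacteria and archaea turn over along environmental gradients, and the
central question of microbial biogeography is *why*: deterministic
environmental selection, or stochastic dispersal and drift? `soilbeta` is
aimed at microbial ecologists with an OTU table (samples × OTUs, rarefied
counts), a rooted phylogeny whose tips are the OTU ids, and per-sample site
metadata (coordinates, soil layer, environmental variables in six groups).
It implements the standard inferential chain, stratified by soil depth
layer and by abundant/rare community class:

* **β-diversity** — Bray–Curtis `Σ|x−y|/Σ(x+y)` (taxonomic) and normalized
  weighted UniFrac `Σ l_b|A_b−B_b| / Σ l_b(A_b+B_b)` (phylogenetic), on
  equal-depth counts; abundant (≥0.1%) / rare (≤0.01%) partitioning.
* **Null models** — βNTI, the standardized effect size of βMNTD against a
  tip-shuffling null (`|βNTI| > 2` ⇒ selection; `> 2` variable, `< −2`
  homogeneous), crossed with RC_Bray, the Raup–Crick rank of observed
  Bray–Curtis in a richness- and depth-preserving random-assembly null
  (`RC > 0.95` dispersal limitation, `< −0.95` homogenizing dispersal),
  yielding the five-way process classification with "undominated" as the
  remainder.
* **Distance–decay** — OLS slopes of similarity on standardized spatial
  (haversine) and composite environmental distance, two-sided Mantel
  significance, and sample-level permutation contrasts of slopes.
* **Variation partitioning** — regression on distance matrices splitting
  β-diversity into unique environmental (a), shared (b), unique spatial (c)
  and residual (d) fractions, with deterministic% = 100·a/(a+c).
* **Drivers** — random-forest importance (%IncMSE) of spatial distance and
  the six single-group environmental distances.
* **Group tests** — PERMANOVA/ANOSIM/MRPP and dispersion homogeneity
  between layers; paired sign-flip contrasts of taxon-group abundances.
* **Niche breadth** — Levins' `B = 1/Σp²` per OTU and community, with
  paired layer t-tests and Tukey letters across classes.
* **Synthetic transect generator** — a 32-site, two-layer, 1500-km
  gradient with lognormal abundances, Brownian niche optima (phylogenetic
  signal), a Gaussian niche filter of tunable strength and an exponential
  dispersal kernel, so every stage can be validated by recovering known
  assembly regimes.

See `vignettes/community-assembly.Rmd` for the models, assumptions and
design choices, and `analysis/01_simulate.R` … `06_niche_breadth.R` for the
full worked analysis sequence (each writes plain TSV tables under
`results/`).

## Worked example

Simulate a strong-selection, well-mixed regime and ask the null models
which processes dominate:

```r
library(soilbeta)
cfg <- simulation_config(n_sites = 10, n_otus = 200, niche_strength = 30,
                         dispersal_km = Inf, layer_effect = FALSE, seed = 42)
dat <- simulate_dataset(cfg)
bn  <- bnti(dat$table, dat$tree, n_rand = 199, seed = 1)
rc  <- raup_crick_bray(dat$table, n_rand = 199, seed = 2)
classify_processes(bn, rc)
#> Ecological process classification over 188 pairs (2 excluded: undefined betaNTI)
#>     variable_selection  homogeneous_selection homogenizing_dispersal
#>                  0.489                  0.005                  0.043
#>   dispersal_limitation            undominated
#>                  0.207                  0.255
```

Selection classes dominate, as they must under a strong niche filter
(`niche_strength = 30`) with unlimited dispersal: pairs at different
gradient positions hold phylogenetically distinct clades, pushing βNTI
past +2. The matching distance–decay fit on the topsoil samples:

```r
md  <- dat$metadata[dat$metadata$layer == "topsoil", ]
attr(md, "group_map") <- attr(dat$metadata, "group_map")
sim <- to_similarity(bray_curtis(dat$table[md$sample_id, ]))
fit_distance_decay(sim, environmental_distance(md), n_perm = 999, seed = 1)
#> distance-decay fit: slope -0.05324, r -0.487, Mantel p 0.001 (45 pairs)
```

Similarity drops by 0.053 per standard deviation of environmental distance
and the Mantel test is maximally significant at 999 permutations. On the
default layered transect (`analysis/05_drivers.R`), the random forest
recovers the generating drivers — contemporary climate ranks first in
topsoil, soil pH in subsoil — and variation partitioning attributes the
unique explained variance overwhelmingly to the environment (deterministic
92.8% topsoil, 99.0% subsoil).

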
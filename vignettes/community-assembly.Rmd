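---
title: "Inferring community assembly processes from soil microbial beta-diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes from soil microbial beta-diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Soil bacterial and archaeal communities turn over along environmental
gradients. Two families of processes drive that turnover: *deterministic*
processes (environmental selection filtering taxa by their niches) and
*stochastic* processes (dispersal limitation, homogenizing dispersal,
ecological drift). `soilbeta` implements the standard inferential toolkit
for separating them on an OTU table, a rooted phylogeny and per-sample site
metadata, stratified by soil depth layer (topsoil vs subsoil) and by
community class (overall, abundant, rare taxa), and ships a synthetic
transect generator with *known* assembly regimes so that every inference
stage can be validated by recovery rather than by eyeballing.

## Beta-diversity

Taxonomic turnover is Bray-Curtis dissimilarity on equal-depth (rarefied)
counts, `BC = sum|x-y| / sum(x+y)`; phylogenetic turnover is weighted
UniFrac: for each branch `b` of length `l_b`, with `A_b`, `B_b` the summed
relative abundances of the tips below it, raw WU is `sum_b l_b |A_b - B_b|`
and the default normalized variant divides by `sum_b l_b (A_b + B_b)` so
both metrics live on [0, 1] and can be compared as similarities
(`1 - dissimilarity`). Rarefaction subsamples without replacement to the
smallest sample total; Bray-Curtis is computed on the rarefied counts rather
than re-normalized proportions, so all samples carry the same sampling
noise.

Abundant and rare taxa default to pooled relative-abundance thresholds:
abundant at >= 0.1%, rare at <= 0.01% of all reads. A stricter
`every_sample` mode requires the condition in each sample individually;
the pooled reading is the default because the per-sample reading makes the
abundant class collapse quickly as sample number grows. Class sub-tables
keep their original rarefied counts (no re-rarefaction), so class results
remain comparable to the overall community.

## Null models and the five-way process classification

betaMNTD between samples A and B is the abundance-weighted mean patristic
distance from each taxon to its nearest relative in the other sample.
betaNTI standardizes it against a null that shuffles tip labels across the
*full* supplied tree (the regional pool), holding the table - abundances
and occupancies - fixed: `(obs - mean(null)) / sd(null)`. Selection leaves
a phylogenetic fingerprint only if niche optima carry phylogenetic signal;
betaNTI > 2 reads as variable selection (more turnover than expected),
betaNTI < -2 as homogeneous selection.

RC_Bray asks the complementary taxonomic question: each null assemblage
preserves the sample's observed richness and read total, drawing taxa from
the regional pool with probability proportional to occupancy frequency,
giving each drawn taxon one read, and allocating the rest multinomially by
regional relative abundance. The observed Bray-Curtis is ranked within the
null distribution and rescaled to [-1, 1]. One null assemblage is built per
sample per randomization and Bray-Curtis taken across all pairs; per-pair
marginal null distributions are identical to drawing nulls pair by pair,
at a fraction of the cost (null values are correlated *across* pairs, which
only matters for joint inference we do not perform).

Pairs combine into five classes: |betaNTI| > 2 splits into variable vs
homogeneous selection by sign; otherwise RC < -0.95 is homogenizing
dispersal, RC > 0.95 dispersal limitation, and the rest undominated.
Boundary values (exactly 2 or 0.95) fall on the stochastic/undominated side
- the extreme classes require strict inequalities. Pairs whose null sd is
zero (e.g. a two-taxon pool, where shuffling changes nothing) get an `NA`
betaNTI, are excluded from the fractions and counted separately; exact
conservation is carried by the integer per-class counts.

Cosmopolitan taxa occur in every sample, so their nearest taxon in any other
sample is themselves at distance zero; when the abundant class is analysed
alone this drives betaMNTD and its null variance towards zero. The
`exclude_conspecifics` flag removes those self-matches from the minimum
(falling back to the self-match only when a sample holds no other taxon).

## Distances, decay and drivers

Spatial distance is haversine on a sphere of radius 6371.0088 km. The
composite environmental distance z-scores each variable across the samples
being analysed, averages the z-scores within each of six variable groups
(historical temperature anomaly; contemporary climate; aboveground
vegetation; soil fertility; soil pH; soil mineral content), and takes the
Euclidean distance over the group composites. The mean-of-z composite was
chosen over a first principal component because it is transparent, has no
sign ambiguity, and is exactly testable; a PCA composite sits behind
`composite = "pca"`. Constant variables are dropped with a warning.

Distance-decay is an OLS fit of pairwise similarity on pairwise distance,
with distances standardized over pairs (mean 0, sd 1) so spatial and
environmental slopes are comparable; significance comes from a two-sided
Mantel test that permutes rows and columns of one matrix jointly - pairs
sharing a sample are not independent, and shuffling pairs independently
gives a visibly narrower (wrong) null. Slope contrasts between two sample
groups use the interaction term of a pooled `similarity ~ distance x group`
model, tested by permuting group labels at the level of whole samples,
never pairs, for the same reason; the classical interaction p-value is
reported alongside for reference.

Variation partitioning is multiple regression on distance matrices over the
vectorized upper triangles: `r2_full = R2(beta ~ env + spatial)`, unique
fractions by difference, shared and residual by subtraction. The returned
`a + b + c + d` sum to 1 exactly (an algebraic identity we deliberately do
not break by flooring); tiny negative unique fractions - a known artefact
of the decomposition - are floored at zero only inside the
deterministic/stochastic percentages `100a/(a+c)` and `100c/(a+c)`, which
use the unique fractions only since apportioning the shared fraction is
arbitrary. Both raw and adjusted-R2 variants are reported. A db-RDA on
principal coordinates would be an alternative operationalization; the
distance-matrix regression was chosen because its four-fraction structure
is exact and directly testable.

Random-forest importance regresses the beta-diversity pairs on the spatial
distance plus the six single-group environmental distances (500 trees,
importance = mean % increase in out-of-bag MSE under predictor
permutation), which tolerates the strong collinearity among gradient-driven
predictors.

Group differences between layers use PERMANOVA, ANOSIM and MRPP on the
dissimilarity matrix directly (no ordination), plus the dispersion
homogeneity test with distance-to-centroid by default (`type = "median"`
available). Per-taxon-group layer contrasts are paired per site and tested
with a two-sided sign-flip permutation - distribution-free and exact in
spirit at 32 sites.

Levins' niche breadth is `B_i = 1 / sum_j p_ij^2` with `p_ij` the fraction
of taxon i's reads in sample j - the effective number of habitats occupied,
between 1 and the number of samples. Community-level breadth aggregates the
per-taxon values; the default is the unweighted mean over the class's taxa
(an abundance-weighted mean is available), and the per-sample variant
averages the breadths of taxa present in each sample, giving the per-site
replication used by the paired layer tests and the Tukey letters across
classes.

## The synthetic transect generator

`simulate_dataset()` emulates the post-processing output of a 16S survey of
a ~1500 km arid-to-mesic grassland transect: 32 sites x 2 depth layers,
500 OTUs, 5000 reads per sample, strongly skewed lognormal regional
abundances (sdlog = 2; the top decile of OTUs carries >70% of reads),
17 environmental variables in the six groups above moving linearly along a
latent gradient `g` with independent noise (sd = 20% of each variable's
range), and realistic orientations (precipitation rises, temperature and pH
fall towards the mesic end). Niche optima evolve on a random phylogeny by
Brownian motion and are rescaled to the gradient, so selection produces the
phylogenetic signal betaNTI needs. Expected abundance of taxon i at sample
s is `lambda_i * exp(-w (h_s - opt_i)^2 / (2 sigma^2)) * exp(-d_si / d_km)`
- lognormal regional abundance, Gaussian niche filter of strength `w` and
width `sigma`, and an exponential dispersal kernel from a per-taxon source
site; reads are multinomial at fixed depth, matching rarefied tables
exactly. With `layer_effect = TRUE` the habitat `h_s` is the
contemporary-climate composite in topsoil and pH in subsoil - the same
composites the analysis side computes - so driver-identification stages
can be validated by recovery.

What the generator does *not* emulate: sequencing error and chimeras,
taxonomy, temporal dynamics, interactions between taxa, and ecological
drift as an explicit birth-death process (stochasticity enters only through
multinomial sampling and the dispersal kernel). Passing recovery tests
therefore shows the inference machinery is sound on data obeying its
assumptions, not that real soil surveys do.

## Calibration results and a known limitation

On neutral well-mixed transects (`w = 0`, `d_km = Inf`; 20 samples x 200
OTUs, 199 randomizations, 10 seeds) betaNTI is well calibrated: |betaNTI| >
2 occurs in roughly 4-7% of pairs, consistent with the nominal two-sided
rate, and per-dataset means hover near zero with unit sd. The permutation
tests (Mantel, PERMANOVA, ANOSIM, MRPP, dispersion, slope contrast) hold
their 5% type-I error within Monte-Carlo error over hundreds of null
replicates.

RC_Bray behaves differently, and deliberately so: in the same neutral
regime it returns -1 for essentially all pairs. Communities drawn
multinomially from one shared regional pool are far *more* similar than the
random-assembly null expects - which is precisely what unlimited
homogenizing dispersal means. A ~5% extreme-value rate would require the
observed data to be generated by the null's own assembly process; a
well-mixed multinomial metacommunity is not such a process, and no
parameter choice within this generator makes it one. We report this as a
property of the index, not a defect of either side: RC_Bray separates
regimes (its value flips towards +1 under dispersal limitation, which is
exactly how the classification uses it) but is not a calibrated test
statistic under this neutral model. The recovery checks confirm the
contrast: a strong-selection regime is dominated by selection classes,
a short-dispersal regime by dispersal limitation, and the neutral regime by
the homogenizing/undominated side.

## Numerical choices and problem sizes

All randomized operations take an explicit seed and are bit-reproducible;
the pipeline derives stage seeds from one master seed and records it in
every output header. Null means and sds accumulate in single precision-safe
sums; degenerate pairs are flagged rather than propagated as NaN. The
nearest-taxon kernel is a small C++ routine (the only compiled code), which
keeps 999-randomization runs on 64-sample, 500-OTU tables in the minutes
range on one core. The validation suite runs its oracle comparisons on 50
random fixtures of up to 10 tips and 6 samples at 1e-10 tolerance, its
calibrations at 199 permutations/randomizations with 300-500 replicates,
and its recovery runs on 10-16-site transects with 200-300 OTUs - sizes
chosen to make the checks sharp while keeping a full run of the suite in
the minutes range.

## Limitations

Only the five-way classification is implemented (no alternative occupancy
nulls such as independent-swap); unweighted UniFrac, Jaccard and
alpha-diversity are out of scope; environmental composites assume group
members point the same way along the gradient (a variable anti-correlated
with its group mates dilutes the composite - use single-group distances or
the PCA composite in that case); and the deterministic/stochastic
percentages inherit every caveat of variation partitioning on distance
matrices, in particular that shared variance is reported but not
apportioned.
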
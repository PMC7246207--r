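---
title: "Pyrodiversity, network structure and resistance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyrodiversity, network structure and resistance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(pyronet)
```

This vignette documents the models behind each stage of the pipeline, the
conventions the package commits to where several defensible choices exist,
and what the synthetic-data generator does and does not emulate.

## Pyrodiversity from fire-history rasters

The landscape input is a stack of aligned burn-severity grids, one per fire,
on 30 m cells (the resolution of standard severity products). Severity
within a fire is categorical; `classify_severity()` turns a continuous
burn-ratio grid into classes by counting breakpoints strictly below each
value, so class boundaries behave as half-open intervals `(t_k, t_{k+1}]`.
Breakpoints are a user input (severity-class systems vary between agencies);
the package default is four classes.

Each cell's *fire-history category* is its full (fire, severity) sequence:
cells burned in the same fires at the same severities share a category,
cells that differ in any fire or any severity do not, and cells never burned
in the record share the reserved category 0 (pre-record fire history is not
modelled). Ids are assigned in lexicographic order of the severity
sequences, which makes them deterministic and invariant to how the grid is
traversed.

Site pyrodiversity is the Gini–Simpson index `1 − Σ p_c²` of category cell
counts within a buffer (default radius 150 m, the scale most predictive of
richness in the fieldwork this design mirrors). Gini–Simpson (rather than
inverse Simpson) is the form consistent with scores reported on a 0.2–0.9
scale for real landscapes: it is bounded in `[0, 1 − 1/k]` for `k`
categories and equals 0 only for a homogeneous buffer. Cell membership uses
the cell-centre-in-circle rule — simple, deterministic, and standard raster
practice; buffers extending past the raster edge simply lose those cells
from the counts. Merging categories can only decrease the index, so
coarsening a severity classification never inflates pyrodiversity.

Raster I/O uses the ESRI ASCII grid format, a plain-text interchange format
readable by every GIS; a stack is a directory of grids plus a
`manifest.csv` (`fire_id,date,path`) that fixes fire order by date. Inputs
must share one grid and CRS — reprojection is out of scope.

## Interaction networks and community metrics

Networks are plants × pollinators matrices of summed visit counts, one per
site × survey date (or pooled per site × year where species-level scores
need one value per site). Species with no interactions in the subset do not
appear: a constructed network has no all-zero rows or columns.

**Redundancy.** Rao's decomposition treats the network as a trait matrix:
a species' "traits" are its partners. With `p` the level's marginal
interaction shares and `d` pairwise dissimilarities between interaction
profiles, redundancy is `R = D − Q` with `D = 1 − Σ p²` (Simpson) and
`Q = p' d p` (Rao quadratic entropy). The identity requires `d ∈ [0, 1]`;
the package uses Bray–Curtis on relative (row-normalised) profiles, which is
bounded and sensitive to composition rather than total activity. Jaccard on
binary profiles is available as an alternative. With a single species
`D = Q = R = 0`. Abundances are interaction marginals rather than
independent specimen counts because the network is the stated data source
for the metric.

**Complementarity.** Total branch length of an average-linkage (UPGMA)
dendrogram on Euclidean distances between raw weighted profiles — the
documented default of the classic bipartite-network implementation of this
metric. Branch-length accounting is stated explicitly because
implementations differ: node height = merge distance, leaves at height 0,
edge length = parent height − child height. Two maximally distinct
single-partner species at unit weight give `2√2`. Levels with one species
return 0 by convention (logged, not an error).

**Generalization.** Mean count of distinct partners (binary links): "number
of partners" is a count, so weights do not enter, and doubling all weights
changes nothing. Mean plant degree × number of plants equals mean pollinator
degree × number of pollinators equals the number of realized links.

## Species roles and flexibility

Role metrics are computed per site × year on round-pooled networks so each
species gets one score per site per year — the form a landscape-wide CV
requires. Centralities use the unweighted one-mode pollinator projection
(pollinators adjacent when they share a plant), matching common practice for
these indices: betweenness normalized by `(n−1)(n−2)/2`, and closeness in
the harmonic form (sum of inverse distances over `n − 1`), which is
well-defined on disconnected projections — an isolated pollinator scores 0,
a member of a complete projection scores 1.

Chao2 rarefied degree uses the bias-corrected incidence estimator
`S_obs + ((m−1)/m)·Q1(Q1−1)/(2(Q2+1))`, with incidence samples the survey
rounds in which the focal species was caught; it never falls below the
observed partner count. Niche overlap is the mean Chao abundance-based
similarity (Sørensen form, `2UV/(U+V)` with the standard unseen-species
correction and `U`, `V` capped at 1) between the focal species' visit
profile and every other pollinator's.

Blüthgen's d′ is the KL divergence of partner use from partner availability
(network marginals), normalized by its attainable bounds. The package uses
the continuous-case bounds — minimum 0 (use proportional to availability)
and maximum `ln(1/q_min)` (all use on the rarest partner) — rather than an
integer-constrained heuristic; both anchors hold exactly (a perfectly
partitioned `[[5,0],[0,5]]` network gives d′ = 1 for both species). The
phrase "reciprocal specialization" in common usage is descriptive; d′ is a
species-level index and is implemented as such.

The six metrics are fused by PCA after centering each metric within year
across species and sites; one PCA is fitted on the pooled centered rows so
both years share an axis (per-year fits are a config alternative). Metrics
are centered but not rescaled, following the source convention; the PC1
orientation is fixed by forcing the species-strength loading non-positive.
On synthetic data PC1 is dominated by the metrics with the largest natural
scale (rarefied degree, strength), and its variance share is accordingly
high; real communities with more metric-to-metric independence will show
lower shares.

*Niche flexibility* is the CV (sample SD over |mean|) of a species' PC1
scores across sites in the pre-drought year; species at fewer than two
sites are excluded, and a zero mean leaves the CV undefined (flagged).
*Partner flexibility* is interaction β-diversity: Bray–Curtis
dissimilarities among the species' relative partner profiles across that
year's site × survey samples, embedded by principal coordinates (negative
eigenvalues corrected in the standard imaginary-axis way, via
`vegan::betadisper`), summarised as mean distance to the centroid. Relative
profiles separate compositional turnover from abundance change, which the
log-ratio response already captures; β is therefore invariant to scaling a
species' counts. Both flexibility covariates are computed in the pre-drought
year, consistent with measuring a propensity before the perturbation.

## Co-extinction cascades

Cascades run on site × year round-pooled networks (per-survey networks are
too sparse — many have a single plant, making every cascade trivial).
Plants are removed in ascending order of their site's pre-drought bloom
totals, ties broken alphabetically, so the procedure is fully deterministic;
a seeded random-order variant of the classic algorithm exists behind the
`order` argument of `simulate_cascade()` for sensitivity work. A pollinator
goes extinct exactly when its last remaining partner is removed. Robustness
is the trapezoidal area under (fraction removed, fraction surviving)
including the (0, 1) anchor: 1:1 specialist networks give exactly 0.5 at any
size, a fully connected `n × n` network gives `1 − 1/(2n)`.

The potential network adds every link observed anywhere in the landscape in
either year, restricted to species recorded at the focal site-year, and is
scored with the same removal order, so potential robustness is never below
observed robustness (adding links can only delay extinctions).

## Mixed models

All models are REML random-intercept fits via `lmerTest`, with
Satterthwaite-approximated denominator df (the convention implied by
fractional df in the style of reporting this package mirrors). Continuous
predictors are mean-centered over the rows entering each model; drought year
is a two-level factor dummy-coded with the severe year as reference;
interaction columns are products of centered parents. When the
between-group variance hits the zero boundary the fit is flagged singular
and the fixed effects coincide with OLS — a property the tests assert. VIFs
(`1/(1−R²)` per predictor) are computed on each model's fixed-effect matrix
and checked against the usual < 2 guideline; note a centered predictor and
its interaction with a balanced dummy factor yield VIF 2.0 exactly, the
boundary of that guideline.

Population resistance is `log(N_extreme / N_severe)` with `N` summed over
rounds; only species present at a site in both years are rows (a zero in
either year is treated as the species failing the inclusion rule, not as a
−∞ log-ratio). The statement "populations maintained" is operationalised as
ratio ≥ 1, i.e. log-ratio ≥ 0; output tables carry the log-ratio so either
threshold can be read off. The floral covariate is the site mean over
plants present both years of the bloom-count log-ratio.

## The synthetic-data generator

The generator emulates the study design the pipeline expects — 18 sites,
four rounds in each of two consecutive drought years, on a 60 × 60 grid of
30 m cells carrying 3 fires with 4 severity classes — with these generative
commitments:

- **Fires** are unions of random circular patches; severity is the class of
  the nearest covering patch centre. Only the resulting categorical mosaic
  matters downstream, so no fire-spread model is attempted.
- **Richness gradient**: site occupancy probability rises linearly with
  pyrodiversity so expected richness gains `richness_slope` (default 6)
  species per trophic level per unit score — a positive
  pyrodiversity→richness relation of realistic magnitude for a
  fire-mosaic landscape.
- **Drought**: the extreme year multiplies bloom rates by
  `drought_bloom_factor` (default 0.5) through a shifted Poisson
  (`1 + Poisson(λ − 1)`), so every present plant keeps at least one bloom:
  communities lose individuals and blooms but not species, and site plant
  pools are drawn once so richness is preserved exactly.
- **Flexibility**: each pollinator draws a partner-switching propensity
  `f ∈ [0, 1]` (default Beta(2, 2)). Visits are allocated to available
  plants with log-linear weights
  `κ(1 − f)·log(pref) + f·log(blooms)` — inflexible species follow fixed
  preferences, flexible species track local bloom abundance, creating the
  specialist/generalist continuum the role metrics measure. At `f = 0` the
  sharp limit is used (all visits to the highest-preference available
  plant), so a fully inflexible species has exactly zero partner turnover
  when its favourite is available everywhere.
- **The planted effect**: the extreme-year visit rate is the severe-year
  rate times `exp(β·PD·(f − f̄) + ε)`, `ε ~ N(0, noise_sd)`, so the expected
  abundance log-ratio is exactly the pyrodiversity × centered-flexibility
  interaction the resistance model estimates (default `β = 1.5`,
  `noise_sd = 0.3` — effect and noise scales that leave the interaction
  detectable but not overwhelming at the design size, with per-dataset
  t-statistics around 3).

One master seed drives every stage through fixed offsets
(`seed·1000 + stage`), so each stage is independently reproducible and a
whole dataset is bit-identical under a repeated seed.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: within-season phenology (round effects are
iid multipliers), pollinator foraging movement and spatial autocorrelation
between nearby sites, taxonomic detection error, the long right tail of
bee abundance distributions (activity is lognormal with moderate spread),
and any feedback of network structure on population dynamics. Tests against
this generator validate the *computations and their couplings*, not the
ecology.

## Problem sizes and numerics

The test suite exercises the metric identities and oracles on hundreds to a
thousand random networks of up to 8 species per level (where brute-force
enumeration of shortest paths and exhaustive UPGMA are feasible), and runs
the parameter-recovery and type-I-error checks at the full design size with
200 replicate datasets each — sizes chosen so the whole suite completes in
minutes while keeping Monte-Carlo margins comfortable. The acceptance
script runs the complete pipeline once at design size plus a 50-replicate
sign-recovery summary.

Numerical conventions worth knowing: Bray–Curtis on identical profiles is
exactly 0 so redundancy identities hold to machine precision; β-diversity
short-circuits to 0 when all dissimilarities are 0 (avoiding a degenerate
PCoA); the Chao–Sørensen `U`, `V` are capped at 1 before combining;
removal-order ties are alphabetical; and all result tables are written
without timestamps so repeated runs are byte-identical.

## Known limitations

- Raster input is ESRI ASCII only; no reprojection or resampling.
- d′ uses continuous-case normalization bounds; values are comparable
  within this package but can differ slightly from integer-constrained
  implementations on small networks.
- Role metrics are computed per site-year (pooled rounds); a per-survey
  alternative would need a different landscape-variability summary.
- The potential network spans both years and all sites; a time-windowed
  union is not implemented.
- `fit_lmm` supports a single random intercept — the only structure the
  analyses here require.
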
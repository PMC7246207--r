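# pyronet

Pyrodiversity — the diversity of fire histories in a landscape — shapes which
plants and pollinators co-occur, and therefore the structure of their
interaction networks and their capacity to resist perturbations such as
extreme drought. `pyronet` is an R package for ecologists who want to run
that full chain of analysis: from burn-severity rasters to site-level
pyrodiversity scores, from visitation surveys to weighted bipartite networks
and their structural metrics, through simulated co-extinction cascades, to
mixed models that ask whether pyrodiversity and species-level interaction
flexibility predict community- and population-level resistance.

## What it computes

**Pyrodiversity.** Every raster cell is assigned a *fire-history category*:
the exact sequence of fires it experienced and the severity class of each
(cells burned in the same fires but at different severities get different
categories; never-burned cells share a reserved category). A site's
pyrodiversity is the Gini–Simpson diversity of categories among cells whose
centres fall within a 150 m buffer:

    PD = 1 − Σ_c p_c² ,  p_c = (cells of category c in buffer) / (cells in buffer)

**Community structure.** For each survey network (plants × pollinators,
weighted by visit counts), per trophic level:

- *Functional redundancy* (Rao): `R = D − Q`, where `D = 1 − Σ p_i²` is
  Simpson diversity of the level's species (abundances = interaction
  marginals) and `Q = Σ_ij d_ij p_i p_j` is Rao quadratic entropy with
  `d_ij` the Bray–Curtis dissimilarity between relative interaction
  profiles. `R = 0` means fully complementary; `R → D` means full overlap.
- *Functional complementarity*: total branch length of a UPGMA dendrogram on
  Euclidean distances between interaction profiles.
- *Generalization*: mean number of distinct partners per species.

**Species roles and flexibility.** Six per-pollinator metrics on site-year
networks (betweenness and harmonic closeness on the one-mode projection,
Chao2 rarefied degree, mean Chao abundance-based niche overlap, Blüthgen
d′, species strength), fused by PCA into a network-niche score (PC1); niche
flexibility is the CV of PC1 across sites, partner flexibility is interaction
β-diversity (multivariate dispersion of partner profiles, mean distance to
centroid under Bray–Curtis).

**Co-extinction robustness.** Plants are removed from lowest to highest
pre-drought bloom abundance; pollinators go extinct when their last partner
disappears. Robustness is the trapezoidal area under the survival curve, for
the observed network and for a "potential" network linking every pair ever
observed interacting anywhere in the landscape (a re-wiring proxy); the
potential network's robustness is never below the observed one's.

**Resistance models.** REML linear mixed models (Satterthwaite df): network
metrics ~ centered pyrodiversity × drought year (site random intercept);
robustness likewise; and population resistance — the log-ratio of a
species' abundance between the extreme- and severe-drought years — against
pyrodiversity × partner flexibility, pyrodiversity × niche flexibility, mean
niche, and the site's floral log-ratio, with a species random intercept.

A synthetic-data generator (`sim_params()`, `gen_dataset()`) reproduces the
sampling design the pipeline expects — 18 sites × 4 rounds × 2 drought
years on a fire-mosaic landscape — with known generative effects, so every
stage is testable without field data.

## Worked example

```r
library(pyronet)
params  <- sim_params(seed = 7)          # 18 sites, 2 years, 3 fires
results <- run_full_analysis(params)

summary_tab <- merge(results$pyrodiv,
  aggregate(robustness ~ site + kind, results$robustness, mean))
head(subset(summary_tab, kind == "observed"), 4)
#>      site pyrodiversity     kind robustness
#> 1 site_01         0.396 observed      0.767
#> 4 site_02         0.622 observed      0.871
#> 6 site_03         0.432 observed      0.805
#> 8 site_04         0.000 observed      0.835

results$resistance_model
#> Linear mixed model (REML, Satterthwaite df); random intercept: pollinator
#>                             term  estimate       se       t     df         p
#> 1                    (Intercept)  0.007980 0.029864  0.2672  23.84 0.7915954
#> ...
#> 7 pyrodiversity_c:partner_beta_c  4.201880 1.607477  2.6140 261.84 0.0094682
#> 8       pyrodiversity_c:cv_pc1_c  0.014656 0.017223  0.8510 266.82 0.3955404
```

Here `site_04` sits in a homogeneous (single fire-history) buffer, so its
pyrodiversity is exactly 0. The positive, significant
`pyrodiversity_c:partner_beta_c` estimate says that in this simulated
landscape, pollinators with above-average partner flexibility kept or grew
their populations between the severe and extreme drought years where
pyrodiversity was high — the generative effect the simulator plants
(`beta_interaction = 1.5` on the true-flexibility scale) recovered through
the full estimated pipeline.

There is also a command-line driver (`inst/cli/pyronet`) with subcommands
`simulate | pyrodiv | netmetrics | roles | cascade | resistance | all`, each
a thin wrapper over the functions above; `all --config cfg.toml --out dir/`
runs the entire pipeline reproducibly from one config file.

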
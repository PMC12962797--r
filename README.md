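# patchdiv

Detecting metacommunity assembly processes — species sorting, mass effects,
patch dynamics, neutral drift — from replicated paired forest districts.

The package is written for the analysis of paired heterogenization
experiments: each *site* holds one treatment district in which structural
between-patch heterogeneity was enhanced (canopy gaps, deadwood; "ESBC")
and one homogeneous control district, each district containing 9 or 15
sampled 50 m × 50 m patches. Arthropod samples from such designs are
heavily incomplete, so every comparison runs on the coverage-standardized
scale. Users are community ecologists who want the full chain — Hill
numbers, coverage standardization, γ = α × β partitioning, null models,
mixed models — as tested, composable functions rather than a one-off
script.

## What it computes

**Diversity partitioning.** Hill numbers
\(^qD = (\sum_i p_i^q)^{1/(1-q)}\) (richness at q = 0, Shannon at q = 1,
Simpson at q = 2) for taxonomic (TD) and functional (FD,
τ-threshold attribute diversity on Gower trait distances) facets, with
coverage-based rarefaction/extrapolation and Chao-style bootstrap
uncertainty. For N patches, γ is the pooled-assemblage diversity, α is
1/N × the diversity of the joint (species × patch) distribution, and
β = γ/α ∈ [1, N] is reported as the Jaccard-type turnover
1−S = (1 − 1/β)/(1 − 1/N) ∈ [0, 1].

**Paired meta-analysis.** Site-level ESBC − control differences for every
facet × scale × q case (18 in all), with bootstrap-replicate SE
propagation, combined across sites by fixed-effect inverse-variance
weighting with 95% normal CIs.

**β-deviation.** Observed pairwise 1−S minus its expectation under the
individual-shuffle null (all of a site's individuals randomly reallocated
among patches, patch totals and site species abundances fixed), attributed
to structural, abiotic and spatial patch-pair distances with a linear
mixed model (treatment-specific slopes, site random intercept, Wald
z-values, marginal/conditional R²).

**Trait-shuffle SES.** Standardized effect sizes of functional turnover
against species-label permutations of the trait matrix, compared between
treatments with a site-random-intercept mixed model.

**Synthetic metacommunities.** A generator producing the full paired
design under tunable mixtures of the four assembly archetypes — used by
the test suite to verify that the pipeline recovers known effects, and
usable for power analysis of similar designs.

## Worked example

The numbered scripts under `analysis/` run a desk-scale rendition of the
design end to end (11 sites × 2 districts × 9 patches, 600-species pool,
~300 sampled individuals per patch):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_diversity_meta.R
Rscript analysis/03_beta_deviation.R
Rscript analysis/04_ses.R
```

Step 1 reports the raw material:

```
Simulated 22 districts / 198 patches: 59542 individuals of 592 detected species
Singletons per district: 96-142 (coverage correction has real work to do)
```

Step 2 prints the 18-case meta-analysis (excerpt):

```
Shared coverage target: 0.7687
   facet scale q estimate       lcl      ucl significant
2     TD gamma 1 16.82889  6.21e+00 27.44345        TRUE
4     TD alpha 0 12.62755  7.93e+00 17.32726        TRUE
7     TD  beta 0  0.01447  8.07e-03  0.02088        TRUE
```

Read: at q = 1 the heterogenized districts hold ~17 effective species more
at the landscape (γ) level; the α increase (~13 effective species at
q = 0) indicates locally enriched patches (mass-effect-like), and the
positive β rows (on the 1−S turnover scale) indicate additional
between-patch differentiation (sorting-like). The generator's default
archetype mixture contains both processes, so this is the expected
signature.

Step 3 prints the β-deviation z-table (excerpt):

```
               term   TD.q0  TD.q1  TD.q2   FD.q0  FD.q1  FD.q2
2    ESBC:Structure -0.0285  2.900  7.247  6.1076 15.671 15.363
5   Control:Spatial  0.1514 -0.327  0.184 -0.6436 -0.227 -0.090
7    R2_conditional  0.0547  0.156  0.340  0.1170  0.339  0.318
```

The dominant ESBC:Structure z-values say that where heterogeneity was
created, patches that differ more in structure also differ more in
composition than random reallocation predicts — the species-sorting
fingerprint. (Spatial effects are weak here because the default mixture
is not dispersal-limited; the test suite exercises a dispersal-limited
pure patch-dynamics regime in which Control:Spatial dominates instead.)

Step 4 compares trait-shuffle SES between treatments:

```
ESBC - control contrast: 0.762 (z = 2.25, significant)
```

Outputs land in `results/` as tidy CSVs (`meta_cases.csv`, `z_table.csv`,
`beta_deviation.csv`, `ses.csv`) with YAML provenance sidecars.

## Layout

- `R/` — the implementation (generator, Hill/coverage core, partitioning,
  bootstrap, meta-analysis, null models, distances, mixed models, I/O).
- `analysis/` — the numbered workflow above.
- `vignettes/methods.Rmd` — estimator choices, parameter meanings and
  defaults, generator assumptions, limitations.
- `tests/testthat/` — unit, property and acceptance suites, including
  exhaustive-enumeration oracles for the coverage and rarefaction
  estimators and recovery suites on the archetype generator.
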
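---
title: "Methods: diversity partitioning, beta-deviation and archetype simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity partitioning, beta-deviation and archetype simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`patchdiv` implements a statistical framework for detecting metacommunity
assembly processes from a replicated paired-district field design: sites
each contain one structurally heterogenized ("ESBC": enhanced structural
beta complexity, canopy gaps plus deadwood) district and one homogeneous
control district, each district holding 9 or 15 sampled 50 m × 50 m
patches. Arthropod samples from such designs are strongly incomplete, so
every diversity quantity in the package is defined on the
coverage-standardized scale. This vignette records the models, the
estimator choices, the tunable parameters, and the limitations — in
particular which aspects of real data the bundled synthetic generator does
and does not emulate.

## Hill numbers and coverage standardization

Diversity of order $q$ is the Hill number
$^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}$, with the analytic limit
$\exp(-\sum_i p_i \ln p_i)$ at $q = 1$ (computed exactly, never by a
numeric $q \to 1$ approach). $q = 0$ counts species regardless of
abundance, $q = 1$ weights by frequency (Shannon), $q = 2$ emphasizes
dominants (Simpson).

Comparing assemblages at equal sample *size* conflates diversity with
detectability, so estimates are standardized to equal sample *coverage*
(the estimated fraction of community abundance belonging to detected
species). The implementation:

* Coverage at the reference sample: $\hat C = 1 - (f_1/n)\,
  \frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}$ with $f_1, f_2$ the singleton and
  doubleton counts ($\hat C = 1$ when $f_1 = 0$).
* Coverage rarefaction for $m < n$:
  $\hat C(m) = 1 - \sum_i \frac{x_i}{n}
  \binom{n-x_i}{m}/\binom{n-1}{m}$. This estimator is *exactly* unbiased
  for the true expected coverage of an $m$-sample — the test suite verifies
  this by exhaustive enumeration over all multinomial parent samples at
  small $n$. Extrapolation beyond $n$ uses the geometric form
  $1 - (f_1/n) A^{m-n+1}$ with the same $A$, making the profile continuous
  at $m = n$.
* Hill-number rarefaction uses exact hypergeometric expectations (again
  enumeration-verified); extrapolation uses the Chao1-governed richness
  form at $q = 0$, a sample-size-weighted mix of the observed and the
  asymptotic (Chao–Wang–Jost) entropy at $q = 1$, and the single
  all-$m$ closed form at $q = 2$. Extrapolation is capped at $m = 2n$, the
  conventional reliability bound; a target beyond the cap is answered with
  the cap estimate plus an explicit flag, never silently.
* Fractional sizes are linearly interpolated between adjacent integers so
  that the coverage profile can be inverted by monotone bisection.

The shared target for a comparison set is `0.95 × C_max`, where `C_max` is
the minimum over the compared assemblages of the expected coverage at each
one's extrapolation cap. The published phrase behind this rule ("0.95 of
the maximum of the observed distribution") admits more than one reading;
this operationalization is the standard convention that keeps one target
reachable for every assemblage, and both the multiplier and the cap are
arguments, not constants. Standardizing to a common coverage also controls
for sites having 9 versus 15 patches.

## Functional diversity

Functional diversity uses the attribute-diversity (threshold) form: with a
Gower distance matrix $d_{ij}$ scaled to $[0,1]$ and a threshold $\tau$,
species $i$'s attribute abundance is
$a_i = \sum_j (1 - \min(d_{ij}, \tau)/\tau)\, p_j$ and
$^qFD = \left(\sum_i p_i a_i^{q-1}\right)^{1/(1-q)}$. When all
between-species distances reach $\tau$ this is the taxonomic Hill number;
when all distances are zero it is 1. $\tau$ defaults to the mean
off-diagonal Gower distance (the "dmean" convention) because no single
published threshold exists for this trait set; it is configurable. Gower
distances come from `cluster::daisy()` (range-normalized numeric traits,
0/1 categorical mismatch, averaged over non-missing traits).

Coverage standardization of FD is the one place the package uses Monte
Carlo: FD at the coverage-matched size $m^\*$ is the mean attribute
diversity of seeded hypergeometric subsamples (default 25 draws; an
argument everywhere). For extrapolated $m^\* > n$ the observed proportions
are used as-is, because undetected species carry no trait information —
FD extrapolation beyond the reference sample is therefore conservative.

## Partitioning and the 1−S turnover

For $N$ patches, $\gamma$ is the (standardized) Hill number of the pooled
assemblage and $\alpha$ is $1/N$ times the Hill number of the joint
distribution that treats every (species, patch) cell as a category — the
only $\alpha$ definition that keeps $\beta = \gamma/\alpha$ inside
$[1, N]$ for all $q$. Both are standardized to the same coverage. The
reported dissimilarity is the Jaccard-type turnover
$1 - S = (1 - 1/\beta)/(1 - 1/N)$, which is 0 for identical patch
compositions and 1 for fully disjunct ones. For the functional facet the
joint cells carry within-patch attribute abundances
$a_{ik} = \sum_j w_{ij} p_{jk}$, which reproduces the same $[1, N]$
bounds. $\gamma = \alpha \beta$ holds to numerical precision by
construction and is asserted to $10^{-10}$ in the tests.

Numerical edge policy: $\beta$ is clamped into $[1, N]$ only within a
small tolerance before the 1−S transform (Monte-Carlo FD rarefaction can
overshoot the boundary by a hair); the raw ratio is always retained, and
`one_minus_S()` itself rejects violations beyond $10^{-9}$.

## Bootstrap and meta-analysis

Uncertainty comes from the Chao-style bootstrap (default $B = 200$): the
species list is augmented by the Chao1 estimate of undetected species
($f_0 = \frac{n-1}{n} f_1^2 / 2f_2$, with the bias-corrected
$\frac{n-1}{n} f_1(f_1-1)/2$ fallback at $f_2 = 0$), detected
probabilities are shrunk by the coverage deficit, the deficit is split
equally among the unseen species, and $n$ individuals are resampled
multinomially. For assemblage sets the joint (species × patch) cells are
resampled the same way, each unseen cell entering as a new pseudo-species
in a patch drawn proportionally to patch totals; trait-based statistics
bootstrap without augmentation (unseen species have no traits).

Site-level treatment effects are $\Delta_s = \hat D_{ESBC} - \hat
D_{control}$ (positive = higher in ESBC). Because both districts of a site
are bootstrapped with replicate streams, $SE_{\Delta}$ is the SD of the
replicate differences, falling back to $\sqrt{SE_E^2 + SE_C^2}$ when
streams are unavailable. Sites are combined by fixed-effect
inverse-variance weighting ($w_s \propto 1/SE_s^2$, 95% normal CI); the
source method propagates district-wise bootstrap CIs without a
heterogeneity model, which is what fixed-effect weighting expresses. A
DerSimonian–Laird random-effects variant sits behind `method = "RE"`. With
both facets, three scales and $q \in \{0, 1, 2\}$ this yields the 18-case
summary; a CI excluding 0 flags a case as significant.

## Null models

*Individual shuffle (beta-deviation).* All individuals of a site are
reassigned uniformly at random to the site's patches with patch totals
fixed, which preserves site-level species abundances (hence site gamma)
exactly; the conservation laws are asserted exactly in the tests. The
shuffle spans both districts of a site by default (a within-district mode
is a sensitivity flag). Beta-deviation is the observed pairwise 1−S minus
the null mean over $R$ shuffles (default $R = 100$; the published
procedure is ambiguous between one randomized data set and an average, so
the averaged form is the default and `R = 1` is supported and flagged).
Null dissimilarities are computed at the same coverage treatment as the
observed ones, so deviation does not conflate assembly with sampling
depth.

*Trait shuffle (SES).* Species labels are permuted across the trait
matrix (equivalently, rows and columns of the distance matrix), the
abundance matrix untouched. The SES of a district's mean pairwise
functional 1−S is $(obs - \bar{null})/sd(null)$ over $R = 100$
permutations; $|SES| > 1.96$ is flagged. A zero null SD leaves the SES
`NA` with an explicit flag. Treatment levels are compared by a Gaussian
mixed model of district SES on treatment with a site random intercept
(the distributional family is not stated in the source; Gaussian is the
default).

## Distances and mixed models

Patch-pair predictors: *structural* = Euclidean distance on z-standardized
(canopy density, deadwood volume); *abiotic* = Euclidean distance across
z-standardized Ellenberg-style indicator means (light excluded upstream);
*spatial* = Euclidean meters. Standardization is across all patches pooled
(per-site scaling is a flag); the structural predictor is a single
composite rather than separate canopy/deadwood terms because the target
summary table reports one "Structure" row per treatment — the raw canopy
and deadwood differences are emitted alongside for anyone wanting the
alternative.

The attribution model is
`deviation ~ treatment + treatment:(structural + abiotic + spatial) + (1 | site)`
fitted by REML (`lme4`): treatment-specific slopes with no pooled distance
main effects, and a site random intercept as the only remedy for the
pseudo-replication of pairwise observations (a patch-level crossed random
effect would be defensible but is deliberately off to match the reference
analysis). Predictors are z-standardized before fitting so the Wald
$z = \hat\beta/SE$ values are comparable across predictors and cases;
variance-partitioning $R^2$ (marginal and conditional) is computed from
the fixed-effect predictor variance, the site variance and the residual
variance. The full interaction re-coding
(`(structural + abiotic + spatial) * treatment`) is fitted alongside —
identical fitted values, but its interaction $z$ directly tests slope
differences. Boundary (singular) fits with zero site variance are valid
fits and are recorded as such; genuine optimizer failures are flagged and
warned, never silent.

## The synthetic generator

The generator exists to exercise the full pipeline under known assembly
regimes; it emulates the study design (11 sites × 2 districts × 9 or 15
patches on a jittered 100 m grid inside ~20 ha; ESBC districts with a
constructed spread of canopy gaps and elevated variable deadwood so the
between-patch variance contrast holds for every site by construction;
five district-level indicator means with patch noise partly tied to canopy
opening) and a regional pool with a lognormal abundance distribution,
niche optima on the canopy and deadwood axes, lognormal dispersal scales,
and a mixed-type trait vector correlated with niche and dispersal at a
configurable `trait_cor` (default 0.7 — traits chosen in such studies are
deliberately response-relevant, hence substantially but not perfectly
coupled).

Latent intensity is an additive mixture on intensities (not on realized
counts, keeping expectations analytically checkable) of four components:

* *species sorting* — Gaussian niche match of species optima to patch
  canopy/deadwood, `niche_breadth` default 0.25 on the unit canopy axis:
  selective enough that a 0.5-deep canopy gap reshuffles composition,
  loose enough that patches share dominants;
* *mass effect* — the sorting intensity at source patches, weighted by
  their resource level (deadwood + canopy opening) and diffused over an
  exponential kernel `exp(-d/dispersal)`;
* *patch dynamics* — occupancy from a seeded colonization–extinction
  spread: each species starts at one founder patch and colonizes with
  distance-decaying pressure for a few steps (extinct-everywhere species
  are re-seeded, expressing regional persistence through recolonization).
  A short seeded spread, rather than a long equilibrium run, is what
  leaves occupancy clustered around founders on a 9-patch grid — an
  equilibrium chain at this graph size mixes the clusters away. The
  archetype additionally requires dispersal limitation: with the default
  150 m kernel (comparable to the 100 m patch spacing) colonization
  saturates the district, so pure-patch-dynamics scenarios in the tests
  use a 40 m kernel;
* *neutral* — the regional abundance distribution, identical across
  patches.

Counts are Poisson draws from the mixed intensity
(`patch_lambda` ≈ 1800 expected latent individuals per patch at the
default, ~450 after the default 25% binomial detection — matching the
order of magnitude of per-patch trap catches such designs report), then
binomially thinned; separating assembly from detection is exactly the
premise of the coverage correction. Everything is deterministic given the
config seed.

What the generator does *not* emulate: temporal turnover and trap
phenology, trap-type differences, within-patch microhabitat structure,
species interactions beyond what the intensity mixture encodes,
non-exponential dispersal, and real trait sets (the trait schema is a
stand-in exercising mixed-type distances, not a reconstruction of any
published trait list). Green tests therefore certify the statistical
machinery under known assembly regimes — they do not certify conclusions
about any particular empirical data set.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run a
desk-scale rendition of the design: 11 sites × 9 patches, a 600-species
pool, ~300 sampled individuals per patch, 150 bootstrap replicates, 50
null replicates, 8 Monte-Carlo draws for FD rarefaction. These sizes keep
a full end-to-end run in minutes on one core while leaving all estimators
in their realistic regime (hundreds of singletons per district). The test
suite uses smaller fixtures chosen per property; the heavy recovery
suites state their sizes inline (e.g. 50 seeded landscapes — 4 sites for
the sorting signature, 7 for the dispersal-limited patch-dynamics
signature, whose per-landscape signal is noisier — and 100 synthetic
meta-analyses of 6 sites for the known-effect recovery).

## Known limitations

* FD rarefaction is Monte Carlo (seeded, hence reproducible), and FD
  extrapolation reuses observed proportions; both are documented
  conservative choices, not asymptotically exact estimators.
* The bootstrap treats unseen joint cells as new pseudo-species; rare
  shared species can therefore be split across patches in replicates,
  slightly inflating replicate beta variance (conservative CIs).
* Fixed-effect meta-analysis assumes the site differences estimate one
  common effect; use `method = "RE"` when between-site heterogeneity is
  of interest.
* Pairwise dissimilarities enter the mixed models as observations with
  only a site random intercept; z-values inherit the usual optimism of
  distance-matrix regressions and should be read as standardized effect
  sizes, not exact frequentist tests.
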
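#!/usr/bin/env Rscript
# Step 3 — beta-deviation against the individual-shuffle null, attributed
# to structural, abiotic and spatial patch-pair distances.
#
# For each site, all individuals are reshuffled among the site's patches
# (patch totals and site-level species abundances fixed) 50 times; the
# pairwise 1-S turnover of the observed data minus the null mean is the
# beta-deviation. A linear mixed model with treatment-specific slopes and a
# site random intercept attributes it to the three distances; z-values are
# the effect-size currency, as in the z-table written to results/.

library(patchdiv)

communities <- read_community("results/data/community.csv")
traits <- read_traits("results/data/traits.csv")
patches <- read_environment("results/data/environment.csv")

cfg <- run_config(R = 50, seed = 2)
bd <- beta_deviation_pipeline(communities, patches, traits, cfg = cfg,
                              out_dir = "results")

cat("Treatment-specific z-values (rows) by facet and order (columns):\n")
print(bd$z_table, digits = 3)
cat("\n|z| > 1.96 marks a distance predictor that explains beta-deviation;\n")
cat("a dominant ESBC:Structure z indicates species sorting along the\n")
cat("manipulated heterogeneity, a dominant Control:Spatial z indicates\n")
cat("patch-dynamics-like spatial structuring in the homogeneous forests.\n")
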
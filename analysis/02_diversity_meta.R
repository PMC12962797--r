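#!/usr/bin/env Rscript
# Step 2 — coverage-standardized diversity partitioning and meta-analysis.
#
# For every district: gamma (pooled), alpha (joint species-by-patch cells
# over N) and beta = gamma/alpha reported as 1-S turnover, standardized to a
# shared coverage target (0.95 of the lowest attainable maximum coverage)
# for TD and FD at q = 0, 1, 2, with 150 Chao-bootstrap replicates. Site
# ESBC-minus-control differences are combined by fixed-effect
# inverse-variance meta-analysis into the 18-case table.

library(patchdiv)

communities <- read_community("results/data/community.csv")
traits <- read_traits("results/data/traits.csv")

cfg <- run_config(B = 150, fd_draws = 8, seed = 1)
res <- diversity_meta_pipeline(communities, traits, cfg = cfg,
                               out_dir = "results")

cat(sprintf("Shared coverage target: %.4f\n", attr(res, "coverage_target")))
cat(sprintf("%d meta-analytic cases; %d with CIs excluding 0:\n",
            nrow(res), sum(res$significant)))
print(res[, c("facet", "scale", "q", "estimate", "lcl", "ucl", "significant")],
      digits = 3)
cat("\nPositive gamma/alpha estimates mean higher diversity in the ESBC\n")
cat("districts; beta rows are on the 1-S turnover scale (0 = identical\n")
cat("patches, 1 = disjunct). Full table in results/meta_cases.csv\n")
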
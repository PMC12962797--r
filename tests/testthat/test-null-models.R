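test_that("individual shuffle obeys its conservation laws exactly", {
  A1 <- tiny_assemblage(S = 15, N = 5, seed = 1)
  A2 <- tiny_assemblage(S = 15, N = 4, seed = 2)
  site_z <- cbind(A1$z, A2$z)
  zs <- shuffle_individuals(site_z, seed = 9)
  expect_equal(rowSums(zs), rowSums(site_z))   # per-species site totals
  expect_equal(colSums(zs), colSums(site_z))   # per-patch totals
  expect_equal(sum(zs > 0) >= 0, TRUE)
  # site gamma (observed richness of the pooled site) preserved exactly
  expect_equal(sum(rowSums(zs) > 0), sum(rowSums(site_z) > 0))
  # single patch: identity
  one <- site_z[, 1, drop = FALSE]
  expect_identical(shuffle_individuals(one, seed = 1), one)
  # deterministic given seed
  expect_identical(shuffle_individuals(site_z, seed = 9), zs)
})

test_that("shuffle matches the multivariate-hypergeometric expectation", {
  # brute force on a tiny site: expected per-patch species presence
  z <- matrix(c(3L, 1L, 0L, 2L, 1L, 1L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("p1", "p2")))
  n <- sum(z); nk <- colSums(z); xs <- rowSums(z)
  # P(species i present in patch k) = 1 - choose(n - x_i, n_k)/choose(n, n_k)
  exp_rich <- vapply(nk, function(m) sum(1 - choose(n - xs, m) / choose(n, m)), numeric(1))
  set.seed(4)
  emp <- rowMeans(vapply(1:4000, function(r) {
    colSums(shuffle_individuals(z) > 0)
  }, numeric(2)))
  expect_lt(max(abs(emp - exp_rich)), 0.05)
})

test_that("beta-deviation is centered near zero when the data are themselves a shuffle", {
  mc <- simulate_metacommunity(1, 9, archetype_config(n_species = 100,
                                                      patch_lambda = 300,
                                                      sampling_fraction = 0.5,
                                                      seed = 6))
  site_sets <- mc$communities
  # make the "observed" data a draw from the null
  z_site <- do.call(cbind, lapply(site_sets, function(A) A$z))
  z_null <- shuffle_individuals(z_site, seed = 77)
  k <- 0
  null_sets <- lapply(site_sets, function(A) {
    idx <- k + seq_len(ncol(A$z)); k <<- k + ncol(A$z)
    assemblage_set(z_null[, idx, drop = FALSE], A$site, A$district, A$treatment)
  })
  bd <- beta_deviation(null_sets, R = 25, q = 0, facet = "TD", seed = 5)
  # Monte-Carlo SE of the mean deviation from the null distribution of the
  # across-pair mean itself (pair deviations are correlated, so a per-pair
  # SE would understate it)
  nrm <- attr(bd, "null_rep_means")
  mc_se <- sd(nrm) * sqrt(1 + 1 / length(nrm))
  expect_lt(abs(mean(bd$deviation)), 2 * mc_se)
  expect_equal(bd$deviation, bd$observed - bd$null_mean)
})

test_that("uneven disjoint patches show positive beta-deviation", {
  # observed dissimilarity 1; the null reallocates the dominant species
  # across both patches, so expected null dissimilarity < 1
  z <- matrix(c(6L, 0L, 0L, 2L), 2, 2, dimnames = list(c("a", "b"), c("p1", "p2")))
  A <- assemblage_set(z, site = "S", district = "D", treatment = "ESBC")
  bd <- beta_deviation(list(A), R = 400, q = 0, seed = 3)
  expect_equal(bd$observed, 1)
  expect_gt(bd$deviation, 0)
})

test_that("single-replicate null is supported and flagged", {
  A <- tiny_assemblage(S = 8, N = 3, seed = 3)
  bd <- beta_deviation(list(A), R = 1, q = 0, seed = 2)
  expect_true(all(bd$flag == "single_replicate"))
  expect_error(beta_deviation(list(A), R = 0), "R must be")
})

test_that("beta-deviation is invariant to species relabeling", {
  A <- tiny_assemblage(S = 10, N = 4, seed = 8)
  bd1 <- beta_deviation(list(A), R = 15, q = 1, seed = 4)
  perm <- sample(nrow(A$z))
  z2 <- A$z[perm, ]
  rownames(z2) <- rownames(A$z)  # same labels, permuted content
  A2 <- assemblage_set(z2, A$site, A$district, A$treatment)
  bd2 <- beta_deviation(list(A2), R = 15, q = 1, seed = 4)
  expect_equal(sort(bd1$observed), sort(bd2$observed), tolerance = 1e-12)
  expect_equal(mean(bd1$deviation), mean(bd2$deviation), tolerance = 0.02)
})

test_that("trait shuffle permutes rows without changing their multiset", {
  tr <- tiny_traits(10)
  ts <- trait_shuffle(tr, seed = 5)
  expect_identical(rownames(ts), rownames(tr))
  expect_identical(sort(ts$num1), sort(tr$num1))
  expect_identical(sort(as.character(ts$guild)), sort(as.character(tr$guild)))
  expect_identical(trait_shuffle(tr, seed = 5), ts)
})

test_that("degenerate SES inputs are flagged, not silently scored", {
  # all-identical trait rows: no functional structure to threshold at all
  A <- tiny_assemblage(S = 6, N = 3, seed = 2)
  tr_same <- data.frame(v = rep(1, 6), g = factor(rep("x", 6)),
                        row.names = rownames(A$z))
  expect_error(gower_distance(tr_same), "tau")
  # identical patch compositions: functional turnover is 0 under every
  # trait permutation, so the null SD collapses and the SES is undefined
  z <- matrix(rep(c(4L, 3L, 2L, 1L), 3), 4, 3,
              dimnames = list(paste0("sp0", 1:4), paste0("p", 1:3)))
  A2 <- assemblage_set(z, "S01", "S01_ESBC", "ESBC")
  ses <- functional_ses(A2, tiny_traits(4), R = 8, q = 0, seed = 2)
  expect_equal(ses$flag, "zero_null_sd")
  expect_true(is.na(ses$ses))
})

test_that("SES under trait independence is standard-normal-like", {
  # traits independent of the abundance structure: across many simulated
  # districts the SES distribution should have mean ~ 0 and SD ~ 1
  set.seed(10)
  ses <- vapply(1:30, function(r) {
    cfg <- archetype_config(n_species = 60, patch_lambda = 250,
                            sampling_fraction = 0.6, trait_cor = 0,
                            w_sorting = 1, w_mass = 0, w_patchdyn = 0,
                            w_neutral = 0, seed = 300 + r)
    mc <- simulate_metacommunity(1, 9, cfg)
    A <- mc$communities[[1]]
    functional_ses(A, mc$traits, R = 60, q = 0, seed = r)$ses
  }, numeric(1))
  expect_lt(abs(mean(ses)), 2 / sqrt(30) * 1.5 + 0.15)
  expect_gt(sd(ses), 0.6)
  expect_lt(sd(ses), 1.5)
})
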
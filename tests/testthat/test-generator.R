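# Small configs keep the simulations fast; the statistical claims they test
# do not depend on landscape size.
small_cfg <- function(...) {
  args <- utils::modifyList(list(n_species = 120, patch_lambda = 350,
                                 sampling_fraction = 0.4), list(...))
  do.call(archetype_config, args)
}

test_that("the paired design has the right arithmetic and is deterministic", {
  cfg <- small_cfg(seed = 3)
  L <- generate_landscape(11, 9, cfg)
  expect_equal(length(unique(L$patches$district)), 22)
  expect_equal(nrow(L$patches), 198)          # 11 x 2 x 9
  expect_equal(sort(unique(table(L$patches$district))), 9)
  L2 <- generate_landscape(11, 9, cfg)
  expect_identical(L$patches, L2$patches)
  expect_error(generate_landscape(3, 10, cfg), "9 or 15")
  mc1 <- simulate_metacommunity(2, 9, small_cfg(seed = 5))
  mc2 <- simulate_metacommunity(2, 9, small_cfg(seed = 5))
  expect_identical(mc1$communities[[1]]$z, mc2$communities[[1]]$z)
})

test_that("ESBC districts have strictly higher canopy and deadwood variance per site", {
  L <- generate_landscape(8, 9, small_cfg(seed = 11))
  p <- L$patches
  for (s in unique(p$site)) {
    ve <- var(p$canopy[p$site == s & p$treatment == "ESBC"])
    vc <- var(p$canopy[p$site == s & p$treatment == "control"])
    expect_gt(ve, vc)
    expect_gt(var(p$deadwood[p$site == s & p$treatment == "ESBC"]),
              var(p$deadwood[p$site == s & p$treatment == "control"]))
  }
})

test_that("species pool has the documented structure", {
  cfg <- small_cfg(seed = 7, sad_sdlog = 1.5)
  pool <- generate_species_pool(cfg)
  expect_equal(nrow(pool), 120)
  expect_true(all(diff(pool$regional_abund) <= 0))  # rank-abundance nonincreasing
  expect_true(is.factor(pool$guild))                # >= 1 categorical trait
  expect_true(all(c("t_niche", "t_disp", "body_size") %in% names(pool)))
  expect_identical(pool, generate_species_pool(cfg))
  expect_error(archetype_config(n_species = 1), "n_species")
  # zero trait correlation: empirical |r| small at large S
  big <- generate_species_pool(archetype_config(n_species = 2000, trait_cor = 0, seed = 2))
  expect_lt(abs(cor(big$t_niche, big$opt_canopy)), 0.1)
  expect_lt(abs(cor(big$t_disp, log(big$dispersal))), 0.1)
})

test_that("pure sorting couples composition to environment in heterogeneous districts", {
  cfg <- small_cfg(w_sorting = 1, w_mass = 0, w_patchdyn = 0, w_neutral = 0, seed = 13)
  mc <- simulate_metacommunity(2, 9, cfg)
  p <- mc$landscape$patches
  rs <- c()
  for (d in unique(p$district[p$treatment == "ESBC"])) {
    z <- mc$communities[[d]]$z
    cdist <- as.matrix(dist(t(sweep(z, 2, colSums(z), "/"))))   # composition
    edist <- as.matrix(dist(p$canopy[match(colnames(z), p$patch)]))
    ut <- upper.tri(cdist)
    rs <- c(rs, cor(cdist[ut], edist[ut], method = "spearman"))
  }
  expect_true(all(rs > 0))
})

test_that("pure neutral assembly gives homogeneous expected shares across patches", {
  # chi-square homogeneity of the patch x species table should be
  # non-significant in >= 90% of replicates
  cfg0 <- small_cfg(w_sorting = 0, w_mass = 0, w_patchdyn = 0, w_neutral = 1)
  pvals <- vapply(1:100, function(r) {
    cfg <- small_cfg(w_sorting = 0, w_mass = 0, w_patchdyn = 0, w_neutral = 1,
                     seed = r, n_species = 40, patch_lambda = 250,
                     sampling_fraction = 1)
    mc <- simulate_metacommunity(1, 9, cfg)
    z <- mc$communities[[1]]$z
    z <- z[rowSums(z) > 0, ]
    suppressWarnings(chisq.test(t(z), simulate.p.value = FALSE)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.90)
})

test_that("mass effect floods the landscape from a single high-resource source patch", {
  # constructed scenario: one patch gets all the resource; under a pure
  # mass-effect mixture its expected (and realized, at high intensity)
  # total abundance is strictly the highest
  cfg <- small_cfg(w_sorting = 0, w_mass = 1, w_patchdyn = 0, w_neutral = 0,
                   seed = 17, patch_lambda = 5000)
  pool <- generate_species_pool(cfg)
  L <- generate_landscape(1, 9, cfg)
  src <- 5
  for (d in unique(L$patches$district)) {
    i <- which(L$patches$district == d)
    L$patches$canopy[i] <- 0.85
    L$patches$deadwood[i] <- 1
    L$patches$deadwood[i[src]] <- 60   # the source
    L$patches$canopy[i[src]] <- 0.35
  }
  latent <- assemble_communities(L, pool, cfg)
  for (d in names(latent)) {
    totals <- colSums(latent[[d]])
    expect_equal(unname(which.max(totals)), src)
    expect_true(all(totals[src] > totals[-src]))
  }
})

test_that("patch dynamics produces distance decay of community similarity", {
  # pooled over landscapes: dissimilarity increases with distance
  # dispersal limitation (kernel short relative to the 100 m patch spacing)
  # is the defining ingredient of the patch-dynamics regime
  rho <- c(); n_tot <- 0
  for (r in 1:20) {
    cfg <- small_cfg(w_sorting = 0, w_mass = 0, w_patchdyn = 1, w_neutral = 0,
                     seed = 100 + r, n_species = 80, patch_lambda = 300,
                     dispersal_scale = 40)
    mc <- simulate_metacommunity(1, 9, cfg)
    p <- mc$landscape$patches
    for (d in names(mc$communities)) {
      z <- mc$communities[[d]]$z
      pd <- p[match(colnames(z), p$patch), ]
      cdist <- as.matrix(dist(t(sweep(z, 2, pmax(colSums(z), 1), "/"))))
      sdist <- as.matrix(dist(cbind(pd$x, pd$y)))
      ut <- upper.tri(cdist)
      rho <- c(rho, cor(cdist[ut], sdist[ut], method = "spearman"))
    }
  }
  tt <- t.test(rho, alternative = "greater")
  expect_lt(tt$p.value, 0.05)   # similarity decays with distance
})

test_that("binomial sampling behaves as specified", {
  z <- matrix(10L, 1, 1, dimnames = list("s1", "p1"))
  latent <- list(d1 = z)
  # fraction 1: identity
  s1 <- sample_communities(latent, 1, seed = 1)
  expect_identical(s1$d1$z[1, 1], 10L)
  # fraction 0.5 on latent 10: mean over 10,000 draws within 3 SE of 5
  draws <- vapply(1:10000, function(i) sample_communities(latent, 0.5, seed = i)$d1$z[1, 1],
                  numeric(1))
  se <- sqrt(10 * 0.25 / 10000)
  expect_lt(abs(mean(draws) - 5), 3 * se)
  expect_error(sample_communities(latent, 0), "sampling_fraction")
  expect_error(sample_communities(latent, 1.2), "sampling_fraction")
  # strong under-sampling leaves singletons in every district
  mc <- simulate_metacommunity(2, 9, small_cfg(seed = 23, sampling_fraction = 0.1))
  for (A in mc$communities) {
    expect_gt(freq_counts(rowSums(A$z))$f1, 0)
  }
  # sampled counts never exceed latent counts
  expect_true(all(mc$communities[[1]]$z <= mc$latent[[1]]))
})
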
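# Build a pair-level dataset from a generated landscape, with a response
# constructed from known coefficients.
make_pairs <- function(n_sites = 6, seed = 1, esbc_struct = 0, ctrl_struct = 0,
                       esbc_spatial = 0, ctrl_spatial = 0, site_sd = 0,
                       resid_sd = 0, scale_first = TRUE) {
  L <- generate_landscape(n_sites, 9, archetype_config(seed = seed, n_species = 10))
  pp <- pair_predictors(L$patches)
  if (scale_first) {
    for (v in c("structural", "abiotic", "spatial")) {
      pp[[v]] <- as.numeric(scale(pp[[v]]))
    }
  }
  set.seed(seed + 500)
  site_eff <- rnorm(n_sites, 0, site_sd)
  names(site_eff) <- sprintf("S%02d", seq_len(n_sites))
  esbc <- pp$treatment == "ESBC"
  pp$deviation <- site_eff[pp$site] +
    ifelse(esbc, esbc_struct, ctrl_struct) * pp$structural +
    ifelse(esbc, esbc_spatial, ctrl_spatial) * pp$spatial +
    rnorm(nrow(pp), 0, resid_sd)
  pp
}

test_that("noiseless treatment-specific slopes are recovered exactly", {
  pp <- make_pairs(esbc_struct = 2, seed = 3)
  fit <- suppressWarnings(fit_beta_deviation_model(pp, scale_predictors = FALSE))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "treatmentESBC:structural"], 2, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "treatmentcontrol:structural"], 0, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "treatmentcontrol:spatial"], 0, tolerance = 1e-6)
})

test_that("nested and interaction codings give identical fitted values", {
  pp <- make_pairs(esbc_struct = 1, ctrl_struct = 0.5, site_sd = 0.5,
                   resid_sd = 0.3, seed = 7)
  f1 <- fit_beta_deviation_model(pp)
  f2 <- full_interaction_model(pp)
  expect_equal(fitted(f1$fit), fitted(f2$fit), tolerance = 1e-9)
  # interaction term z tests the slope difference between treatments
  co2 <- f2$coefficients
  expect_true("structural:treatmentESBC" %in% co2$term)
})

test_that("conditional R2 follows the variance-partition formula", {
  pp <- make_pairs(esbc_struct = 1, ctrl_struct = 1, site_sd = 1,
                   resid_sd = 1, seed = 11)
  fit <- fit_beta_deviation_model(pp)
  r2 <- conditional_r2(fit)
  X <- model.matrix(fit$fit)
  vf <- var(as.numeric(X %*% lme4::fixef(fit$fit)))
  denom <- vf + fit$var_site + fit$sigma2
  expect_equal(unname(r2["marginal"]), vf / denom, tolerance = 1e-10)
  expect_equal(unname(r2["conditional"]), (vf + fit$var_site) / denom, tolerance = 1e-10)
  expect_gte(r2["conditional"], r2["marginal"])
  expect_true(all(r2 >= 0 & r2 <= 1))
  # no random-effect variance in the generator: conditional ~ marginal
  pp0 <- make_pairs(esbc_struct = 1, ctrl_struct = 1, site_sd = 0,
                    resid_sd = 1, seed = 13)
  fit0 <- fit_beta_deviation_model(pp0)
  expect_lt(fit0$r2_conditional - fit0$r2_marginal, 0.02)
})

test_that("type-I error of the slope z-tests is near nominal", {
  slopes <- c("treatmentcontrol:structural", "treatmentESBC:structural",
              "treatmentcontrol:abiotic", "treatmentESBC:abiotic",
              "treatmentcontrol:spatial", "treatmentESBC:spatial")
  hits <- matrix(FALSE, 60, 6, dimnames = list(NULL, slopes))
  for (r in 1:60) {
    pp <- make_pairs(seed = 100 + r, site_sd = 1, resid_sd = 1)
    fit <- fit_beta_deviation_model(pp)
    co <- fit$coefficients
    hits[r, ] <- abs(co$z[match(slopes, co$term)]) > 1.96
  }
  for (s in slopes) expect_gte(mean(!hits[, s]), 0.90)
})

test_that("interaction test is powered for a true slope difference", {
  # treatment labels are re-drawn at district level so both groups span the
  # same predictor range; the test targets the model machinery, not the
  # (deliberately unequal) landscape variance contrast
  sig <- vapply(1:40, function(r) {
    pp <- make_pairs(seed = 200 + r, site_sd = 0, resid_sd = 0)
    set.seed(900 + r)
    dists <- unique(pp$district)
    relabel <- setNames(sample(rep(c("ESBC", "control"), length.out = length(dists))),
                        dists)
    pp$treatment <- relabel[pp$district]
    esbc <- pp$treatment == "ESBC"
    pp$deviation <- ifelse(esbc, 1, 0) * pp$structural + rnorm(nrow(pp), 0, 1)
    f <- full_interaction_model(pp)
    co <- f$coefficients
    abs(co$z[co$term == "structural:treatmentESBC"]) > 1.96
  }, logical(1))
  expect_gte(mean(sig), 0.80)
})

test_that("degenerate (collinear or constant) predictors are rejected", {
  pp <- make_pairs(seed = 5)
  pp$structural <- 1  # all distances equal
  expect_error(fit_beta_deviation_model(pp), "degenerate|collinear")
  pp2 <- make_pairs(seed = 5)
  pp2$abiotic <- pp2$structural
  expect_error(fit_beta_deviation_model(pp2, scale_predictors = FALSE), "collinear")
})

test_that("SES comparison recovers a treatment shift with the right sign", {
  # identical SES across treatments: contrast ~ 0
  set.seed(3)
  base <- data.frame(site = rep(sprintf("S%02d", 1:11), each = 2),
                     treatment = rep(c("control", "ESBC"), 11))
  base$ses <- rnorm(22, 0, 0.5)
  s0 <- base; s0$ses <- rep(rnorm(11, 0, 0.3), each = 2)
  cmp0 <- suppressWarnings(compare_ses(s0))
  expect_lt(abs(cmp0$contrast), 1e-6)
  # ESBC shifted by -1 at residual SD 0.5: negative significant contrast
  hits <- vapply(1:50, function(r) {
    set.seed(400 + r)
    d <- base
    d$ses <- rnorm(22, 0, 0.5) + ifelse(d$treatment == "ESBC", -1, 0)
    cmp <- compare_ses(d)
    cmp$significant && cmp$contrast < 0
  }, logical(1))
  expect_gte(mean(hits), 0.80)
  expect_error(compare_ses(base[base$treatment == "ESBC", ]), "both treatment")
})

test_that("z table has the Table-1 shape", {
  pp <- make_pairs(seed = 9, esbc_struct = 1, resid_sd = 1)
  fits <- list(TD.q0 = fit_beta_deviation_model(pp),
               TD.q1 = fit_beta_deviation_model(pp))
  zt <- z_value_table(fits)
  expect_equal(nrow(zt), 7)  # six slope terms + conditional R2
  expect_equal(ncol(zt), 3)
  expect_equal(zt$term[7], "R2_conditional")
  expect_true(all(is.finite(zt$TD.q0)))
})
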
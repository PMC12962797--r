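#' Mixed model of beta-deviation on treatment-specific distance predictors
#'
#' Fits, by REML, the linear mixed model
#' `deviation ~ treatment + treatment:(structural + abiotic + spatial) +
#' (1 | site)`: nested treatment-specific slopes (one Structure, Abiotic and
#' Spatial slope per treatment, no pooled main effects of the distances) and
#' a site random intercept capturing within- and among-district dependence
#' of the pairwise observations. Predictors are z-standardized before
#' fitting (so Wald z-values are comparable across predictors); the response
#' is left on the dissimilarity-deviation scale.
#'
#' @param pairs data.frame joining a beta-deviation table to pair
#'   predictors: columns `deviation`, `treatment`, `site`, `structural`,
#'   `abiotic`, `spatial`.
#' @param scale_predictors z-standardize the three distances (default TRUE).
#' @return list of class `model_fit`: `coefficients` (term, estimate, se,
#'   z), `sigma2`, `var_site`, `r2_marginal`, `r2_conditional`,
#'   `converged`, `fit` (the lmer object), `coding`.
#' @export
fit_beta_deviation_model <- function(pairs, scale_predictors = TRUE) {
  dat <- .prep_pairs(pairs, scale_predictors)
  f <- deviation ~ treatment + treatment:structural + treatment:abiotic +
    treatment:spatial + (1 | site)
  .fit_lmm(f, dat, coding = "nested")
}

#' Full interaction recoding of the beta-deviation model
#'
#' The same model re-coded as main effects plus treatment interactions
#' (`deviation ~ (structural + abiotic + spatial) * treatment + (1 | site)`)
#' so that the interaction z-values directly test slope differences between
#' treatments. Fitted values are identical to the nested coding; only the
#' parameterization differs.
#'
#' @inheritParams fit_beta_deviation_model
#' @return `model_fit` (see [fit_beta_deviation_model()]).
#' @export
full_interaction_model <- function(pairs, scale_predictors = TRUE) {
  dat <- .prep_pairs(pairs, scale_predictors)
  f <- deviation ~ (structural + abiotic + spatial) * treatment + (1 | site)
  .fit_lmm(f, dat, coding = "interaction")
}

.prep_pairs <- function(pairs, scale_predictors) {
  need <- c("deviation", "treatment", "site", "structural", "abiotic", "spatial")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- pairs
  dat$treatment <- factor(dat$treatment, levels = c("control", "ESBC"))
  if (any(is.na(dat$treatment))) stop("treatment must be 'control' or 'ESBC'")
  if (length(unique(dat$site)) < 2) stop("need at least 2 sites")
  if (scale_predictors) {
    for (v in c("structural", "abiotic", "spatial")) {
      s <- stats::sd(dat[[v]])
      if (s == 0) stop("degenerate predictor (zero variance): ", v)
      dat[[v]] <- (dat[[v]] - mean(dat[[v]])) / s
    }
  }
  X <- stats::model.matrix(~ treatment * (structural + abiotic + spatial), dat)
  if (qr(X)$rank < ncol(X)) stop("predictors are collinear after coding; refusing to fit")
  dat
}

.fit_lmm <- function(formula, dat, coding) {
  fit <- suppressMessages(lme4::lmer(formula, data = dat, REML = TRUE))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  singular <- any(grepl("singular", msgs, ignore.case = TRUE))
  real <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  converged <- length(real) == 0  # a boundary (singular) fit is a valid fit
  if (!converged) warning("lmer convergence diagnostics: ", paste(real, collapse = "; "))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], z = sm[, "Estimate"] / sm[, "Std. Error"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_site <- sum(vc$vcov[vc$grp != "Residual"])
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  r2 <- .nakagawa_r2(fit, var_site, sigma2)
  structure(list(coefficients = coefs, sigma2 = sigma2, var_site = var_site,
                 r2_marginal = r2[1], r2_conditional = r2[2],
                 converged = converged, singular = singular, messages = msgs, fit = fit,
                 coding = coding, n = nrow(dat)),
            class = "model_fit")
}

.nakagawa_r2 <- function(fit, var_site, sigma2) {
  X <- stats::model.matrix(fit)
  var_fixed <- stats::var(as.numeric(X %*% lme4::fixef(fit)))
  tot <- var_fixed + var_site + sigma2
  if (tot <= 0) stop("zero total variance")
  c(var_fixed / tot, (var_fixed + var_site) / tot)
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance-partitioning (Nakagawa-style) coefficients of determination:
#' marginal = var(fixed)/(var(fixed) + var(random) + var(residual)),
#' conditional adds the random-intercept variance to the numerator.
#'
#' @param fit a `model_fit` from this package.
#' @return named numeric vector `c(marginal, conditional)`.
#' @export
conditional_r2 <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  c(marginal = fit$r2_marginal, conditional = fit$r2_conditional)
}

#' @export
print.model_fit <- function(x, ...) {
  cat("mixed model (", x$coding, " coding), n = ", x$n, "\n", sep = "")
  print(x$coefficients, digits = 4)
  cat(sprintf("site var %.4g | residual var %.4g | R2 marginal %.3f | R2 conditional %.3f\n",
              x$var_site, x$sigma2, x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Compare SES levels between control and ESBC districts
#'
#' Gaussian mixed model of the district-level standardized effect sizes on
#' treatment with a site random intercept; reports the ESBC-minus-control
#' contrast and its Wald z.
#'
#' @param ses data.frame from [functional_ses()] rows (columns `ses`,
#'   `treatment`, `site`).
#' @return list: `contrast` (ESBC - control), `se`, `z`, `significant`
#'   (|z| > 1.96), `fit`.
#' @export
compare_ses <- function(ses) {
  if (length(unique(ses$treatment)) < 2) stop("both treatment levels required")
  if (length(unique(ses$site)) < 2) stop("need at least 2 sites")
  dat <- ses[!is.na(ses$ses), ]
  dat$treatment <- factor(dat$treatment, levels = c("control", "ESBC"))
  fit <- lme4::lmer(ses ~ treatment + (1 | site), data = dat, REML = TRUE)
  sm <- summary(fit)$coefficients
  est <- sm["treatmentESBC", "Estimate"]
  se <- sm["treatmentESBC", "Std. Error"]
  list(contrast = est, se = se, z = est / se, significant = abs(est / se) > 1.96,
       fit = fit)
}

#' Table of treatment-specific z-values across diversity cases
#'
#' Assembles the Table-1-shaped summary: rows are the six
#' treatment:predictor terms plus the conditional R-squared, columns the
#' (facet, q) cases.
#'
#' @param fits named list of `model_fit`s, names like `"TD.q0"`.
#' @return data.frame with a `term` column and one column per case.
#' @export
z_value_table <- function(fits) {
  terms <- c("Control:Structure", "ESBC:Structure", "Control:Abiotic",
             "ESBC:Abiotic", "Control:Spatial", "ESBC:Spatial")
  lookup <- c("Control:Structure" = "treatmentcontrol:structural",
              "ESBC:Structure" = "treatmentESBC:structural",
              "Control:Abiotic" = "treatmentcontrol:abiotic",
              "ESBC:Abiotic" = "treatmentESBC:abiotic",
              "Control:Spatial" = "treatmentcontrol:spatial",
              "ESBC:Spatial" = "treatmentESBC:spatial")
  out <- data.frame(term = c(terms, "R2_conditional"), stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    z <- f$coefficients$z[match(lookup[terms], f$coefficients$term)]
    out[[nm]] <- c(z, f$r2_conditional)
  }
  out
}
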
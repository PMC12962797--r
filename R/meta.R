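#' Coverage-standardized diversity estimates for one district
#'
#' Computes gamma, alpha and beta (as 1-S turnover) for each requested facet
#' and order q, with Chao-style bootstrap standard errors and percentile
#' confidence intervals. All cases share one set of bootstrap replicate
#' assemblages per facet, so downstream paired differences can propagate
#' replicate streams.
#'
#' @param A `assemblage_set` for the district.
#' @param qs diversity orders (default 0, 1, 2).
#' @param facets `"TD"`, `"FD"` or both.
#' @param coverage shared coverage target (NULL = observed reference).
#' @param D `trait_dist` (needed for FD).
#' @param B bootstrap replicates (default 200).
#' @param seed RNG seed.
#' @param fd_draws Monte-Carlo draws for FD rarefaction.
#' @return data.frame with columns `site`, `district`, `treatment`, `facet`,
#'   `scale` (gamma/alpha/beta), `q`, `value`, `se`, `lcl`, `ucl`; the
#'   bootstrap replicate streams are attached as attribute `replicates`, a
#'   named list keyed `facet.scale.q`. Beta rows carry the 1-S dissimilarity.
#' @export
district_diversity <- function(A, qs = c(0, 1, 2), facets = c("TD", "FD"),
                               coverage = NULL, D = NULL, B = 200, seed = 1,
                               fd_draws = 25) {
  stopifnot(inherits(A, "assemblage_set"))
  scales <- c("gamma", "alpha", "beta")
  case_value <- function(dec, scale) switch(scale, gamma = dec$gamma,
                                            alpha = dec$alpha, beta = dec$dissim)
  rows <- list()
  reps_list <- list()
  for (facet in facets) {
    boots <- bootstrap_assemblages(A, B = B, seed = seed, augment = (facet == "TD"))
    for (q in qs) {
      dec <- decompose(A, q, facet, coverage, D, fd_draws = fd_draws, fd_seed = seed)
      repmat <- vapply(seq_along(boots), function(b) {
        d <- decompose(boots[[b]], q, facet, coverage, D,
                       fd_draws = fd_draws, fd_seed = seed + b)
        c(d$gamma, d$alpha, d$dissim)
      }, numeric(3))
      for (si in seq_along(scales)) {
        sc <- scales[si]
        key <- paste(facet, sc, q, sep = ".")
        reps_list[[key]] <- repmat[si, ]
        rows[[length(rows) + 1L]] <- data.frame(
          site = A$site, district = A$district, treatment = A$treatment,
          facet = facet, scale = sc, q = q,
          value = case_value(dec, sc),
          se = stats::sd(repmat[si, ]),
          lcl = stats::quantile(repmat[si, ], 0.025, names = FALSE),
          ucl = stats::quantile(repmat[si, ], 0.975, names = FALSE),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- reps_list
  out
}

#' ESBC-minus-control difference for one site and one diversity case
#'
#' Positive differences mean higher diversity in the treated (ESBC)
#' district. When bootstrap replicate streams are available for both
#' districts the difference SE is the standard deviation of the paired
#' replicate differences; otherwise it falls back to
#' \eqn{\sqrt{SE_E^2 + SE_C^2}}.
#'
#' @param est_e,est_c single-case estimate lists with fields `value`, `se`,
#'   and optionally `replicates`, plus `facet`, `scale`, `q`.
#' @return list of class `paired_difference`: `site`, `facet`, `scale`, `q`,
#'   `delta`, `se`, `method`.
#' @export
pair_difference <- function(est_e, est_c) {
  for (f in c("facet", "scale", "q")) {
    if (!identical(est_e[[f]], est_c[[f]])) stop("mismatched case: ", f)
  }
  delta <- est_e$value - est_c$value
  re <- est_e$replicates
  rc <- est_c$replicates
  if (!is.null(re) && !is.null(rc) && length(re) == length(rc)) {
    se <- stats::sd(re - rc)
    method <- "paired_replicates"
  } else {
    se <- sqrt(est_e$se^2 + est_c$se^2)
    method <- "independent_se"
  }
  structure(list(site = est_e$site, facet = est_e$facet, scale = est_e$scale,
                 q = est_e$q, delta = delta, se = se, method = method),
            class = "paired_difference")
}

#' Fixed-effect inverse-variance combination of site-level differences
#'
#' Weights \eqn{w_s \propto 1/SE_s^2}, combined estimate
#' \eqn{\hat\Delta = \sum_s w_s \Delta_s}, standard error
#' \eqn{(\sum_s SE_s^{-2})^{-1/2}}, normal-approximation 95% CI. Sites with
#' zero SE are floored at `se_floor` with a warning. A random-effects
#' (DerSimonian-Laird) variant is available via `method = "RE"`.
#'
#' @param differences list of `paired_difference` objects for one case.
#' @param method `"FE"` (default) or `"RE"`.
#' @param se_floor minimum admissible per-site SE.
#' @return list of class `meta_result`: `facet`, `scale`, `q`, `estimate`,
#'   `se`, `lcl`, `ucl`, `z`, `weights`, `significant` (CI excludes 0),
#'   `n_sites`, `flag`.
#' @export
combine_differences <- function(differences, method = c("FE", "RE"),
                                se_floor = 1e-8) {
  method <- match.arg(method)
  if (length(differences) == 0) stop("no differences to combine")
  case <- differences[[1]][c("facet", "scale", "q")]
  for (d in differences) {
    if (!identical(d[c("facet", "scale", "q")], case)) stop("differences mix cases")
  }
  delta <- vapply(differences, `[[`, numeric(1), "delta")
  se <- vapply(differences, `[[`, numeric(1), "se")
  flag <- "ok"
  if (length(delta) == 1) {
    warning("single site: returning the site difference unchanged")
    flag <- "single_site"
  }
  if (any(se < se_floor)) {
    warning(sum(se < se_floor), " site(s) with SE below floor; floored at ", se_floor)
    se <- pmax(se, se_floor)
  }
  w_inv <- 1 / se^2
  if (method == "RE" && length(delta) > 1) {
    # DerSimonian-Laird between-site variance
    fe <- sum(w_inv * delta) / sum(w_inv)
    Q <- sum(w_inv * (delta - fe)^2)
    df <- length(delta) - 1
    tau2 <- max(0, (Q - df) / (sum(w_inv) - sum(w_inv^2) / sum(w_inv)))
    w_inv <- 1 / (se^2 + tau2)
  }
  w <- w_inv / sum(w_inv)
  est <- sum(w * delta)
  se_comb <- 1 / sqrt(sum(w_inv))
  lcl <- est - 1.96 * se_comb
  ucl <- est + 1.96 * se_comb
  structure(list(facet = case$facet, scale = case$scale, q = case$q,
                 estimate = est, se = se_comb, lcl = lcl, ucl = ucl,
                 z = est / se_comb, weights = w,
                 significant = (lcl > 0 || ucl < 0),
                 n_sites = length(delta), method = method, flag = flag),
            class = "meta_result")
}

# Extract one case (facet, scale, q) from a district_diversity table as the
# estimate list pair_difference() consumes.
.case_estimate <- function(tab, facet, scale, q) {
  i <- which(tab$facet == facet & tab$scale == scale & tab$q == q)
  if (length(i) != 1) stop("case not found (or duplicated): ", facet, "/", scale, "/q=", q)
  reps <- attr(tab, "replicates")[[paste(facet, scale, q, sep = ".")]]
  list(site = tab$site[i], facet = facet, scale = scale, q = q,
       value = tab$value[i], se = tab$se[i], replicates = reps)
}

#' Meta-analysis over all diversity cases
#'
#' Combines ESBC-minus-control differences across sites for every case
#' facet x scale x q (2 x 3 x 3 = 18 with the defaults), mirroring the
#' forest-plot summary of a paired district design.
#'
#' @param district_tables list of `district_diversity()` tables, two per
#'   site (one ESBC, one control district).
#' @param qs,facets cases to combine.
#' @param method meta-analytic model, `"FE"` or `"RE"`.
#' @return data.frame with one row per case: `facet`, `scale`, `q`,
#'   `estimate`, `se`, `lcl`, `ucl`, `z`, `significant`, `n_sites`; the
#'   `meta_result` objects are attached as attribute `results`.
#' @export
run_all_cases <- function(district_tables, qs = c(0, 1, 2),
                          facets = c("TD", "FD"), method = "FE") {
  sites <- unique(vapply(district_tables, function(t) as.character(t$site[1]), character(1)))
  by_site <- lapply(sites, function(s) {
    tabs <- Filter(function(t) as.character(t$site[1]) == s, district_tables)
    trt <- vapply(tabs, function(t) as.character(t$treatment[1]), character(1))
    if (!setequal(trt, c("ESBC", "control")) || length(tabs) != 2) {
      stop("site ", s, " must have exactly one ESBC and one control district")
    }
    list(e = tabs[[which(trt == "ESBC")]], c = tabs[[which(trt == "control")]])
  })
  names(by_site) <- sites
  rows <- list()
  results <- list()
  for (facet in facets) for (scale in c("gamma", "alpha", "beta")) for (q in qs) {
    diffs <- lapply(by_site, function(p) {
      pair_difference(.case_estimate(p$e, facet, scale, q),
                      .case_estimate(p$c, facet, scale, q))
    })
    mr <- combine_differences(diffs, method = method)
    key <- paste(facet, scale, q, sep = ".")
    results[[key]] <- mr
    rows[[key]] <- data.frame(facet = facet, scale = scale, q = q,
                              estimate = mr$estimate, se = mr$se,
                              lcl = mr$lcl, ucl = mr$ucl, z = mr$z,
                              significant = mr$significant,
                              n_sites = mr$n_sites, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
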
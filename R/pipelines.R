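#' Diversity meta-analysis pipeline (gamma/alpha/beta x q x facet)
#'
#' The first headline analysis: per-district coverage-standardized diversity
#' estimates with Chao-style bootstrap uncertainty, ESBC-minus-control
#' differences per site, and fixed-effect inverse-variance combination
#' across sites for every facet x scale x q case. The shared coverage
#' target is `coverage_mult` times the minimum, over all districts, of the
#' expected coverage at each district's extrapolation cap, so one target is
#' reachable everywhere (this also controls for sites having 9 versus 15
#' patches).
#'
#' @param communities named list of district `assemblage_set`s.
#' @param traits trait table (required when `"FD"` is among the facets).
#' @param cfg settings from [run_config()].
#' @param out_dir optional directory for the tidy case table + provenance.
#' @return the [run_all_cases()] table; the shared coverage target is
#'   attached as attribute `coverage_target`, the per-district tables as
#'   attribute `district_tables`.
#' @export
diversity_meta_pipeline <- function(communities, traits = NULL,
                                    cfg = run_config(), out_dir = NULL) {
  if ("FD" %in% cfg$facets && is.null(traits)) stop("FD requested but no trait table given")
  pooled <- lapply(communities, function(A) rowSums(A$z))
  joints <- lapply(communities, function(A) as.numeric(A$z))
  target <- coverage_target(c(pooled, joints), mult = cfg$coverage_mult,
                            cap_mult = cfg$cap_mult)
  D <- if ("FD" %in% cfg$facets) gower_distance(traits) else NULL
  tables <- lapply(seq_along(communities), function(i) {
    district_diversity(communities[[i]], qs = cfg$qs, facets = cfg$facets,
                       coverage = target, D = D, B = cfg$B,
                       seed = cfg$seed + i, fd_draws = cfg$fd_draws)
  })
  res <- run_all_cases(tables, qs = cfg$qs, facets = cfg$facets,
                       method = cfg$meta_method)
  attr(res, "coverage_target") <- target
  attr(res, "district_tables") <- tables
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, "meta_cases.csv"), row.names = FALSE)
    .write_provenance(file.path(out_dir, "meta_provenance.yaml"), cfg,
                      list(coverage_target = target,
                           n_districts = length(communities)))
  }
  res
}

#' Beta-deviation pipeline (null models, distances, mixed models, SES)
#'
#' The second headline analysis: per-site individual-shuffle beta-deviation
#' for every facet x q, joined to the structural/abiotic/spatial patch-pair
#' predictors, mixed-model attribution with treatment-specific slopes, and
#' the trait-shuffle SES comparison between treatments.
#'
#' @param communities named list of district `assemblage_set`s.
#' @param patches patch environment/coordinate table (one row per patch).
#' @param traits trait table (for FD beta-deviation and the SES analysis).
#' @param cfg settings from [run_config()]; `cfg$coverage` may hold a
#'   coverage target for the pairwise dissimilarities (default NULL =
#'   observed reference sample).
#' @param out_dir optional output directory.
#' @return list: `deviations` (pair-level table), `pairs` (predictors),
#'   `fits` (per facet.q `model_fit`s, nested coding), `interaction_fits`,
#'   `z_table` (Table-1 shape), `ses` (district-level SES rows),
#'   `ses_comparison`.
#' @export
beta_deviation_pipeline <- function(communities, patches, traits = NULL,
                                    cfg = run_config(), out_dir = NULL) {
  miss <- setdiff(unique(patches$district), names(communities))
  if (length(miss) > 0) stop("patch table lists unknown district(s): ", paste(miss, collapse = ", "))
  coverage <- cfg$coverage  # NULL = reference-sample dissimilarities
  D <- if (!is.null(traits)) gower_distance(traits) else NULL
  if ("FD" %in% cfg$facets && is.null(D)) stop("FD requested but no trait table given")

  sites <- unique(vapply(communities, function(A) as.character(A$site), character(1)))
  preds <- pair_predictors(patches, scale_scope = cfg$scale_scope)
  key <- function(d, a, b) paste(d, pmin(a, b), pmax(a, b), sep = "\r")
  preds$.key <- key(preds$district, preds$patch_a, preds$patch_b)

  deviations <- list()
  for (facet in cfg$facets) for (q in cfg$qs) {
    dev <- lapply(seq_along(sites), function(si) {
      s <- sites[si]
      site_sets <- Filter(function(A) as.character(A$site) == s, communities)
      beta_deviation(site_sets, R = cfg$R, q = q, facet = facet,
                     coverage = coverage, D = D,
                     seed = cfg$seed + 1000L * si, scope = cfg$null_scope)
    })
    deviations[[paste(facet, q, sep = ".q")]] <- do.call(rbind, dev)
  }

  fits <- list()
  ifits <- list()
  for (nm in names(deviations)) {
    dv <- deviations[[nm]]
    dv$.key <- key(dv$district, dv$patch_a, dv$patch_b)
    m <- match(dv$.key, preds$.key)
    if (any(is.na(m))) stop("patch key mismatch between community and environment tables")
    dat <- cbind(dv, preds[m, c("structural", "abiotic", "spatial")])
    fits[[nm]] <- fit_beta_deviation_model(dat)
    ifits[[nm]] <- full_interaction_model(dat)
  }
  ztab <- z_value_table(fits)

  ses <- NULL
  ses_cmp <- NULL
  if (!is.null(traits)) {
    ses <- do.call(rbind, lapply(seq_along(communities), function(i) {
      functional_ses(communities[[i]], traits, R = cfg$R, q = cfg$qs[1],
                     coverage = coverage, seed = cfg$seed + i)
    }))
    ses_cmp <- compare_ses(ses)
  }
  out <- list(deviations = deviations, pairs = preds, fits = fits,
              interaction_fits = ifits, z_table = ztab, ses = ses,
              ses_comparison = ses_cmp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ztab, file.path(out_dir, "z_table.csv"), row.names = FALSE)
    utils::write.csv(preds[setdiff(names(preds), ".key")],
                     file.path(out_dir, "pair_predictors.csv"), row.names = FALSE)
    dev_all <- do.call(rbind, lapply(deviations, function(d) d[setdiff(names(d), ".key")]))
    utils::write.csv(dev_all, file.path(out_dir, "beta_deviation.csv"), row.names = FALSE)
    if (!is.null(ses)) utils::write.csv(ses, file.path(out_dir, "ses.csv"), row.names = FALSE)
    .write_provenance(file.path(out_dir, "beta_deviation_provenance.yaml"), cfg,
                      list(n_pairs = nrow(preds)))
  }
  out
}
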
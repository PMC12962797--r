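#' Shuffle individuals among the patches of a site
#'
#' Every observed individual is reassigned uniformly at random to one of the
#' site's patches, holding each patch's total abundance fixed at its
#' observed value. Per-species site totals are untouched, so site-level
#' gamma-diversity and the relative abundance of every species in the site
#' are preserved exactly; only the allocation of individuals to patches is
#' randomized.
#'
#' @param z species x patch count matrix spanning all patches of the site
#'   (both districts).
#' @param seed RNG seed; `NULL` uses the current RNG stream (for use inside
#'   replicate loops).
#' @return shuffled matrix with identical row and column sums.
#' @export
shuffle_individuals <- function(z, seed = NULL) {
  z <- as.matrix(z)
  if (ncol(z) < 2) return(z)  # single patch: shuffle is the identity
  n_patch <- colSums(z)
  if (sum(n_patch) < 1) stop("empty site")
  doit <- function() {
    ids <- sample(rep.int(seq_len(nrow(z)), rowSums(z)))
    grp <- rep.int(seq_len(ncol(z)), n_patch)
    zs <- matrix(0L, nrow(z), ncol(z), dimnames = dimnames(z))
    for (k in seq_len(ncol(z))) {
      zs[, k] <- tabulate(ids[grp == k], nbins = nrow(z))
    }
    zs
  }
  if (is.null(seed)) doit() else .with_seed(seed, doit())
}

#' Beta-deviation of patch pairs against the individual-shuffle null
#'
#' Observed pairwise 1-S turnover per within-district patch pair minus its
#' expectation under R independent individual shuffles of the whole site
#' (ESBC and control districts together, which preserves site gamma and
#' species relative abundances). The null SD is retained for diagnostics.
#' Null dissimilarities are computed at the same coverage target as the
#' observed ones.
#'
#' @param site_sets list of the site's `assemblage_set`s (one per district),
#'   sharing a species list.
#' @param R null replicates (>= 1; R = 1 is flagged `single_replicate`).
#' @param q diversity order.
#' @param facet `"TD"` or `"FD"`.
#' @param coverage coverage target (NULL = observed reference sample).
#' @param D `trait_dist` for FD.
#' @param seed RNG seed.
#' @param scope `"site"` (default: shuffle spans both districts) or
#'   `"district"` (sensitivity mode: shuffle within district only).
#' @return data.frame keyed (site, district, treatment, patch_a, patch_b,
#'   facet, q) with `observed`, `null_mean`, `null_sd`, `deviation`, `flag`.
#' @export
beta_deviation <- function(site_sets, R = 100, q = 0, facet = "TD",
                           coverage = NULL, D = NULL, seed = 1,
                           scope = c("site", "district")) {
  scope <- match.arg(scope)
  if (R < 1) stop("R must be >= 1")
  if (length(site_sets) < 1) stop("no districts supplied")
  species <- rownames(site_sets[[1]]$z)
  for (A in site_sets) {
    if (!identical(rownames(A$z), species)) stop("districts must share a species list")
  }
  zs <- lapply(site_sets, function(A) A$z)
  ncols <- vapply(zs, ncol, integer(1))
  dist_of <- rep(seq_along(zs), ncols)
  site_z <- do.call(cbind, zs)

  obs <- lapply(seq_along(site_sets), function(i) {
    pb <- pairwise_beta(site_sets[[i]], q, facet, coverage, D, fd_seed = seed)
    pb$district <- site_sets[[i]]$district
    pb$treatment <- site_sets[[i]]$treatment
    pb
  })
  obs <- do.call(rbind, obs)
  npair <- nrow(obs)
  null_mat <- matrix(NA_real_, npair, R)
  .with_seed(seed, {
    for (r in seq_len(R)) {
      zr <- if (scope == "site") {
        shuffle_individuals(site_z)
      } else {
        do.call(cbind, lapply(seq_along(zs), function(i) shuffle_individuals(zs[[i]])))
      }
      row0 <- 0L
      for (i in seq_along(site_sets)) {
        Ai <- assemblage_set(zr[, dist_of == i, drop = FALSE],
                             site_sets[[i]]$site, site_sets[[i]]$district,
                             site_sets[[i]]$treatment)
        pb <- pairwise_beta(Ai, q, facet, coverage, D, fd_seed = seed + r)
        null_mat[row0 + seq_len(nrow(pb)), r] <- pb$dissim
        row0 <- row0 + nrow(pb)
      }
    }
  })
  out <- data.frame(site = site_sets[[1]]$site, district = obs$district,
                    treatment = obs$treatment, patch_a = obs$patch_a,
                    patch_b = obs$patch_b, facet = facet, q = q,
                    observed = obs$dissim,
                    null_mean = rowMeans(null_mat),
                    null_sd = apply(null_mat, 1, stats::sd),
                    deviation = obs$dissim - rowMeans(null_mat),
                    flag = if (R == 1) "single_replicate" else "ok",
                    stringsAsFactors = FALSE)
  # distribution of the across-pair mean dissimilarity under the null: the
  # correct Monte-Carlo yardstick for "is the mean deviation zero" (pair
  # deviations sharing a patch are correlated, so a per-pair SE understates
  # the uncertainty of the mean)
  attr(out, "null_rep_means") <- colMeans(null_mat)
  out
}

#' Permute species labels across the trait matrix
#'
#' Applies a uniformly random permutation of species labels to whole trait
#' rows; the multiset of trait rows is unchanged, the species-abundance
#' matrix (and hence its spatial pattern) is untouched by construction.
#'
#' @param traits trait data.frame rownamed by species.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return permuted trait table with the original rownames.
#' @export
trait_shuffle <- function(traits, seed = NULL) {
  if (nrow(traits) < 2) stop("need at least 2 species")
  doit <- function() {
    perm <- sample.int(nrow(traits))
    out <- traits[perm, , drop = FALSE]
    rownames(out) <- rownames(traits)
    out
  }
  if (is.null(seed)) doit() else .with_seed(seed, doit())
}

# Mean pairwise functional 1-S of a district given a similarity context.
.mean_pairwise_fd <- function(A, q, coverage, D, fd_seed) {
  pb <- pairwise_beta(A, q, "FD", coverage, D, fd_seed = fd_seed)
  mean(pb$dissim)
}

#' Standardized effect size of functional beta-diversity
#'
#' Normalizes the observed mean pairwise functional 1-S of a district by the
#' mean and standard deviation of R trait-shuffle null replicates (species
#' labels permuted across the trait matrix; abundances untouched). |SES| >
#' 1.96 is flagged significant; a zero null SD leaves the SES undefined and
#' flagged.
#'
#' @param A district `assemblage_set`.
#' @param traits trait table covering all species of `A`.
#' @param R trait-shuffle replicates (default 100).
#' @param q diversity order.
#' @param coverage coverage target (NULL = observed).
#' @param seed RNG seed.
#' @param tau optional Gower threshold override.
#' @return one-row data.frame: site, district, treatment, q, observed,
#'   null_mean, null_sd, ses, significant, flag.
#' @export
functional_ses <- function(A, traits, R = 100, q = 0, coverage = NULL,
                           seed = 1, tau = NULL) {
  stopifnot(inherits(A, "assemblage_set"))
  if (R < 2) stop("R must be >= 2")
  traits <- traits[rownames(A$z), , drop = FALSE]
  D <- gower_distance(traits, tau = tau)
  obs <- .mean_pairwise_fd(A, q, coverage, D, fd_seed = seed)
  null_vals <- .with_seed(seed, {
    vapply(seq_len(R), function(r) {
      perm <- sample.int(nrow(traits))
      Dr <- D
      Dr$d <- D$d[perm, perm]
      dimnames(Dr$d) <- dimnames(D$d)
      .mean_pairwise_fd(A, q, coverage, Dr, fd_seed = seed + r)
    }, numeric(1))
  })
  mu <- mean(null_vals)
  sdv <- stats::sd(null_vals)
  ses <- if (sdv > 0) (obs - mu) / sdv else NA_real_
  data.frame(site = A$site, district = A$district, treatment = A$treatment,
             q = q, observed = obs, null_mean = mu, null_sd = sdv, ses = ses,
             significant = !is.na(ses) && abs(ses) > 1.96,
             flag = if (sdv > 0) "ok" else "zero_null_sd",
             stringsAsFactors = FALSE)
}
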
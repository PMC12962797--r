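#' Configuration for the metacommunity archetype generator
#'
#' Mixture weights over the four assembly archetypes plus the scales that
#' govern them. Weights are normalized to sum to 1 internally. Defaults
#' emulate a beech-forest beetle metacommunity at the scale of the paired
#' district design: ~1200 regional species with a lognormal abundance
#' distribution, moderate niche selectivity on the canopy/deadwood axes,
#' dispersal on the order of within-district patch spacing, and strong
#' under-sampling so that singletons are plentiful.
#'
#' @param w_sorting,w_mass,w_patchdyn,w_neutral nonnegative mixture weights
#'   of the species-sorting, mass-effect, patch-dynamics and neutral
#'   assembly components.
#' @param niche_breadth Gaussian niche breadth on the scaled environmental
#'   axes (canopy density in \[0,1\]).
#' @param dispersal_scale median exponential dispersal kernel scale, meters.
#' @param sad_meanlog,sad_sdlog lognormal species-abundance parameters of
#'   the regional pool.
#' @param n_species regional pool size.
#' @param sampling_fraction binomial detection fraction in (0, 1].
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @param patch_lambda expected latent individuals per patch.
#' @param trait_cor correlation between traits and niche/dispersal.
#' @return list of class `archetype_config`.
#' @export
archetype_config <- function(w_sorting = 0.3, w_mass = 0.2, w_patchdyn = 0.3,
                             w_neutral = 0.2, niche_breadth = 0.25,
                             dispersal_scale = 150, sad_meanlog = 2,
                             sad_sdlog = 1.5, n_species = 1200,
                             sampling_fraction = 0.25, seed = 1,
                             patch_lambda = 1800, trait_cor = 0.7) {
  w <- c(sorting = w_sorting, mass = w_mass, patchdyn = w_patchdyn, neutral = w_neutral)
  if (any(w < 0) || sum(w) <= 0) stop("archetype weights must be nonnegative with positive sum")
  if (niche_breadth <= 0 || dispersal_scale <= 0 || patch_lambda <= 0) {
    stop("scales must be strictly positive")
  }
  if (n_species < 2) stop("n_species must be >= 2")
  if (sampling_fraction <= 0 || sampling_fraction > 1) stop("sampling_fraction must be in (0, 1]")
  structure(list(w = w / sum(w), niche_breadth = niche_breadth,
                 dispersal_scale = dispersal_scale, sad_meanlog = sad_meanlog,
                 sad_sdlog = sad_sdlog, n_species = as.integer(n_species),
                 sampling_fraction = sampling_fraction, seed = as.integer(seed),
                 patch_lambda = patch_lambda, trait_cor = trait_cor),
            class = "archetype_config")
}

#' Generate the regional species pool
#'
#' Each species gets a lognormal regional abundance, niche optima on the
#' canopy-density and (scaled) deadwood axes, an exponential dispersal-kernel
#' scale, and a trait vector correlated (with configurable r) with niche and
#' dispersal: two numeric traits, log body size, and a categorical habitat
#' guild — enough to exercise mixed-type Gower distances.
#'
#' @param config `archetype_config`.
#' @return data.frame, one row per species.
#' @export
generate_species_pool <- function(config) {
  stopifnot(inherits(config, "archetype_config"))
  S <- config$n_species
  r <- config$trait_cor
  .with_seed(config$seed, {
    phi <- stats::rlnorm(S, config$sad_meanlog, config$sad_sdlog)
    ord <- order(phi, decreasing = TRUE)
    phi <- phi[ord]
    opt_canopy <- stats::runif(S, 0.2, 1)
    opt_deadwood <- stats::rbeta(S, 1.2, 2)   # scaled deadwood axis in [0,1]
    dispersal <- stats::rlnorm(S, log(config$dispersal_scale), 0.6)
    mix <- function(sig) r * sig + sqrt(max(0, 1 - r^2)) * stats::rnorm(S)
    t_niche <- mix(as.numeric(scale(opt_canopy)))
    t_disp <- mix(as.numeric(scale(log(dispersal))))
    body_size <- exp(stats::rnorm(S, 1, 0.6))
    guild_latent <- r * as.numeric(scale(opt_deadwood)) + sqrt(max(0, 1 - r^2)) * stats::rnorm(S)
    guild <- cut(guild_latent, stats::quantile(guild_latent, 0:4 / 4),
                 labels = c("litter", "bark", "deadwood", "canopy"),
                 include.lowest = TRUE)
    data.frame(species = sprintf("sp%04d", seq_len(S)),
               regional_abund = phi, opt_canopy = opt_canopy,
               opt_deadwood = opt_deadwood, dispersal = dispersal,
               t_niche = t_niche, t_disp = t_disp, body_size = body_size,
               guild = guild, stringsAsFactors = FALSE)
  })
}

#' Generate the physical landscape of a paired district design
#'
#' `n_sites` sites, each with one ESBC and one control district of
#' `patches_per_district` 50 m x 50 m patches on a jittered 100 m grid
#' (3x3 or 3x5) inside a ~20 ha footprint. Control districts get
#' homogeneous canopy/deadwood; ESBC districts get a constructed spread of
#' canopy gaps and elevated, variable deadwood, so the between-patch
#' variance of both is strictly larger in the ESBC district of every site.
#' Five Ellenberg-style indicator means (light excluded) vary mostly at the
#' district level with patch-level noise partly linked to canopy opening.
#'
#' @param n_sites number of sites (>= 1).
#' @param patches_per_district 9 or 15.
#' @param config `archetype_config`.
#' @return list of class `landscape`: `patches` data.frame (site, district,
#'   treatment, patch, x, y, canopy, deadwood, E1..E5), plus the call
#'   parameters.
#' @export
generate_landscape <- function(n_sites, patches_per_district = 9, config = archetype_config()) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (!patches_per_district %in% c(9, 15)) {
    stop("patches_per_district must be 9 or 15 (got ", patches_per_district, ")")
  }
  P <- patches_per_district
  grid <- expand.grid(gx = 0:2, gy = seq_len(P / 3) - 1)
  .with_seed(config$seed + 1L, {
    rows <- list()
    for (s in seq_len(n_sites)) {
      site_x <- (s - 1) * 10000
      for (trt in c("ESBC", "control")) {
        dist_x <- site_x + if (trt == "ESBC") 0 else 1000
        x <- dist_x + grid$gx * 100 + stats::runif(P, -10, 10)
        y <- grid$gy * 100 + stats::runif(P, -10, 10)
        if (trt == "control") {
          canopy <- pmin(pmax(stats::rnorm(P, 0.85, 0.02), 0), 1)
          deadwood <- stats::rlnorm(P, log(5), 0.2)
        } else {
          gap <- sample(seq(0, 1, length.out = P))  # constructed spread
          canopy <- pmin(pmax(0.85 - 0.5 * gap + stats::rnorm(P, 0, 0.02), 0), 1)
          deadwood <- (5 + 45 * gap) * stats::rlnorm(P, 0, 0.2)
        }
        base <- stats::rnorm(5, 5, 0.5)
        E <- sapply(1:5, function(j) base[j] + stats::rnorm(P, 0, 0.15))
        E[, 1] <- E[, 1] + 0.5 * (0.85 - canopy)   # moisture-like link to opening
        rows[[length(rows) + 1L]] <- data.frame(
          site = sprintf("S%02d", s),
          district = sprintf("S%02d_%s", s, trt),
          treatment = trt,
          patch = sprintf("S%02d_%s_p%02d", s, trt, seq_len(P)),
          x = x, y = y, canopy = canopy, deadwood = deadwood,
          E1 = E[, 1], E2 = E[, 2], E3 = E[, 3], E4 = E[, 4], E5 = E[, 5],
          stringsAsFactors = FALSE)
      }
    }
    structure(list(patches = do.call(rbind, rows), n_sites = n_sites,
                   patches_per_district = P, config = config),
              class = "landscape")
  })
}

# Distance matrix between the patches of one district.
.district_distmat <- function(pd) {
  as.matrix(stats::dist(cbind(pd$x, pd$y)))
}

# Species-sorting intensity: Gaussian niche match on scaled canopy and
# deadwood axes, weighted by regional abundance.
.sorting_intensity <- function(pool, pd, nb) {
  dw_scaled <- pmin(pd$deadwood / 50, 1)
  match_canopy <- exp(-outer(pool$opt_canopy, pd$canopy, "-")^2 / (2 * nb^2))
  match_dw <- exp(-outer(pool$opt_deadwood, dw_scaled, "-")^2 / (2 * (2 * nb)^2))
  pool$regional_abund * match_canopy * match_dw
}

# Patch-dynamics occupancy: seeded colonization-extinction. Every species
# starts from one founder patch and spreads for a few steps with
# distance-decaying colonization pressure; species regionally extinct are
# re-seeded (persistence at the regional level through recolonization, the
# patch-dynamics premise). The short, seeded spread leaves occupancy
# clustered around founders, which is what produces the archetype's
# distance decay of community similarity. Species are binned into dispersal
# classes so each step is a handful of matrix products.
.patchdyn_occupancy <- function(pool, dmat, steps = 5, ext = 0.05, col_rate = 5,
                                nbins = 5) {
  S <- nrow(pool)
  P <- nrow(dmat)
  qs <- unique(stats::quantile(pool$dispersal, seq(0, 1, length.out = nbins + 1)))
  bin <- cut(pool$dispersal, qs, include.lowest = TRUE, labels = FALSE)
  kernels <- lapply(seq_along(qs[-1]), function(b) {
    scale_b <- stats::median(pool$dispersal[bin == b])
    K <- exp(-dmat / scale_b)
    diag(K) <- 0
    K
  })
  occ <- matrix(FALSE, S, P)
  occ[cbind(seq_len(S), sample.int(P, S, replace = TRUE))] <- TRUE
  for (t in seq_len(steps)) {
    pressure <- matrix(0, S, P)
    for (b in seq_along(kernels)) {
      sel <- bin == b
      if (any(sel)) pressure[sel, ] <- occ[sel, , drop = FALSE] %*% kernels[[b]]
    }
    p_col <- 1 - exp(-col_rate * pressure)
    col_ev <- matrix(stats::runif(S * P), S, P) < p_col
    ext_ev <- matrix(stats::runif(S * P), S, P) < ext
    occ <- (occ & !ext_ev) | (!occ & col_ev)
    dead <- rowSums(occ) == 0
    if (any(dead)) occ[cbind(which(dead), sample.int(P, sum(dead), replace = TRUE))] <- TRUE
  }
  occ
}

#' Assemble latent communities on a landscape
#'
#' Expected patch composition is an additive mixture on intensities of four
#' components: species sorting (Gaussian niche match to patch environment),
#' mass effect (sorting intensity at source patches, weighted by their
#' resource level and diffused over the exponential dispersal kernel),
#' patch dynamics (occupancy from seeded colonization-extinction with
#' distance-decaying colonization), and neutral (regional abundances,
#' identical across patches). Each component is normalized to unit district
#' total — preserving its own between-patch total structure — then latent
#' counts are Poisson draws from the mixed intensity.
#'
#' @param landscape from [generate_landscape()].
#' @param pool from [generate_species_pool()].
#' @param config `archetype_config` shared with both.
#' @return named list (by district id) of species x patch latent count
#'   matrices.
#' @export
assemble_communities <- function(landscape, pool, config) {
  stopifnot(inherits(landscape, "landscape"))
  w <- config$w
  patches <- landscape$patches
  districts <- unique(patches$district)
  .with_seed(config$seed + 2L, {
    out <- lapply(districts, function(d) {
      pd <- patches[patches$district == d, ]
      P <- nrow(pd)
      dmat <- .district_distmat(pd)
      total <- config$patch_lambda * P

      comp <- list()
      if (w["sorting"] > 0 || w["mass"] > 0) {
        sorting <- .sorting_intensity(pool, pd, config$niche_breadth)
      }
      comp$sorting <- if (w["sorting"] > 0) sorting else NULL
      if (w["mass"] > 0) {
        resource <- 0.2 + pmin(pd$deadwood / 50, 1) + (0.85 - pd$canopy)
        source_int <- sweep(sorting, 2, resource, "*")
        qs <- unique(stats::quantile(pool$dispersal, seq(0, 1, length.out = 6)))
        bin <- cut(pool$dispersal, qs, include.lowest = TRUE, labels = FALSE)
        mass <- matrix(0, nrow(pool), P)
        for (b in seq_along(qs[-1])) {
          sel <- bin == b
          if (!any(sel)) next
          K <- exp(-dmat / stats::median(pool$dispersal[sel]))
          mass[sel, ] <- source_int[sel, , drop = FALSE] %*% K
        }
        comp$mass <- mass
      }
      if (w["patchdyn"] > 0) {
        occ <- .patchdyn_occupancy(pool, dmat)
        comp$patchdyn <- pool$regional_abund * occ
      }
      if (w["neutral"] > 0) {
        comp$neutral <- matrix(pool$regional_abund, nrow(pool), P)
      }
      lambda <- matrix(0, nrow(pool), P)
      for (nm in names(comp)) {
        if (is.null(comp[[nm]]) || w[[nm]] == 0) next
        cs <- sum(comp[[nm]])
        if (cs > 0) lambda <- lambda + w[[nm]] * comp[[nm]] / cs
      }
      zc <- matrix(stats::rpois(length(lambda), total * lambda), nrow(pool), P,
                   dimnames = list(pool$species, pd$patch))
      zc
    })
    names(out) <- districts
    out
  })
}

#' Binomial under-sampling of latent communities
#'
#' Independent binomial thinning of every latent count, emulating incomplete
#' trapping: at realistic fractions this yields many singletons, which is
#' what the coverage standardization downstream is for.
#'
#' @param latent list of latent count matrices (from
#'   [assemble_communities()]).
#' @param sampling_fraction detection probability in (0, 1].
#' @param seed RNG seed.
#' @param meta `landscape` (used to label the resulting assemblage sets).
#' @return named list of `assemblage_set` objects, one per district.
#' @export
sample_communities <- function(latent, sampling_fraction, seed = 1, meta = NULL) {
  if (sampling_fraction <= 0 || sampling_fraction > 1) {
    stop("sampling_fraction must be in (0, 1]")
  }
  .with_seed(seed, {
    out <- lapply(names(latent), function(d) {
      zc <- latent[[d]]
      zs <- matrix(stats::rbinom(length(zc), as.vector(zc), sampling_fraction),
                   nrow(zc), ncol(zc), dimnames = dimnames(zc))
      site <- NA; trt <- NA
      if (!is.null(meta)) {
        pd <- meta$patches[meta$patches$district == d, ]
        site <- pd$site[1]; trt <- pd$treatment[1]
      }
      assemblage_set(zs, site = site, district = d, treatment = trt)
    })
    names(out) <- names(latent)
    out
  })
}

#' Simulate a full synthetic metacommunity
#'
#' Convenience wrapper: species pool, landscape, latent assembly and
#' binomial sampling in one deterministic step.
#'
#' @param n_sites number of paired sites (default 11, the study design).
#' @param patches_per_district 9 or 15.
#' @param config `archetype_config`.
#' @return list of class `metacommunity`: `landscape`, `pool`, `latent`,
#'   `communities` (assemblage sets by district), `traits` (trait table
#'   rownamed by species), `config`.
#' @export
simulate_metacommunity <- function(n_sites = 11, patches_per_district = 9,
                                   config = archetype_config()) {
  pool <- generate_species_pool(config)
  landscape <- generate_landscape(n_sites, patches_per_district, config)
  latent <- assemble_communities(landscape, pool, config)
  communities <- sample_communities(latent, config$sampling_fraction,
                                    seed = config$seed + 3L, meta = landscape)
  traits <- pool[, c("t_niche", "t_disp", "body_size", "guild")]
  rownames(traits) <- pool$species
  structure(list(landscape = landscape, pool = pool, latent = latent,
                 communities = communities, traits = traits, config = config),
            class = "metacommunity")
}
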
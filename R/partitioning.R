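#' Construct an assemblage set
#'
#' A set of N patch assemblages over a shared species list: the unit of
#' gamma/alpha/beta decomposition. Stored as a species x patch count matrix
#' plus design labels.
#'
#' @param z species x patch matrix of nonnegative integer counts (rownames =
#'   species, colnames = patch ids).
#' @param site,district,treatment design labels (scalars).
#' @return object of class `assemblage_set`.
#' @export
assemblage_set <- function(z, site = NA, district = NA, treatment = NA) {
  z <- as.matrix(z)
  if (any(z < 0) || any(is.na(z))) stop("counts must be nonnegative and non-missing")
  if (is.null(rownames(z))) rownames(z) <- paste0("sp", seq_len(nrow(z)))
  if (is.null(colnames(z))) colnames(z) <- paste0("patch", seq_len(ncol(z)))
  structure(list(z = z, site = site, district = district, treatment = treatment),
            class = "assemblage_set")
}

#' @export
print.assemblage_set <- function(x, ...) {
  cat("assemblage_set:", nrow(x$z), "species x", ncol(x$z), "patches",
      "| site", x$site, "| district", x$district, "| treatment", x$treatment, "\n")
  invisible(x)
}

#' Jaccard-type turnover (1-S transformation) of multiplicative beta
#'
#' Maps beta from \[1, N\] onto \[0, 1\]:
#' \eqn{1-S = (1 - 1/\beta)/(1 - 1/N)}; 0 means identical patch
#' compositions, 1 completely disjunct ones.
#'
#' @param beta multiplicative beta-diversity in \[1, N\].
#' @param N number of assemblages.
#' @param tol tolerance for clamping beta at the boundary (default 1e-9).
#' @return dissimilarity in \[0, 1\].
#' @export
one_minus_S <- function(beta, N, tol = 1e-9) {
  if (N < 2) stop("N must be >= 2")
  if (any(beta < 1 - tol) || any(beta > N + tol)) {
    stop("beta outside [1, N]: ", paste(signif(beta[beta < 1 - tol | beta > N + tol], 6), collapse = ", "))
  }
  beta <- pmin(pmax(beta, 1), N)
  (1 - 1 / beta) / (1 - 1 / N)
}

# Local-RNG helper: evaluates expr under a fixed seed and restores the
# caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Multiplicative gamma = alpha x beta decomposition of an assemblage set
#'
#' Gamma is the (optionally coverage-standardized) Hill number of the pooled
#' assemblage; alpha is 1/N times the Hill number of the joint distribution
#' that treats every (species, patch) cell as a category — the only alpha
#' that keeps beta in \[1, N\] for all q; beta = gamma/alpha, reported with
#' its 1-S (Jaccard-type turnover) normalization. Both gamma and alpha are
#' standardized to the same coverage target.
#'
#' @param A `assemblage_set`.
#' @param q diversity order.
#' @param facet `"TD"` (taxonomic) or `"FD"` (functional).
#' @param coverage `NULL` for the observed (reference-sample) decomposition,
#'   or a coverage target in (0, 1).
#' @param D `trait_dist` object (required for FD).
#' @param fd_draws Monte-Carlo subsample draws for FD rarefaction.
#' @param fd_seed seed for the FD rarefaction draws.
#' @param cap_mult extrapolation cap multiplier.
#' @return list with `gamma`, `alpha`, `beta` (clamped into \[1, N\]),
#'   `beta_raw` (= gamma/alpha exactly), `dissim` (1-S), `q`, `facet`,
#'   `coverage`, `N`, `flag`.
#' @export
decompose <- function(A, q, facet = "TD", coverage = NULL, D = NULL,
                      fd_draws = 25, fd_seed = 1, cap_mult = 2) {
  stopifnot(inherits(A, "assemblage_set"))
  facet <- match.arg(facet, c("TD", "FD"))
  z <- A$z
  N <- ncol(z)
  if (N < 2) stop("need at least 2 patches for beta-diversity")
  if (any(colSums(z) == 0)) stop("empty patch in assemblage set")
  if (facet == "FD" && is.null(D)) stop("FD requested without a trait distance matrix")
  pooled <- rowSums(z)
  joint <- as.numeric(z)
  flag <- "ok"
  if (is.null(coverage)) {
    if (facet == "TD") {
      gamma <- hill_number(pooled, q)
      alpha <- hill_number(joint, q) / N
    } else {
      keep <- pooled > 0
      W <- .fd_weights(D, rownames(z)[keep])
      px <- pooled[keep]
      names(px) <- rownames(z)[keep]
      gamma <- functional_hill_number(px, D, q)
      alpha <- .fd_joint(z[keep, , drop = FALSE], W, q) / N
    }
  } else {
    mg <- size_for_coverage(pooled, coverage, cap_mult)
    ma <- size_for_coverage(joint, coverage, cap_mult)
    if (mg$flag != "ok" || ma$flag != "ok") flag <- "coverage_unreachable"
    if (facet == "TD") {
      gamma <- hill_at_size(pooled, mg$m, q)
      alpha <- hill_at_size(joint, ma$m, q) / N
    } else {
      keep <- pooled > 0
      W <- .fd_weights(D, rownames(z)[keep])
      gamma <- .with_seed(fd_seed, .fd_at_size(pooled[keep], W, q, mg$m, fd_draws))
      alpha <- .with_seed(fd_seed + 1, .fd_at_size(z[keep, , drop = FALSE], W, q, ma$m, fd_draws)) / N
    }
  }
  beta_raw <- gamma / alpha
  beta <- pmin(pmax(beta_raw, 1), N)
  list(gamma = gamma, alpha = alpha, beta = beta, beta_raw = beta_raw,
       dissim = one_minus_S(beta, N), q = q, facet = facet,
       coverage = if (is.null(coverage)) NA_real_ else coverage, N = N, flag = flag)
}

#' Pairwise patch-level dissimilarity within an assemblage set
#'
#' Runs the N = 2 decomposition for every unordered patch pair and returns
#' the 1-S turnover per pair. Pairs involving an empty patch are skipped
#' with a warning.
#'
#' @inheritParams decompose
#' @return data.frame with columns `patch_a`, `patch_b`, `dissim`, `beta`,
#'   `gamma`, `alpha`.
#' @export
pairwise_beta <- function(A, q, facet = "TD", coverage = NULL, D = NULL,
                          fd_draws = 25, fd_seed = 1, cap_mult = 2) {
  stopifnot(inherits(A, "assemblage_set"))
  z <- A$z
  N <- ncol(z)
  if (N < 2) stop("need at least 2 patches")
  patches <- colnames(z)
  totals <- colSums(z)
  pairs <- utils::combn(N, 2)
  out <- vector("list", ncol(pairs))
  skipped <- 0L
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (totals[a] == 0 || totals[b] == 0) {
      skipped <- skipped + 1L
      next
    }
    sub <- assemblage_set(z[, c(a, b), drop = FALSE], A$site, A$district, A$treatment)
    dec <- decompose(sub, q, facet, coverage, D, fd_draws, fd_seed + j, cap_mult)
    out[[j]] <- data.frame(patch_a = patches[a], patch_b = patches[b],
                           dissim = dec$dissim, beta = dec$beta,
                           gamma = dec$gamma, alpha = dec$alpha,
                           stringsAsFactors = FALSE)
  }
  if (skipped > 0) warning(skipped, " patch pair(s) skipped (empty patch)")
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
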
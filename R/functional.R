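#' Gower distance matrix from a mixed-type trait table
#'
#' Range-normalized numeric traits, 0/1 mismatch for categorical traits,
#' averaged over non-missing traits (computed via [cluster::daisy()]). The
#' functional-group threshold tau defaults to the mean off-diagonal distance
#' ("dmean" convention).
#'
#' @param traits data.frame of traits, one row per species (rownames =
#'   species); columns numeric, ordered, or factor/character.
#' @param tau functional-distinctness threshold; default mean off-diagonal
#'   Gower distance.
#' @return object of class `trait_dist`: list with `d` (symmetric matrix in
#'   \[0,1\], zero diagonal) and `tau`.
#' @export
gower_distance <- function(traits, tau = NULL) {
  if (nrow(traits) < 2) stop("need at least 2 species")
  if (any(apply(traits, 1, function(r) all(is.na(r))))) stop("all-missing trait row")
  traits <- as.data.frame(traits)
  for (j in seq_along(traits)) {
    if (is.character(traits[[j]]) || is.logical(traits[[j]])) {
      traits[[j]] <- factor(traits[[j]])
    }
  }
  d <- as.matrix(cluster::daisy(traits, metric = "gower"))
  rownames(d) <- colnames(d) <- rownames(traits)
  if (is.null(tau)) tau <- mean(d[upper.tri(d)])
  if (is.na(tau) || tau <= 0) stop("tau must be positive (all species functionally identical?)")
  structure(list(d = d, tau = tau), class = "trait_dist")
}

# Functional similarity weights 1 - min(d, tau)/tau for a species subset.
.fd_weights <- function(D, species, tau = NULL) {
  if (is.null(tau)) tau <- D$tau
  d <- D$d
  missing <- setdiff(species, rownames(d))
  if (length(missing) > 0) stop("species missing from trait distance matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  dm <- d[species, species, drop = FALSE]
  1 - pmin(dm, tau) / tau
}

#' Functional Hill number (attribute diversity) of an assemblage
#'
#' Effective number of functionally distinct groups under the
#' tau-thresholded attribute-diversity framework: each species' attribute
#' abundance is \eqn{a_i = \sum_j (1 - \min(d_{ij},\tau)/\tau) p_j}, and
#' \eqn{{}^qFD = (\sum_i p_i a_i^{q-1})^{1/(1-q)}} with the q = 1 limit
#' \eqn{\exp(-\sum_i p_i \ln a_i)}. When all between-species distances reach
#' tau this reduces to the taxonomic Hill number; when all distances are 0 it
#' equals 1.
#'
#' @param x named abundance vector (names = species).
#' @param D `trait_dist` object covering all species with positive counts.
#' @param q diversity order.
#' @param tau optional threshold override.
#' @return effective number of functional groups.
#' @export
functional_hill_number <- function(x, D, q, tau = NULL) {
  x <- x[x > 0]
  if (length(x) == 0) stop("all-zero abundance vector")
  if (is.null(names(x))) stop("abundance vector must be named by species")
  p <- as.numeric(x) / sum(x)
  W <- .fd_weights(D, names(x), tau)
  a <- as.numeric(W %*% p)
  if (abs(q - 1) < 1e-10) exp(-sum(p * log(a))) else sum(p * a^(q - 1))^(1 / (1 - q))
}

# Attribute diversity of the joint (species x patch) distribution. Cell
# proportions p_ik = z_ik / n_total; the cell attribute is the within-patch
# sum a_ik = sum_j w_ij p_jk, which makes the joint diversity exactly
# N x gamma-FD for N identical equally sized patches.
.fd_joint <- function(z, W, q) {
  n <- sum(z)
  P <- z / n
  A <- W %*% P            # a_ik for every cell
  keep <- P > 0
  p <- P[keep]
  a <- A[keep]
  if (abs(q - 1) < 1e-10) exp(-sum(p * log(a))) else sum(p * a^(q - 1))^(1 / (1 - q))
}

# Seeded hypergeometric subsample of a count vector (without replacement).
.subsample_counts <- function(x, m) {
  n <- sum(x)
  if (m >= n) return(x)
  ids <- rep.int(seq_along(x), x)
  take <- sample(ids, m, replace = FALSE)
  tabulate(take, nbins = length(x))
}

# Coverage-standardized functional diversity by Monte-Carlo rarefaction:
# evaluate attribute diversity on hypergeometric subsamples of the
# coverage-matched size m*; observed proportions are used when m* >= n
# (unseen species carry no trait information). `z` may be a vector (gamma)
# or a species x patch matrix (joint alpha); W is the similarity matrix for
# the species rows of `z`.
.fd_at_size <- function(z, W, q, m, ndraws = 25) {
  zv <- as.numeric(z)
  n <- sum(zv)
  eval_fd <- function(zz) {
    if (is.matrix(z)) {
      .fd_joint(matrix(zz, nrow = nrow(z)), W, q)
    } else {
      keep <- zz > 0
      p <- zz[keep] / sum(zz)
      a <- as.numeric(W[keep, keep, drop = FALSE] %*% p)
      if (abs(q - 1) < 1e-10) exp(-sum(p * log(a))) else sum(p * a^(q - 1))^(1 / (1 - q))
    }
  }
  m_int <- min(round(m), n)
  if (m_int >= n) return(eval_fd(zv))
  mean(vapply(seq_len(ndraws), function(b) eval_fd(.subsample_counts(zv, m_int)), numeric(1)))
}
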
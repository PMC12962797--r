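#' Chao-style bootstrap of an assemblage statistic
#'
#' Augments the species list with the Chao1 estimate of undetected species,
#' assigns them equal shares of the estimated coverage deficit, shrinks
#' detected probabilities accordingly, resamples n individuals multinomially
#' per replicate, and recomputes the statistic. With no singletons the
#' augmentation vanishes and this is a plain multinomial bootstrap of the
#' observed proportions.
#'
#' @param x named abundance vector.
#' @param statistic function of a named count vector returning a scalar.
#' @param B bootstrap replicates (default 200).
#' @param seed RNG seed.
#' @param augment add estimated undetected species (default TRUE; turn off
#'   for statistics, such as trait-based ones, undefined for unseen species).
#' @return list with `value` (observed statistic), `se`, `ci` (2.5/97.5
#'   percentiles), `replicates`, `B`.
#' @export
bootstrap_estimate <- function(x, statistic, B = 200, seed = 1, augment = TRUE) {
  if (B < 2) stop("B must be >= 2")
  x <- x[x > 0]
  if (is.null(names(x))) names(x) <- paste0("sp", seq_along(x))
  n <- sum(x)
  pool <- .bootstrap_probs(x, augment)
  reps <- .with_seed(seed, {
    draws <- stats::rmultinom(B, n, pool)
    rownames(draws) <- names(pool)
    apply(draws, 2, statistic)
  })
  list(value = statistic(x), se = stats::sd(reps),
       ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE),
       replicates = reps, B = B)
}

# Bootstrap cell probabilities: observed proportions shrunk by the coverage
# deficit, plus ceiling(f0) unseen categories sharing the deficit equally.
.bootstrap_probs <- function(x, augment = TRUE) {
  n <- sum(x)
  phat <- x / n
  Chat <- sample_coverage(x)
  f0 <- if (augment) ceiling(estimate_f0(x)) else 0
  if (f0 == 0 || Chat >= 1) return(phat)
  lam <- (1 - Chat) / sum(phat * (1 - phat)^n)
  ptilde <- phat * (1 - lam * (1 - phat)^n)
  p0 <- rep((1 - Chat) / f0, f0)
  names(p0) <- paste0(".unseen", seq_len(f0))
  c(ptilde, p0)
}

#' Bootstrap replicate assemblage sets
#'
#' Resamples the joint (species x patch) cell distribution of an assemblage
#' set Chao-bootstrap style: the cell vector is augmented with estimated
#' undetected cells (each becoming a new pseudo-species assigned to a patch
#' drawn proportionally to patch totals) and n individuals are resampled
#' multinomially per replicate.
#'
#' @param A `assemblage_set`.
#' @param B replicates.
#' @param seed RNG seed.
#' @param augment augment with unseen cells (default TRUE).
#' @return list of `B` assemblage sets.
#' @export
bootstrap_assemblages <- function(A, B = 200, seed = 1, augment = TRUE) {
  stopifnot(inherits(A, "assemblage_set"))
  z <- A$z
  S <- nrow(z); N <- ncol(z)
  joint <- as.numeric(z)                     # column-major cell vector
  keep <- which(joint > 0)
  xk <- joint[keep]
  names(xk) <- paste0("c", keep)
  pool <- .bootstrap_probs(xk, augment)
  n <- sum(z)
  unseen <- grepl("^\\.unseen", names(pool))
  n_unseen <- sum(unseen)
  obs_row <- (keep - 1L) %% S + 1L
  obs_col <- (keep - 1L) %/% S + 1L
  .with_seed(seed, {
    patch_of_unseen <- if (n_unseen > 0) {
      sample.int(N, n_unseen, replace = TRUE, prob = colSums(z) / n)
    } else integer(0)
    lapply(seq_len(B), function(b) {
      draw <- stats::rmultinom(1, n, pool)[, 1]
      zb <- matrix(0L, nrow = S + n_unseen, ncol = N,
                   dimnames = list(c(rownames(z),
                                     if (n_unseen > 0) paste0(".unseen", seq_len(n_unseen))),
                                   colnames(z)))
      zb[cbind(obs_row, obs_col)] <- draw[!unseen]
      if (n_unseen > 0) zb[cbind(S + seq_len(n_unseen), patch_of_unseen)] <- draw[unseen]
      zb <- zb[, colSums(zb) > 0, drop = FALSE]
      assemblage_set(zb, A$site, A$district, A$treatment)
    })
  })
}
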
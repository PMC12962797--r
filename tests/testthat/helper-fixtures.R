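# Shared fixtures and brute-force oracles, all built in code.

# Tiny deterministic assemblage set: S species, N patches, counts from a
# seeded multinomial with patch-specific tilts.
tiny_assemblage <- function(S = 12, N = 4, n_per_patch = 60, seed = 1,
                            site = "S01", district = "S01_ESBC",
                            treatment = "ESBC") {
  set.seed(seed)
  base <- rlnorm(S, 1, 1)
  z <- sapply(seq_len(N), function(k) {
    tilt <- rlnorm(S, 0, 0.6)
    as.integer(rmultinom(1, n_per_patch, base * tilt))
  })
  rownames(z) <- sprintf("sp%02d", seq_len(S))
  colnames(z) <- paste0(district, "_p", seq_len(N))
  assemblage_set(z, site, district, treatment)
}

# Small mixed-type trait table for S species.
tiny_traits <- function(S = 12, seed = 2) {
  set.seed(seed)
  data.frame(num1 = rnorm(S), num2 = runif(S, 0, 10),
             guild = factor(sample(c("a", "b", "c"), S, replace = TRUE)),
             row.names = sprintf("sp%02d", seq_len(S)))
}

# Exhaustive-subsampling oracle: exact hypergeometric expectation of a
# statistic of a size-m subsample of the observed individuals.
enumerate_subsample_expectation <- function(x, m, statistic) {
  x <- x[x > 0]
  n <- sum(x)
  stopifnot(n <= 14, m <= n)
  ids <- rep.int(seq_along(x), x)
  subs <- utils::combn(n, m)
  mean(apply(subs, 2, function(j) statistic(tabulate(ids[j], nbins = length(x)))))
}

# Exhaustive enumeration over multinomial parent samples of size n from a
# known community: exact expectation of a statistic of the sample.
enumerate_parent_expectation <- function(p, n, statistic) {
  S <- length(p)
  stopifnot(S <= 4, n <= 14)
  grid <- do.call(expand.grid, rep(list(0:n), S))
  grid <- grid[rowSums(grid) == n, , drop = FALSE]
  vals <- apply(grid, 1, function(x) statistic(as.numeric(x)))
  probs <- apply(grid, 1, function(x) dmultinom(as.numeric(x), prob = p))
  sum(vals * probs)
}

# Paired-difference stub for meta tests.
pd_stub <- function(delta, se, site = "S01", facet = "TD", scale = "gamma", q = 0) {
  structure(list(site = site, facet = facet, scale = scale, q = q,
                 delta = delta, se = se, method = "stub"),
            class = "paired_difference")
}
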
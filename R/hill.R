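#' Hill number of order q
#'
#' Effective number of equally abundant species,
#' \eqn{{}^qD = (\sum_i p_i^q)^{1/(1-q)}} for \eqn{q \ne 1} and the
#' continuous limit \eqn{\exp(-\sum_i p_i \ln p_i)} at \eqn{q = 1}, summing
#' over species with nonzero counts. q = 0 is species richness, q = 1 the
#' exponential of Shannon entropy, q = 2 the inverse Simpson concentration.
#'
#' @param x abundance vector (nonnegative counts, at least one positive).
#' @param q diversity order, nonnegative real.
#' @return effective species number (>= 1).
#' @export
hill_number <- function(x, q) {
  x <- as.numeric(x)
  x <- x[x > 0]
  if (length(x) == 0) stop("all-zero abundance vector")
  if (q < 0) stop("q must be nonnegative")
  p <- x / sum(x)
  if (abs(q - 1) < 1e-10) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

# Spec'd estimator component: A = (n-1) f1 / ((n-1) f1 + 2 f2), the slope of
# the coverage deficit; shared by sample_coverage and coverage extrapolation
# so that the coverage profile is continuous at m = n.
.coverage_A <- function(n, f1, f2) {
  if (f1 == 0) return(0)
  (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
}

#' Estimated sample coverage of an assemblage
#'
#' Good-Turing coverage estimate
#' \eqn{\hat C = 1 - (f_1/n) \cdot (n-1) f_1 / ((n-1) f_1 + 2 f_2)}:
#' the estimated proportion of total community abundance belonging to species
#' detected in the sample. Returns 1 when there are no singletons.
#'
#' @param x abundance vector.
#' @return coverage estimate in \[0, 1\].
#' @export
sample_coverage <- function(x) {
  fc <- freq_counts(x)
  if (fc$n < 1) stop("empty assemblage")
  if (fc$f1 == 0) return(1)
  1 - fc$f1 / fc$n * .coverage_A(fc$n, fc$f1, fc$f2)
}

#' Expected sample coverage at an arbitrary sample size
#'
#' Coverage rarefaction/extrapolation profile. For integer m < n the
#' unbiased estimator
#' \eqn{\hat C(m) = 1 - \sum_i (x_i/n) \binom{n-x_i}{m} / \binom{n-1}{m}};
#' at m = n it equals [sample_coverage()]; for m > n the geometric
#' extrapolation \eqn{1 - (f_1/n) A^{m-n+1}}. Fractional sizes are linearly
#' interpolated between adjacent integers.
#'
#' @param x abundance vector.
#' @param m sample size(s), >= 1, may be fractional.
#' @return expected coverage, same length as `m`; monotone nondecreasing.
#' @export
coverage_profile <- function(x, m) {
  if (any(m < 1)) stop("m must be >= 1")
  x <- as.numeric(x)
  x <- x[x > 0]
  fc <- freq_counts(x)
  n <- fc$n
  A <- .coverage_A(n, fc$f1, fc$f2)
  cov_int <- function(mi) {
    if (mi < n) {
      xx <- x[(n - x) >= mi]
      1 - sum(xx / n * exp(lchoose(n - xx, mi) - lchoose(n - 1, mi)))
    } else if (mi == n) {
      1 - fc$f1 / n * A
    } else {
      1 - fc$f1 / n * A^(mi - n + 1)
    }
  }
  vapply(m, function(mi) {
    lo <- floor(mi)
    hi <- ceiling(mi)
    if (lo == hi) return(cov_int(mi))
    w <- mi - lo
    (1 - w) * cov_int(lo) + w * cov_int(hi)
  }, numeric(1))
}

# Chao-Wang-Jost asymptotic Shannon entropy estimator. The tail series
# (1-A)^(1-n) * (-log A - sum_{r<n} (1-A)^r / r) is evaluated as the
# equivalent convergent series sum_{j>=1} (1-A)^j / (j + n - 1) to avoid
# overflow at large n.
.entropy_asymptotic <- function(x) {
  x <- as.numeric(x)
  x <- x[x > 0]
  n <- sum(x)
  if (n < 2) return(0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  part1 <- sum(x / n * (digamma(n) - digamma(x)))
  if (f1 == 0) return(part1)
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2) else if (f1 > 1) 2 / ((n - 1) * (f1 - 1) + 2) else 1
  if (A >= 1) return(part1)
  r <- 1 - A
  jmax <- min(1e6, ceiling(log(1e-14) / log(r)))
  j <- seq_len(jmax)
  tail <- sum(r^j / (j + n - 1))
  part1 + f1 / n * tail
}

# Expected Hill number of integer-size subsamples / extrapolated samples.
# Interpolation (m <= n) uses exact hypergeometric expectations; the q = 2
# estimator is a single closed form valid for every m >= 1; extrapolation
# uses the Chao1-governed richness form (q = 0) and a sample-size-weighted
# mix of observed and asymptotic entropy (q = 1).
.hill_size_int <- function(x, m, q) {
  x <- as.numeric(x)
  x <- x[x > 0]
  n <- sum(x)
  S_obs <- length(x)
  if (m < 1) stop("m must be >= 1")
  if (abs(q - 2) < 1e-10) {
    inner <- sum(x * (x - 1)) / (n * (n - 1))
    return(1 / (1 / m + (1 - 1 / m) * inner))
  }
  if (m <= n) {
    if (q == 0) {
      return(sum(1 - exp(lchoose(n - x, m) - lchoose(n, m))))
    }
    xm <- pmin(x, m)
    idx <- rep(seq_along(x), xm)
    kk <- sequence(xm)
    w <- stats::dhyper(kk, x[idx], n - x[idx], m)
    if (abs(q - 1) < 1e-10) {
      return(exp(-sum(w * (kk / m) * log(kk / m))))
    }
    return(sum(w * (kk / m)^q)^(1 / (1 - q)))
  }
  # extrapolation
  f1 <- sum(x == 1)
  if (q == 0) {
    f0 <- estimate_f0(x)
    if (f0 == 0 || f1 == 0) return(S_obs)
    return(S_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^(m - n)))
  }
  if (abs(q - 1) < 1e-10) {
    p <- x / n
    H_obs <- -sum(p * log(p))
    H_asy <- max(.entropy_asymptotic(x), H_obs)
    return(exp(n / m * H_obs + (1 - n / m) * H_asy))
  }
  stop("extrapolation supported for q in {0, 1, 2} only")
}

#' Expected Hill number at an arbitrary sample size
#'
#' Rarefaction (m <= n, exact hypergeometric expectation) and extrapolation
#' (m > n) of the order-q Hill number. Fractional sizes are linearly
#' interpolated between adjacent integers so that coverage-based
#' standardization can operate on a continuous size axis.
#'
#' @param x abundance vector.
#' @param m target sample size(s) >= 1, possibly fractional.
#' @param q diversity order (any q >= 0 for rarefaction; 0, 1, 2 for
#'   extrapolation).
#' @return expected effective species number at each `m`.
#' @export
hill_at_size <- function(x, m, q) {
  vapply(m, function(mi) {
    lo <- floor(mi)
    hi <- ceiling(mi)
    if (lo == hi) return(.hill_size_int(x, mi, q))
    w <- mi - lo
    (1 - w) * .hill_size_int(x, lo, q) + w * .hill_size_int(x, hi, q)
  }, numeric(1))
}

#' Invert the coverage profile: sample size matching a target coverage
#'
#' Finds the (fractional) sample size m* whose expected coverage equals the
#' target, by monotone search over integers and linear interpolation in
#' between. When the target exceeds the coverage attainable at the
#' extrapolation cap (`cap_mult * n`), the cap is returned with a flag.
#'
#' @param x abundance vector.
#' @param target coverage target in (0, 1).
#' @param cap_mult extrapolation cap as a multiple of n (default 2).
#' @return list with `m` (size), `coverage` (achieved), `flag`
#'   (`"ok"` or `"coverage_unreachable"`).
#' @export
size_for_coverage <- function(x, target, cap_mult = 2) {
  if (target <= 0 || target >= 1) stop("coverage target must be in (0, 1)")
  fc <- freq_counts(x)
  n <- fc$n
  cap <- max(ceiling(cap_mult * n), 2)
  cov_cap <- coverage_profile(x, cap)
  if (target >= cov_cap) {
    return(list(m = cap, coverage = cov_cap, flag = if (target > cov_cap + 1e-12) "coverage_unreachable" else "ok"))
  }
  cov1 <- coverage_profile(x, 1)
  if (target <= cov1) return(list(m = 1, coverage = cov1, flag = "ok"))
  lo <- 1L
  hi <- as.integer(cap)
  # smallest integer with coverage >= target
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (coverage_profile(x, mid) >= target) hi <- mid else lo <- mid
  }
  c_lo <- coverage_profile(x, lo)
  c_hi <- coverage_profile(x, hi)
  m_star <- if (c_hi - c_lo > 1e-14) lo + (target - c_lo) / (c_hi - c_lo) else as.numeric(hi)
  list(m = m_star, coverage = target, flag = "ok")
}

#' Coverage-standardized Hill number
#'
#' Standardizes an assemblage's order-q diversity to a common coverage level:
#' inverts the coverage profile to the matching (fractional) sample size and
#' evaluates the expected Hill number there.
#'
#' @param x abundance vector.
#' @param coverage target coverage in (0, 1).
#' @param q diversity order.
#' @param cap_mult extrapolation cap multiplier (default 2).
#' @return list with `value`, `m`, `coverage`, `flag`.
#' @export
standardize_to_coverage <- function(x, coverage, q, cap_mult = 2) {
  sz <- size_for_coverage(x, coverage, cap_mult)
  if (sz$flag != "ok") {
    warning("coverage target ", coverage, " unreachable at extrapolation cap; returning estimate at the cap")
  }
  list(value = hill_at_size(x, sz$m, q), m = sz$m, coverage = sz$coverage, flag = sz$flag)
}

#' Shared coverage target for a set of compared assemblages
#'
#' Operationalizes standardization "to a fraction of the maximum of the
#' observed distribution": the target is `mult` times C_max, where C_max is
#' the minimum, across the compared assemblages, of the expected coverage at
#' each assemblage's extrapolation cap (2n by default). The target is then
#' always reachable for every assemblage.
#'
#' @param xs list of abundance vectors.
#' @param mult coverage multiplier (default 0.95).
#' @param cap_mult extrapolation cap multiplier (default 2).
#' @return coverage target in (0, 1).
#' @export
coverage_target <- function(xs, mult = 0.95, cap_mult = 2) {
  if (!is.list(xs)) xs <- list(xs)
  cmax <- min(vapply(xs, function(x) {
    n <- sum(as.numeric(x)[as.numeric(x) > 0])
    coverage_profile(x, max(ceiling(cap_mult * n), 2))
  }, numeric(1)))
  mult * cmax
}
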
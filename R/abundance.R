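#' Construct an abundance vector
#'
#' The atom of all diversity computations: a named vector of nonnegative
#' integer species counts for one assemblage. Zero counts are kept (they are
#' ignored by the estimators) so that species lists can stay aligned across
#' assemblages.
#'
#' @param x numeric vector of nonnegative integer counts, optionally named by
#'   species.
#' @return an object of class `abundance` (a named integer vector).
#' @export
abundance <- function(x) {
  if (length(x) == 0) stop("empty abundance vector")
  if (any(is.na(x))) stop("NA counts are not allowed")
  if (any(x < 0)) stop("negative counts are not allowed")
  if (any(abs(x - round(x)) > 1e-8)) stop("counts must be integers")
  v <- as.integer(round(x))
  if (is.null(names(x))) names(v) <- paste0("sp", seq_along(v)) else names(v) <- names(x)
  structure(v, class = c("abundance", "integer"))
}

#' Frequency-count summary of an abundance vector
#'
#' @param x counts.
#' @return list with `n` (total individuals), `S_obs` (observed richness),
#'   `f1`, `f2` (singleton and doubleton counts).
#' @export
freq_counts <- function(x) {
  x <- as.numeric(x)
  pos <- x[x > 0]
  list(n = sum(pos), S_obs = length(pos),
       f1 = sum(pos == 1), f2 = sum(pos == 2))
}

#' Chao1-style estimate of undetected richness
#'
#' f0 = ((n-1)/n) f1^2 / (2 f2); bias-corrected fallback
#' ((n-1)/n) f1 (f1-1) / 2 when f2 = 0.
#'
#' @param x counts.
#' @return nonnegative estimate of the number of undetected species.
#' @export
estimate_f0 <- function(x) {
  fc <- freq_counts(x)
  if (fc$n < 1) stop("empty assemblage")
  if (fc$f1 == 0) return(0)
  if (fc$f2 > 0) {
    (fc$n - 1) / fc$n * fc$f1^2 / (2 * fc$f2)
  } else {
    (fc$n - 1) / fc$n * fc$f1 * (fc$f1 - 1) / 2
  }
}
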
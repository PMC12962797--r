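#' Patch-pair predictors: structural, abiotic and spatial distance
#'
#' For every unordered within-district patch pair, three nonnegative
#' predictors: structural distance (Euclidean on z-standardized canopy
#' density and deadwood volume), abiotic distance (Euclidean across
#' z-standardized Ellenberg-style indicator means, light excluded), and
#' spatial distance (Euclidean meters on projected coordinates).
#' Standardization is across all patches of the analysis set pooled over
#' sites (default) so effect sizes are comparable across sites; per-site
#' scaling is available as a sensitivity flag.
#'
#' @param patches data.frame with columns site, district, treatment, patch,
#'   x, y, canopy, deadwood, and the indicator columns.
#' @param ellenberg_cols names of the indicator columns (default
#'   `E1`..`E5`).
#' @param scale_scope `"pooled"` (default) or `"site"`.
#' @return data.frame keyed (site, district, treatment, patch_a, patch_b)
#'   with `structural`, `abiotic`, `spatial`, plus the raw canopy and
#'   deadwood differences.
#' @export
pair_predictors <- function(patches, ellenberg_cols = paste0("E", 1:5),
                            scale_scope = c("pooled", "site")) {
  scale_scope <- match.arg(scale_scope)
  need <- c("site", "district", "treatment", "patch", "x", "y", "canopy", "deadwood", ellenberg_cols)
  miss <- setdiff(need, names(patches))
  if (length(miss) > 0) stop("missing patch columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(patches[, c("x", "y", "canopy", "deadwood", ellenberg_cols)])))) {
    stop("non-finite environment or coordinate values")
  }
  zscale <- function(df) {
    cbind(struct = scale(df[, c("canopy", "deadwood")]),
          abio = scale(df[, ellenberg_cols]))
  }
  if (scale_scope == "pooled") {
    Z <- zscale(patches)
  } else {
    Z <- matrix(NA_real_, nrow(patches), 2 + length(ellenberg_cols))
    for (s in unique(patches$site)) {
      i <- patches$site == s
      Z[i, ] <- zscale(patches[i, ])
    }
  }
  sm <- Z[, 1:2, drop = FALSE]
  am <- Z[, -(1:2), drop = FALSE]
  out <- list()
  for (d in unique(patches$district)) {
    i <- which(patches$district == d)
    if (length(i) < 2) next
    prs <- utils::combn(length(i), 2)
    a <- i[prs[1, ]]; b <- i[prs[2, ]]
    out[[d]] <- data.frame(
      site = patches$site[a], district = d, treatment = patches$treatment[a],
      patch_a = patches$patch[a], patch_b = patches$patch[b],
      structural = sqrt(rowSums((sm[a, , drop = FALSE] - sm[b, , drop = FALSE])^2)),
      abiotic = sqrt(rowSums((am[a, , drop = FALSE] - am[b, , drop = FALSE])^2)),
      spatial = sqrt((patches$x[a] - patches$x[b])^2 + (patches$y[a] - patches$y[b])^2),
      d_canopy = abs(patches$canopy[a] - patches$canopy[b]),
      d_deadwood = abs(patches$deadwood[a] - patches$deadwood[b]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Structural distance between two patch environments
#'
#' Euclidean distance on (canopy, deadwood) after z-standardization across
#' the reference patch set.
#'
#' @param env_a,env_b lists/rows with `canopy` and `deadwood`.
#' @param ref data.frame of all patches defining the standardization.
#' @return nonnegative scalar.
#' @export
structural_distance <- function(env_a, env_b, ref) {
  for (e in list(env_a, env_b)) {
    if (is.null(e$canopy) || is.null(e$deadwood) || is.na(e$canopy) || is.na(e$deadwood)) {
      stop("patch missing canopy or deadwood value")
    }
  }
  mu <- c(mean(ref$canopy), mean(ref$deadwood))
  sg <- c(stats::sd(ref$canopy), stats::sd(ref$deadwood))
  sg[sg == 0] <- 1
  za <- (c(env_a$canopy, env_a$deadwood) - mu) / sg
  zb <- (c(env_b$canopy, env_b$deadwood) - mu) / sg
  sqrt(sum((za - zb)^2))
}

#' Abiotic distance between two patches (Ellenberg indicator space)
#'
#' Euclidean distance across z-standardized indicator dimensions (light
#' excluded upstream).
#'
#' @param e_a,e_b indicator vectors of equal length.
#' @param ref matrix/data.frame of all patches' indicator values defining
#'   the standardization.
#' @return nonnegative scalar.
#' @export
abiotic_distance <- function(e_a, e_b, ref) {
  e_a <- as.numeric(e_a); e_b <- as.numeric(e_b)
  if (length(e_a) != length(e_b)) stop("indicator vectors differ in length")
  ref <- as.matrix(ref)
  if (ncol(ref) != length(e_a)) stop("reference has wrong number of indicator columns")
  mu <- colMeans(ref)
  sg <- apply(ref, 2, stats::sd)
  sg[sg == 0] <- 1
  sqrt(sum(((e_a - mu) / sg - (e_b - mu) / sg)^2))
}

#' Spatial distance between two patches in meters
#'
#' @param a,b coordinate pairs `c(x, y)` in projected meters.
#' @return Euclidean distance in meters.
#' @export
spatial_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 2 || length(b) != 2 || any(!is.finite(c(a, b)))) {
    stop("coordinates must be finite (x, y) pairs")
  }
  sqrt(sum((a - b)^2))
}
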
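#' Write communities as a long-format CSV
#'
#' Canonical on-disk representation: one row per (site, district, treatment,
#' patch, species) with a positive abundance; sparse, human-diffable,
#' RFC-4180 CSV.
#'
#' @param communities named list of `assemblage_set`s.
#' @param path output file.
#' @export
write_community <- function(communities, path) {
  rows <- lapply(communities, function(A) {
    z <- A$z
    idx <- which(z > 0, arr.ind = TRUE)
    data.frame(site = A$site, district = A$district, treatment = A$treatment,
               patch = colnames(z)[idx[, 2]], species = rownames(z)[idx[, 1]],
               abundance = z[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$district, out$patch, out$species), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Delimiter sniffing: comma or tab, whichever splits the header wider.
.read_delim_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1)
  sep <- if (length(strsplit(hdr, "\t")[[1]]) > length(strsplit(hdr, ",")[[1]])) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "", fileEncoding = "UTF-8")
}

#' Read a long-format community table into assemblage sets
#'
#' Validates the table (required columns, nonnegative integer abundances,
#' unique keys, known treatment labels, treatment constant within district —
#' violations are reported with data row numbers), drops zero-abundance rows
#' with a message, harmonizes the species list across each site's districts,
#' and returns one `assemblage_set` per district.
#'
#' @param path CSV or TSV file.
#' @return named list of `assemblage_set`s keyed by district.
#' @export
read_community <- function(path) {
  df <- .read_delim_table(path)
  need <- c("site", "district", "treatment", "patch", "species", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  rowno <- seq_len(nrow(df)) + 1L  # file line numbers (header = line 1)
  bad <- which(!is.finite(df$abundance) | df$abundance < 0 | df$abundance != round(df$abundance))
  if (length(bad) > 0) {
    stop("invalid abundance at line(s) ", paste(utils::head(rowno[bad], 5), collapse = ", "))
  }
  bad <- which(!df$treatment %in% c("ESBC", "control"))
  if (length(bad) > 0) {
    stop("unknown treatment label at line(s) ", paste(utils::head(rowno[bad], 5), collapse = ", "))
  }
  key <- paste(df$site, df$district, df$patch, df$species, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (site, district, patch, species) at line(s) ",
         paste(utils::head(rowno[dup], 5), collapse = ", "))
  }
  for (d in unique(df$district)) {
    if (length(unique(df$treatment[df$district == d])) > 1) {
      stop("treatment not constant within district ", d)
    }
  }
  nzero <- sum(df$abundance == 0)
  if (nzero > 0) {
    message("dropping ", nzero, " zero-abundance row(s)")
    df <- df[df$abundance > 0, ]
  }
  out <- list()
  for (s in unique(df$site)) {
    ds <- df[df$site == s, ]
    species <- sort(unique(ds$species))  # union across the site's districts
    for (d in unique(ds$district)) {
      dd <- ds[ds$district == d, ]
      patches <- sort(unique(dd$patch))
      z <- matrix(0L, length(species), length(patches),
                  dimnames = list(species, patches))
      z[cbind(match(dd$species, species), match(dd$patch, patches))] <- dd$abundance
      out[[d]] <- assemblage_set(z, site = s, district = d,
                                 treatment = dd$treatment[1])
    }
  }
  out
}

#' Write / read the patch environment table
#'
#' Columns: site, district, treatment, patch, x, y, canopy, deadwood,
#' E1..E5 (Ellenberg-style indicator means, light excluded).
#'
#' @param patches patch data.frame (e.g. `landscape$patches`).
#' @param path file path.
#' @export
write_environment <- function(patches, path) {
  utils::write.csv(patches, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  df <- .read_delim_table(path)
  need <- c("site", "district", "treatment", "patch", "x", "y", "canopy", "deadwood")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Write / read the species trait table
#'
#' @param traits trait data.frame rownamed by species.
#' @param path file path.
#' @export
write_traits <- function(traits, path) {
  out <- cbind(species = rownames(traits), traits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  df <- .read_delim_table(path)
  if (!"species" %in% names(df)) stop("trait table needs a 'species' column")
  rn <- df$species
  df$species <- NULL
  rownames(df) <- rn
  df
}

#' Run configuration with the study's default settings
#'
#' Defaults reproduce the stated analysis settings: coverage multiplier
#' 0.95, q in {0, 1, 2}, both facets, 200 bootstrap replicates, 100 null
#' replicates. A YAML file can override any field.
#'
#' @param path optional YAML file.
#' @param ... direct overrides.
#' @return list of settings.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(coverage_mult = 0.95, qs = c(0, 1, 2), facets = c("TD", "FD"),
              B = 200, R = 100, seed = 1, scale_scope = "pooled",
              null_scope = "site", meta_method = "FE", fd_draws = 25,
              cap_mult = 2)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

# Provenance sidecar: enough to reproduce a run bit-for-bit.
.write_provenance <- function(path, cfg, extra = list()) {
  prov <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 package_version = as.character(utils::packageVersion("patchdiv"))),
            cfg, extra)
  yaml::write_yaml(prov, path)
  invisible(path)
}
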
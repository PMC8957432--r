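#' Nodal station distance bands
#'
#' Nodal stations are grouped by distance from the primary tumour into three
#' bands: locoregional (within 5 cm), intermediate (between 5 and 10 cm,
#' alongside the great vessels) and central (more than 10 cm, at the origin
#' of the great vessels). The order of the vector is the anatomical order
#' used for sorting and for monotonicity of [classify_distance()].
#'
#' @export
distance_bands <- c("locoregional", "intermediate", "central")

#' Tumour site vocabulary
#'
#' The eight primary tumour localisations recognised by the station map,
#' from cecum to inferior rectum.
#'
#' @export
tumor_sites <- c(
  "cecum", "ascending", "transverse", "descending",
  "sigmoid", "superior_rectum", "middle_rectum", "inferior_rectum"
)

#' Classify tumour-to-station distance into a band
#'
#' Maps a distance (cm) from the primary tumour to one of the three station
#' bands. The boundary convention is closed on the left band: `[0, 5]` is
#' locoregional, `(5, 10]` intermediate and `(10, Inf)` central, so that
#' "within 5 cm" includes 5 cm exactly. The convention is centralised here
#' and used everywhere else.
#'
#' @param distance_cm non-negative finite distance(s) in cm.
#' @return ordered factor with levels `locoregional < intermediate < central`.
#' @examples
#' classify_distance(c(0, 3, 5, 7.5, 10, 12))
#' @export
classify_distance <- function(distance_cm) {
  if (!is.numeric(distance_cm) || any(!is.finite(distance_cm))) {
    abort2("nodeconcord_domain_error",
           "classify_distance(): distance must be finite and numeric")
  }
  if (any(distance_cm < 0)) {
    abort2("nodeconcord_domain_error",
           "classify_distance(): distance must be non-negative")
  }
  idx <- ifelse(distance_cm <= 5, 1L, ifelse(distance_cm <= 10, 2L, 3L))
  factor(distance_bands[idx], levels = distance_bands, ordered = TRUE)
}

registry_columns <- c("code", "band", "anatomic_label", "applicable_sites")

validate_registry_df <- function(df, source = "registry") {
  missing_cols <- setdiff(registry_columns, names(df))
  if (length(missing_cols) > 0) {
    abort2("nodeconcord_format_error",
           sprintf("%s: missing column(s): %s", source,
                   paste(missing_cols, collapse = ", ")))
  }
  df <- df[registry_columns]
  df$code <- as.character(df$code)
  df$band <- as.character(df$band)
  df$anatomic_label <- as.character(df$anatomic_label)
  df$applicable_sites <- as.character(df$applicable_sites)

  bad_band <- which(!df$band %in% distance_bands)
  if (length(bad_band) > 0) {
    abort2("nodeconcord_format_error",
           sprintf("%s: unknown band '%s' at line %d (allowed: %s)",
                   source, df$band[bad_band[1]], bad_band[1] + 1L,
                   paste(distance_bands, collapse = ", ")))
  }
  dup <- which(duplicated(df$code))
  if (length(dup) > 0) {
    abort2("nodeconcord_format_error",
           sprintf("%s: duplicated station code '%s' at line %d",
                   source, df$code[dup[1]], dup[1] + 1L))
  }
  sites_list <- strsplit(df$applicable_sites, ";", fixed = TRUE)
  for (i in seq_along(sites_list)) {
    bad <- setdiff(trimws(sites_list[[i]]), tumor_sites)
    if (length(bad) > 0) {
      abort2("nodeconcord_format_error",
             sprintf("%s: unknown tumour site '%s' at line %d (allowed: %s)",
                     source, bad[1], i + 1L, paste(tumor_sites, collapse = ", ")))
    }
  }
  # completeness: at least one station per band for every site
  for (site in tumor_sites) {
    has_site <- vapply(sites_list, function(s) site %in% trimws(s), logical(1))
    bands_here <- unique(df$band[has_site])
    missing_bands <- setdiff(distance_bands, bands_here)
    if (length(missing_bands) > 0) {
      abort2("nodeconcord_format_error",
             sprintf("%s: site '%s' has no station in band(s): %s",
                     source, site, paste(missing_bands, collapse = ", ")))
    }
  }
  df$band <- factor(df$band, levels = distance_bands, ordered = TRUE)
  class(df) <- c("station_registry", "data.frame")
  df
}

#' Load a station registry from a TSV file
#'
#' The registry file is UTF-8 tab-separated with header
#' `code<TAB>band<TAB>anatomic_label<TAB>applicable_sites`; sites are
#' semicolon-separated labels from [tumor_sites]. Station codes must be
#' unique, every band label must be one of [distance_bands], and every
#' tumour site must be covered by at least one station per band.
#'
#' @param path path to the TSV file.
#' @return a `station_registry` data frame.
#' @seealso [default_registry()], [write_registry()]
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) {
    abort2("nodeconcord_format_error",
           sprintf("registry file not found: %s", path))
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  validate_registry_df(df, source = basename(path))
}

#' Write a station registry to a TSV file
#'
#' Inverse of [load_registry()]; `load_registry(write_registry(r, f))`
#' reproduces `r` field for field.
#'
#' @param registry a `station_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "station_registry"))
  out <- as.data.frame(registry)
  out$band <- as.character(out$band)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Default station registry
#'
#' A compact JSCCR-style registry shipped with the package: one station per
#' band for each of the eight tumour sites (24 stations). The two codes with
#' published site attachments are included as such: station 241
#' (paracolic, sigmoid) and station 251 (superior rectal). The full official
#' JSCCR atlas is deliberately not reproduced; supply your own TSV via
#' [load_registry()] for real station-level work.
#'
#' @return a `station_registry` data frame.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "stations_default.tsv",
                      package = "nodeconcord", mustWork = TRUE)
  load_registry(path)
}

#' Stations applicable to a tumour site
#'
#' Returns the subset of the registry whose `applicable_sites` contains
#' `site`, ordered band-then-code.
#'
#' @param registry a `station_registry`.
#' @param site one of [tumor_sites].
#' @return a `station_registry` subset (never empty for a valid registry).
#' @examples
#' stations_for_site(default_registry(), "sigmoid")
#' @export
stations_for_site <- function(registry, site) {
  stopifnot(inherits(registry, "station_registry"))
  if (length(site) != 1 || !site %in% tumor_sites) {
    abort2("nodeconcord_domain_error",
           sprintf("unknown tumour site '%s' (allowed: %s)",
                   as.character(site)[1], paste(tumor_sites, collapse = ", ")))
  }
  keep <- vapply(strsplit(registry$applicable_sites, ";", fixed = TRUE),
                 function(s) site %in% trimws(s), logical(1))
  out <- registry[keep, , drop = FALSE]
  out <- out[order(out$band, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# map station codes to bands; errors on codes absent from the registry
station_band <- function(codes, registry) {
  stopifnot(inherits(registry, "station_registry"))
  idx <- match(as.character(codes), registry$code)
  if (anyNA(idx)) {
    bad <- unique(as.character(codes)[is.na(idx)])
    abort2("nodeconcord_domain_error",
           sprintf("station code(s) not in registry: %s",
                   paste(bad, collapse = ", ")))
  }
  registry$band[idx]
}

#' @export
print.station_registry <- function(x, ...) {
  cat(sprintf("<station_registry> %d stations (%s)\n", nrow(x),
              paste(sprintf("%s: %d", distance_bands,
                            table(factor(x$band, levels = distance_bands))),
                    collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}
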
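#' Enhancement pattern vocabulary
#'
#' The five internal enhancement patterns read on the venous phase of
#' contrast-enhanced CT: homogenous, dotted (small spots of enhancement),
#' linear (belt-like low enhancement), central (bright central spot) and
#' peripheral (hypodense centre, hyperdense rim). This is a closed
#' vocabulary; the spelling "homogeneous" is accepted as an input alias of
#' "homogenous" by [validate_pattern()].
#'
#' @export
enhancement_patterns <- c("homogenous", "dotted", "linear", "central", "peripheral")

#' Suspicion criteria names
#'
#' The three morphological criteria of suspicion recorded per CT-visible
#' node, in the canonical column order of the CT node table.
#'
#' @export
suspicion_criteria <- c("roundness", "heterogeneous_density", "irregular_border")

#' Classify node short-axis size into a bin
#'
#' Nodes are grouped by short-axis diameter into three bins: small
#' (< 5 mm), mid (5-10 mm) and large (> 10 mm). Both boundaries belong to
#' the mid bin: the definitions "< 5", "5-10" and "> 10" make `[5, 10]`
#' inclusive at both ends the only consistent partition of `(0, Inf)`.
#'
#' @param short_axis_mm positive finite short-axis diameter(s) in mm.
#' @return ordered factor with levels `small < mid < large`.
#' @examples
#' classify_size_bin(c(4, 5, 10, 34))
#' @export
classify_size_bin <- function(short_axis_mm) {
  if (!is.numeric(short_axis_mm) || any(!is.finite(short_axis_mm))) {
    abort2("nodeconcord_domain_error",
           "classify_size_bin(): size must be finite and numeric")
  }
  if (any(short_axis_mm <= 0)) {
    abort2("nodeconcord_domain_error",
           "classify_size_bin(): size must be positive")
  }
  idx <- ifelse(short_axis_mm < 5, 1L, ifelse(short_axis_mm <= 10, 2L, 3L))
  factor(c("small", "mid", "large")[idx],
         levels = c("small", "mid", "large"), ordered = TRUE)
}

#' Size-conditional suspicion rule
#'
#' A CT-visible node is labelled suspicious depending on its size bin and
#' on how many of the three criteria of suspicion (roundness, heterogeneous
#' density, irregular border) are present:
#' nodes under 5 mm need all three criteria; nodes of 5-10 mm need at least
#' two; nodes over 10 mm are always suspicious.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param short_axis_mm positive short-axis diameter(s) in mm.
#' @param roundness,heterogeneous_density,irregular_border logical flags.
#' @return logical vector: `TRUE` where the node is suspicious.
#' @examples
#' is_suspicious(4, TRUE, TRUE, TRUE)    # TRUE: all three criteria
#' is_suspicious(12, FALSE, FALSE, FALSE) # TRUE: size alone
#' @export
is_suspicious <- function(short_axis_mm, roundness, heterogeneous_density,
                          irregular_border) {
  bin <- classify_size_bin(short_axis_mm)
  n_crit <- as.integer(roundness) + as.integer(heterogeneous_density) +
    as.integer(irregular_border)
  if (any(is.na(n_crit))) {
    abort2("nodeconcord_domain_error",
           "is_suspicious(): criteria flags must be non-missing logicals")
  }
  unname(
    (bin == "small" & n_crit == 3L) |
      (bin == "mid" & n_crit >= 2L) |
      (bin == "large")
  )
}

#' Validate an enhancement-pattern label
#'
#' Case-insensitive match against [enhancement_patterns]; "homogeneous" is
#' accepted as an alias of the canonical spelling "homogenous". Any other
#' label (including the historical "spotted", which the dotted pattern
#' resembles but does not alias) is a vocabulary error.
#'
#' @param label character vector of pattern labels.
#' @return character vector of canonical pattern labels.
#' @examples
#' validate_pattern(c("Dotted", "homogeneous"))
#' @export
validate_pattern <- function(label) {
  x <- tolower(trimws(as.character(label)))
  x[x == "homogeneous"] <- "homogenous"
  bad <- setdiff(unique(x), enhancement_patterns)
  if (length(bad) > 0) {
    abort2("nodeconcord_vocabulary_error",
           sprintf("unknown enhancement pattern '%s' (allowed: %s)",
                   bad[1], paste(enhancement_patterns, collapse = ", ")))
  }
  x
}

ct_columns <- c("node_id", "patient_id", "station_code", "short_axis_mm",
                "roundness", "heterogeneous_density", "irregular_border",
                "pattern")

#' Read and validate a CT node table
#'
#' Reads the CT node CSV (columns `node_id, patient_id, station_code,
#' short_axis_mm, roundness, heterogeneous_density, irregular_border,
#' pattern`; flags as 0/1). The derived `suspicious` column is always
#' recomputed from the rule in [is_suspicious()]; if the file carries a
#' `suspicious` column, stored values inconsistent with the rule are a hard
#' error, protecting every downstream concordance statistic.
#'
#' @param path CSV file path, or a data frame already in the schema.
#' @return data frame with the canonical columns plus logical flags and a
#'   recomputed `suspicious` column.
#' @export
read_ct_nodes <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ct_columns, names(df))
  if (length(missing_cols) > 0) {
    abort2("nodeconcord_format_error",
           sprintf("CT node table: missing column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  stored_suspicious <- if ("suspicious" %in% names(df))
    check_flag01(df$suspicious, "suspicious") else NULL
  df$short_axis_mm <- as.numeric(df$short_axis_mm)
  for (cc in suspicion_criteria) df[[cc]] <- check_flag01(df[[cc]], cc)
  df$pattern <- validate_pattern(df$pattern)
  df$station_code <- as.character(df$station_code)
  df$suspicious <- is_suspicious(df$short_axis_mm, df$roundness,
                                 df$heterogeneous_density, df$irregular_border)
  if (!is.null(stored_suspicious) && !identical(stored_suspicious, df$suspicious)) {
    bad <- which(stored_suspicious != df$suspicious)
    abort2("nodeconcord_format_error",
           sprintf(paste0("CT node table: stored 'suspicious' flag disagrees ",
                          "with the suspicion rule for node(s): %s"),
                   paste(utils::head(df$node_id[bad], 5), collapse = ", ")))
  }
  df[c(ct_columns, "suspicious")]
}
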
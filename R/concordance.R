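#' Concordance category of a station
#'
#' Classifies a station by its CT-suspicious count and its histologically
#' positive count: `positive` (suspicious nodes and positive nodes),
#' `negative` (neither), `false_positive` (suspicious on CT, nothing
#' positive under the microscope) and `false_negative` (positive nodes the
#' imaging criteria did not match).
#'
#' @param n_suspicious,n_positive non-negative counts (vectorised).
#' @return factor with the four category levels.
#' @examples
#' correlation_category(3, 2)  # positive
#' correlation_category(0, 4)  # false_negative
#' @export
correlation_category <- function(n_suspicious, n_positive) {
  if (any(!is.finite(n_suspicious)) || any(!is.finite(n_positive)) ||
      any(n_suspicious < 0) || any(n_positive < 0)) {
    abort2("nodeconcord_domain_error",
           "correlation_category(): counts must be non-negative")
  }
  lv <- c("positive", "negative", "false_positive", "false_negative")
  out <- ifelse(n_suspicious > 0,
                ifelse(n_positive > 0, "positive", "false_positive"),
                ifelse(n_positive > 0, "false_negative", "negative"))
  factor(out, levels = lv)
}

#' Suspicious-to-positive ratio (SPR)
#'
#' The ratio between the number of CT-suspicious nodes and the number of
#' histologically positive nodes, the concordance statistic this analysis
#' is organised around. With zero positive nodes the ratio is undefined and
#' reported as `NA` - never as 0 or infinity.
#'
#' @param n_suspicious,n_positive non-negative counts (vectorised).
#' @return numeric; `NA` where `n_positive == 0`.
#' @examples
#' compute_spr(241, 412)
#' @export
compute_spr <- function(n_suspicious, n_positive) {
  if (any(!is.finite(n_suspicious)) || any(!is.finite(n_positive)) ||
      any(n_suspicious < 0) || any(n_positive < 0)) {
    abort2("nodeconcord_domain_error",
           "compute_spr(): counts must be non-negative")
  }
  ifelse(n_positive > 0, n_suspicious / n_positive, NA_real_)
}

#' Lymph node ratio (LNR)
#'
#' Metastatic nodes divided by harvested nodes.
#'
#' @param n_positive count of metastatic nodes, `0 <= n_positive <= n_harvested`.
#' @param n_harvested count of harvested nodes, must be positive.
#' @return numeric in `[0, 1]`.
#' @examples
#' compute_lnr(170, 1809)
#' @export
compute_lnr <- function(n_positive, n_harvested) {
  if (any(!is.finite(n_positive)) || any(!is.finite(n_harvested)) ||
      any(n_harvested <= 0) || any(n_positive < 0) ||
      any(n_positive > n_harvested)) {
    abort2("nodeconcord_domain_error",
           "compute_lnr(): need 0 <= n_positive <= n_harvested, n_harvested > 0")
  }
  n_positive / n_harvested
}

histo_columns <- c("node_id", "patient_id", "station_code", "metastatic")

#' Read and validate a histology node table
#'
#' Columns: `node_id, patient_id, station_code, metastatic` (flag 0/1).
#'
#' @param path CSV file path, or a data frame already in the schema.
#' @return validated data frame with a logical `metastatic` column.
#' @export
read_histo_nodes <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(histo_columns, names(df))
  if (length(missing_cols) > 0) {
    abort2("nodeconcord_format_error",
           sprintf("histology node table: missing column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  df$metastatic <- check_flag01(df$metastatic, "metastatic")
  df$station_code <- as.character(df$station_code)
  df[histo_columns]
}

patient_columns <- c("patient_id", "sex", "age", "tumor_site")

#' Read and validate a patient table
#'
#' Required columns: `patient_id, sex, age, tumor_site`; the staging
#' columns `pT, pN, pM` are optional and may be blank.
#'
#' @param path CSV file path, or a data frame already in the schema.
#' @return validated data frame.
#' @export
read_patients <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(patient_columns, names(df))
  if (length(missing_cols) > 0) {
    abort2("nodeconcord_format_error",
           sprintf("patient table: missing column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$patient_id)) {
    abort2("nodeconcord_format_error", "patient table: duplicated patient_id")
  }
  bad <- setdiff(unique(df$tumor_site), tumor_sites)
  if (length(bad) > 0) {
    abort2("nodeconcord_format_error",
           sprintf("patient table: unknown tumour site '%s'", bad[1]))
  }
  df
}

#' Station-level concordance of CT and histology node sets
#'
#' Aggregates both node tables per station (node-to-node identity across
#' modalities is never assumed: CT typically sees fewer nodes than the
#' pathologist harvests) and assigns each station that appears in either
#' table its concordance category via [correlation_category()].
#'
#' @param ct_nodes CT node table ([read_ct_nodes()] schema).
#' @param histo_nodes histology node table ([read_histo_nodes()] schema).
#' @param registry a `station_registry`; every station code must resolve.
#' @return data frame with one row per station: `station_code, band, n_ct,
#'   n_suspicious, n_harvested, n_positive, spr, category`.
#' @export
station_concordance <- function(ct_nodes, histo_nodes, registry) {
  ct <- read_ct_nodes(ct_nodes)
  hi <- read_histo_nodes(histo_nodes)
  codes <- sort(unique(c(ct$station_code, hi$station_code)))
  band <- station_band(codes, registry)
  count_by <- function(code, vec_codes, w = NULL) {
    if (is.null(w)) w <- rep(1L, length(vec_codes))
    vapply(code, function(cd) sum(w[vec_codes == cd]), numeric(1))
  }
  n_ct <- count_by(codes, ct$station_code)
  n_suspicious <- count_by(codes, ct$station_code, as.integer(ct$suspicious))
  n_harvested <- count_by(codes, hi$station_code)
  n_positive <- count_by(codes, hi$station_code, as.integer(hi$metastatic))
  data.frame(
    station_code = codes,
    band = band,
    n_ct = n_ct,
    n_suspicious = n_suspicious,
    n_harvested = n_harvested,
    n_positive = n_positive,
    spr = compute_spr(n_suspicious, n_positive),
    category = correlation_category(n_suspicious, n_positive),
    row.names = NULL
  )
}

#' Per-pattern association with metastasis
#'
#' For each enhancement pattern `k`, builds the 2x2 table (pattern `k` vs
#' all other patterns) x (metastatic vs non-metastatic) and estimates the
#' odds of metastasis for pattern `k` relative to the pooled rest, with the
#' Haldane-Anscombe zero-cell correction enabled. The orientation is always
#' the odds of metastasis; for patterns the literature reads as markers of
#' benign nodes (homogenous), the reciprocal gives the non-metastasis
#' orientation.
#'
#' @param pattern character vector of pattern labels ([validate_pattern()]).
#' @param metastatic logical vector, same length.
#' @return data frame with one row per pattern present in the data:
#'   `pattern, n, n_metastatic, odds_ratio, ci_low, ci_high, p_value,
#'   correction_applied`.
#' @export
pattern_association <- function(pattern, metastatic) {
  if (length(pattern) == 0) {
    abort2("nodeconcord_domain_error", "pattern_association(): empty input")
  }
  if (length(pattern) != length(metastatic)) {
    abort2("nodeconcord_domain_error",
           "pattern_association(): pattern and metastatic lengths differ")
  }
  pattern <- validate_pattern(pattern)
  metastatic <- as.logical(metastatic)
  present <- enhancement_patterns[enhancement_patterns %in% pattern]
  if (length(present) < 2) {
    abort2("nodeconcord_domain_error",
           "pattern_association(): all nodes share one pattern; comparison group is empty")
  }
  rows <- lapply(present, function(k) {
    is_k <- pattern == k
    or <- odds_ratio(contingency_2x2(
      sum(is_k & metastatic), sum(is_k & !metastatic),
      sum(!is_k & metastatic), sum(!is_k & !metastatic)
    ), zero_cell_correction = TRUE)
    data.frame(pattern = k, n = sum(is_k), n_metastatic = sum(is_k & metastatic),
               odds_ratio = or$odds_ratio, ci_low = or$ci_low,
               ci_high = or$ci_high, p_value = or$p_value,
               correction_applied = or$correction_applied)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-level concordance summary
#'
#' The full concordance analysis of one cohort:
#' \itemize{
#'   \item per-band and per-site SPR, pooling suspicious and positive counts
#'     before dividing (a ratio of sums, never a mean of ratios);
#'   \item overall LNR;
#'   \item the node-level 2x2 cross-tabulating CT nodes against a
#'     station-level metastasis label (a CT node counts as LNM+ iff its
#'     patient-station contains at least one metastatic harvested node) -
#'     a reconstruction, since CT and histology node sets cannot be matched
#'     one to one - with chi-square and diagnostic metrics;
#'   \item the patient-level 2x2 (test-positive iff >= 1 suspicious node,
#'     disease-positive iff >= 1 metastatic node) with diagnostic metrics;
#'   \item per-patient-station concordance category counts and the
#'     per-pattern odds ratios.
#' }
#'
#' @param patients patient table ([read_patients()] schema).
#' @param ct_nodes CT node table ([read_ct_nodes()] schema).
#' @param histo_nodes histology node table ([read_histo_nodes()] schema).
#' @param registry a `station_registry` (default [default_registry()]).
#' @param yates pass the Yates correction through to the node-level chi-square.
#' @return object of class `cohort_summary`.
#' @export
cohort_summary <- function(patients, ct_nodes, histo_nodes,
                           registry = default_registry(), yates = FALSE) {
  pats <- read_patients(patients)
  ct <- read_ct_nodes(ct_nodes)
  hi <- read_histo_nodes(histo_nodes)

  orphan <- setdiff(unique(c(ct$patient_id, hi$patient_id)), pats$patient_id)
  if (length(orphan) > 0) {
    abort2("nodeconcord_integrity_error",
           sprintf("node tables reference unknown patient_id(s): %s",
                   paste(utils::head(orphan, 5), collapse = ", ")))
  }
  ct$band <- station_band(ct$station_code, registry)
  hi$band <- station_band(hi$station_code, registry)

  pooled_spr <- function(split_ct, split_hi, levels) {
    s <- vapply(levels, function(l) sum(ct$suspicious[split_ct == l]), numeric(1))
    p <- vapply(levels, function(l) sum(hi$metastatic[split_hi == l]), numeric(1))
    data.frame(level = levels, n_suspicious = s, n_positive = p,
               spr = compute_spr(s, p), row.names = NULL)
  }
  spr_band <- pooled_spr(ct$band, hi$band, distance_bands)
  names(spr_band)[1] <- "band"
  site_of <- stats::setNames(pats$tumor_site, pats$patient_id)
  spr_site <- pooled_spr(site_of[ct$patient_id], site_of[hi$patient_id],
                         tumor_sites)
  names(spr_site)[1] <- "tumor_site"

  lnr <- compute_lnr(sum(hi$metastatic), nrow(hi))

  # node-level 2x2: station-level metastasis label per patient-station
  ps_positive <- unique(paste(hi$patient_id, hi$station_code, sep = "\r")[hi$metastatic])
  ct_lnm <- paste(ct$patient_id, ct$station_code, sep = "\r") %in% ps_positive
  node_table <- contingency_2x2(
    sum(ct$suspicious & ct_lnm), sum(ct$suspicious & !ct_lnm),
    sum(!ct$suspicious & ct_lnm), sum(!ct$suspicious & !ct_lnm)
  )
  node_chisq <- tryCatch(pearson_chi_square(node_table, yates = yates),
                         nodeconcord_domain_error = function(e) NULL)

  # patient-level 2x2
  test_pos <- vapply(pats$patient_id,
                     function(p) any(ct$suspicious[ct$patient_id == p]), logical(1))
  disease_pos <- vapply(pats$patient_id,
                        function(p) any(hi$metastatic[hi$patient_id == p]), logical(1))
  patient_table <- contingency_2x2(
    sum(test_pos & disease_pos), sum(test_pos & !disease_pos),
    sum(!test_pos & disease_pos), sum(!test_pos & !disease_pos)
  )

  # per-patient-station categories
  cats <- unlist(lapply(pats$patient_id, function(p) {
    sc <- station_concordance(ct[ct$patient_id == p, , drop = FALSE],
                              hi[hi$patient_id == p, , drop = FALSE], registry)
    as.character(sc$category)
  }))
  category_counts <- table(factor(cats, levels = levels(correlation_category(0, 0))))

  # per-pattern odds ratios against the station-level metastasis label
  patterns <- tryCatch(pattern_association(ct$pattern, ct_lnm),
                       nodeconcord_domain_error = function(e) NULL)

  out <- list(
    n_patients = nrow(pats),
    n_ct_nodes = nrow(ct),
    n_suspicious = sum(ct$suspicious),
    n_harvested = nrow(hi),
    n_positive = sum(hi$metastatic),
    lnr = lnr,
    spr_band = spr_band,
    spr_site = spr_site,
    node_table = node_table,
    node_chisq = node_chisq,
    node_metrics = diagnostic_metrics(node_table),
    patient_table = patient_table,
    patient_metrics = diagnostic_metrics(patient_table),
    category_counts = category_counts,
    pattern_or = patterns
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patients, %d CT nodes (%d suspicious, %.2f%%), %d harvested (%d positive)\n",
              x$n_patients, x$n_ct_nodes, x$n_suspicious,
              100 * x$n_suspicious / max(x$n_ct_nodes, 1),
              x$n_harvested, x$n_positive))
  cat(sprintf("LNR %.4f | patient-positive %d/%d\n", x$lnr,
              sum(x$patient_table[, 1]), x$n_patients))
  cat("\nSPR by band:\n"); print(x$spr_band, row.names = FALSE)
  cat("\nSPR by tumour site:\n"); print(x$spr_site, row.names = FALSE)
  cat("\nNode-level table (suspicion x station-level LNM label):\n")
  if (!is.null(x$node_chisq)) print(x$node_chisq) else print(x$node_table)
  cat("node-level metrics: ",
      paste(sprintf("%s %.3f", names(x$node_metrics), x$node_metrics),
            collapse = ", "), "\n")
  cat("patient-level metrics:",
      paste(sprintf("%s %.3f", names(x$patient_metrics), x$patient_metrics),
            collapse = ", "), "\n")
  cat("\nConcordance categories (patient-station):\n")
  print(x$category_counts)
  if (!is.null(x$pattern_or)) {
    cat("\nEnhancement-pattern odds ratios (odds of LNM+):\n")
    print(x$pattern_or, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
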
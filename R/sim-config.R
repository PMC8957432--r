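default_site_counts <- c(cecum = 13, ascending = 2, transverse = 10,
                         descending = 6, sigmoid = 20, superior_rectum = 23,
                         middle_rectum = 20, inferior_rectum = 18)

default_target_ors <- c(homogenous = 1 / 1.99, dotted = 7.84, linear = 0.48,
                        central = 2.85, peripheral = 3.25)

sim_config_fields <- c(
  "n_patients", "male_fraction", "age_mean", "age_sd", "age_range",
  "site_probabilities", "harvested_median", "harvested_sdlog",
  "harvested_range", "ct_to_histo_ratio", "size_median_mm", "size_sdlog",
  "size_range_mm", "pattern_prevalences", "overall_node_metastasis_rate",
  "target_pattern_ors", "criteria_sensitivity", "criteria_specificity",
  "patient_positive_fraction", "band_probabilities", "seed"
)

#' Synthetic-cohort configuration
#'
#' Builds (and validates) the full parameterisation of the synthetic cohort
#' generator. Every default reproduces a marginal of the study the
#' generator emulates: 112 patients with a 78:34 male:female split, age
#' 65.60 +/- 10.99 years truncated to 27-88, the eight tumour-site
#' frequencies, about 16 harvested nodes per case (median 15, range 1-60),
#' a CT-visible fraction of 1079/1809, node short-axis sizes log-normal
#' with median 6 mm truncated to 2-34 mm, an overall node metastasis rate
#' of 0.0939 with 33.93% of patients node-positive, and per-pattern
#' metastasis odds-ratio targets (the homogenous target is stored in
#' metastasis orientation as 1/1.99, since that pattern marks
#' non-metastatic nodes).
#'
#' The default `pattern_prevalences` are not free numbers: they are
#' computed by [consistent_pattern_prevalences()] so that the prevalences,
#' the overall rate and all five odds-ratio targets are exactly jointly
#' attainable (anchoring the homogenous:linear ratio at the observed
#' 43.72:28.83 and fixing small central/peripheral prevalences).
#'
#' @param ... named fields overriding the defaults; unknown names are an
#'   error. See the field list in the package vignette.
#' @return validated object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_patients = 10, seed = 7)
#' @export
sim_config <- function(...) {
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    abort2("nodeconcord_config_error", "sim_config(): all arguments must be named")
  }
  unknown <- setdiff(names(over), sim_config_fields)
  if (length(unknown) > 0) {
    abort2("nodeconcord_config_error",
           sprintf("sim_config(): unknown field(s): %s",
                   paste(unknown, collapse = ", ")))
  }
  cfg <- list(
    n_patients = 112L,
    male_fraction = 78 / 112,
    age_mean = 65.60,
    age_sd = 10.99,
    age_range = c(27, 88),
    site_probabilities = default_site_counts / sum(default_site_counts),
    harvested_median = 15,
    harvested_sdlog = 0.4,
    harvested_range = c(1, 60),
    ct_to_histo_ratio = 1079 / 1809,
    size_median_mm = 6,
    size_sdlog = 0.5,
    size_range_mm = c(2, 34),
    pattern_prevalences = NULL,  # filled below unless overridden
    overall_node_metastasis_rate = 0.0939,
    target_pattern_ors = default_target_ors,
    criteria_sensitivity = c(roundness = 0.85, heterogeneous_density = 0.70,
                             irregular_border = 0.60),
    criteria_specificity = c(roundness = 0.78, heterogeneous_density = 0.87,
                             irregular_border = 0.92),
    patient_positive_fraction = 0.3393,
    band_probabilities = c(locoregional = 0.56, intermediate = 0.28,
                           central = 0.16),
    seed = 1L
  )
  cfg[names(over)] <- over
  if (is.null(cfg$pattern_prevalences)) {
    cfg$pattern_prevalences <-
      if (cfg$overall_node_metastasis_rate > 0)
        consistent_pattern_prevalences(cfg$target_pattern_ors,
                                       cfg$overall_node_metastasis_rate)
      else
        stats::setNames(c(0.4372, 0.0593, 0.3460, 0.04, 0.03) /
                          sum(c(0.4372, 0.0593, 0.3460, 0.04, 0.03)),
                        enhancement_patterns)
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) abort2("nodeconcord_config_error", msg)
  chk(is.numeric(cfg$n_patients) && cfg$n_patients >= 1 &&
        cfg$n_patients == round(cfg$n_patients),
      "n_patients must be a positive integer")
  prob1 <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  chk(prob1(cfg$male_fraction), "male_fraction must be a probability in [0, 1]")
  chk(prob1(cfg$overall_node_metastasis_rate) && cfg$overall_node_metastasis_rate < 1,
      "overall_node_metastasis_rate must lie in [0, 1)")
  chk(prob1(cfg$patient_positive_fraction),
      "patient_positive_fraction must be a probability in [0, 1]")
  chk(cfg$overall_node_metastasis_rate <= cfg$patient_positive_fraction ||
        cfg$overall_node_metastasis_rate == 0,
      "overall_node_metastasis_rate cannot exceed patient_positive_fraction")
  simplex <- function(x, n) is.numeric(x) && length(x) == n &&
    all(x >= 0) && abs(sum(x) - 1) <= 1e-9
  chk(simplex(cfg$site_probabilities, 8), "site_probabilities must be 8 values summing to 1")
  chk(simplex(cfg$pattern_prevalences, 5), "pattern_prevalences must be 5 values summing to 1")
  chk(simplex(cfg$band_probabilities, 3), "band_probabilities must be 3 values summing to 1")
  chk(is.numeric(cfg$target_pattern_ors) && length(cfg$target_pattern_ors) == 5 &&
        all(cfg$target_pattern_ors > 0), "target_pattern_ors must be 5 positive values")
  chk(prob1(cfg$criteria_sensitivity) && length(cfg$criteria_sensitivity) == 3,
      "criteria_sensitivity must be 3 probabilities")
  chk(prob1(cfg$criteria_specificity) && length(cfg$criteria_specificity) == 3,
      "criteria_specificity must be 3 probabilities")
  chk(is.numeric(cfg$ct_to_histo_ratio) && cfg$ct_to_histo_ratio > 0 &&
        cfg$ct_to_histo_ratio <= 1, "ct_to_histo_ratio must lie in (0, 1]")
  chk(cfg$age_sd > 0 && length(cfg$age_range) == 2 &&
        cfg$age_range[1] < cfg$age_range[2], "invalid age distribution")
  chk(cfg$harvested_median >= 1 && cfg$harvested_sdlog >= 0 &&
        length(cfg$harvested_range) == 2 &&
        cfg$harvested_range[1] >= 1 &&
        cfg$harvested_range[1] <= cfg$harvested_median &&
        cfg$harvested_median <= cfg$harvested_range[2],
      "invalid harvested-per-case distribution")
  chk(cfg$size_sdlog >= 0 && length(cfg$size_range_mm) == 2 &&
        cfg$size_range_mm[1] > 0 &&
        cfg$size_range_mm[1] <= cfg$size_median_mm &&
        cfg$size_median_mm <= cfg$size_range_mm[2],
      "invalid node size distribution")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed must be a single integer")
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a flat YAML file
#'
#' The file is a flat key:value document whose keys mirror the
#' [sim_config()] field names exactly; vectors are YAML lists. Unknown keys
#' are an error. Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    abort2("nodeconcord_config_error", sprintf("config file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  named_fields <- list(site_probabilities = tumor_sites,
                       pattern_prevalences = enhancement_patterns,
                       target_pattern_ors = enhancement_patterns,
                       criteria_sensitivity = suspicion_criteria,
                       criteria_specificity = suspicion_criteria,
                       band_probabilities = distance_bands)
  for (nf in names(named_fields)) {
    if (!is.null(raw[[nf]])) {
      v <- unlist(raw[[nf]])
      if (!is.null(names(v)) && all(names(v) %in% named_fields[[nf]])) {
        v <- v[named_fields[[nf]]]
      }
      raw[[nf]] <- unname(stats::setNames(as.numeric(v), names(v)))
      names(raw[[nf]]) <- named_fields[[nf]]
    }
  }
  for (nf in c("age_range", "harvested_range", "size_range_mm")) {
    if (!is.null(raw[[nf]])) raw[[nf]] <- as.numeric(unlist(raw[[nf]]))
  }
  do.call(sim_config, raw)
}

#' Write a simulation configuration as flat YAML
#'
#' @param cfg a `sim_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- lapply(unclass(cfg), function(x) if (is.numeric(x)) unname(x) else x)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d patients, seed %d\n", x$n_patients, x$seed))
  cat(sprintf("  node metastasis rate %.4f, patient-positive fraction %.4f\n",
              x$overall_node_metastasis_rate, x$patient_positive_fraction))
  cat(sprintf("  pattern prevalences: %s\n",
              paste(sprintf("%s %.3f", enhancement_patterns,
                            x$pattern_prevalences), collapse = ", ")))
  cat(sprintf("  OR targets: %s\n",
              paste(sprintf("%s %.3g", enhancement_patterns,
                            x$target_pattern_ors), collapse = ", ")))
  invisible(x)
}
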
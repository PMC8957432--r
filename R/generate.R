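# truncated draws by rejection; falls back to the bounds-midpoint only if the
# acceptance region is effectively empty (cannot happen under sane configs)
rtrunc <- function(n, rfun, lower, upper, max_tries = 1000) {
  out <- rfun(n)
  bad <- which(out < lower | out > upper)
  tries <- 0
  while (length(bad) > 0 && tries < max_tries) {
    out[bad] <- rfun(length(bad))
    bad <- which(out < lower | out > upper)
    tries <- tries + 1
  }
  if (length(bad) > 0) out[bad] <- (lower + upper) / 2
  out
}

#' Generate a synthetic CT/histology cohort
#'
#' Simulates one cohort with the statistical structure this package
#' analyses: per patient a sex, an age (truncated normal), a tumour site,
#' and a harvested-node count (rounded log-normal, clamped to the
#' configured range); per harvested node a station (band sampled from the
#' band probabilities, then a uniform station among the registry stations
#' of that band applicable to the patient's site) and a metastatic status.
#' Node positivity is clustered within patients: a latent fraction
#' `patient_positive_fraction` of patients is metastasis-prone and their
#' nodes are positive with probability `rate / fraction`, which preserves
#' the overall node metastasis rate exactly in expectation.
#'
#' A CT-visible subset of the nodes (fraction `ct_to_histo_ratio`) forms
#' the CT table: each visible node gets a short-axis size (truncated
#' log-normal), an enhancement pattern drawn conditionally on its
#' metastatic status from the calibrated pattern-metastasis joint
#' distribution ([calibrate_pattern_probabilities()]), and three criteria
#' flags drawn independently per criterion with the configured
#' sensitivity/specificity against the node's metastasis label. The
#' derived `suspicious` flag always comes from [is_suspicious()].
#'
#' Randomness is hierarchical: each patient has its own substream derived
#' from `config$seed` and the patient index, so patient `i`'s data do not
#' change when `n_patients` changes. The global RNG state is left
#' untouched.
#'
#' @param config a [sim_config()].
#' @param registry a `station_registry` (default [default_registry()]).
#' @return object of class `ln_cohort`: list of data frames `patients`,
#'   `ct_nodes`, `histo_nodes`, plus the `config` used.
#' @examples
#' coh <- generate_cohort(sim_config(n_patients = 5, seed = 1))
#' sapply(coh[c("patients", "ct_nodes", "histo_nodes")], nrow)
#' @export
generate_cohort <- function(config, registry = default_registry()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  rate <- cfg$overall_node_metastasis_rate

  if (rate > 0) {
    p_cond <- calibrate_pattern_probabilities(cfg$target_pattern_ors,
                                              cfg$pattern_prevalences, rate)
    if (abs(attr(p_cond, "achieved_rate") - rate) > 1e-6) {
      abort2("nodeconcord_infeasible_error", paste0(
        "generate_cohort(): pattern prevalences, metastasis rate and OR targets ",
        "are jointly inconsistent; use consistent_pattern_prevalences()"))
    }
    # pattern distribution conditional on node metastasis status (Bayes)
    pat_pos <- cfg$pattern_prevalences * p_cond / rate
    pat_neg <- cfg$pattern_prevalences * (1 - p_cond) / (1 - rate)
    pat_pos <- pat_pos / sum(pat_pos)
    pat_neg <- pat_neg / sum(pat_neg)
    r_prone <- rate / cfg$patient_positive_fraction
  } else {
    pat_pos <- pat_neg <- cfg$pattern_prevalences / sum(cfg$pattern_prevalences)
    r_prone <- 0
  }

  # stations per (site, band), validated up front
  site_band_stations <- lapply(stats::setNames(tumor_sites, tumor_sites),
    function(site) {
      st <- stations_for_site(registry, site)
      lapply(stats::setNames(distance_bands, distance_bands), function(b) {
        codes <- st$code[as.character(st$band) == b]
        if (length(codes) == 0) {
          abort2("nodeconcord_config_error",
                 sprintf("registry lacks a %s station for site %s", b, site))
        }
        codes
      })
    })

  n <- cfg$n_patients
  pat_rows <- vector("list", n)
  ct_rows <- vector("list", n)
  hi_rows <- vector("list", n)

  with_preserved_seed({
    for (i in seq_len(n)) {
      set.seed(substream_seed(cfg$seed, i))
      pid <- sprintf("P%04d", i)
      male <- stats::runif(1) < cfg$male_fraction
      age <- round(rtrunc(1, function(m) stats::rnorm(m, cfg$age_mean, cfg$age_sd),
                          cfg$age_range[1], cfg$age_range[2]), 1)
      site <- sample(tumor_sites, 1, prob = cfg$site_probabilities)
      n_harv <- max(cfg$harvested_range[1],
                    min(cfg$harvested_range[2],
                        round(stats::rlnorm(1, log(cfg$harvested_median),
                                            cfg$harvested_sdlog))))
      prone <- stats::runif(1) < cfg$patient_positive_fraction
      met <- stats::runif(n_harv) < (if (prone) r_prone else 0)

      bands <- sample(distance_bands, n_harv, replace = TRUE,
                      prob = cfg$band_probabilities)
      codes <- vapply(bands, function(b) {
        cand <- site_band_stations[[site]][[b]]
        if (length(cand) == 1) cand else sample(cand, 1)
      }, character(1))

      nid <- sprintf("%s-N%03d", pid, seq_len(n_harv))
      hi_rows[[i]] <- list(node_id = nid, patient_id = rep(pid, n_harv),
                           station_code = unname(codes),
                           metastatic = as.integer(met))

      visible <- stats::runif(n_harv) < cfg$ct_to_histo_ratio
      m <- sum(visible)
      if (m > 0) {
        vmet <- met[visible]
        size <- round(rtrunc(m, function(k)
          stats::rlnorm(k, log(cfg$size_median_mm), cfg$size_sdlog),
          cfg$size_range_mm[1], cfg$size_range_mm[2]), 1)
        pattern <- character(m)
        if (any(vmet)) pattern[vmet] <- sample(enhancement_patterns,
                                               sum(vmet), replace = TRUE,
                                               prob = pat_pos)
        if (any(!vmet)) pattern[!vmet] <- sample(enhancement_patterns,
                                                 sum(!vmet), replace = TRUE,
                                                 prob = pat_neg)
        flag <- function(j) {
          pr <- ifelse(vmet, cfg$criteria_sensitivity[j],
                       1 - cfg$criteria_specificity[j])
          as.integer(stats::runif(m) < pr)
        }
        ct_rows[[i]] <- list(node_id = nid[visible],
                             patient_id = rep(pid, m),
                             station_code = unname(codes[visible]),
                             short_axis_mm = size,
                             roundness = flag(1),
                             heterogeneous_density = flag(2),
                             irregular_border = flag(3),
                             pattern = pattern)
      }

      n_pos <- sum(met)
      pT <- sample(c("T1", "T2", "T3", "T4"), 1,
                   prob = c(4, 13, 57, 38) / 112)
      pat_rows[[i]] <- list(patient_id = pid,
                            sex = if (male) "M" else "F",
                            age = age,
                            tumor_site = site,
                            pT = pT,
                            pN = if (n_pos == 0) "N0" else
                              if (n_pos <= 3) "N1" else "N2",
                            pM = "")
    }
  })

  bind_rows_list <- function(rows) {
    rows <- rows[!vapply(rows, is.null, logical(1))]
    cols <- names(rows[[1]])
    out <- lapply(stats::setNames(cols, cols),
                  function(cn) unlist(lapply(rows, `[[`, cn), use.names = FALSE))
    as.data.frame(out, stringsAsFactors = FALSE)
  }

  ct <- bind_rows_list(ct_rows)
  ct$suspicious <- is_suspicious(ct$short_axis_mm, ct$roundness == 1,
                                 ct$heterogeneous_density == 1,
                                 ct$irregular_border == 1)
  out <- list(patients = bind_rows_list(pat_rows),
              ct_nodes = ct,
              histo_nodes = bind_rows_list(hi_rows),
              config = cfg)
  class(out) <- "ln_cohort"
  out
}

#' @export
print.ln_cohort <- function(x, ...) {
  cat(sprintf("<ln_cohort> %d patients, %d CT nodes, %d harvested nodes (%d metastatic)\n",
              nrow(x$patients), nrow(x$ct_nodes), nrow(x$histo_nodes),
              sum(x$histo_nodes$metastatic)))
  invisible(x)
}

#' Realized vs configured cohort marginals
#'
#' Tabulates, for one simulated cohort, each realized marginal next to its
#' configured target: male fraction, age mean and SD, median harvested
#' nodes per case, node size median and range, pattern prevalences, node
#' metastasis rate and the patient-positive fraction.
#'
#' @param cohort an `ln_cohort` from [generate_cohort()].
#' @return data frame with columns `marginal, configured, realized`.
#' @export
marginal_report <- function(cohort) {
  stopifnot(inherits(cohort, "ln_cohort"))
  cfg <- cohort$config
  pats <- cohort$patients; ct <- cohort$ct_nodes; hi <- cohort$histo_nodes
  harv_per_case <- as.numeric(table(factor(hi$patient_id,
                                           levels = pats$patient_id)))
  pat_pos <- tapply(hi$metastatic, factor(hi$patient_id,
                                          levels = pats$patient_id), sum) > 0
  prev_real <- as.numeric(table(factor(ct$pattern,
                                       levels = enhancement_patterns))) / nrow(ct)
  rows <- rbind(
    data.frame(marginal = "male_fraction", configured = cfg$male_fraction,
               realized = mean(pats$sex == "M")),
    data.frame(marginal = "age_mean", configured = cfg$age_mean,
               realized = mean(pats$age)),
    data.frame(marginal = "age_sd", configured = cfg$age_sd,
               realized = stats::sd(pats$age)),
    data.frame(marginal = "harvested_median", configured = cfg$harvested_median,
               realized = stats::median(harv_per_case)),
    data.frame(marginal = "size_median_mm", configured = cfg$size_median_mm,
               realized = stats::median(ct$short_axis_mm)),
    data.frame(marginal = "size_min_mm", configured = cfg$size_range_mm[1],
               realized = min(ct$short_axis_mm)),
    data.frame(marginal = "size_max_mm", configured = cfg$size_range_mm[2],
               realized = max(ct$short_axis_mm)),
    data.frame(marginal = paste0("pattern_", enhancement_patterns),
               configured = unname(cfg$pattern_prevalences),
               realized = prev_real),
    data.frame(marginal = "node_metastasis_rate",
               configured = cfg$overall_node_metastasis_rate,
               realized = mean(hi$metastatic)),
    data.frame(marginal = "patient_positive_fraction",
               configured = cfg$patient_positive_fraction,
               realized = mean(pat_pos)),
    data.frame(marginal = "ct_to_histo_ratio", configured = cfg$ct_to_histo_ratio,
               realized = nrow(ct) / nrow(hi)),
    data.frame(marginal = "suspicious_fraction", configured = NA_real_,
               realized = mean(ct$suspicious))
  )
  rownames(rows) <- NULL
  rows
}

#' Write a cohort to CSV files
#'
#' Writes `patients.csv`, `ct_nodes.csv` and `histo_nodes.csv` into a
#' directory, in the canonical schemas (flags as 0/1; the derived
#' `suspicious` column is not written - it is recomputed on load).
#'
#' @param cohort an `ln_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ln_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(cohort$patients, "patients.csv")
  wr(cohort$ct_nodes[ct_columns], "ct_nodes.csv")
  wr(cohort$histo_nodes, "histo_nodes.csv")
  invisible(dir)
}

#' Read a cohort from a directory of CSV files
#'
#' Inverse of [write_cohort()]; all three tables are validated and the
#' CT `suspicious` column recomputed.
#'
#' @param dir directory containing `patients.csv`, `ct_nodes.csv`,
#'   `histo_nodes.csv`.
#' @return object of class `ln_cohort` (without a `config`).
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("patients.csv", "ct_nodes.csv", "histo_nodes.csv"))
  missing_files <- need[!file.exists(need)]
  if (length(missing_files) > 0) {
    abort2("nodeconcord_format_error",
           sprintf("cohort directory is missing: %s",
                   paste(basename(missing_files), collapse = ", ")))
  }
  out <- list(patients = read_patients(need[1]),
              ct_nodes = read_ct_nodes(need[2]),
              histo_nodes = read_histo_nodes(need[3]),
              config = NULL)
  class(out) <- "ln_cohort"
  out
}
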
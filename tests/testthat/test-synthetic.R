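test_that("null odds-ratio targets calibrate to the overall rate", {
  p <- calibrate_pattern_probabilities(rep(1, 5), rep(0.2, 5), 0.0939)
  expect_equal(as.numeric(p), rep(0.0939, 5), tolerance = 1e-10)
  expect_equal(attr(p, "achieved_rate"), 0.0939, tolerance = 1e-10)
})

test_that("two-pattern calibration matches a brute-force grid oracle", {
  # consistent two-pattern problem: the rest-pooled OR of pattern 2 is
  # forced to be the reciprocal of pattern 1's
  prev <- c(0.5, 0.5); rate <- 0.2; ors <- c(4, 0.25)
  p <- calibrate_pattern_probabilities(ors, prev, rate)
  # oracle: scan p1 on a 1e-6 grid; p2 from the rate constraint; pick the
  # p1 whose rest-pooled odds ratio is closest to 4
  grid <- seq(1e-6, rate / prev[1] - 1e-6, by = 1e-6)
  p2g <- (rate - prev[1] * grid) / prev[2]
  orr <- (grid / (1 - grid)) / (p2g / (1 - p2g))
  best <- grid[which.min(abs(orr - ors[1]))]
  expect_equal(unname(p[1]), best, tolerance = 1e-5)
  expect_equal(sum(prev * p), rate, tolerance = 1e-8)
  q2 <- (rate - prev[2] * p[2]) / (1 - prev[2])
  expect_equal((p[[2]] / (1 - p[[2]])) / (q2 / (1 - q2)), 0.25,
               tolerance = 1e-6)
})

test_that("over-determined targets warn and report the achieved rate", {
  expect_warning(
    p <- calibrate_pattern_probabilities(
      c(1 / 1.99, 7.84, 0.48, 2.85, 3.25),
      c(0.4372, 0.15, 0.2883, 0.08, 0.0445), 0.0939),
    "over-determined")
  expect_gt(abs(attr(p, "achieved_rate") - 0.0939), 1e-6)
})

test_that("invalid calibration inputs are rejected", {
  expect_error(calibrate_pattern_probabilities(c(1, -2), c(0.5, 0.5), 0.1),
               class = "nodeconcord_domain_error")
  expect_error(calibrate_pattern_probabilities(c(1, 1), c(0.7, 0.5), 0.1),
               class = "nodeconcord_domain_error")
  expect_error(calibrate_pattern_probabilities(c(1, 1), c(0.5, 0.5), 0),
               class = "nodeconcord_domain_error")
})

test_that("default prevalences make rate and all five OR targets jointly exact", {
  cfg <- sim_config()
  p <- calibrate_pattern_probabilities(cfg$target_pattern_ors,
                                       cfg$pattern_prevalences,
                                       cfg$overall_node_metastasis_rate)
  expect_equal(sum(cfg$pattern_prevalences * p),
               cfg$overall_node_metastasis_rate, tolerance = 1e-8)
  pooled <- sum(cfg$pattern_prevalences * p)
  q <- (pooled - cfg$pattern_prevalences * p) / (1 - cfg$pattern_prevalences)
  or_hat <- (p / (1 - p)) / (q / (1 - q))
  expect_equal(as.numeric(or_hat), as.numeric(cfg$target_pattern_ors),
               tolerance = 1e-6)
})

test_that("cohorts are deterministic given config and seed", {
  cfg <- sim_config(n_patients = 12, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$ct_nodes, c2$ct_nodes)
  expect_identical(c1$histo_nodes, c2$histo_nodes)
  c3 <- generate_cohort(sim_config(n_patients = 12, seed = 78))
  expect_false(identical(c1$histo_nodes, c3$histo_nodes))
})

test_that("per-patient substreams survive changes of the patient count", {
  small <- generate_cohort(sim_config(n_patients = 8, seed = 5))
  large <- generate_cohort(sim_config(n_patients = 20, seed = 5))
  expect_identical(small$patients, large$patients[1:8, ])
  expect_identical(small$histo_nodes,
                   large$histo_nodes[large$histo_nodes$patient_id %in%
                                       small$patients$patient_id, ])
})

test_that("generation leaves the global RNG stream untouched", {
  set.seed(31415)
  before <- .Random.seed
  invisible(generate_cohort(sim_config(n_patients = 3, seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("a zero metastasis rate yields a metastasis-free cohort", {
  coh <- generate_cohort(sim_config(n_patients = 20, seed = 4,
                                    overall_node_metastasis_rate = 0,
                                    patient_positive_fraction = 0))
  expect_equal(sum(coh$histo_nodes$metastatic), 0)
  sc <- station_concordance(coh$ct_nodes, coh$histo_nodes, default_registry())
  expect_true(all(sc$category %in% c("negative", "false_positive")))
  expect_true(all(is.na(sc$spr)))
})

test_that("simulated sizes and harvested counts respect their configured ranges", {
  cfg <- sim_config(n_patients = 60, seed = 21)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$ct_nodes$short_axis_mm >= cfg$size_range_mm[1]))
  expect_true(all(coh$ct_nodes$short_axis_mm <= cfg$size_range_mm[2]))
  harv <- table(coh$histo_nodes$patient_id)
  expect_true(all(harv >= cfg$harvested_range[1] &
                    harv <= cfg$harvested_range[2]))
  expect_true(all(coh$patients$age >= cfg$age_range[1] &
                    coh$patients$age <= cfg$age_range[2]))
})

test_that("marginal report tracks configured targets", {
  coh <- generate_cohort(sim_config(seed = 1))
  mr <- marginal_report(coh)
  expect_true(all(c("marginal", "configured", "realized") %in% names(mr)))
  size_med <- mr$realized[mr$marginal == "size_median_mm"]
  expect_gte(size_med, 5); expect_lte(size_med, 7)
  probs <- mr$realized[grepl("^pattern_|fraction|rate|ratio", mr$marginal)]
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("realized node metastasis rate is centred on the configured rate", {
  rates <- vapply(1:40, function(k) {
    mean(generate_cohort(sim_config(seed = 1000 + k))$histo_nodes$metastatic)
  }, numeric(1))
  expect_equal(mean(rates), 0.0939, tolerance = 0.02 / 0.0939)
})

test_that("degenerate and invalid configurations are rejected", {
  expect_error(sim_config(n_patients = 0), class = "nodeconcord_config_error")
  expect_error(sim_config(male_fraction = 1.5), class = "nodeconcord_config_error")
  expect_error(sim_config(not_a_field = 1), class = "nodeconcord_config_error")
  expect_error(sim_config(band_probabilities = c(0.5, 0.5, 0.5)),
               class = "nodeconcord_config_error")
  # rate above the patient-positive fraction cannot be realised
  expect_error(sim_config(overall_node_metastasis_rate = 0.5,
                          patient_positive_fraction = 0.3),
               class = "nodeconcord_config_error")
  # inconsistent prevalences refuse to generate
  expect_error(
    suppressWarnings(generate_cohort(
      sim_config(pattern_prevalences = c(0.4372, 0.15, 0.2883, 0.08, 0.0445)))),
    class = "nodeconcord_infeasible_error")
})
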
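test_that("correlation categories partition the four count situations", {
  expect_equal(as.character(correlation_category(3, 2)), "positive")
  expect_equal(as.character(correlation_category(0, 0)), "negative")
  expect_equal(as.character(correlation_category(5, 0)), "false_positive")
  expect_equal(as.character(correlation_category(0, 4)), "false_negative")
  # exactly one category for any pair of counts
  grid <- expand.grid(s = 0:3, p = 0:3)
  cats <- correlation_category(grid$s, grid$p)
  expect_false(anyNA(cats))
  expect_error(correlation_category(-1, 0), class = "nodeconcord_domain_error")
})

test_that("SPR is a guarded ratio satisfying spr * positives == suspicious", {
  expect_equal(compute_spr(10, 10), 1)
  expect_equal(compute_spr(241, 412), 0.585, tolerance = 0.0005 / 0.585)
  expect_true(is.na(compute_spr(5, 0)))
  set.seed(2)
  s <- sample(0:50, 100, replace = TRUE)
  p <- sample(0:20, 100, replace = TRUE)
  spr <- compute_spr(s, p)
  defined <- !is.na(spr)
  expect_equal(spr[defined] * p[defined], s[defined])
  expect_true(all(is.na(spr[!defined]) & p[!defined] == 0))
})

test_that("LNR is positives over harvested with strict preconditions", {
  expect_equal(round(compute_lnr(170, 1809), 4), 0.094)
  expect_equal(compute_lnr(0, 12), 0)
  expect_equal(compute_lnr(12, 12), 1)
  expect_error(compute_lnr(1, 0), class = "nodeconcord_domain_error")
  expect_error(compute_lnr(13, 12), class = "nodeconcord_domain_error")
})

test_that("station concordance composes counts, SPR and category per station", {
  fx <- two_patient_fixture()
  reg <- default_registry()
  p1 <- station_concordance(fx$ct[fx$ct$patient_id == "P1", ],
                            fx$histo[fx$histo$patient_id == "P1", ], reg)
  r241 <- p1[p1$station_code == "241", ]
  expect_equal(r241$n_ct, 2)
  expect_equal(r241$n_suspicious, 2)
  expect_equal(r241$n_harvested, 3)
  expect_equal(r241$n_positive, 1)
  expect_equal(r241$spr, 2)
  expect_equal(as.character(r241$category), "positive")
  # station 242 appears on both sides but has no suspicion and no positives
  r242 <- p1[p1$station_code == "242", ]
  expect_equal(as.character(r242$category), "negative")
  expect_true(is.na(r242$spr))
  expect_error(
    station_concordance(fx$ct, transform(fx$histo, station_code = "999"), reg),
    "999", class = "nodeconcord_domain_error")
})

test_that("station concordance equals a brute-force group-by recount", {
  coh <- generate_cohort(sim_config(n_patients = 15, seed = 123))
  reg <- default_registry()
  sc <- station_concordance(coh$ct_nodes, coh$histo_nodes, reg)
  for (i in seq_len(nrow(sc))) {
    cd <- sc$station_code[i]
    ct_sub <- coh$ct_nodes[coh$ct_nodes$station_code == cd, ]
    hi_sub <- coh$histo_nodes[coh$histo_nodes$station_code == cd, ]
    expect_equal(sc$n_ct[i], nrow(ct_sub))
    expect_equal(sc$n_suspicious[i], sum(ct_sub$suspicious))
    expect_equal(sc$n_harvested[i], nrow(hi_sub))
    expect_equal(sc$n_positive[i], sum(hi_sub$metastatic))
  }
  expect_setequal(sc$station_code,
                  union(coh$ct_nodes$station_code, coh$histo_nodes$station_code))
})

test_that("cohort summary reproduces the hand-computed two-patient fixture", {
  fx <- two_patient_fixture()
  s <- cohort_summary(fx$patients, fx$ct, fx$histo)

  expect_equal(s$n_ct_nodes, 6)
  expect_equal(s$n_suspicious, 4)
  expect_equal(s$n_harvested, 10)
  expect_equal(s$n_positive, 3)
  expect_equal(s$lnr, 0.3)

  # bands: locoregional pools stations 241 + 251; 242 intermediate; 271 central
  expect_equal(s$spr_band$n_suspicious, c(3, 0, 1))
  expect_equal(s$spr_band$n_positive, c(3, 0, 0))
  expect_equal(s$spr_band$spr, c(1, NA, NA))

  sig <- s$spr_site[s$spr_site$tumor_site == "sigmoid", ]
  expect_equal(sig$spr, 2)
  rec <- s$spr_site[s$spr_site$tumor_site == "superior_rectum", ]
  expect_equal(rec$spr, 1)

  # node-level 2x2 against the station-level metastasis label
  expect_equal(as.vector(t(unclass(s$node_table))), c(3, 1, 1, 1))
  expect_equal(unname(s$node_metrics),
               c(3 / 4, 1 / 2, 3 / 4, 1 / 2))

  # both patients are suspicious-positive and disease-positive
  expect_equal(as.vector(t(unclass(s$patient_table))), c(2, 0, 0, 0))
  expect_equal(unname(s$patient_metrics["sensitivity"]), 1)
  expect_true(is.na(s$patient_metrics["specificity"]))

  expect_equal(as.integer(s$category_counts),
               c(2, 1, 1, 0))  # positive, negative, false_positive, false_negative

  expect_error(
    cohort_summary(fx$patients[1, ], fx$ct, fx$histo),
    class = "nodeconcord_integrity_error")
})

test_that("pattern association builds one pooled-rest table per pattern", {
  # constructed null: both patterns have identical metastasis odds
  pattern <- rep(c("dotted", "linear"), each = 20)
  met <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 10)
  pa <- pattern_association(pattern, met)
  expect_equal(pa$odds_ratio, c(1, 1))
  expect_equal(pa$n, c(20, 20))

  # known counts: dotted 8/2 vs rest 5/25
  pattern2 <- c(rep("dotted", 10), rep("homogenous", 30))
  met2 <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 5), rep(FALSE, 25))
  pa2 <- pattern_association(pattern2, met2)
  expect_equal(pa2$odds_ratio[pa2$pattern == "dotted"], (8 * 25) / (2 * 5))

  expect_error(pattern_association(rep("dotted", 5), rep(TRUE, 5)),
               class = "nodeconcord_domain_error")
  expect_error(pattern_association(character(0), logical(0)),
               class = "nodeconcord_domain_error")
})

test_that("band SPR pools counts before dividing (ratio of sums)", {
  # two locoregional stations with SPRs 3/1 and 0/2: pooled SPR must be 1,
  # not the mean of the per-station ratios
  patients <- data.frame(patient_id = "P1", sex = "M", age = 60,
                         tumor_site = "sigmoid")
  ct <- data.frame(node_id = paste0("C", 1:3), patient_id = "P1",
                   station_code = "241", short_axis_mm = 12,
                   roundness = 0, heterogeneous_density = 0,
                   irregular_border = 0, pattern = "dotted")
  histo <- data.frame(node_id = paste0("H", 1:3), patient_id = "P1",
                      station_code = c("241", "251", "251"),
                      metastatic = c(1, 1, 1))
  # note: 251 applies to superior_rectum in the registry but is still a
  # resolvable code; band pooling is what is under test
  s <- cohort_summary(patients, ct, histo)
  loco <- s$spr_band[s$spr_band$band == "locoregional", ]
  expect_equal(loco$n_suspicious, 3)
  expect_equal(loco$n_positive, 3)
  expect_equal(loco$spr, 1)
})
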
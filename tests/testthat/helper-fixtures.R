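# A fully hand-checkable two-patient cohort used across the concordance and
# reporting tests. Every expected statistic below is computed by hand from
# these ten harvested nodes and six CT observations.
two_patient_fixture <- function() {
  patients <- data.frame(
    patient_id = c("P1", "P2"),
    sex = c("M", "F"),
    age = c(60, 70),
    tumor_site = c("sigmoid", "superior_rectum"),
    stringsAsFactors = FALSE
  )
  ct <- data.frame(
    node_id = paste0("C", 1:6),
    patient_id = c("P1", "P1", "P1", "P2", "P2", "P2"),
    station_code = c("241", "241", "242", "251", "271", "251"),
    short_axis_mm = c(12, 6, 4, 7, 3, 9),
    roundness = c(0, 1, 1, 1, 1, 1),
    heterogeneous_density = c(0, 1, 0, 1, 1, 0),
    irregular_border = c(0, 0, 0, 1, 1, 0),
    pattern = c("homogenous", "homogenous", "dotted", "dotted",
                "peripheral", "linear"),
    stringsAsFactors = FALSE
  )
  histo <- data.frame(
    node_id = paste0("H", 1:10),
    patient_id = c(rep("P1", 4), rep("P2", 6)),
    station_code = c("241", "241", "241", "242",
                     "251", "251", "251", "271", "271", "251"),
    metastatic = c(1, 0, 0, 0, 1, 1, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  list(patients = patients, ct = ct, histo = histo)
}

# independent truth-table oracle for the suspicion rule: one literal row per
# (size bin, criteria combination), written out from the rule's prose
suspicion_truth_table <- function() {
  combos <- expand.grid(r = c(FALSE, TRUE), h = c(FALSE, TRUE),
                        b = c(FALSE, TRUE),
                        bin = c("small", "mid", "large"),
                        stringsAsFactors = FALSE)
  combos$n_crit <- combos$r + combos$h + combos$b
  combos$expected <- with(combos, ifelse(
    bin == "large", TRUE,
    ifelse(bin == "mid", n_crit >= 2, n_crit == 3)))
  combos$size_mm <- c(small = 3, mid = 7, large = 15)[combos$bin]
  combos
}
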
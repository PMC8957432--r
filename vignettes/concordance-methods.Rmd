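---
title: "Station-level CT/histology lymph-node concordance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Station-level CT/histology lymph-node concordance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodeconcord)
```

## The problem

Preoperative staging of colorectal cancer depends on deciding, from
contrast-enhanced CT, which abdominopelvic lymph nodes are likely to carry
metastases. After surgery the pathologist reports, per nodal station, how
many nodes were harvested and how many were positive. The two readings
cannot be compared node by node — CT typically resolves far fewer nodes
than the pathologist retrieves — so the natural unit of comparison is the
**nodal station**: a named anatomical group of nodes, assigned to one of
three distance bands relative to the primary tumour (locoregional
&le; 5 cm, intermediate 5–10 cm along the feeding vessels, central
> 10 cm at the vessel origins, in the JSCCR tradition).

`nodeconcord` implements that comparison: the station data model, the
rule-based CT suspicion classifier, the station/band/site concordance
statistics, the 2×2 association machinery, and a calibrated synthetic
cohort generator used to validate the whole pipeline when the original
hospital data are not available.

## Station map

A registry is a table of stations: a short string code (string, never an
integer, to preserve leading characters in other coding systems), a band,
a free-text anatomical label, and the set of tumour sites it applies to.
Eight tumour sites are recognised, cecum through inferior rectum. The
shipped default registry has one station per band per site (24 stations)
and includes the two codes with published site attachments — 241
(paracolic, sigmoid) and 251 (superior rectal). It is deliberately
illustrative: the full official JSCCR atlas is not reproduced, and users
doing real station-level work should supply their own TSV.

`classify_distance()` centralises the band boundary convention:
`[0, 5]` cm locoregional, `(5, 10]` intermediate, `(10, Inf)` central.
"Within 5 cm" is read as inclusive; since the source phrasing does not
assign the boundary explicitly, the choice is documented here and kept in
one function so it can be changed in one place.

## The suspicion rule

CT-visible nodes are binned by short-axis diameter: small (< 5 mm), mid
(5–10 mm), large (> 10 mm). Both boundaries belong to the mid bin — with
bins written "< 5", "5–10", "> 10", the closed interval `[5, 10]` is the
only consistent completion of the partition. A node is **suspicious** if

* small and all three criteria of suspicion are present
  (roundness, heterogeneous density, irregular border),
* mid and at least two criteria are present,
* large (always).

Of the 24 combinations of size bin and criteria, 13 are suspicious. The
`suspicious` flag is always *recomputed* from the rule; a stored flag
that disagrees is a hard load error, because a silently inconsistent flag
would contaminate every downstream concordance statistic.

Enhancement patterns form a closed five-value vocabulary — homogenous,
dotted, linear, central, peripheral — recorded by the radiologist from
the venous phase; the package treats them as categorical input and makes
no attempt at pixel-level classification. The spelling "homogeneous" is
accepted as a read alias; the historical term "spotted" (an older name
for a dotted-like pattern) is deliberately not aliased, to avoid silently
conflating definitions from different reading protocols.

## Concordance statistics

Per station (and per patient-station inside `cohort_summary()`), the
suspicious CT count `s` and the positive histology count `p` give one of
four categories: positive (`s>0, p>0`), negative (`0, 0`),
false positive (`s>0, p=0`), false negative (`0, p>0`).

The **SPR** (suspicious-to-positive ratio) is `s / p`, reported as `NA`
when `p = 0` — never 0 or infinity, and never serialised as `Inf`.
Band-level and site-level SPRs pool counts *before* dividing (a ratio of
sums): a mean of per-station ratios would weight empty stations absurdly
and is undefined whenever any station has no positives. The **LNR**
(lymph node ratio) is metastatic over harvested nodes.

Two 2×2 tables are built per cohort:

* **Node level** — CT nodes (rows: suspicious / not) against a
  *station-level* metastasis label: a CT node counts as LNM+ iff its
  patient-station contains at least one metastatic harvested node. This
  is a reconstruction, and the only reading under which every CT node can
  carry a histology label at all; it necessarily dilutes per-node effects
  (a benign node parked in a metastatic station is labelled LNM+), which
  is visible in the attenuated pattern odds ratios the summary prints.
* **Patient level** — a patient is test-positive iff they have at least
  one suspicious node and disease-positive iff at least one metastatic
  node. The source protocol never states its patient-level rule; the
  &ge;1 threshold is this package's choice and is the natural screening
  reading.

Statistics on a 2×2 `(a, b; c, d)`:

* `pearson_chi_square()` — plain Pearson statistic with df = 1, expected
  counts `r_i c_j / n`, per-cell contributions `(O-E)^2/E`, upper-tail
  p-value. No continuity correction by default (the printed expecteds and
  contributions of the table this reproduces are only consistent with the
  uncorrected statistic); Yates is available behind `yates = TRUE`.
* `odds_ratio()` — cross-product `ad/bc`; Haldane–Anscombe 0.5 added to
  *every* cell when any cell is zero (flagged in the result); Woolf
  log-normal 95% CI `exp(log OR ± 1.96 · sqrt(1/a+1/b+1/c+1/d))`; Wald
  two-sided p on `log OR`. The CI method is a package choice — the
  source does not state one — and a Fisher exact p is available behind a
  flag for sensitivity analyses.
* `diagnostic_metrics()` — sensitivity `a/(a+c)`, specificity `d/(b+d)`,
  PPV `a/(a+b)`, NPV `d/(c+d)`, each `NA` when its denominator is empty.

`pattern_association()` builds, for each pattern, the (pattern vs pooled
rest) × (metastatic vs not) table and reports the odds of metastasis for
the pattern. One orientation is fixed for all rows; for patterns that
mark *benign* nodes (homogenous), the reciprocal is the natural
"indicator of non-metastatic nodes" reading, and that is the orientation
the acceptance script reports for the homogenous pattern.

## The synthetic cohort generator

The generator emulates the marginal structure of a single-centre cohort
of 112 colorectal-cancer patients: 78:34 male:female; age 65.60 ± 10.99
years, truncated normal on [27, 88]; tumour sites with frequencies
13/2/10/6/20/23/20/18 across the eight sites; harvested nodes per case
from a rounded log-normal with median 15 (sdlog 0.4, clamped to [1, 60],
giving a mean near the observed 1809/112 ≈ 16.2); CT sees a random
subset of the harvested nodes with probability 1079/1809; short-axis
sizes log-normal with median 6 mm and sdlog 0.5, resampled into
[2, 34] mm; station bands drawn with probabilities (0.56, 0.28, 0.16)
matching the observed locoregional share of CT nodes, then a uniform
station among the registry stations of that band for the patient's site.

Node positivity is clustered within patients: a latent 33.93% of
patients are metastasis-prone, and their nodes are positive with
probability `0.0939 / 0.3393`, so the marginal node metastasis rate is
exactly 0.0939 while the patient-positive fraction stays near its
target. (The realised fraction of patients with &ge;1 positive node sits
about one percentage point below the latent fraction, because a prone
patient can draw zero positives.)

Criteria flags are drawn independently per criterion given the node's
metastasis status, with sensitivities (0.85, 0.70, 0.60) and
specificities (0.78, 0.87, 0.92) chosen once so that the suspicion rule
marks about 22% of CT nodes suspicious, matching the observed 241/1079,
with roundness the commonest criterion. Inter-criterion correlation is a
config extension point, not modelled by default. Node size is drawn
independently of metastasis status; the suspicion–metastasis association
therefore flows entirely through the criteria flags.

### Calibrating pattern probabilities to odds-ratio targets

Each pattern `k` has a prevalence `π_k` and a conditional metastasis
probability `p_k`. The targets are rest-pooled odds ratios
`OR_k = odds(p_k) / odds(q_k)` with
`q_k = (r − π_k p_k) / (1 − π_k)` the rate pooled over the other
patterns, plus the overall rate constraint `Σ π_k p_k = r`. Each OR
equation is strictly monotone in `p_k` and is solved exactly by scalar
root-finding (`uniroot`, tolerance 1e-14).

A point that matters: with all five prevalences fixed, the six
conditions (five ORs + the rate) **over-determine** the five `p_k`. For
the published OR targets at rate 0.0939, no completion of the two
printed prevalences (homogenous 43.72%, linear 28.83%) satisfies all six
— the unique exactly-OR-consistent solution sits at a pooled rate of
0.54. The package therefore treats the prevalence vector itself as part
of the calibration: `consistent_pattern_prevalences()` keeps the
homogenous:linear ratio at the printed 43.72:28.83, fixes small central
(0.04) and peripheral (0.03) prevalences, gives the dotted pattern the
remaining mass, and solves the overall homogenous level by root-finding
on the joint-consistency residual. The defaults come out as
(homogenous 0.5247, dotted 0.0594, linear 0.3460, central 0.04,
peripheral 0.03); with them, the rate and all five ORs are
simultaneously exact (residuals below 1e-12), and
`calibrate_pattern_probabilities()` warns whenever a user supplies an
over-determined combination (reporting the achieved pooled rate), while
`generate_cohort()` refuses to run on one. The homogenous target is
stored in metastasis orientation as 1/1.99, the reciprocal of its
published benign-direction value.

Given a consistent `(π, p, r)`, generation draws each node's metastasis
status first (preserving the patient clustering) and then its pattern
from the Bayes-inverted conditionals `P(k | M±) ∝ π_k p_k` /
`π_k (1 − p_k)`; the realised pattern–metastasis joint distribution then
has exactly the target rate, prevalences and odds ratios in expectation.

### Randomness and reproducibility

All randomness derives from `config$seed`. Each patient gets a private
substream seeded by a Lehmer-style hash of (seed, patient index), so a
cohort is byte-identical across runs and patient `i`'s data do not
change when `n_patients` changes. The global `.Random.seed` is saved and
restored around generation. Truncated draws (age, size) use rejection
sampling, which preserves the distribution's shape inside the bounds
exactly (a clamp would pile mass on the boundaries).

## Validation design and problem sizes

The test-suite checks fall into three groups:

* **Exact reproductions** — the published 2×2 table (statistic 92.6485,
  expected 92.02 and contribution 44.48 in the suspicious/LNM+ cell),
  the printed cohort proportions, and the 24-row suspicion truth table.
* **Structural properties** — chi-square equals its closed form
  `n(ad−bc)² / (r₁r₂c₁c₂)` on random tables and matches
  `stats::chisq.test(correct = FALSE)`; odds ratios are invariant to
  row scaling; `SPR × positives = suspicious` wherever defined;
  metrics pair up under table transposition; station counts equal a
  brute-force recount; cohorts are seed-deterministic.
* **Parameter recovery** — 200 simulated cohorts at the default size
  (112 patients, ~1800 nodes; ~15 s total) recover the dotted-pattern
  metastasis OR and the homogenous-pattern non-metastasis OR at their
  calibrated targets (medians within a few percent of 7.84 and 1.99),
  and the realised node metastasis rate averages to 0.0939 within ±0.01.

The published patient-level sensitivity/specificity/PPV/NPV
(80%/69%/0.42/0.92) and the band/site SPR values are *not* verification
targets: the former are not derivable from the printed 2×2 counts (their
unit of analysis is unstated), and the inputs behind the latter were
never printed. Both are computed by the package for any cohort, but no
test pins them to the published numbers.

## What passing tests do and do not show

The generator reproduces marginals and one calibrated conditional
structure (pattern ↔ metastasis), with clustering only at the patient
level. Real data differ in ways the simulation does not attempt: spatial
correlation of metastases along drainage pathways (here metastasis is
independent of band and station given the patient), size–metastasis
dependence, correlated reader criteria, inter-observer variation, and a
station registry that is anatomically complete. Passing the recovery
tests shows the estimators and the calibration are mutually coherent at
realistic sample sizes — not that the synthetic cohorts are a substitute
for the hospital data.

## Known limitations

* The registry shipped as default is a minimal scaffold, not an atlas.
* The node-level 2×2 rests on the station-level label reconstruction
  described above; its metrics are not comparable across studies that
  label nodes differently.
* Per-pattern odds ratios computed against the station-level label are
  attenuated relative to the node-truth ORs; parameter-recovery checks
  therefore join CT observations to their underlying nodes by id, which
  is available only for synthetic cohorts.
* Tumour dimensions, survival, and the V/L/n/b histology covariates are
  out of scope; `pT`/`pM` columns in synthetic patients are cosmetic.
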
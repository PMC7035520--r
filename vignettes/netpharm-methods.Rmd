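---
title: "Methods: screening, network and bioassay models in netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, network and bioassay models in netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

netpharm implements the quantitative core of a network-pharmacology screen
of herbal compound libraries and the bench statistics used to validate the
resulting hit. This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic generators do and do not
emulate.

## 1. Signed-probability ADMET screening

Upstream ADMET classifiers report each endpoint as a *signed probability*
in [−1, 1]: the sign is the predicted class (absorbable / inhibitor vs
not), the magnitude the classifier's confidence. The screen applies two
rules:

* **Absorption.** A compound is kept only if both the HIA and Caco-2
  predictions are strictly positive. The boundary value 0 fails: the rule
  is phrased in terms of *positive* predictions, and 0 carries no class
  label. This is a deliberate, documented tie-break.
* **Metabolism.** The five CYP450 inhibition predictions are summed with
  per-isoform accuracy weights, `score = Σ cyp_k · q_k`, and compounds with
  `score ≤ score_floor` (default 0) are discarded. Negative (non-inhibitor)
  predictions subtract from the score as printed in classifier reports;
  they are not clamped.

The default weights `cyp_weights()` are the published overall predictive
accuracies of the five isoform classifiers — 0.8147, 0.8018, 0.8551,
0.8054, 0.6450 — applied **positionally to the report column order 1A2,
2C9, 2D6, 2C19, 3A4**. Accuracy listings elsewhere sometimes order the
isoforms 1A2, 2C9, 2C19, 2D6, 3A4; we verified against the bundled
32-compound table that only the positional (column-order) mapping
reproduces every printed score to 8 decimals, so that mapping is the
package's contract. Scores are stored at full double precision; 8 decimal
places are only a write-time formatting default (`write_admet_table()`).

The discard rule on the *composite* score (rather than on any single
negative CYP entry) is also a considered choice: confident non-inhibitor
predictions are common among otherwise excellent candidates — most
compounds in the bundled table carry at least one — so per-entry discarding
would empty the library. A per-entry rule can still be emulated with
`score_floor` plus pre-filtering if a user wants it.

## 2. Bipartite networks and hubs

The compound–target network is a simple undirected bipartite graph: ids
are namespaced by role (an id may not appear as both compound and target),
duplicate edges collapse to one (count retained in `n_duplicate_edges`),
and degree is the number of incident edges. Hub extraction uses an
**inclusive** threshold, `degree ≥ min_degree`, with 10 as the
conventional default. Percentages (`role_fraction()`) are kept at full
precision internally; rounding is presentation-only.

`subnetwork_by_compounds()` defaults to keeping isolated targets because
family subnetworks (e.g. the stilbenes) are conventionally drawn against
the full target panel; the flag makes the other convention available.

The target–disease–group network is a tri-layer graph whose only edge
types are target–disease and disease–group; diseases may belong to several
MeSH-style groups (acute and chronic myeloid leukemia, for instance, sit
in both C04 and C15). Strict mode rejects group-less diseases; lenient
mode bins them as "unclassified".

SIF exports are Cytoscape-loadable but the format itself cannot carry node
attributes, so the writer emits a `<path>.noa` TSV sidecar (id, role,
annotations) which `read_network()` consumes; GraphML carries everything
in one file via igraph. Round trips are exact in both formats.

## 3. Bioassay statistics

**Inhibition rate.** `100·(A_ctrl − A_treat)/A_ctrl` with the replicate
mean as `A_ctrl`. The rate may be negative (growth promotion, as seen with
mitogen-stimulated PBMCs); it is reported as-is. Per-well rates are exposed
for dispersion reporting.

**IC50.** Four-parameter log-logistic least squares,
`y = bottom + (top − bottom)/(1 + (d/IC50)^(−h))`, fitted with
Levenberg–Marquardt (minpack.lm) on per-well percent inhibition.
Numerical choices: the model is parameterized in `log(IC50)` so the
estimate stays positive; the start is the geometric mean dose; the Hill
slope is multi-started over ±{0.5, 1, 2, 4} and the lowest-RSS fit wins;
after fitting, if `bottom > top` the asymptotes are swapped and the slope
negated (an identical curve), so `bottom ≤ top` always holds. A flat
response is non-identifiable and returns `converged = FALSE` rather than
an arbitrary curve. Fitting viability (`100 − y`) gives the same IC50 as
fitting inhibition, which the tests assert to 1e-6.

**2^−ΔΔCt.** Replicate-mean Ct values, reference gene GAPDH by default;
`ΔΔCt = (Ct_g,grp − Ct_ref,grp) − (Ct_g,ctl − Ct_ref,ctl)`. The statistic
is invariant to plate-wide Ct shifts, asserted as a property test.

**Quadrant gating.** An event is positive on a channel only when its
intensity strictly exceeds the gate; equality counts as negative. The
boundary choice is arbitrary but fixed and documented for
bit-reproducibility. Quadrants follow the apoptosis convention (Q1 late
apoptotic, Q2 necrotic, Q3 viable, Q4 early apoptotic);
`apoptotic_fraction()` exposes both `early` (Q4) and `total` (Q1+Q4)
because published "apoptosis %" panels do not always state which pooling
they use.

**JC-1.** No standard numeric gate exists for JC-1 data, so the package
uses a ratio formulation: an event is depolarized when aggregate/monomer
< `ratio_threshold` (default 1). Zero-monomer events have an undefined
ratio and are excluded with a logged count.

**Dose trend.** Spearman correlation of dose vs response with a two-sided
permutation p-value, `p = (1 + #{|ρ*| ≥ |ρ|})/(n_perm + 1)`. A rank-based
statistic was chosen because instrument responses are monotone but rarely
linear in dose; the permutation null avoids distributional assumptions at
plate-sized n. Constant responses get statistic 0 by convention.

**Group comparisons.** `compare_groups()` is a thin reporting utility —
one-way ANOVA plus pairwise Welch t against control, no multiplicity
correction — mirroring common practice in bench reports; it is
presentation-level, not inferential machinery.

## 4. Synthetic data: what it emulates, and what it does not

Each generator is a pure function of its arguments including an explicit
seed (bit-identical on repeat), and returns the planted truth alongside
the data so recovery tests never re-derive it.

* `simulate_compound_library()` plants an **exact** pass count
  (`round(pass_fraction · n)`), not a binomial expectation, so count
  assertions are deterministic; magnitudes are uniform on [0.5, 1] to mimic
  confident classifier output, and planted passers are adjusted (sign
  flips on the worst-weighted entries) until their composite score is
  positive.
* `simulate_bipartite_edges()` plants hub targets with degrees in
  [10, 30] against a background of degree ≤ 3 (the ranges are validated to
  be separated), so threshold extraction has an exact answer. Default
  sizes, 118 compounds × 141 targets, match the scale of a realistic
  screen.
* `simulate_dose_response()` inverts the inhibition-rate formula exactly:
  treated absorbance is `A_ctrl·(1 − y/100)` with the 4PL curve `y`, plus
  Gaussian noise stated in percentage points (default 3). Default truth is
  IC50 13.61 µg/mL, Hill 1.5, two-fold doses 1–128 µg/mL, triplicate — a
  typical cytotoxicity plate for a moderately potent natural product.
* `simulate_ct_table()` plants fold changes as `−log2(fold)` Ct shifts in
  the treated group with a constant reference gene; defaults follow the
  apoptosis-induction pattern (Bad and Bax up, Bcl-2 and Bcl-xL down).
* `simulate_flow_events()` draws quadrant counts from a multinomial and
  intensities from half-log-normal components offset strictly to the
  correct side of each gate, so gating recovers the drawn counts exactly;
  `simulate_jc1_events()` does the analogous construction around the ratio
  gate. Log-normal components were chosen for realism; any strictly
  gate-respecting family would serve.

What the generators do **not** emulate: chemistry (compound ids are
arbitrary labels, not SMILES-derived), spectral spillover/compensation in
flow data, amplification-efficiency differences between qPCR primer pairs,
edge-effect or drift structure in plates, and the correlation structure of
real interaction databases. Passing recovery tests therefore demonstrates
the correctness of the *computations* under clean generative assumptions,
not robustness to instrument artefacts.

## 5. Problem sizes and determinism

The shipped tests run the full suite at the scales the methods are meant
for — the 32-compound bundled table, 118 × 141 networks over 10 seeds, 200
noisy plates for IC50 recovery, 10,000–20,000 flow events, and 500 null
datasets at 199 permutations each for trend-test calibration — totalling
well under a minute of compute. The power example for the trend test uses
10,000 permutations. All randomness flows from explicit seeds;
`run_pipeline()` derives every stage's seed from the single configured one
and excludes timestamps from `report.json`, so a report is a pure function
of inputs and configuration.

## 6. Known limitations

* The score-floor rule (composite > 0) is a documented reconstruction of a
  screening convention, not a uniquely determined rule; alternative floors
  are a parameter away.
* IC50 estimates from 4PL fits are unreliable when the dose range does not
  bracket the inflection; the `converged` flag catches degeneracy but not
  extrapolation — inspect `autoplot()` output.
* The permutation trend test is calibrated for plate-sized designs
  (3–10 dose levels, 2–6 replicates); very large designs would warrant an
  asymptotic test instead.
* `compare_groups()` deliberately applies no multiple-testing correction;
  treat its p-values as descriptive.
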
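---
title: "Methods: untargeted lipidomics contrasts between bacterial strains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted lipidomics contrasts between bacterial strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidcontrast)
```

## The problem

Untargeted LC-QTOF lipidomics compares the lipid repertoires of
bacterial strains — here an *E. coli* food source (OP50) against two
*Lactobacillus rhamnosus* strains (HA-114, R0011) — from per-run MS
feature lists: each detected peak is an (m/z, retention time,
intensity) triple in one ionization polarity. The package turns those
peak lists into (i) per-comparison differential feature tables with
false-discovery-rate control, (ii) accurate-mass lipid annotations
confirmed across polarities, and (iii) per-strain lipid-class
composition summaries. All stages are validated against a
ground-truthed simulator of the same study design (3 strains × 6
replicates, dual polarity).

## Pipeline model and assumptions

**Alignment.** Runs are aligned per polarity by greedy median-anchored
clustering: observations sorted by m/z join the open group whose
running median m/z is within 5 ppm and median RT within 15 s; if a
sample already contributes a peak to the group, the more intense peak
is kept and the weaker one seeds a new group. Medians make the
grouping robust to a stray peak and keep the procedure deterministic
and O(n log n). The algorithm and both gates are package choices — no
published tolerance accompanies the upstream study design — and both
are configurable (`pipeline_config(ppm_tolerance =,
rt_align_tolerance_s =)`). On well-separated data (true entities
spaced by more than about 3× the gates) the result is provably the
same as all-pairs single-linkage clustering, and the test suite
asserts that equivalence against a brute-force oracle.

**Strain-pair processing.** The aligned matrix is divided into the
three two-strain datasets first and filtered second, preserving the
stated order of operations:

1. features with 100% missing values in one strain move to an
   *exclusives* table (qualitative presence/absence evidence — a lipid
   absent from one strain cannot carry a fold change);
2. only features observed in at least 80% of one strain's replicates
   are kept; with n = 6 the ceiling rule makes this ≥ 5 of 6, the only
   exact reading of "80% of presence" at that sample size;
3. missing cells are imputed at 0.9 × the per-feature minimum, the
   standard left-censoring device for intensities that fell below
   detection;
4. intensities are log2-transformed and normalized by full-pairwise
   cyclic loess (span 0.7, 3 iterations), delegated to
   `limma::normalizeCyclicLoess(method = "pairs")` — the reference
   implementation of exactly this M-vs-A local-regression procedure.
   "Scale data" is interpreted as the log2 scale, the domain in which
   cyclic loess is defined; the base is configurable. The grand mean
   of log intensities is conserved by construction (the pairwise
   ± half-trend corrections cancel), and a constant offset between
   samples is removed — both are asserted as properties in the tests.

Imputation precedes normalization, following the stated order of the
original workflow; the two wrapper functions can be called in either
order by a user who wants the alternative.

**Statistics.** Each feature is tested by a linear model of log2
normalized intensity on the two-level strain indicator; the two-sided
p-value of the strain coefficient is identical to a pooled-variance
two-sample comparison (Welch is available via `welch = TRUE`). With
two groups, this is the natural concrete form of "regression
analysis"; the suite verifies agreement with an independent `t.test()`
oracle to 1e-10. Multiple testing is handled by Storey q-values
implemented in the package (no q-value estimator ships with the
environment's base stack): π0 is estimated on the λ grid 0.05–0.95 by
`#{p > λ}/(m(1−λ))`, smoothed with a 3-df cubic smoothing spline and
read off at λ = 0.95, clipped to (0, 1]; q-values are the BH step-up
quantity scaled by π0. With fewer than 100 p-values the spline is
unstable and π0 falls back to 1 (a warning says so) — q-values then
equal Benjamini–Hochberg exactly, which the tests assert.

**Significance gates.** A feature is significant iff p < 0.01
(strict) and fold change > 1.5 or < 0.667 (strict). Fold change is
the ratio of arithmetic group means of back-transformed normalized
intensities, first-named strain in the numerator; a geometric-mean
mode exists. The q-value is reported alongside but does not gate:
where both a p cut and a q cut are quoted for such designs, the p cut
is the operative one and q is descriptive. Strictness at the
boundaries is a documented convention (a feature at exactly fc = 1.5
is not called).

**Annotation.** Features are matched against a lipid library by
accurate mass (< 5 ppm, strict) through class-specific ion forms:
FFA [M+NH4]+ / [M−H]−, PE [M+H]+ / [M−H]−, PG [M+NH4]+ / [M−H]−,
PC [M+H]+ / [M+FA−H]−, MGDG and DGDG [M+NH4]+ only, LPG [M−H]− only.
Dual-polarity classes are confirmed only when the partner ion is
found in the opposite polarity within 30 s of retention time;
single-polarity classes are confirmed on their one ion. When several
library lipids survive for one feature all are reported, ranked by
ppm — annotation is at sum-composition level without MS/MS, so no
winner is forced. Features sharing one lipid name within a polarity
get isomer suffixes a, b, … in ascending RT order (ties by m/z, then
feature id); the lettering is a package convention.

Masses are computed from elemental formulas over CODATA monoisotopic
atomic masses; the charge carrier is the proton with the electron
mass folded into the 1.007276 Da constant, and [M+FA−H]− uses formic
acid (+44.998203 Da).

**Composition.** Per strain, a confirmed lipid entity (name + isomer
letter; a confirmed positive/negative pair is one entity) counts when
its feature is observed — pre-imputation — in at least 80% of that
strain's replicates; counts are aggregated by subclass and normalized.
Imputation is a device for pairwise statistics, not evidence of
presence, so composition always reads the raw missingness pattern.
By default only cross-polarity-confirmed annotations enter the
summary (`composition_confirmed_only = FALSE` relaxes this; whether
the original pie charts used all candidates or confirmed ones is not
documented, and confirmed-only is the conservative choice). Internal
standards are excluded throughout.

**Internal standards.** The six spiked standards (LPC 13:0,
PC 19:0/19:0, PC 14:0/14:0, PS 12:0/12:0, PG 15:0/15:0, PE 17:0/17:0)
are carried in the library flagged `is_standard` and used only as a
QC check — detected or not, at what ppm error, in how many samples.
They play no role in normalization (cyclic loess handles that) or in
composition. Because a spiked standard is present in essentially
every run, the QC lookup takes the best-covered in-tolerance feature
rather than the nearest-ppm one, which protects against coincidental
isobars. Note the standards duplicate sum compositions that also
exist as library species (PC 14:0/14:0 *is* PC 28:0), so annotation
candidate lists can legitimately contain both names for one feature.

## The bundled library

The annotation surface is a generated, editable stand-in for a
full-scale reference database (which is not redistributable): free
fatty acids C12–C24 with 0–3 double bonds, with and without a
hydroxyl, plus sum-composition PE/PG/PC/MGDG/DGDG/LPG species with 28
to 40 total acyl carbons and 0–3 double bonds, and the six standards
— about 420 records, every mass derived from its elemental formula.
Users with their own library supply a delimited file (`name`,
`subclass`, `formula` and/or `monoisotopic_mass`) through
`read_lipid_library()`; when both formula and mass are given they must
agree within 1e-4 Da.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions: strains OP50,
HA-114, R0011 with 6 replicates each; dual-polarity acquisition; a
~80 min gradient (true RTs uniform on 60–4800 s); truncated-Gaussian
mass error (scale 1 ppm, hard-bounded at ±5 ppm, matching a 5 ppm
instrument); Gaussian RT jitter (3 s); log-normal intensities with
log2 s.d. `log2(1 + noise_cv)`, `noise_cv = 0.2` — within-strain
variance is not published for this design, so 20% is a modeling
choice typical of untargeted bacterial lipidomics; 5% random dropout
(an optional left-censoring mode quadruples dropout in the lowest
intensity quartile, stressing the minimum-based imputation); 20%
unknown features with no library counterpart; 30 of 150 lipids
carrying a planted threefold change in one randomly chosen strain.

Per-strain class mixes were fixed once to reproduce the qualitative
composition picture — the OP50-like strain PE-rich with no MGDG/DGDG,
the two *L. rhamnosus*-like strains carrying both glycolipid classes:

| subclass | OP50 | HA-114 | R0011 |
|----------|-----:|-------:|------:|
| FFA      | 0.25 | 0.30   | 0.25  |
| PE       | 0.45 | 0.15   | 0.15  |
| PG       | 0.15 | 0.15   | 0.15  |
| PC       | 0.10 | 0.10   | 0.12  |
| MGDG     | 0    | 0.12   | 0.13  |
| DGDG     | 0    | 0.08   | 0.10  |
| LPG      | 0.05 | 0.10   | 0.10  |

Lipid identities are drawn from the pooled mix and each strain
expresses a lipid with a class-dependent probability chosen so the
expected composition of its *expressed* lipids matches its configured
mix exactly (a χ² goodness-of-fit property in the tests). Baseline
log2 intensities are shared across strains, so unplanted lipids are
true nulls. The biological deviation in one sample is shared between
the two adduct ions of a lipid — they are the same molecules — while
the relative response of the second ion form is a per-lipid constant.

Deliberate idealizations: no chromatographic peak shapes,
isotopologues, in-source fragments, adducts beyond the rule table,
batch drift, or RT warping between runs. Two consequences matter for
interpretation. First, true entities are placed so that near-isobaric
lipids (within 0.1 Da, including the standards' slots) never coelute
within 120 s; real data contain coeluting isobars, so perfect
noiseless annotation recovery demonstrates correctness of the
arithmetic, not expected field performance. Second, unknown-feature
masses are rejection-sampled to sit more than 10 ppm from every
library adduct m/z — "no library counterpart" holds by construction,
so annotation precision on synthetic data is exact rather than
seed-dependent. Passing tests therefore validate the pipeline's logic
and calibration under the stated error model, not robustness to
instrument artifacts the model omits.

Randomness flows from one master seed; each stage derives a child
seed deterministically, so fixtures regenerate byte-identically.

## Numerical choices and degenerate inputs

- All thresholds are strict inequalities; ties at a gate are
  excluded, documented above.
- Zero residual variance with zero effect gives p = 1; with nonzero
  effect, p is driven to the 0 limit and a degenerate-variance
  warning is emitted.
- A feature reaching imputation with no observed value is impossible
  after the filters; encountering one raises an internal-consistency
  error rather than silently imputing nothing.
- Isomer letters and candidate lists are fully tie-broken (RT, then
  m/z, then feature id), so every output is reproducible
  bit-for-bit.
- The alignment retires candidate groups once the sorted m/z sweep
  passes 3× the ppm gate below the current peak, bounding the scan
  without changing results.

## Problem sizes used in validation

The test suite exercises the pipeline at the study's own scale
(3 × 6 samples, 150 ground-truth lipids, ≈ 300 aligned features per
run) and uses 20-seed batteries of 1000-feature two-group matrices
for null calibration (the fraction of null features with p < 0.01
must stay in [0.005, 0.02]) and 100-lipid two-strain simulations for
recovery (planted threefold changes: sensitivity ≥ 0.8 at empirical
FDR ≤ 0.1). Alignment is checked against an exhaustive oracle on
≤ 200-observation instances, where brute force is cheap and exact.

## Known limitations

- Sum-composition annotation only: positional/double-bond isomers
  (e.g. n-7 vs n-9) are indistinguishable by accurate mass, and no
  MS/MS evidence is used anywhere.
- The greedy alignment is not a warping method; systematic RT drift
  between batches must be corrected upstream.
- π0 estimation needs ≥ 100 features to beat the BH fallback.
- Exclusive features are reported qualitatively and never appear in
  volcano tables; a strain-unique lipid is evidence, but not a
  p-value.

## A worked run

```{r example}
cfg <- sim_config(seed = 1)
truth <- generate_ground_truth(cfg)
obs <- simulate_observations(truth, cfg)
report <- run_pipeline(obs, samples = sample_sheet(cfg),
                       comparisons = list(c("HA-114", "OP50"),
                                          c("R0011", "OP50"),
                                          c("HA-114", "R0011")))
report
```

```{r composition}
subset(report$composition, strain == "OP50" & count > 0)
```

The OP50-like strain shows no MGDG/DGDG entities, matching the
planted design; the exclusives tables in each comparison carry the
strain-unique lipids.
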
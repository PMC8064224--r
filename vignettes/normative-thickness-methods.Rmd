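---
title: "Methods: normative retinal thickness analysis for mouse OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative retinal thickness analysis for mouse OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retnorm)
```

# Scope and data model

`retnorm` analyses segmented mouse SD-OCT volumes. The segmentation itself
(a neural-network or manual delineation of nine layer interfaces) is
upstream of this package; the input here is an *interface set*: nine
ordered depth surfaces over the 512 × 512 en-face grid, with 1024 depth
pixels spanning 1.4 mm, so one depth pixel is 1400/1024 ≈ 1.3672 µm
(`axial_pitch_um()`). Everything downstream — thickness maps, block
aggregation, normative databases, group statistics, deviation scoring — is
implemented and tested here, together with a synthetic generator that
produces interface sets with the geometric structure the analysis assumes.

Thickness is measured along the A-scan (axial) direction as the depth
difference between bounding interfaces. This is the usual OCT convention;
it slightly overestimates the anatomical (surface-normal) thickness where
layers are tilted, identically so for all groups, which leaves comparisons
unaffected. Because layer *k* shares its lower interface with layer
*k* + 1, the eight layer maps sum exactly to the total retinal thickness
(TRT) map at every position; this telescoping identity is asserted in the
test suite and is the single strongest internal consistency check of the
thickness stage.

# Orientation, validity, blocks

Left eyes are mirrored onto the right-eye convention before any pooling, so
the left half of every standardized map is temporal and the right half
nasal. The flip is an involution on the pixel grid and idempotent on the
orientation flag (a second call is a logged no-op), preventing accidental
double mirroring.

Each of the 512 × 512 values then passes an ordered list of validity
predicates; the mask is the conjunction of the rule outcomes and the
entering mask, and rules are evaluated against the entering mask so the
result does not depend on rule order. Defaults:

* **non-negativity** — a negative thickness is a segmentation error;
* **physiological bounds** — `[0, 3 × reference mean]` for the layer; the
  factor 3 is deliberately generous (it must not clip genuine biology) and
  is configurable;
* **robust z-score** — `|value − median| / MAD ≤ 6`, with the
  normal-consistent MAD (constant 1.4826). The median/MAD pair resists the
  very outliers being flagged; a 6-MAD fence only removes gross
  segmentation failures. A constant map has MAD 0; the rule then passes
  everywhere rather than dividing by zero.

Maps are cropped 512 → 510 centrally (one row/column per edge — the
smallest symmetric crop making nine equal blocks) and averaged over
3 × 3 blocks of 170 × 170 values, indexed 1..9 row-major from the top-left
of the standardized map. Block means use valid positions only. A block is
retained when at least 90 % of its 28,900 positions are valid; the boundary
is inclusive, and the comparison is done in integer arithmetic
(`10 · count ≥ 9 · total`) so that exactly-90 % blocks are never lost to
floating-point representation. Whole-area means are computed on the full
uncropped 512 × 512 valid set — the whole-area and block summaries are
separate reporting modes, not derived from one another — and refuse to
report when fewer than half the positions are valid (configurable).

# Normative databases

A normative cell is `(mean, sample sd, n)` for one
(group, eye, age, layer, region) key, with region `whole` or
`block1`..`block9`. Cells are built per eye and for both eyes combined;
eyes are treated as independent samples when combining, which matches the
per-age cohort sizes of the packaged tables (≈ the sum of the per-eye
counts). The sd uses the *n* − 1 denominator. Cells with fewer than two
eyes are omitted: a one-eye sd is undefined and such a cell could never be
used for scoring.

The package ships the published whole-area tables for both cohorts (nine
layers × four ages, both eyes combined, with per-age N) plus the
body-weight summaries; files are plain CSV, checked against an md5 recorded
at packaging time. Per-block reference tables are not shipped —
`load_packaged("block_reference")` is a schema loader for a user-supplied
CSV in the database dialect (UTF-8, comma-separated, `.` decimal, columns
`group, eye, age_months, layer, region, mean_um, sd_um, n`). Numbers are
written with 17 significant digits so a save/load round-trip is bit-exact.

Normality screening uses the one-sample Kolmogorov–Smirnov test against a
normal with the sample's own mean and sd. Estimating the parameters from
the same sample makes the plain KS p-value conservative (the Lilliefors
effect); since block-level screening errs on the side of *keeping* the
normal model, this conservatism is acceptable for its purpose, but a
Lilliefors-corrected variant (`method = "lilliefors"`) and fixed-parameter
arguments are provided, and the fixed-parameter form is what the
null-calibration test uses.

# Group and longitudinal statistics

`two_sample_test()` accepts raw samples or `(mean, sd, n)` summaries, so
printed tables are first-class inputs. Welch's unequal-variance form with
Satterthwaite df is the default — layer variances differ visibly between
cohorts, and Welch costs essentially nothing when they do not — with the
pooled Student form available for sensitivity checks. Significance tiers
5 % / 1 % / 0.1 % are strict (`p = 0.05` is `ns`). No correction is applied
across layers, blocks or ages for the cross-sectional contrasts; the only
multiplicity correction in the package is Tukey's, inside the longitudinal
analysis. The nasal–temporal asymmetry test is operationalized as a paired
contrast per eye — mean of retained nasal-column blocks (3, 6, 9) minus
mean of retained temporal-column blocks (1, 4, 7) — followed by a paired
two-sided *t* test across eyes.

`ranova()` is the one-within-factor repeated-measures ANOVA on
complete-case subjects (all four monthly ages present;
`select_complete_cases()` enforces this and reports the attrition):
`F = MS_time / MS_subject×time` with (t − 1) and (n − 1)(t − 1) df. The
uncorrected p is primary; the Greenhouse–Geisser epsilon and adjusted p are
reported alongside for sphericity-sensitive reading. Degenerate tables are
rejected rather than silently computed: a table with no within-subject
variability (e.g. a duplicated subject) has a zero error term, while a
table constant over time returns F = 0, p = 1. `tukey_pairwise()` refers
`q = |Δ| / √(MS_err/n)` to the studentized range with the RANOVA error df;
it also reports the unadjusted p on the *same* contrast and error term.
Monotonicity (Tukey p ≥ unadjusted p) is guaranteed only on that shared
error term — against a per-pair paired *t*, which uses its own pair
variance, the inequality can genuinely fail, which is why the package
reports `p_unadjusted` explicitly.

# Deviation scoring

An individual eye's retained blocks are scored against the matching
normative cells: `z = (T − mean)/sd` and the two-sided tail
`p = 2(1 − Φ(|z|))`. "More extreme" is read two-sided; that is the only
reading under which the mean itself scores p = 1.00, and it treats thinning
and thickening symmetrically. Non-retained blocks are not scored. The
rendering convention is blue below / red above the normative mean with
intensity 1 − p; linear in 1 − p (not in |z|) because the display is meant
to saturate only as values become genuinely improbable. p-values are
displayed to two decimals; full precision is kept internally.

# The synthetic generator

`generate_interfaces()` builds a volume from per-layer thickness fields

```
T_l(r, c) = base_l + s_nt · x(c) + s_d · d(r, c) + ε,   ε ~ N(0, σ²), clamped ≥ 0
```

stacked below a flat top surface (depth 200 px by default). Design
choices:

* **Mean-centred gradients.** `x(c) = (c − 1)/511 − 0.5` and the
  normalized disc distance `d` minus its grid mean. Centring makes
  `base_l` the whole-area mean by construction, so cohort parameters can be
  read straight from whole-area normative cells; a slope `s_nt` separates
  the two edge columns by exactly `s_nt` µm.
* **Disc position.** The scan sits above the optic disc, horizontally
  centred on it, so the default disc centre is the midpoint of the bottom
  edge; configurable.
* **Defaults.** `s_nt = 2` µm (nasal thicker), `s_d = −5` µm per unit
  normalized distance (thinning away from the disc), `σ = 2` µm per-pixel
  noise — of the order of the system's 3 µm axial resolution. The two
  slope magnitudes are nominal: no quantitative gradient magnitudes are
  available to calibrate them, so they are chosen once to be visible
  against the noise without distorting layer means (centring guarantees
  the latter).
* **Noise on thickness, not depth.** Noise is i.i.d. per layer and
  position on the thickness field; that is what the downstream statistics
  are sensitive to, and stacking clamped non-negative thicknesses keeps
  the nine interfaces monotone by construction — clamping can never
  reorder surfaces.
* **Left eyes** are generated natively mirrored (nasal left), so the
  orientation-standardization stage is genuinely exercised.

`sample_cohort()` draws per-eye layer means from normative cells,
`Normal(mean, scale · sd)`, for the layers under study; unsampled layers sit
at their cell means. When TRT is among the sampled layers, the eight
structural thicknesses are rescaled proportionally so their sum equals the
TRT draw. The printed whole-area TRT of a real cohort does not exactly
equal the sum of the printed layer means (per-layer value exclusions are
independent), but inside any one generated volume the telescoping identity
must hold; proportional reconciliation resolves this by making the
generated TRT follow the normative TRT distribution while perturbing each
layer by well under its own sd. Sampling only the layer under study keeps
its recovered cohort mean exactly unbiased, which is how the
parameter-recovery checks are run.

What the generator does *not* emulate: OCT speckle and intensity artefacts,
segmentation-error spatial correlation (injected invalidity is random or
block-confined, not boundary-shaped), eye-to-eye correlation within an
animal, and longitudinal within-subject correlation (cohorts at different
ages are drawn independently). Passing tests therefore demonstrate the
correctness of the measurement and statistical machinery under the stated
generative model, not robustness to real acquisition pathology.

# Problem sizes and determinism

Every stochastic routine takes an explicit integer seed and is
bit-reproducible given it. The test suite runs the type-I-error
calibrations at 1,000 replicates (n = 30 designs), the deviation-calibration
uniformity check at 2,000 blocks, the asymmetry null at 500 replicates of
12-eye cohorts, and the full-pipeline parameter-recovery checks at the
reference cohort sizes (103, 84 and 104 eyes) — sizes chosen so each check
has meaningful power while the whole suite stays in the low minutes on one
CPU. The acceptance script re-runs the three cohort recoveries and the
analytic/threshold checks from scratch in about a minute.

# Known limitations

* Physiological bounds and gradient magnitudes are nominal defaults, not
  fitted to imaging data; users with their own cohorts should set bounds
  from their own reference statistics.
* The KS default is the uncorrected test (see above); for formal normality
  inference use the Lilliefors variant.
* Combining OD and OS as independent samples ignores within-animal
  correlation; cells built this way slightly understate the sd of a truly
  independent-eyes population.
* The RANOVA is the classical univariate form; no mixed-effects fallback
  for incomplete cases is provided — incomplete subjects are dropped, and
  reported.
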
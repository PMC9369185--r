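---
title: "Methods: the random-assignment null model for single-vesicle tetraspanin colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the random-assignment null model for single-vesicle tetraspanin colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraspot)
```

## The measurement and its data model

Multiplexed immunocapture chips (SP-IRIS platforms such as the ExoView R100)
immobilize single small extracellular vesicles (sEVs) on antibody spots
against the tetraspanins CD9, CD63 and CD81, plus a mouse-IgG isotype-control
spot that estimates nonspecific adhesion. Each captured particle is counted
and, when large enough, sized label-free by light interference; the practical
sizing floor is about 50 nm. Three-colour immunofluorescence against the same
three tetraspanins then phenotypes every particle, and particles with
sufficient fluorescence are detected irrespective of whether they could be
sized. `tetraspot` models this as a `chip_experiment`: one row per detected
particle with its capture spot, three channel-positivity flags and an
optional diameter in nm (`NA` = fluorescent but below the sizing floor).

Two conventions govern everything downstream:

* **Capture positivity.** A particle immobilized on an anti-X spot is scored
  X-positive regardless of its fluorescence in the X channel, because capture
  itself is antigen-specific evidence. Consequently each captured particle's
  observable phenotype reduces to its two non-capture channel flags — four
  *colocalization categories* per spot: capture-only (also called "single
  positive" or "non-colocalizing"), capture+A, capture+B, and triple
  positive, with A and B the two non-capture tetraspanins in the canonical
  order CD9, CD63, CD81. `tabulate_spot()` implements this; a
  `strict_capture` flag provides the alternative reading (capture-channel
  fluorescence required) for sensitivity analysis.
* **Fluorescence gating.** Particles dark in all three channels are
  interferometric-only detections. They stay in the particle table but are
  excluded from colocalization tabulation by default;
  `include_nonfluorescent = TRUE` counts them as capture-only instead, so
  both readings remain testable.

## The random-assignment null model

The scientific question is whether tetraspanins co-occur on individual
vesicles more (or less) often than chance. The null model assumes channel
signals are assigned to particles independently, each marker with its
per-spot marginal frequency. For a spot with non-capture markers A and B,
let \(p_A\) and \(p_B\) be the fractions of captured particles positive for
A and B. Under conditional independence given capture, the product rule
gives

\[
\begin{aligned}
P(\text{capture-only}) &= (1-p_A)(1-p_B), &
P(\text{capture+}A) &= p_A\,(1-p_B),\\
P(\text{capture+}B) &= (1-p_A)\,p_B, &
P(\text{triple}) &= p_A\,p_B .
\end{aligned}
\]

The capture marker's own probability is fixed at 1 by the capture-positivity
convention, which is why the model is applied *per spot*, conditioned on the
capture marker; the complement \(1-p\) is used for markers absent from a
category. `marker_marginals()` recovers \(p_A = f_{\text{capture+}A} +
f_{\text{triple}}\) (and likewise \(p_B\)) from a colocalization table, and
`predict_random()` evaluates the product rule exactly. A Monte-Carlo twin,
`simulate_random_reassignment()`, draws particles with independent marker
assignment and converges to the closed form; it serves as a simulation
cross-check, not as the estimator.

Deviations are reported as fold ratios (measured/predicted, rounded
half-away-from-zero to one decimal in reports, kept at full precision in the
objects) with a direction flag. A fold above 1 for the triple category means
coordinated sorting of tetraspanins into the same vesicles; above 1 for
capture-only, an excess of single-marker vesicles.

```{r worked}
tb <- coloc_table("CD63", fractions = c(0.631, 0.111, 0.103, 0.155),
                  sample_label = "MSC (hPL)")
pred <- predict_random(marker_marginals(tb))
pred
deviation_fold(tb, pred)[, c("category", "measured", "predicted", "fold_1dp")]
```

## Printed-percentage inputs and renormalization

Published per-spot tables usually print percentages at one decimal, so their
sums drift to 99.8–100.2. `read_fraction_table()` accepts such tables
(validated to 100 ± 0.2) and by default stores the fractions *as printed*
rather than renormalizing. This is deliberate: marginals formed by summing
printed one-decimal percentages, exactly as a spreadsheet recomputation
would form them, reproduce published predicted percentages at print
precision, whereas renormalizing first can shift a predicted category by 0.1
of a percentage point when the printed sum is 100.1. Renormalization to an
exact unit sum remains available (`renormalize = TRUE`) and changes no
conclusion — only the last printed digit. Count-backed tables are never
renormalized; a violated sum invariant raises an error.

Fraction-only tables carry no particle counts (published figures typically
print none), so they support prediction and fold reporting but yield
p-values only with a user-supplied nominal `n`, and every such result is
flagged approximate.

## Testing randomness: degrees of freedom and methods

`test_randomness()` compares observed category counts with the predicted
fractions. The key statistical subtlety is where the prediction came from:

* **Marginals estimated from the same table** (the default pipeline): the
  four categories are exactly the 2×2 layout of A-positivity by
  B-positivity, and the null is independence with both margins estimated.
  The Pearson statistic then has \(3 - 2 = 1\) degree of freedom — using 3
  would make the test so conservative it would essentially never reject.
  The package verifies this calibration by simulation: on chips generated
  with truly independent markers the rejection rate at \(\alpha = 0.05\)
  sits near 5%.
* **Externally supplied marginals** (`manual_marginals()`): nothing is
  estimated and all 3 degrees of freedom remain.

Three methods are available. `chi_square` is the default; if any expected
count falls below 5 it falls back automatically to `monte_carlo`, with a
note in the report. `exact_multinomial` enumerates all category compositions
(feasible up to n = 200) against fixed external marginals; with
self-estimated marginals it becomes Fisher's conditional exact test on the
2×2 table, the exact analogue of the 1-df chi-square. `monte_carlo` is a
parametric bootstrap that re-estimates the marginals in every resample when
they were self-estimated, which is what keeps it calibrated under the
composite null. Across a report, p-values are adjusted by Benjamini–Hochberg
(`randomness_report()`); the adjustment spans all spot-level tests in the
run.

## The synthetic chip generator

`simulate_chip()` provides data with exactly the statistical structure the
analysis assumes, so every pipeline stage can be validated against known
ground truth. The generative model:

1. **Population.** `n_vesicles` i.i.d. joint phenotypes over all 8 marker
   sets (including the marker-negative set, standing in for contaminant
   particles), and i.i.d. log-normal true diameters.
2. **Capture.** Each vesicle encounters *one* tetraspanin spot, drawn with
   probability proportional to `capture_affinity`, and is immobilized there
   if and only if it truly bears that antigen; otherwise it is washed away
   (counted as dropped). Marker-negative vesicles adhere to the IgG control,
   as does an extra Poisson stream (`background_rate` per captured
   particle). The encounter-then-match formulation matters: because the
   encountered spot is independent of the vesicle's *other* markers, the
   non-capture markers of on-spot particles keep their population joint
   distribution conditional on the capture marker. The tempting alternative
   — always capture the vesicle and choose among its eligible spots — makes
   multi-positive vesicles split their probability across spots and thereby
   induces an artificial positive association (odds ratio 4/3 at equal
   affinities) between the non-capture markers on every spot, i.e. it breaks
   the very null the model is meant to embody. Under encounter-then-match,
   an independent-marker population is *self-consistent* with the random
   model, which is what makes generator-based calibration tests meaningful.
3. **Detection.** Channel flags are the true marker states flipped
   independently with rates `fn_rate` / `fp_rate`; the observed diameter is
   the true diameter times `shrinkage_factor` (vesicles shrink when chips
   are dried), quantized to 0.01 nm as an instrument would report it, and
   recorded only at or above `sizing_floor_nm` — smaller particles remain
   fluorescent-but-unsized. Ground truth is kept in an attribute for oracle
   tests and never serialized.

Default parameters, chosen once as a realistic sEV preparation: log-normal
size with ln-mean \( \ln 60 \) and ln-sd 0.25 (5–95 percentile band ≈
40–110 nm, matching typical reported ranges); `shrinkage_factor = 0.85`
(drying shrinkage is real but unquantified, so the factor is free);
`sizing_floor_nm = 50`; marker prevalences 65/55/50% for CD9/CD63/CD81,
independent across markers, leaving ~8% marker-negative background;
`fn_rate = fp_rate = 0.02`; equal capture affinities; `background_rate =
0.02`. What the generator does *not* emulate: correlated channel noise,
spatial or intensity structure within spots, antibody binding kinetics,
cross-spot recapture, and optical sizing error beyond quantization. Passing
tests on synthetic data therefore demonstrate the statistical machinery, not
instrument physics.

## Sizing summaries

`size_percentiles()` reports the 5/25/50/75/95th percentiles of the sized
particles per spot (box = interquartile range, whiskers = 5–95%), using
linear interpolation between closest ranks (R's `quantile` type 7) — the
most common convention, stated here because published summaries rarely name
an estimator. Fluorescent-but-unsized particles are counted separately,
never imputed. Note that figure legends in this literature sometimes
describe the box as the "25 to 50 percentile range"; as a 25–50 box is not a
standard plot element, the package treats that as the conventional 25–75
interquartile box.

## Replicates, reports and reproducibility

Colocalization fractions are computed within each (biological, technical)
replicate and averaged unweighted across replicates with an SEM
(`coloc_summary()`), mirroring how mean-of-replicates percentages are
reported in this literature; whether published percentages were averaged
before or after normalization is generally unstated, so the
per-replicate-then-average convention is this package's choice. The IgG
control is compared, never subtracted: `assess_background()` flags a spot
whose count is within 1.5× of the IgG count (threshold tunable), because
colocalization fractions from a background-level spot are not
interpretable — the flag travels into the randomness report.

`run_pipeline()` orchestrates simulate/read → tabulate → random model →
sizing and writes a deterministic report bundle (TSV reports with the seed
in every header, a JSON twin of the randomness report, and a manifest);
identical configurations produce byte-identical bundles. All randomness in
the package flows through explicit seeds.

## Numerical choices and degenerate inputs

* Reported percentages and folds round half-away-from-zero at one decimal
  (`round_half_up()`), matching print conventions; objects keep full
  precision.
* Closed-form predictions are exact products; the identity marginals →
  prediction → marginals holds to machine precision and is tested.
* `fold` is undefined (flagged, `NA`) when the predicted fraction is 0 and
  the measured is positive; direction is still reported.
* Empty spots raise an explicit error distinct from spots with particles
  but no sizes; neither ever surfaces as a division by zero.
* Degenerate marginals (0 or 1) are valid and exercised in tests; the
  Monte-Carlo reassignment handles them without special-casing.

The validation suite runs the calibration and power studies at 1,000
simulated chips of 5,000 vesicles (≈500 particles per spot) with marker
prevalence 30% per tetraspanin — large enough for stable rejection-rate
estimates while keeping the whole suite fast; the power study moves 15
percentage points of phenotype mass from the single-positive phenotypes into
the triple, a deviation of the size the platform is meant to detect.

## Limitations

The null model is conditional independence per spot; the package deliberately
does not fit dependence structure (log-linear interactions, copulas) beyond
reporting deviations from the null. Fraction-only inputs cannot support exact
inference, only printed-precision prediction and folds. Sizes are reported as
measured on the dried chip; no shrinkage correction is applied at analysis
time, since the true factor is unknown — shrinkage exists only inside the
simulator's measurement model.
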
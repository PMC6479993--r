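---
title: "Methods: fingerprint fusion for geographical authentication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint fusion for geographical authentication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Dried sclerotia of the medicinal fungus *Macrohyporia cocos* are peeled
into two separately traded products — the inner part (Poria) and the
epidermis (Poriae Cutis) — whose quality depends on where the material was
cultivated. `fusefinger` implements a chemometric workflow that
authenticates the geographic origin of such material from three
complementary fingerprints per sample: liquid chromatograms recorded at
242 nm and 210 nm, and an ATR-FTIR spectrum. Eight origin classes are
discriminated by partial least squares discriminant analysis (PLS-DA),
either from a single technique or after fusing several techniques (and
the two parts of one sclerotium) at low or mid level.

Because no public measurement set accompanies this design, the package
ships a first-class synthetic generator that reproduces the study's
sampling plan — 78 sclerotia (10 per class for classes 1–7, 8 for
class 8), two parts each, 156 samples — and the artefacts the real
preprocessing has to deal with: run-to-run retention-time shifts,
an early-eluting baseline, detector noise, and bands that exist in one
part only.

# The synthetic study conditions

`sim_params()` holds every generator knob; the defaults define the
simulated study conditions and are used by all seeded end-to-end checks.

* **Chromatograms** are sums of Gaussian peaks (an exponentially modified
  Gaussian option exists for tailing peaks) on a 0–60 min (inner) or
  0–65 min (epidermis) axis at 0.5 s spacing — 7201 and 7801 points. Each
  injection draws one rigid retention shift (sd 2 s) shared by its two
  detection channels, on top of a baseline `2.0·exp(-t/2.5 min)`
  concentrated before 11 min, and additive noise (sd 0.003).
* **Spectra** are sums of Gaussian bands (Lorentzian selectable) on a
  4000–650 cm⁻¹ axis at 2 cm⁻¹ spacing (1676 points). Band centers follow
  the absorptions reported for this material (2964, 2927, 2873, 1704,
  1643, 1452, 1373, 1259, 891 cm⁻¹, a dominant polysaccharide envelope
  across 1200–950 cm⁻¹, the broad O–H stretch near 3350 cm⁻¹) plus minor
  unassigned fingerprint-region bands; 2964 and 1704 cm⁻¹ are present in
  the epidermis only. The grid spacing of 2 cm⁻¹ is a storage-typical
  choice for a 4 cm⁻¹ instrument resolution.
* **Class structure.** Peak/band heights are multiplied by
  `exp(class effect + within-sample jitter + global intensity factor)`.
  Class effects are drawn once per channel and part from the template
  seed (`rng_seed`), so they are a fixed property of the simulated world;
  per-channel *confusable pairs* — (7,8) at 242 nm, (2,3) and (5,6) at
  210 nm, (4,5) in FTIR — receive nearly identical templates
  (residual sd 0.035 against within-sample sd 0.04–0.05). Each single
  technique therefore confuses a different pair of origins while their
  fusion separates all eight; epidermis templates get 0.6× the class
  separation of inner-part templates, making the epidermis the weaker
  part. These effect sizes were calibrated so the fitted models
  reproduce the expected pattern (FTIR the best single technique,
  LC210 the worst, low-level fusion perfect on calibration and
  validation, low-level ahead of mid-level in Q²) and then frozen.
* The generator does **not** emulate instrument physics, real
  concentration scales, nonlinear (non-rigid) retention drift beyond the
  optional mild linear stretch, heteroscedastic detector noise, or
  ATR-correction artefacts. Passing tests therefore demonstrate that the
  algorithms recover known structure under realistic nuisance, not that
  any particular real dataset would classify perfectly.

# Retention-time alignment (COW)

Correlation optimized warping divides the reference into `N ≈ (n-1)/seg`
segments with fixed boundaries and lets the matching sample boundaries
move by at most `slack` points per segment, both endpoints fixed. Each
candidate sample segment is linearly interpolated onto its reference
segment and scored by Pearson correlation; dynamic programming returns
the boundary set maximising the summed correlations — the global optimum
of the discretised problem (verified in the tests against exhaustive
enumeration on ≤ 60-point signals).

Two numerical choices matter and are part of the scored objective:

* **Degenerate segments.** A segment whose variance is below 1e-10 of the
  signal's per-point variance carries no shape information; its Pearson
  correlation would be numerical noise (±1 on Gaussian tails of order
  1e-20), which the DP would otherwise chase. Such segments score 0.
* **Tie-breaking.** Degenerate stretches leave the boundary placement
  undetermined, so a tiny quadratic penalty (1e-6/(slack+1)² per squared
  point of displacement) pulls undetermined boundaries toward the
  identity warp. The penalty is orders of magnitude below any real
  correlation difference.

The reference chromatogram is the one most similar to all others (highest
mean Pearson correlation, ties to the lowest index), selected per
channel×part dataset. The segment/slack search (`grid_search_cow`) scans
the segment 10–200 × slack 1–20 space (a coarse log-spaced subgrid by
default; `grid = "full"` enumerates it) and maximises mean post-warp
correlation subject to a peak-preservation constraint: no sample's total
area may change by more than `area_tol` (default 5%). Ties prefer the
smaller slack, then the larger segment — the less aggressive warp. A
"simplicity" criterion variant discounting aggressive warps by
`1 − slack/segment` is selectable. The default pipeline uses fixed
segment 100 / slack 5 (≈ 2.5 s of cumulative freedom per 50 s of signal,
ample for 2 s shift draws); the search remains available per block.

After alignment the fixed preprocessing order is **align → reduce →
crop**: one point in three is kept (7201 → 2401, 7801 → 2601; the first
point of each triple), then everything up to and including 11 min is
discarded (→ 1960 and 2160 points). The inclusive crop threshold is
forced by the arithmetic: 441 points of a 1.5 s grid lie in [0, 11] min.

# FTIR preprocessing

Savitzky–Golay second derivative (order-2 polynomial, 15-point window,
derivative with respect to index position; absorptions appear as negative
peaks, no sign flip) resolves overlapped bands, then the ATR
diamond-crystal region 2600–1750 cm⁻¹ (426 of 1676 points) is excluded,
leaving two contiguous segments and 1250 variables. The derivative is
exact for quadratics, and edge points come from one-sided fits
(`signal::sgolayfilt`). Derivative-then-exclude is the default order,
matching a workflow where the derivative is computed in the acquisition
software and the region dropped before chemometric analysis;
exclude-then-derivative (per contiguous segment, avoiding the splice) is
available and differs only near the cut. Taking the derivative against
index rather than wavenumber only rescales each variable, which the
subsequent unit-variance scaling cancels.

# Data fusion

*Low-level* fusion concatenates the preprocessed variable blocks after
matching rows on the pairing key — `sample_id` when fusing techniques
within one part, `sclerotium_id` when fusing the two parts of one
sclerotium (each block must then contribute exactly one row per
sclerotium). Any unmatched or duplicated key is a hard "correspondence
violation" error; silent reordering is never allowed, and every fused
column records its block of origin.

*Mid-level* fusion first compresses each block to PCA scores. Blocks are
centered and unit-variance scaled; the number of components is chosen by
7-fold element-wise *speckled* cross-validation: elements are assigned to
folds along diagonals, held-out elements are EM-imputed from the rank-k
reconstruction, and k minimises the prediction error sum of squares
(PRESS), capped at `k_max = 20`. A simpler rule — smallest k reaching 90%
cumulative explained variance — is selectable. When a calibration subset
is given, scaling and loadings are fitted on it alone and applied to the
validation rows, so no validation information leaks into the features.

# PLS-DA

The classifier is NIPALS PLS2 on autoscaled predictors and a centered
one-hot response (8 columns). Component selection follows the
per-component cross-validation convention of the SIMCA family: for each
candidate component the current residual matrices are refitted on the
training part of every fold (venetian-blind assignment over row order;
scaling fitted once on the workset), and the held-out incremental error
gives `Q²ₐ = 1 − PRESSₐ/SSₐ₋₁`. The selected `A` is the largest count
whose every component passes `Q²ₐ ≥ 0.05`; when the first component
already fails, the model's status is `"failed"` — a value, not an
exception, because a dataset genuinely can fail to support a discriminant
model (the label-shuffling test exercises exactly this).

Reported figures of merit: `R²Y(cum) = 1 − RSS_A/SSY` (fit to the
response), `R²X(cum)` (explained predictor variance, reported alongside
since "explained variance" is otherwise ambiguous between the X- and
Y-sides), and `Q²(cum) = 1 − Π(PRESSₐ/SSₐ₋₁)` (multiplicative
convention; a plain `1 − PRESS_A/SSY` full-path variant is selectable).
Classes are assigned by the argmax of the predicted membership row, ties
to the lowest class index. Variable importance in projection is

VIP_j = sqrt( p · Σₐ SSYₐ·(w_{aj}/‖wₐ‖)² / Σₐ SSYₐ ),

whose mean square is 1 by construction (Σ VIP² = p, asserted to 1e-8).
The permutation test refits the model 30 times under uniformly permuted
labels with the identical selection procedure, records each permuted
R²Y(cum)/Q²(cum) (failed fits as 0) and the correlation between permuted
and original one-hot labels, and passes when every permuted value is
strictly below the original.

# Evaluation

The Kennard–Stone maximin algorithm splits each 78-row dataset into 52
calibration and 26 validation samples (ratio 2:1) on the autoscaled
matrix the model will use: the most distant pair first, then repeatedly
the sample farthest from the selected set; all ties to the lowest index,
so the split is deterministic. For a block set that feeds both a low- and
a mid-level model, the split is computed once on the low-level
concatenation, so paired models (and the two-part combinations, whose
rows are sclerotia) share it — mid-level PCA is then fitted on the
calibration rows of that split.

Per-class metrics are one-vs-rest: sensitivity TP/(TP+FN), specificity
TN/(TN+FP), and efficiency as their product, exactly as printed in the
original equations; the common geometric-mean variant √(sens·spec) is
available behind a flag in case the printed product silently dropped a
root. Accuracy is the trace of the confusion matrix over its total,
reported as a percentage with two decimals. Metrics of an empty class
are `NA`, never 0. `compare_models()` ranks model rows by validation
accuracy, then Q²(cum), and reduces the table to three data-driven
booleans: fused ≥ single (validation accuracy), low-level ≥ mid-level
(Q²cum), inner ≥ epidermis (validation accuracy).

# The pipeline

`run_pipeline(pipeline_config(seed = ...))` chains all stages for a
recipe table; the default table is the 24 dataset×level combinations of
the study (5 single-technique, 9 low-level, 10 mid-level rows, including
the six two-part combinations). One master seed fans out to per-stage
child seeds, so reruns are bit-identical; each recipe is isolated — a
failing recipe is recorded with its message, never aborting the run. The
permutation test is configured per recipe (`permute_recipes`) rather than
run for all 24, since 720 refits would dominate the runtime; the
acceptance script runs it for the headline low-level FTIR–LC242 model.

```{r}
library(fusefinger)
report <- run_pipeline(pipeline_config(seed = 1))
report$models
```

# Problem sizes and limitations

The shipped checks run the full-size design (156 samples, 7201/7801-point
chromatograms, 1676-point spectra). The seeded repeatability suite that
verifies the qualitative orderings uses 20 seeds with a four-recipe
subset (the headline fusion model, its mid-level counterpart, and its two
constituent single techniques), which exercises every stage while keeping
a complete run in minutes; the full 24-recipe table is run once per seed
in the acceptance script.

Known limitations: COW here is strictly one-dimensional and rigid-shift
oriented (no peak detection, no multivariate warping); high-level
(decision-level) fusion is out of scope; the only PLS algorithm is
NIPALS — SIMPLS, OPLS-DA and sparse variants are not provided (a second
algorithm would change VIP values only marginally while doubling the
surface to validate); and the permutation pass criterion is the strict
"all permuted below original" rule — no regression-line extrapolation
over the label correlations is attempted.
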
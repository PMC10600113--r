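---
title: "paleojaw: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{paleojaw: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleojaw)
```

paleojaw implements a four-stage comparative analysis of the ankylosaur
feeding apparatus: dry-skull muscle force estimation, third-class lever
mechanics of biting, mesh-weighted post-processing of finite-element stress
fields, and phylogenetic comparative analysis of mandibular mechanical
advantage. This vignette records the models, the assumptions behind them,
the defaults, and the numerical and design choices a maintainer should know
about.

## Dry-skull muscle forces

For a muscle of reconstructed length ML (mm) and volume MV (mm³):

* fibre length FL = ML/3 — the standard approximation for parallel-fibred
  reptilian jaw adductors whose fibre architecture cannot be observed in
  fossils; no pennation correction is attempted;
* PCSA = MV/FL (mm²);
* F = PCSA × σ with σ = 0.3 N mm⁻², the conventional isometric stress for
  reptilian jaw muscle. σ is a `sigma` argument everywhere so sensitivity
  analyses can vary it; forces are simply proportional to it.

All arithmetic is at full floating precision; nothing is rounded between
steps. The packaged measurement tables print intermediate quantities (FL,
PCSA) rounded to one decimal, so chains recomputed from ML and MV can differ
from transcribed printed values by up to ~0.4% (the worst case is the
largest pterygoideus muscle, where a 0.03 mm fibre-length rounding moves
the force by that much). Tests therefore compare the full-precision chain to
transcribed values at 0.5% relative tolerance, and relative muscle force
(printed at one decimal of percent) additionally at the printed precision
(±0.05), which for the smallest entries is the wider of the two.

Forces are **unilateral** (one side of the head); nothing in the package
doubles them. Size is removed by isometric scaling,
`F_scaled = F · S_ref/S_src`, with S the total cranium-plus-mandible surface
area: under isometry both force (∝ cross-section) and surface area scale as
length², so the ratio enters to the first power. For the packaged skulls the
scaled total is 2013.9 N against an unscaled 1428.7 N, a ~41% increase; note
that some published summaries of these data describe the increase as 29%,
which is inconsistent with the tabulated surface areas — the tables are
taken as normative. One transcribed scaled cell (the smaller
pseudotemporalis) likewise disagrees with its own row arithmetic by 0.7%
(118.8 vs 83.7 × 1.40962 = 118.0 N); the package reproduces the arithmetic,
and the discrepancy is treated as a transcription artefact of the source
table rather than a target.

## Lever mechanics

The jaw is modelled as a static, bilaterally symmetric, two-dimensional
third-class lever about the jaw joint. For each muscle:

* `F_res = F_mus · cos α · cos β`, with α and β the deviations of the line
  of action from vertical in the sagittal and coronal planes. Angles are
  accepted in degrees — the unit of every measurement table — and converted
  internally; radians never appear in interfaces. Angles ≥ 90° are rejected
  (such a muscle could not adduct).
* `L_in = d · sin q`, with d the joint-to-insertion diagonal and q the angle
  between line of action and d. A moment arm cannot exceed d, so q > 90° is
  replaced by its supplement; q = 90° (L_in = d) and α = β = 0 are allowed.
* `F_bite = F_res · L_in / L_out` and `MA = L_in / L_out`.

Two precedence rules reflect how the packaged tables were evidently
computed. First, bite forces are always recomputed from `F_mus` through the
cosine resolution, never taken from a transcribed resultant-force column:
for the ankylosaurid specimen the transcribed bite-force cells are exactly
consistent with the cosine path but not with the printed resultant column
(which is unexplained in the source and disagrees by up to ~35% for the
ventral pterygoideus). Second, a measured in-lever, when supplied, wins over
`d·sin q`: two transcribed rows contradict the trigonometric identity (one
by 2.9 mm) while the bite-force columns follow the printed in-levers. With
these rules, all 21 ankylosaurid bite-force cells reproduce within 1%, the
three totals within 0.5%, and all 21 mechanical-advantage cells at the
printed two decimals. Six of the seven printed in-levers agree with
`d·sin q` to 0.2 mm (five to 0.1 mm); the outlier is documented rather than
patched. The nodosaurid panels of the transcribed bite table are internally
inconsistent (their cells follow the printed resultant column and out-lever
distances that are not the printed ones, which appear to be copied from the
other specimen's panel); they load and compute cleanly but are not used for
validation.

## FE stress post-processing

The package post-processes per-element solver output; it does not solve
elasticity, mesh geometry, or assign material properties. Von Mises stress
is computed from six tensor components in the fixed order
(xx, yy, zz, xy, yz, xz) when not supplied directly. The summary statistic
is the Mesh-Weighted Arithmetic Mean, the element-weight-weighted mean of
von Mises stress. The weight is element volume for solid meshes (the
natural size measure for tetrahedral meshes; an area column works equally
for shells) — the schema deliberately carries a generic `weight` column.
Sums are accumulated by R's extended-precision (long double) summation, so
multi-million-element fields are stable; tests verify agreement with an
independent streaming mean to 1e-10 relative at 10⁵ elements.

No automatic exclusion of constraint-adjacent artefacts is performed — that
would be a heuristic invisible to the reader; instead `mwam()` and
`summarize_stress_field()` accept an explicit element-id exclusion list.
Paired model comparison (e.g. original vs secondary-palate-removed) is the
signed percent difference of MWAMs relative to the original. The weight
fraction above a display cap (default 4 MPa) summarises hot-spot extent.

The published stress magnitudes for the two skulls are not reproducible on
a desktop — they require the CT-derived meshes and an FE solve — so the
test suite substitutes property-based checks: uniform-field identity,
min/max bounding, invariance to element order and weight rescaling, merge
conservation, and the robustness ordering that motivates the statistic (a
negligible-weight stress spike moves the MWAM less than the unweighted
mean).

## Mechanical advantage evolution

For the comparative sample, anterior and posterior MA come from 2D
measurements (in-lever to the coronoid process centre of the adductor
insertion; out-levers to the two ends of the tooth row); any consistent
unit works.

**Calibration.** The cladogram is dated against tip first appearances:
every node to the oldest descendant FAD, the root pushed back by a
`root_buffer` (default 1 Myr — the source analysis does not state its
value, and 1 Myr is the smallest round buffer that guarantees repair time
exists). Zero-duration branches are then repaired root-outward by the
"equal" rule: the span of the first ancestral branch with positive duration
is divided equally along the path down to the offending branch. Repair only
lifts node dates, never lowers them, so dates away from repair chains equal
the naive minimum-age dates. Note that under minimum-age dating the tip (or
subtree) attaining each node's age always creates a zero-length branch, so
the repair always engages somewhere; with a positive buffer the result
provably has strictly positive durations and monotone ages, which the suite
checks across 1000 random 24-tip trees with deliberately clashing FADs.
Tips terminate at their FAD; last appearances are retained for range
display only. Polytomies are rejected with an explicit error rather than
silently randomly resolved.

**Ancestral states.** MA evolves under single-rate Brownian motion. The
state estimate at a node is the GLS mean of tips on the tree re-rooted at
that node, which equals the branch-length-weighted squared-change-parsimony
solution and the joint maximum-likelihood reconstruction; the suite checks
it against both an independent numerical maximizer of the joint likelihood
(to 1e-6) and an established independent implementation. The rate estimate
is the profile-ML `σ̂² = (x−μ̂)ᵀC⁻¹(x−μ̂)/n`, which carries the classical
(n−1)/n bias when the root state is estimated; at the 24-taxon sample size
that bias (4.2%) is real and detectable, so the recovery test asserts
unbiasedness of the corrected estimator n/(n−1)·σ̂² and separately checks
the raw estimator against its exact expectation. Conditional variances
σ̂²/(1ᵀC⁻¹1) are reported per node; no confidence-band drawing is provided.
Zero-length branches are rejected with an error pointing at recalibration.

**Phylomorphospace.** Tips are placed at their observed (AMA, PMA) exactly
— observed data are never smoothed — nodes at their estimates, and the edge
list follows the topology.

## Synthetic data

Generators are pure functions of an explicit, mandatory seed. They emulate:
muscle sets with log-normal lengths and volumes at ankylosaur magnitudes
(analytic forces returned alongside); element stress fields with log-normal
weights and stresses, optional constant fields and optional
negligible-weight spike injection; and comparative datasets (random binary
topology, FADs in a stated window with deliberate ties, BM traits with
known rate and root, true internal states returned). Defaults — 7 muscles,
10⁴ elements, 24 tips — match the scale of the packaged analysis while
keeping every test seconds-fast; the statistical suites use 10⁵ elements,
500 rate-recovery replicates and 1000 calibration trees, sizes chosen so
Monte-Carlo error is decisive for the properties asserted. What the
generators do not emulate: spatial correlation of stress within a mesh,
muscle-by-muscle anatomical correlations, non-uniform fossil sampling, and
topology uncertainty — so passing tests demonstrate correctness of the
estimators, not robustness to those realities. The packaged 24-taxon
comparative fixture (`*_synthetic.*`) uses real genus names but synthetic
ages and trait values spanning the observed ranges, with the nodosaurid
lineage given the higher posterior MA; it stands in for a supplementary
dataset that is not distributed in tabular form.

## Degenerate inputs and errors

Non-positive lengths, volumes, areas, levers and weights raise
`invalid_measurement`/`invalid_field` conditions; angle-domain violations
raise `invalid_orientation`; schema problems (missing columns, unknown
muscles, thousands separators, duplicated ids) raise `schema` errors that
name the file, column and offending rows, and `validate_and_load()`
aggregates them across files before any computation. The pipeline aborts
with the failing stage's name and preserves partial outputs. Output bundles
contain no timestamps, so a rerun at the same config and seed is
byte-identical — the manifest records package version, seed and a config
hash.

## Known limitations

* Static bite model: no gape-dependence, no jaw-joint reaction forces, no
  3D moment arms from meshes, no dynamic (Hill-type) muscle behaviour.
* Isometric σ and the ML/3 fibre approximation set absolute force scales;
  comparisons between skulls are far more robust than absolute newtons.
* The equal calibration is the only dating method offered; no cal3/mbl
  variants, and no OU or early-burst trait models.
* MWAM weights must be supplied by the solver export; the package cannot
  recover element volumes from connectivity.
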
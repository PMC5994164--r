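---
title: "Phylogenetic eigenvector maps for palaeophysiological inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic eigenvector maps for palaeophysiological inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteopem)
```

## The inference problem

Physiological rates fossilise only indirectly. Bone histology preserves a
quantitative trace: highly vascularised fibrolamellar bone is deposited
fast and, across extant amniotes, the degree of cortical vascularisation
correlates with both local bone apposition rate and resting metabolic
rate. `osteopem` turns that correlation into a predictive model. Extant
species supply training pairs (primary osteon density, measured response);
extinct taxa are grafted as extra tips onto the time-calibrated phylogeny
and receive predictions that respect both their measured density and their
phylogenetic position.

Two response variables are supported by the same code path and differ only
in input files and unit labels: mass-corrected resting metabolic rate
(mL O₂ h⁻¹ g⁻⁰·⁶⁷) and periosteal bone apposition rate (μm/day).

## The predictor: primary osteon density

Vascular density is measured as an **area fraction**: the area of primary
osteons — each vascular canal *together with* its lamellar infill — divided
by the whole compact-bone area in the field of view. Counting infill with
the canal makes juvenile extant bone (open canals) and adult or fossil bone
(infilled osteons) commensurable, and an area fraction, unlike a
canal-count density, does not change when canals run parallel rather than
perpendicular to the section plane.

On a labelled mask (0 = background/medullary space, 1 = compact bone
matrix, 2 = primary osteon), `osteon_density()` is exactly
`#2 / (#1 + #2)` over the region of interest; background never enters the
denominator. Measurements are taken in **four** cortical regions — to
buffer mechanical-stress-related local structure — and averaged
arithmetically into the species value (`species_density()`); how the four
regions should be pooled is genuinely open, and the arithmetic mean was
chosen as the simplest unbiased pooling, with per-region values always
retained in the report. Coordinates are 0-based with half-open bounds.
Segmentation of raw micrographs into labels is out of scope: the package
consumes already-labelled masks (PNG/TIFF, 8-bit labels).

## PEM construction

For a rooted tree with tips `1..n` and edges `1..m`, the influence matrix
`B` records which edges lie on each root-to-tip path (preorder edge
ordering, so bases are reproducible). Edge `j` of length `b_j` (Ma) gets
weight `w_j = ψ b_j^((1−a)/2)`:

* `a = 0` — square-root weighting; the weighted cross-product
  `(Bw)(Bw)ᵀ` then *equals* the Brownian-motion covariance matrix of the
  tips (shared root-to-tip path lengths), which the tests verify against a
  brute-force path-enumeration oracle to 1e-10;
* `a = 1` — all edges weigh `ψ` regardless of length (punctuated-like
  divergence);
* `ψ` is fixed at 1: the regression coefficients absorb any overall trait
  scale, so `ψ` is not identifiable from a single-trait fit (scaling `ψ`
  by `c` scales singular values by `c` and leaves eigenvectors unchanged,
  a tested invariant).

Columns of the weighted matrix are centred over the training tips and the
thin SVD taken. Numerical rank is decided explicitly: singular values below
`1e-10 × max(d)` are dropped. SVD signs are fixed by making each
eigenvector's first nonzero entry positive, so fitted bases are
platform-reproducible; centring guarantees at most `n − 1` eigenvectors.

**Fossil tips and the edge set.** The analysis tree (extant + grafted
fossils) is built first; the training basis is computed over extant tips
only, but on the edge set of the *full* tree. Edges lying only on fossil
paths contribute constant (all-zero) columns that centring removes, while a
fossil's score vector `s = (row_w − colmeans) V diag(1/d)` is computed from
its own influence row over the same edges. A target whose weighted row
coincides with a training tip reproduces that tip's eigenvector row
exactly, which anchors the LOOCV identity below.

Branch lengths of empirical Ma-scale trees are rounded to the nearest
integer Ma before analysis (half-up — `2.5 → 3` — because "nearest" needs a
deterministic tie rule). Branches that round to zero are retained and
logged, not clamped: the weight function maps them to weight 0 for
`a < 1`, which is the faithful degenerate behaviour. Rounding is an option
(`round_branches`) because synthetic trees are not on an integer-Ma scale.

## Model fitting, selection, validation

The regression of `log10(response)` on an intercept, selected eigenvectors
and `log10(density)` is plain OLS; base-10 logs are used because both
source datasets and the resulting figures are conventionally reported in
log10 units, and back-transformation is plain exponentiation without bias
correction (predictions are reported in natural units as printed in
comparative datasets).

AICc counts *all* estimated parameters (`k` = coefficients + residual
variance): `AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)`. Candidates with
`n − k − 1 ≤ 0` or singular designs are rejected, not raised. Model search
has two nested loops:

* **eigenvector selection** (`selection = "forward"`, default): the
  eigenvectors are offered in order of decreasing singular value and
  accepted while AICc decreases; `"all"` and `"none"` are run-time
  alternatives. Eigenvector selection strategy is this package's design
  choice, exposed as an option precisely because it is a choice.
* **steepness** (`a = "grid"`, default): `a ∈ {0, 0.01, …, 1}`, the
  selected model's AICc minimised over the grid. Whether the original
  analyses estimated steepness or used a default is not documented; both
  modes (`"grid"`, fixed numeric) are exposed and neither is asserted as
  historically authentic.

Ties within `1e-9` AICc go to fewer parameters, then to smaller `a` —
zero-residual fits (AICc `-Inf`) are handled by the same rule. When even
the base model lacks the degrees of freedom for the AICc correction
(possible at the 4-species minimum), the base regression is fitted anyway
and AICc reported as undefined.

**LOOCV** re-does *everything* per fold — basis, steepness grid,
eigenvector selection — with the held-out species scored as a target.
PRESS is the sum of squared log10 errors over completed folds; a failing
fold is flagged, never silently dropped. The suite checks the LOOCV path
against a brute-force oracle that rebuilds each fold from serialized
Newick/CSV files (equality to 1e-10 over 20 datasets).

**Intervals.** The 95% bounds are **prediction** intervals by default,
`point ± t(0.975, n−p) √(σ² (1 + hᵀ(XᵀX)⁻¹h))`, because the natural reading
of a per-fossil uncertainty box is the uncertainty of a *new observation*;
`interval = "confidence"` switches to mean intervals (drop the `1 +`).
Whether published per-fossil "95% confidence intervals" in this literature
are prediction or confidence intervals is typically ambiguous; the default
is the wider, more conservative reading. Simulated coverage under the
generator's conditions is checked to lie in [0.90, 0.99].

## Ancestral states

After prediction, the complete sample set (observed responses at extant
tips, predicted values at fossil tips, all on log10 scale) is mapped onto
the tree by maximum-likelihood Brownian-motion reconstruction —
equivalently GLS with the BM covariance — via the re-rooting estimator;
the tests verify it against an explicit-covariance GLS oracle to 1e-8.
Fossil predictions enter as *known* values: prediction uncertainty is not
propagated into ancestral states (a recorded limitation, shared with the
standard workflow this mirrors). Zero-length internal edges are collapsed
for the computation and collapsed nodes inherit their parent's estimate;
constant tip values yield the degenerate exact reconstruction (that value
everywhere, variance 0). Internal estimates are convex combinations of tip
values, so they always lie within the observed range — a tested invariant.
Reconstruction is done on the log scale (consistent with the model);
node and edge-gradient exports carry both log10 and natural values since
either may be wanted for a colour scale.

## The synthetic-data generator

Every stage is testable without external data:

* **Trees** — pure-birth (Yule) time trees, conditioned on `n` or stopped
  at time `t`. Default birth rate 1 per lineage per Ma: together with the
  default BM rate this keeps simulated log10 traits within the ~2 orders
  of magnitude spanned by real amniote RMR data. (The rate only sets the
  time unit's meaning; all invariants are scale-free.)
* **Traits** — `log10 y = β₀ + β₁ log10 d + BM(σ²_BM) + N(0, σ_e²)`, with
  `log10 d` uniform between the log bounds of the density range. Defaults
  `β₀ = 0, β₁ = 1, σ²_BM = 0.5/Ma, σ_e = 0.1`, density range (0.01, 0.5) —
  the conditions used throughout the recovery and calibration tests. Every
  latent value is returned as a truth record.
* **Masks** — a circular bone field with non-overlapping rasterized discs
  of osteon placed at random until the target area fraction is first
  reached (the sampled radius range adaptively shifts to its small end as
  the section crowds, so fractions up to ~0.5 stay reachable). The
  recorded achieved fraction is *exactly* what `osteon_density()` returns,
  because both count the same pixels.

Synthetic fossils are made by hiding the response of a known tip
(`as_target()`), so prediction-recovery tests have exact truth. What the
generator does *not* emulate: real osteon shape and spatial clustering,
measurement error in densities, tree mis-calibration, and non-BM trait
evolution — so green tests demonstrate correctness of the machinery under
the model's own assumptions, not robustness to their violation.

## Problem sizes and determinism

The test suite and the acceptance script use 2–64-tip trees, 200-replicate
slope-recovery and 500-replicate coverage runs at 32 tips, 100-tree oracle
sweeps, and 200-px masks; these sizes give stable Monte-Carlo estimates
while keeping a full run in well under a minute on one core. All
randomness flows through explicit seeds; identical configurations produce
byte-identical report bundles (a tested property, with the output
directory excluded from the provenance echo for exactly that reason).

## Known limitations

* Fossil prediction uncertainty is not propagated into ancestral states.
* One steepness parameter for the whole tree; no per-edge steepness, no
  reticulations.
* Single co-predictor (osteon density); multi-predictor selection would
  need a different search strategy at these sample sizes.
* The AICc-based forward selection is greedy; with strongly correlated
  eigenvector effects an exhaustive search could select differently.
* Reproduction of the published per-fossil values requires the original
  deposited inputs, which are not redistributed with the package.
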
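---
title: "Models and methods behind corticonn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind corticonn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(corticonn)
```

This vignette is the package's own account of the science it implements:
the statistical models, their assumptions, the tunable parameters and the
numerical and design choices that were genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Data model

A *connectome* is a directed adjacency over named cortical areas with
tri-state entries: present (1), absent (0) or unknown (`NA`). The third
state is essential for tract-tracing compilations: a pair that was never
tested is not an absent connection, and `corticonn` never imputes unknown
to absent. Matrices may be rectangular (rows = injected areas, columns =
all areas), as produced by retrograde-injection studies; analyses that
need complete information (cliques, efficiency) first restrict to the
*edge-complete block* via `edge_complete_subgraph()`, implemented as a
greedy elimination of the area with the most unknown pairs — exact in the
common case where the fully known block is the injected square block.

Each area carries a cytoarchitectonic value (ordinal cortical type, e.g.
1–5 with intermediate levels allowed, or neuronal density in neurons/mm³
— never mixed within a species), atlas-native coordinates, and a
rostrocaudal coordinate normalized to [0, 1] with 1 = most rostral.
Distances may be geodesic, Euclidean or ordinal border counts; ordinal
scales are treated as numeric before rescaling, because both enter the
same logistic model.

## 2. Wiring model

For ordered pairs with known status, both predictors are linearly
rescaled to [0, 1] *within species and over exactly the analyzed pairs*
(`build_pair_table()`), so that pooled cross-species models compare
relative, not absolute, gradients. The model is a binary logistic
regression (`fit_logistic()`, delegated to `stats::glm`'s IRLS with
log-likelihood tolerance 1e−8, ≤ 100 iterations); the cross-species model
adds a 0/1 species dummy — reference level the alphabetically first
species, a convention the tests pin down because the interaction's sign
depends on it — and a species × dissimilarity interaction, evaluated with
a likelihood-ratio test on 1 df. There is deliberately no
species × distance interaction. Perfect separation or non-convergence is
flagged (`converged = FALSE`, warning) while coefficients are still
reported; the spec's examples and error contract disagree on this point
and the error contract won.

Robustness of the dissimilarity effect to the subjectivity of ordinal
typing is probed by `type_reassignment_robustness()`: a fraction *f* of
areas is moved one type up or down at random (clamped: reflected at the
scale ends; stretched: the top may be exceeded), the model refit, and the
coefficient compared with a full label-permutation null.

## 3. Laminar origin

NSG% = 100·N_SG/(N_SG + N_IG) summarizes where a projection originates:
near 0 infragranular ("feedback"-like), near 100 supragranular
("feedforward"-like), near 50 "lateral". Its predictors are the signed
cytoarchitectonic difference cyto(origin) − cyto(termination) and the
signed rostrocaudal offset. The offset sign convention in the source
literature is internally inconsistent; `corticonn` fixes **positive =
rostral origin projecting to caudal termination**, i.e.
rc(origin) − rc(termination), and the antisymmetry is tested.

Prediction uses support vector regression with C = 1. Only C is fixed by
the protocol we follow; the kernel is chosen **linear** with
ε = 0.1·SD(training NSG%), for three reasons: a linear model makes
cross-species extrapolation well-posed, gives the testable antisymmetry
property of the predicted NSG% matrix, and avoids inventing kernel
hyperparameters the protocol never stated. No SVM backend exists in the
supported dependency set, so the primal problem
½‖w‖² + C·Σ max(0, |r| − ε) is solved directly by BFGS from a ridge
start (`svr_fit()`); with one or two predictors this is a 2–3 parameter
convex problem and the piecewise-linear loss is unproblematic in
practice (the recovery and null tests exercise it).

Evaluation is strictly out of sample: 70% of records train, 30% test,
repeated (default 1,000; tests and pipeline use smaller documented
values), Spearman ρ between held-out actual and predicted values per
repetition. Predictors are standardized on the training split only.
Nulls retrain on shuffled NSG% (100 shuffles; each shuffle uses 50 — the
tests use fewer — internal repetitions rather than 1,000, a documented
tractability deviation). Predictor sets are compared with a paired
sign-flip permutation test on per-repetition ρ differences, which
requires the two evaluations to share a seed stream. Binary
feedforward/feedback labels reuse the identical protocol with the SVR
trained on labels coded 0/100 and held-out scores assessed by ROC AUC
(Mann–Whitney form, ties 0.5).

Extrapolation to a cortex without tract tracing (`map_human_regions()` +
`extrapolate_to_target()`) averages the cell densities of the
cytoarchitectonic areas assigned to each target region, min–max
normalizes densities within species (source and target densities are on
different measurement scales — this is a declared knob, not a claim of
equivalence), and predicts NSG% for *every* ordered region pair,
irrespective of whether a connection exists; predictions are clipped to
[0, 100].

## 4. Two-sample machinery

The energy statistic is the Aslan–Zech logarithmic-potential form
Φ = −n⁻²Σ_within(x) ln|Δ| − m⁻²Σ_within(y) ln|Δ| + (nm)⁻¹Σ_between ln|Δ|,
larger = more separated, with |Δ| clipped below at ε = 1e−8 so tied
values contribute a large-but-finite potential rather than an infinity;
dropping zero distances instead would silently change sample sizes. The
KS statistic is the exact ECDF sup handling ties. Both tests build their
null by pooling and re-splitting labels; **all** permutation p-values in
the package use the add-one rule (b + 1)/(m + 1), hence lie in (0, 1]
and are never exactly zero. Both loops are in C++ (the pairwise log
potential is precomputed once, so each permutation costs O(N²) array
sums); the energy test is still quadratic per permutation, which is why
pipeline defaults keep present/absent comparisons to a few thousand
pairs.

Partial Spearman correlations use the first-order formula on Spearman
correlations; the degenerate case |r·z| = 1 errors rather than returning
a 0/0 limit.

## 5. Core–periphery and communication

Cliques are undefined on a directed graph until a projection rule is
declared. The default is **mutual** (undirected edge iff both directions
present) with **any** available; the published clique sizes for the real
datasets may depend on this undeclared choice, so both are surfaced and
the partition records which rule produced it. Maximal cliques come from
an in-package Bron–Kerbosch with pivoting and degeneracy-order outer
loop, verified against exhaustive subset enumeration. The core is the
union of *all* maximum-size cliques (ties kept); significance compares
the maximum clique size with 1,000 surrogates from Maslov–Sneppen
directed double-edge swaps — 10·|E| accepted swaps per surrogate,
rejecting self-loops and duplicate edges, preserving every in- and
out-degree exactly (tested exactly, not approximately).

Communication efficiency is computed on binary graphs only.
Shortest-path in/out efficiency is the mean of reciprocal BFS hop counts
(1/∞ = 0, normalization by n − 1). Random-walk efficiency is the mean
reciprocal mean-first-passage time, with MFPTs from the fundamental
matrix Z = (I − P + 1πᵀ)⁻¹ of the row-normalized transition matrix,
H(i,j) = (Z(j,j) − Z(i,j))/π(j). This requires strong connectivity; the
package errors with the component decomposition rather than silently
restricting (restriction to the largest strongly connected component is
an explicit option in analyses built on top, never a default). Core and
periphery are compared per measure with KS permutation tests on
core/periphery label shuffles.

## 6. The synthetic cortex: what a green test establishes

`synthetic_spec()` encodes the stated world the analyses assume: areas
on a 10 mm sheet (uniform, grid or line layout), cytoarchitecture as a
monotone function of distance from a gradient origin mapped onto the 1–5
type range plus Gaussian noise (SD 0.25 by default; equal-frequency
binning for ordinal scales so every level is populated), wiring sampled
independently per ordered pair from the logistic model with default
(β₀, β_d, β_c) = (0, −3, −2) — coefficients of the magnitude the wiring
analyses are designed to detect — and NSG% = 50 + 30·(signed cyto
difference scaled by its SD) + N(0, 5²), clipped to [0, 100]. The signed
difference is symmetric around zero by construction, so scaling by the
SD *without re-centering* keeps equal-cytoarchitecture pairs at exactly
50, the lateral midpoint. An optional planted reciprocal clique provides
ground truth for core recovery. Default 100 areas sits in the range of
the real compilations (29–63 injected areas); the LR-calibration tests
use 50 per species and the recovery tests 150, as their protocols state.

What the generator does *not* emulate: reciprocity correlations outside
the planted core (sampling is independent per direction, matching the
likelihood actually fitted), cortical folding or realistic geodesics,
heavy-tailed degree distributions, and connection weights. A green
recovery test therefore establishes that the estimators are correct and
calibrated under the model they assume — not that real cortices satisfy
that model.

## 7. Numerical choices and limitations

* Rescaling refuses constant vectors (degenerate affine map) rather than
  returning 0.5s.
* The logistic engine is `stats::glm`; tests verify its optimum against
  an independent BFGS maximizer of the likelihood to 1e−6.
* Permutation counts: module tests use reduced counts for speed; the
  acceptance suite runs the stated 1,000-dataset calibrations with 199
  permutations per test, at which the add-one threshold p ≤ 0.05 is an
  exact 0.05-level rule.
* Randomness: every public entry point takes a `seed`; `NULL` leaves the
  RNG stream untouched. The pipeline derives all stage seeds from one
  master seed by fixed offsets.
* The pipeline config is JSON (not YAML): the supported dependency set
  guarantees jsonlite but no YAML parser.
* Headline values tied to the external published matrices (specific
  energy statistics, pooled coefficients, cat/marmoset clique sizes)
  require those matrices as inputs; the package reproduces the full
  procedure but ships no stand-in "real" data.
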
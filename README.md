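# corticonn

Comparative analysis of mammalian cortical connectomes: what the physical
and cytoarchitectonic organization of the cerebral cortex says about which
cortico-cortical connections exist, where they originate in the cortical
laminae, and how the network's densely interconnected core communicates.

The package is aimed at systems/comparative neuroanatomists working with
directed, binary, possibly incomplete (present / absent / *unknown*)
tract-tracing connectomes of the kind compiled for mouse, cat, marmoset and
macaque, together with per-area cytoarchitectonic measurements (ordinal
cortical type 1–5 or neuronal density in neurons/mm³) and spatial
coordinates.

## What it computes

**Wiring.** For every ordered area pair with known status, the predictors —
interareal distance *d* and cytoarchitectonic dissimilarity
*c* = |cyto(i) − cyto(j)| — are linearly rescaled to [0, 1] within species,
and connection existence is modeled as

  P(A<sub>ij</sub> = 1) = σ(β₀ + β_d·d01 + β_c·c01),

with cross-species pooling adding a 0/1 species factor and a
species × c01 interaction, assessed by a likelihood-ratio test (df = 1).
Present-vs-absent distributions are compared with the Aslan–Zech
logarithmic-potential energy statistic under label permutation.

**Laminar origin.** NSG% — the percentage of retrogradely labeled
projection neurons found in supragranular layers, 100·N_SG/(N_SG+N_IG) —
is predicted from the signed cytoarchitectonic difference
cyto(origin) − cyto(termination) and, as a competing axis, the signed
rostrocaudal offset, using linear ε-SVR (C = 1) evaluated out of sample
(70/30 splits, repeated; Spearman ρ between held-out actual and predicted
values; shuffled-label nulls; paired sign-flip comparison of predictor
sets; ROC AUC for binary feedforward/feedback labels). A model trained on
one species extrapolates NSG% to all ordered pairs of another cortex after
min–max density normalization within species.

**Core–periphery.** Maximal cliques of the (mutually or any-direction
projected) connectome are enumerated with Bron–Kerbosch (pivoting,
degeneracy order); the core is the union of the largest cliques, its
significance judged against 1,000 degree-matched surrogates built by
directed double-edge swaps. Core and periphery are compared on
cytoarchitecture and on four communication-efficiency measures: in/out
shortest-path efficiency (mean of 1/D) and in/out diffusion efficiency
(mean of 1/MFPT, mean first-passage times from the fundamental matrix of
the random walk).

A synthetic-cortex generator (`synthetic_spec()` / `generate_cortex()`)
produces spatially embedded areas with a noisy cytoarchitectonic gradient,
logistic-model wiring, monotone-noisy NSG%, and an optionally planted
reciprocal clique — with full ground truth retained, so every stage has a
parameter-recovery test without any external data.

## Worked example

```r
library(corticonn)
spec  <- synthetic_spec(n_areas = 50, planted_core_size = 7, seed = 7)
cx    <- generate_cortex(spec)
pairs <- build_pair_table(cx$connectome)
fit_logistic(pairs)
compare_present_absent(pairs, "c01", n_perm = 1000, seed = 1)
evaluate_out_of_sample(cx$laminar, "cyto_diff", n_rep = 200, seed = 2)
part <- detect_core(edge_complete_subgraph(cx$connectome),
                    n_null = 1000, seed = 3)
part
all(cx$truth$planted_core %in% part$core)
```

prints

```
<logistic fit> n = 2450, logLik = -1011.342
                   coef        se            p
(Intercept)  0.02907242 0.1181098 8.055681e-01
d01         -2.92127237 0.3307256 1.019782e-18
c01         -1.47255788 0.3703312 6.998795e-05
<permutation test> statistic = 0.1268, p = 0.000999 (1000 permutations)
<out-of-sample eval> predictors {cyto_diff}: median rho = 0.979 over 200 reps (0 excluded)
<core partition> 1 clique(s) of size 7; core 7 areas, periphery 43, p = 0.000999
[1] TRUE
```

Reading this: the fitted distance and dissimilarity coefficients (−2.92,
−1.47) recover the generative values (−3, −2) within ~2 standard errors;
present connections join significantly more cytoarchitectonically similar
areas than absent ones (energy statistic 0.127, permutation p ≈ 0.001);
held-out NSG% is predicted with median ρ ≈ 0.98 from the cytoarchitectonic
difference alone; and the planted 7-area reciprocal clique is recovered as
the network core, larger than every one of 1,000 degree-matched surrogate
maxima (p = 1/1001).

The same analyses run on real CSV inputs via `load_connectome()` /
`laminar_table()`, or from the command line:

```sh
Rscript -e 'corticonn::corticonn_cli()' simulate --seed 7 --out sim/
Rscript -e 'corticonn::corticonn_cli()' run-all  --seed 7 --out results/
```

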
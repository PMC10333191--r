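---
title: "Methods: connectivity gradients, eccentricity, and their statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity gradients, eccentricity, and their statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own methods: the model each
stage implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one convention exists. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. From time series to gradients

Per subject, the vertex×vertex functional connectivity matrix is the
pairwise Pearson correlation of the vertex time series
(`compute_fc()`). Vertices with zero temporal variance are flagged, set to
zero correlation, excluded from the embedding, and re-inserted as missing
values downstream.

The connectivity matrix is sparsified row-wise (`sparsify_rows()`):
each row keeps its `ceiling(density · (N−1))` largest off-diagonal values
in *signed* order — no binarization, matching the convention of the
gradient toolboxes this pipeline family follows — with `density = 0.10`
by default. The result is generally asymmetric; the subsequent cosine
similarity between rows (`cosine_affinity()`) is symmetric by
construction. Negative cosine similarities are clipped to zero because the
diffusion normalization requires a nonnegative affinity; with a 10%-dense
nonnegative-dominated input, clipping affects few entries.

`diffusion_embedding()` applies the anisotropic normalization
`W = D^−α A D^−α` with α = 0.5 (the density-correcting midpoint between
graph Laplacian and Laplace–Beltrami limits), row-normalizes `W` to a
Markov operator, and computes its eigenvectors through the symmetric
conjugate `D_w^−1/2 W D_w^−1/2`, which is numerically stabler than a
non-symmetric solve; the tests verify agreement with a dense
non-symmetric eigendecomposition of the same operator. The trivial
constant eigenvector at eigenvalue 1 is discarded. Components are scaled
by `λ/(1−λ)` — the diffusion-time-agnostic convention — and
`scaling = "eigenvector"` returns plain unit-norm eigenvectors instead;
the downstream eccentricity statistic is insensitive to this choice up to
a per-component scale. Variance explained is reported as
`λ_i / Σ λ_j` over all retained positive non-trivial eigenvalues. Ten
components are computed by default; eccentricity uses the first three.

A group template is the same pipeline applied to the element-wise mean
connectivity of a reference group (`group_template()`), conventionally
the controls. Individual embeddings are aligned to the template by
orthogonal Procrustes rotation (`procrustes_align()`): rotation and
reflection, no scaling, so that inter-subject distances in gradient space
are preserved. Sign ambiguity of eigenvectors is resolved by the rotation
itself.

**Connectivity of the affinity graph.** Thresholding keeps each row's top
edges, so an affinity built from exactly block-structured connectivity is
block-diagonal and the embedding is undefined; `diffusion_embedding()`
refuses disconnected graphs with the component count. Real cortical
connectivity does not have this problem because network borders are
transitional — the very premise of gradient analysis — and the synthetic
generator reproduces it through border mixing (below).

## 2. Gradient eccentricity

`eccentricity()` is the Euclidean distance of each vertex to the centroid
of *that subject's own* aligned 3-D gradient coordinates. The centroid is
per subject, not the template centroid, because the statistic describes
dispersion of the individual gradient space; alignment is required first
(unaligned input is an error) since individual spaces are rotationally
arbitrary. The statistic is invariant under any orthogonal transform
applied jointly to the three components, which the tests check to
machine precision.

Community summaries (`community_profile()`) report the mean and SD over
all vertices and subjects per community, and a z-score versus controls
computed per vertex — `(mean_patients − mean_controls)/SD_controls` —
then averaged over the community's vertices, so the effective n is the
number of vertices in the community; a subject-level variant is available
(`z_level = "subject"`).

## 3. Linear models and corrections

All vertex- and community-level tests are ordinary least squares with a
single-degree-of-freedom contrast (`fit_glm()`): age effects
(`~ age + sex + head_motion`), case–control contrasts
(`~ group + age + sex + head_motion`), and the disease × age interaction
(`~ group * age + sex + head_motion`, contrast `group:age`). Group is
treatment-coded (the contrast is patient-vs-control), sex is sum-coded so
main effects are evaluated at the factor mean. Degenerate constant
responses return `t = 0, p = 1` rather than `0/0`.

The covariate-control models regress **age on eccentricity** plus a
competing covariate (FCD or cortical thickness), sex, and motion
(`covary_model()`), reporting eccentricity's partial coefficient — note
the regression direction, which is unusual but follows the formulation
this analysis family prints. OLS is the default because it admits an
exact normal-equations oracle in the tests; `method = "rlm"` provides an
M-estimator robust fit for data with outlying subjects.

**Family-wise error** over vertices uses max-statistic Freedman–Lane
permutation (`fwe_correct()`): the reduced model without the contrast is
fitted, its residual rows are permuted and added back to the reduced fit,
the full model is refitted, and the maximum |t| over vertices forms the
null; `p_FWE = (1 + #{max-null ≥ |t|})/(n_perm + 1)`. This replaces
random-field theory: it needs no smoothness estimation, is exact under
exchangeability, and is itself testable by simulation. Community-level
families use Benjamini–Hochberg FDR (`fdr_correct()`, `p.adjust`).

**Calibration and its limits.** The test suite verifies, over 500
replicate null cohorts run through the full pipeline, that the
family-wise error of the interaction test sits inside the binomial 95%
band around 0.05. Two conditions matter for that experiment and are worth
knowing about in applications. First, eccentricity maps must be
exchangeable across subjects: if the alignment template is estimated from
the *analyzed* controls, control maps are slightly better aligned than
patient maps, the groups differ in residual scale, and the permutation
null is mildly anticonservative (we measured ≈7–9% family-wise error at
30+30 subjects on a 162-vertex mesh). The calibration experiment
therefore aligns to a normative template from an independent control
sample; with large template groups, as in typical applications, the
overfit shrinks with 1/√n. Second, an age-dependent coupling slope makes
eccentricity *variance* age-dependent, another (mild) exchangeability
violation. Neither caveat affects the validity of the statistic under the
global null the calibration tests.

`effect_size_reduction()` quantifies covariate control as the percent
drop of the cluster-mean |t| (or |beta|) between the base and the
controlled model; the measure is configurable because "effect size" is
not uniquely defined for this design, and reductions of either sign are
reported as computed. `bootstrap_stability()` subsamples subjects without
replacement at fixed group ratio and correlates the recomputed
interaction t-map with the full-sample map. `demographics_tests()` uses
the Pearson chi-square *without* continuity correction — with the
continuity correction the canonical 70/70 vs 50/41 sex table does not
reproduce its printed statistic of 0.54 — and pooled-variance two-sample
t-tests; `pooled_t_summary()` exposes the summary-statistic form.
Clinical correlations drop subjects with missing scores listwise (count
recorded), and positive durations are log-transformed on request.

## 4. Spin permutation nulls

`spin_indices()` draws Haar-uniform rotations (sign-corrected QR of a
Gaussian matrix, determinant +1), rotates the location coordinates, and
reassigns each original location to its nearest rotated location by
maximum dot product. The classic nearest-neighbour construction is not
guaranteed bijective; collisions are counted and reported per spin. When
both hemispheres are present, the right hemisphere uses the x-mirrored
rotation so that anatomically mirrored maps spin consistently, and
assignments stay within hemisphere. Parcel-level spins use parcel
centroids re-projected to the sphere (`parcel_centroids()`).

`spin_test()` rotates the *statistical* map (map_a) — the convention when
one map is a derived statistic and the other a reference — and compares
|r| two-sided: `p_spin = (1 + #{|null r| ≥ |observed r|})/(n_spins + 1)`.
Missing locations (the medial-wall analogue) are dropped pairwise per
spin. A small-angle rotation can reproduce the identity reassignment on a
coarse mesh, so the minimum attainable p can exceed `1/(n_spins+1)` by
the number of such ties; the p formula counts them. Default 5000 spins;
the calibration tests use 200 spins over 500 replicates, which bounds the
attainable p granularity but estimates the rejection *rate* without bias.

## 5. PLS decoding and enrichment

For a univariate response the first PLS component has a closed form: the
weight vector is the normalized cross-covariance `w = X'y/‖X'y‖` and the
scores are `t = Xw`. Gene columns are z-scored by default (the usual
treatment of regional expression matrices; configurable). Variance
explained in expression is `‖t(t't)^{-1}t'X‖²_F/‖X‖²_F`. The spin
significance of the association uses the squared covariance captured by
the component — for univariate y, monotone in `‖X'y‖²` — recomputed under
spins of the map, one-sided upper. Bootstrap gene ranking resamples
parcels with replacement, re-derives the weight vector, aligns its sign
to the original component (without alignment, sign flips inflate the SE),
and forms `Z = w/SE_boot` with two-sided normal p-values, BH correction,
and selection at `q < 0.05`.

Over-representation of the selected list in annotation sets is Fisher's
exact test: the two-sided p sums all hypergeometric outcomes no more
probable than the observed table (computed directly from the
hypergeometric mass with the same relative-error guard as
`stats::fisher.test`, against which the tests check agreement, and
against exhaustive enumeration for every background up to 60). Odds
ratios use the Haldane 0.5 correction when a cell is empty, flagged in
the output. `developmental_enrichment()` applies the same test to a
complete 6-region × 10-period grid (60 cells) with BH across cells.

## 6. The synthetic-data generator

`make_sphere_mesh()` builds a subdivided icosahedron (12, 42, 162, 642,
2562 or 10242 vertices) and grows contiguous community (default 7) and
parcel patches by size-balanced region growing from farthest-point seeds,
yielding near-equal, connected patches; parcels are drawn independently
of communities, as real parcellations do not nest within networks.

`simulate_cohort()` gives each community an AR(1) latent signal
(coefficient 0.3 — enough temporal smoothness to stand in for band-limited
hemodynamic signals without an explicit spectrum model) plus one global
latent that creates between-community connectivity. Vertex `v` in
community `k` of subject `s` mixes its community latent with weight
`w_sk = base + slope_k·(age_s − age_min) − patient_s·interaction_k·(age_s − age_min)`,
so within-community coupling grows linearly with age — hence gradient
dispersion and eccentricity grow with age — and patients lose a share of
that growth in designated communities: the planted disease × age
interaction. Near community borders, vertices mix in the adjacent
community's latent with a weight that decays with graph distance from
the border (`border_mixing`, default 0.35 at the border, e-folding 1.5
steps). This smooth-transition structure is what keeps the thresholded
affinity graph connected; setting it to zero recovers exactly
block-constant connectivity for construction tests. Defaults
(`base_coupling` 0.45, `global_coupling` 0.4, `noise_sd` 0.8, ages
uniform on 4–14 years, head motion ≈ 0.11 ± 0.05 mm) put within- and
between-community correlations in the plausible range for cleaned BOLD
data while keeping single-subject embeddings estimable from 50–150
timepoints. Clinical columns (AED state, seizure counts, positive
seizure-free durations, onset ages, cognitive scores on a 100 ± 15
scale, present for a patient subset) are generated independent of the
imaging signal, except an optional planted coupling between attention
and a subject's mean within-community coupling used to test
clinical-correlation recovery.

What the generator does *not* emulate: hemodynamic forward models,
motion artifacts, spatially varying noise, scanner drift, structural or
diffusion data, or real network geometry. Passing tests therefore show
that the estimators recover the planted statistical structure through
the full pipeline — not that the pipeline is robust to every artifact of
real fMRI.

`simulate_expression()` plants `n_associated` genes that track the
projection of parcel centroids on a chosen 3-D axis (or, via
`target_map`, any supplied per-parcel map — used by the demonstration
study to plant genes along the realized typical-development map, since
the realized alteration pattern is the product of planted slopes *and*
embedding geometry and need not follow any single geometric axis).
Remaining genes are spatially smooth noise (white noise diffused
`smoothness` steps on the mesh graph, then parcel-averaged). The
annotation collection contains one set enriched for the associated genes
among random sets, with the enriched identity recorded in the ground
truth, as is everything else needed to score recovery.

## 7. Reproducibility and scale choices

Every stochastic function takes a seed and restores the caller's RNG
state; identical seeds give byte-identical meshes, cohorts, tables, and
expression matrices, and `run_pipeline()` writes a manifest (resolved
configuration, seed, checksums) from which a run can be reproduced. The
test-suite problem sizes — 162-vertex meshes, 30+30 subjects, 199
permutations and 200 spins for the calibration loops, 500 null
replicates, bootstrap sizes of 200 — were chosen as the smallest scales
at which the calibration bands and recovery rates are statistically
meaningful; the packaged study in `analysis/` runs at 642 vertices, 100
parcels, and 75 subjects. Mesh sizes are restricted to icosphere counts,
so specifications phrased at round numbers (e.g. "100 vertices") map to
the nearest feasible size (162).

## 8. Known limitations

- Eccentricity is a *global* statistic: a coupling change planted in one
  community moves the embedding, the alignment, and the centroid, so some
  signal leaks into neighbouring communities (amplified by border
  mixing). Community-level inference should be read as "where is the
  effect concentrated", not "which communities are affected at all"; the
  effect-recovery tests accordingly require the designated community to
  dominate the map, not to be the only rejection.
- The FCD "mediation" analysis is covariate control plus effect-size
  reduction, not formal causal mediation.
- Nearest-neighbour spin tests are approximate on coarse meshes
  (collisions, identity ties) and the generator's smooth maps are
  friendlier than real cortical maps with a medial wall.
- Longitudinal and mixed-effects designs are out of scope; all models are
  cross-sectional OLS.
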
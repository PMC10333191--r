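# gradecc — connectivity-gradient eccentricity analysis

`gradecc` characterizes the **hierarchy of cortical functional
connectivity** and how it changes with age in case–control developmental
cohorts. It is aimed at researchers who study network segregation in
pediatric imaging cohorts (e.g., developmental epilepsies) and who need the
entire chain — gradients, eccentricity, group statistics, spatial nulls,
and transcriptomic decoding — as tested, scriptable R functions. Every
stage can be exercised on synthetic cohorts generated by the package
itself, so the full analysis is reproducible without any imaging or
expression download.

## The method

For each subject with a vertex×time signal matrix:

1. **Connectivity**: pairwise Pearson correlation between all vertex time
   series, `FC[i,j] = cor(x_i, x_j)`.
2. **Row thresholding**: per row, keep the top 10% of edges
   (`ceiling(0.10 · (N−1))` largest values), zero the rest.
3. **Affinity**: cosine similarity between thresholded rows (negatives
   clipped at 0), a symmetric nonnegative matrix.
4. **Diffusion map embedding** with manifold parameter α = 0.5:
   `W = D^−α A D^−α` is row-normalized to a Markov operator whose leading
   non-trivial eigenvectors are the *connectivity gradients* G1, G2, G3, …
5. **Alignment**: individual embeddings are aligned to a group template
   (embedding of the control-mean FC) by orthogonal Procrustes rotation.
6. **Gradient eccentricity**: per vertex, the Euclidean distance to the
   centroid of all vertices in the subject's aligned 3-D gradient space —
   a scalar summary of how segregated a vertex's position in the
   hierarchy is.

Group analysis is mass-univariate OLS per vertex or community: age
effects, case–control contrasts, and the **disease × age interaction**
(the group difference in the age slope), with sex and head motion as
covariates. Family-wise error over vertices is controlled by
**max-statistic Freedman–Lane permutation**; community results use
Benjamini–Hochberg FDR. Spatial correlations between maps are tested
against **spin permutation** nulls (random sphere rotations with
nearest-neighbour reassignment, mirrored across hemispheres when both are
present). A statistical map can be decoded against a parcel×gene
expression matrix by **partial least squares**: for a univariate map the
PLS1 weights are the normalized cross-covariance `X'y/‖X'y‖`, gene
contributions are ranked by bootstrap Z (weight over bootstrap SE), the
`q < 0.05` gene list is tested for over-representation in annotation sets
by **Fisher's exact test**, including a 6-region × 10-period developmental
profile grid. Functional connectivity density (FCD; connections with
r > 0.3 per vertex) serves as the competing covariate in the
`Age ~ 1 + Eccentricity + FCD + Sex + Head motion + e` models and in
effect-size–reduction analyses.

## Worked example

```r
library(gradecc)

mesh   <- make_sphere_mesh(642, n_communities = 7, n_parcels = 100, seed = 3)
slopes <- seq(0.02, 0.06, length.out = 7)          # coupling growth per year
truth  <- ground_truth(within_coupling_slope = slopes,
                       interaction_effect   = 0.6 * slopes)
cohort <- simulate_cohort(mesh, n_patients = 40, n_controls = 35,
                          truth = truth, n_timepoints = 120, seed = 4)

con <- cohort$table$group == "control"
cg  <- cohort_gradients(cohort$timeseries, template_subjects = which(con))
ECC <- do.call(rbind, lapply(cg$gradients,
                             function(g) eccentricity(g)$values))

cor(cohort$table$age[con], rowMeans(ECC[con, ]))
imap <- fwe_correct(ECC, cohort$table, ~ group * age + sex + head_motion,
                    "group:age", n_perm = 999, seed = 5)
sum(imap$p_fwe <= 0.05)
```

On the packaged study (`analysis/` scripts, master seed `20260927`) this
chain prints:

```
first three gradients explain 39.2% of the eigenvalue mass
Mean eccentricity rises with age in controls: r = 0.95
Cross-community correlation (age change vs interaction): r = -0.92, p = 0.003
Interaction t-map vs control age t-map: r = -0.93, p_spin = 0.0002 (5000 spins)
PLS1: 11.6% of expression variance, scores vs map r = 0.96, p_spin = 0.0002
142 genes selected at q < 0.05; planted annotation set set01 at q = 1.21e-10
Developmental grid: top cell cortex|middle_late_childhood (planted cortex|middle_late_childhood)
```

Reading: eccentricity grows with age (the planted dispersion of the
gradient space), patients lose that growth most in the fastest-developing
communities (negative cross-community correlation), the alteration map is
spatially tied to typical development (spin test), and the PLS decoding
recovers the genes and the annotation cell that the generator planted.

## The analysis workflow

The numbered drivers under `analysis/` run the study end to end and write
their tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | cohort simulation + demographics table |
| `02_gradients.R` | per-subject gradients, control template |
| `03_eccentricity.R` | eccentricity, community profiles, age effects |
| `04_interaction_stats.R` | interaction/case–control maps, FWE, FCD control, stability |
| `05_spin.R` | spin test of the map correlation |
| `06_transcriptomics.R` | PLS decoding, bootstrap Z, enrichment |

`run_pipeline()` performs the same sequence programmatically and writes a
JSON manifest (resolved configuration, seed, file checksums) so a run is
reconstructible from its outputs.

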
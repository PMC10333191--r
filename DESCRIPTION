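Package: gradecc
Title: Functional Connectivity Gradient Eccentricity Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Characterizes the functional connectivity hierarchy of the
    cortex and its change with age in case-control cohorts. Builds
    per-subject diffusion-map gradients from vertex-wise functional
    connectivity (row-thresholded, cosine-affinity, anisotropic diffusion
    embedding), aligns them to a group template by Procrustes rotation, and
    summarizes the three leading gradients as a per-vertex eccentricity (the
    distance to the centroid of the individual 3D gradient space). Provides
    vertex- and community-level linear models (age effects, disease-by-age
    interactions, case-control contrasts, covariate-controlled fits) with
    max-statistic Freedman-Lane permutation family-wise error control,
    spherical spin-permutation nulls for spatial correlations, partial least
    squares decoding of statistical maps against regional gene expression
    with bootstrap gene ranking, and Fisher exact enrichment over gene set
    collections. A synthetic-data module generates sphere meshes,
    community-structured BOLD-like cohorts, and spatially smooth expression
    matrices with planted effects so that every stage is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Matrix,
    MASS
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
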
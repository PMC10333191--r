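# Synthetic meshes, cohorts and expression: construction invariants,
# determinism, and recovery of planted structure.

test_that("sphere mesh vertices are unit-norm with full, contiguous labels", {
  mesh <- make_sphere_mesh(642, n_communities = 7, n_parcels = 50, seed = 1)
  expect_equal(nrow(mesh$vertices), 642)
  expect_lt(max(abs(sqrt(rowSums(mesh$vertices^2)) - 1)), 1e-9)
  # no empty community or parcel
  expect_equal(sort(unique(mesh$community)), 1:7)
  expect_equal(sort(unique(mesh$parcel)), 1:50)
  # every patch is one connected component on the mesh graph
  adj <- gradecc:::mesh_adjacency(mesh$faces, 642)
  expect_true(all(gradecc:::label_components(adj, mesh$community) == 1L))
  expect_true(all(gradecc:::label_components(adj, mesh$parcel) == 1L))
})

test_that("mesh construction is deterministic and validates its bounds", {
  expect_identical(make_sphere_mesh(162, 7, 20, seed = 3),
                   make_sphere_mesh(162, 7, 20, seed = 3))
  expect_error(make_sphere_mesh(100, 7, 20, seed = 1),
               "subdivided-icosahedron")
  expect_error(make_sphere_mesh(162, 7, 5, seed = 1), "n_communities")
  expect_error(make_sphere_mesh(162, 7, 60, seed = 1), "4 \\* n_parcels")
})

test_that("mirrored mesh flips x and hemisphere, keeping labels", {
  mesh <- small_mesh()
  mir <- mirror_mesh(mesh)
  expect_equal(mir$vertices[, 1], -mesh$vertices[, 1])
  expect_equal(mir$vertices[, 2:3], mesh$vertices[, 2:3])
  expect_true(all(mir$hemisphere == "right"))
  expect_identical(mir$community, mesh$community)
})

test_that("cohort bookkeeping matches the requested design", {
  mesh <- small_mesh()
  co <- simulate_cohort(mesh, 140, 91, n_timepoints = 50, seed = 11)
  expect_equal(nrow(co$table), 231)
  expect_equal(as.vector(table(co$table$group)), c(91, 140))
  expect_true(all(co$table$age >= 4 & co$table$age <= 14))
  expect_true(all(is.na(co$table$aed[co$table$group == "control"])))
  sfd <- co$table$seizure_free_duration
  expect_true(all(sfd[co$table$group == "patient"] > 0))
  expect_equal(co$truth$seed, 11L)
  expect_length(co$timeseries, 231)
  # determinism
  co2 <- simulate_cohort(mesh, 140, 91, n_timepoints = 50, seed = 11)
  expect_identical(co$timeseries[[5]], co2$timeseries[[5]])
  expect_identical(co$table, co2$table)
})

test_that("cohort rejects empty groups and bad age ranges", {
  mesh <- small_mesh()
  expect_error(simulate_cohort(mesh, 0, 10, seed = 1), "non-empty")
  expect_error(simulate_cohort(mesh, 5, 5, age_range = c(2, 10), seed = 1),
               "age_range")
  expect_error(simulate_cohort(mesh, 5, 5, n_timepoints = 10, seed = 1),
               "n_timepoints")
})

test_that("noise-free, mixing-free cohort gives exactly block-constant FC", {
  mesh <- small_mesh()
  tr <- ground_truth(within_coupling_slope = 0, noise_sd = 0,
                     global_coupling = 0, border_mixing = 0)
  co <- simulate_cohort(mesh, 1, 1, truth = tr, n_timepoints = 60, seed = 2)
  C <- compute_fc(co$timeseries[[1]])
  for (k in 1:2) {
    ix <- which(mesh$community == k)
    expect_equal(max(abs(C[ix, ix] - 1)), 0, tolerance = 1e-12)
  }
  # between-community blocks constant too (one latent per community)
  i1 <- which(mesh$community == 1)
  i2 <- which(mesh$community == 2)
  expect_lt(diff(range(C[i1, i2])), 1e-10)
})

test_that("expression generator plants exactly the recorded gene set", {
  mesh <- small_mesh()
  ex <- simulate_expression(mesh, n_genes = 200, n_associated = 25,
                            seed = 4)
  expect_length(ex$truth$associated_genes, 25)
  expect_equal(dim(ex$expression), c(20, 200))
  expect_false(anyNA(ex$expression))
  expect_true(ex$truth$enriched_set_id %in% names(ex$sets$sets))
  # planted genes overrepresented in the enriched set relative to others
  enr <- ex$sets$sets[[ex$truth$enriched_set_id]]
  planted <- colnames(ex$expression)[ex$truth$associated_genes]
  others <- vapply(ex$sets$sets, function(s) length(intersect(s, planted)),
                   numeric(1))
  expect_equal(names(which.max(others)), ex$truth$enriched_set_id)
  # determinism
  ex2 <- simulate_expression(mesh, n_genes = 200, n_associated = 25,
                             seed = 4)
  expect_identical(ex$expression, ex2$expression)
})

test_that("noise-free associated genes track the axis projection exactly", {
  mesh <- small_mesh()
  ex <- simulate_expression(mesh, n_genes = 50, n_associated = 5,
                            axis = c(0, 0, 1), smoothness = 0,
                            assoc_noise_sd = 0, seed = 9)
  proj <- as.numeric(parcel_centroids(mesh) %*% c(0, 0, 1))
  for (g in ex$truth$associated_genes) {
    expect_equal(cor(ex$expression[, g], proj), 1, tolerance = 1e-12)
  }
})

test_that("planted genes can track a supplied target map instead of the
           geometric axis", {
  mesh <- small_mesh()
  target <- gradecc:::with_seed(3, rnorm(mesh$n_parcels))
  ex <- simulate_expression(mesh, n_genes = 60, n_associated = 8,
                            target_map = target, assoc_noise_sd = 0,
                            smoothness = 0, seed = 5)
  for (g in ex$truth$associated_genes) {
    expect_equal(cor(ex$expression[, g], target), 1, tolerance = 1e-12)
  }
  expect_error(simulate_expression(mesh, n_genes = 60, n_associated = 8,
                                   target_map = target[-1], seed = 5),
               "per parcel")
})

test_that("expression generator rejects impossible enrichment requests", {
  mesh <- small_mesh()
  expect_error(simulate_expression(mesh, n_genes = 50, n_associated = 0,
                                   make_enriched_set = TRUE, seed = 1),
               "nothing to enrich")
  expect_error(simulate_expression(mesh, n_genes = 50, n_associated = 50,
                                   seed = 1), "n_associated")
})

test_that("planted community interaction is recovered through the full
           pipeline and null communities stay quiet", {
  mesh <- small_mesh()
  tr <- ground_truth(interaction_effect = c(0.03, rep(0, 6)))
  hits <- 0L
  top_ranked <- 0L
  n_rep <- 25L
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(mesh, 30, 30, truth = tr, n_timepoints = 120,
                          seed = 100 + r)
    cg <- cohort_gradients(co$timeseries,
                           template_subjects =
                             which(co$table$group == "control"))
    ECC <- gradecc:::ecc_matrix(lapply(cg$gradients, eccentricity))
    im <- interaction_map(community_means(ECC, mesh$community), co$table)
    q <- fdr_correct(im$p_uncorrected)
    if (q[1] < 0.05) hits <- hits + 1L
    # specificity: eccentricity is a global statistic, so some planted
    # signal leaks into neighbouring communities; the designated community
    # must still dominate the map
    if (which.max(abs(im$t)) == 1L) top_ranked <- top_ranked + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
  expect_gte(top_ranked, ceiling(0.9 * n_rep))
})

test_that("age-increasing coupling yields eccentricity that grows with age
           in controls", {
  mesh <- small_mesh()
  co <- small_cohort()
  cg <- cohort_gradients(co$timeseries,
                         template_subjects =
                           which(co$table$group == "control"))
  ECC <- gradecc:::ecc_matrix(lapply(cg$gradients, eccentricity))
  con <- co$table$group == "control"
  expect_gt(cor(co$table$age[con], rowMeans(ECC[con, ])), 0.5)
})
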
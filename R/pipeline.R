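# Resolved configuration and the end-to-end pipeline driver.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with the pipeline's
#' default values: 10 percent row density, diffusion normalization
#' alpha = 0.5, 10 computed components with eccentricity over the first 3,
#' connectivity-density threshold r = 0.3, and the permutation/spin/
#' bootstrap resolutions. Simulation sizes describe the synthetic cohort
#' the driver generates when no inputs are supplied.
#'
#' @param density Row sparsification density (0.10).
#' @param alpha Diffusion normalization exponent (0.5).
#' @param n_components Components computed per embedding (10).
#' @param eccentricity_dims Components entering eccentricity (3).
#' @param fcd_threshold Correlation cutoff of the FCD map (0.3).
#' @param n_perm Permutations for FWE correction (1999).
#' @param n_spins Spin rotations (5000; overridable for small runs).
#' @param n_boot Bootstrap resamples for gene ranking (1000).
#' @param fdr_alpha FDR threshold (0.05).
#' @param seed Master seed; every stage derives its stream from it.
#' @param n_vertices,n_communities,n_parcels Synthetic mesh sizes.
#' @param n_patients,n_controls,n_timepoints Synthetic cohort sizes.
#' @param n_genes,n_associated Synthetic expression sizes.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(density = 0.10, alpha = 0.5,
                            n_components = 10L, eccentricity_dims = 3L,
                            fcd_threshold = 0.3, n_perm = 1999L,
                            n_spins = 5000L, n_boot = 1000L,
                            fdr_alpha = 0.05, seed = 1L,
                            n_vertices = 162L, n_communities = 7L,
                            n_parcels = 20L, n_patients = 20L,
                            n_controls = 20L, n_timepoints = 120L,
                            n_genes = 300L, n_associated = 30L) {
  cfg <- as.list(environment())
  stopifnot(cfg$density > 0, cfg$density <= 1, cfg$alpha >= 0,
            cfg$fcd_threshold > 0, cfg$fcd_threshold < 1,
            cfg$n_perm >= 99, cfg$n_spins >= 10, cfg$n_boot >= 100,
            cfg$fdr_alpha > 0, cfg$fdr_alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

stage_done <- function(files) all(file.exists(files))

#' Run the full gradient-eccentricity pipeline on a (synthetic) cohort
#'
#' Executes the analysis end to end: cohort simulation (unless a cohort is
#' supplied), per-subject gradients and template alignment, eccentricity
#' and community profiles, disease-by-age and case-control statistics with
#' permutation FWE, FCD covariate control with effect-size reduction, a
#' spin test relating typical and atypical age effects, and PLS
#' transcriptomic decoding with bootstrap gene ranking and enrichment.
#' Every intermediate is written as delimited text under `output_dir` and a
#' JSON manifest records the resolved configuration, seeds, and file
#' checksums. With `resume = TRUE`, the expensive gradient/eccentricity
#' stage is re-read from its existing outputs instead of recomputed;
#' downstream statistics are always re-derived.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for outputs (created if needed).
#' @param cohort Optional `cohort_sim` (otherwise simulated from the
#'   config).
#' @param expression Optional `expression_sim`.
#' @param resume Reuse existing stage outputs.
#' @return Invisibly, a list with the key results (`template`,
#'   `eccentricity`, `stat_maps`, `spin`, `pls`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir,
                         cohort = NULL, expression = NULL, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(output_dir, ...)
  log_msg <- function(...) message("[run_pipeline] ", ...)

  # stage 1: cohort --------------------------------------------------------
  mesh_prefix <- pth("mesh")
  tab_path <- pth("subjects.csv")
  truth_path <- pth("ground_truth.json")
  if (is.null(cohort)) {
    mesh <- make_sphere_mesh(config$n_vertices, config$n_communities,
                             config$n_parcels,
                             seed = child_seed(config$seed, 1))
    cohort <- simulate_cohort(mesh, config$n_patients, config$n_controls,
                              truth = ground_truth(interaction_effect =
                                c(0.03, rep(0, config$n_communities - 1L))),
                              n_timepoints = config$n_timepoints,
                              seed = child_seed(config$seed, 2))
    cohort$mesh <- mesh
  }
  mesh <- cohort$mesh
  if (is.null(mesh)) stop("cohort must carry its mesh (cohort$mesh)")
  write_mesh(mesh, mesh_prefix)
  write_subject_table(cohort$table, tab_path)
  write_ground_truth(cohort$truth, truth_path)
  tab <- cohort$table
  log_msg("stage simulate: ", nrow(tab), " subjects, ",
          nrow(mesh$vertices), " vertices")

  # stage 2: gradients + eccentricity --------------------------------------
  ecc_path <- pth("eccentricity_maps.csv")
  tve_path <- pth("template_variance_explained.csv")
  if (resume && stage_done(c(ecc_path, tve_path))) {
    log_msg("stage gradients: reusing ", ecc_path)
    ECC <- as.matrix(data.table::fread(ecc_path)[, -1])
    dimnames(ECC) <- NULL
    tve <- as.data.frame(data.table::fread(tve_path))
    template <- NULL
  } else {
    cg <- cohort_gradients(cohort$timeseries,
                           template_subjects = which(tab$group == "control"),
                           density = config$density, alpha = config$alpha,
                           k = config$n_components)
    template <- cg$template
    eccs <- lapply(cg$gradients, eccentricity,
                   dims = config$eccentricity_dims)
    ECC <- ecc_matrix(eccs)
    dimnames(ECC) <- NULL
    dt <- data.table::data.table(subject_id = tab$subject_id)
    data.table::fwrite(cbind(dt, data.table::as.data.table(ECC)), ecc_path)
    tve <- data.frame(component = seq_along(template$variance_explained),
                      variance_explained = template$variance_explained)
    data.table::fwrite(tve, tve_path)
    log_msg("stage gradients: first ", config$eccentricity_dims,
            " components explain ",
            sprintf("%.1f%%",
                    100 * sum(tve$variance_explained[
                      seq_len(config$eccentricity_dims)])),
            " of template eigenvalue mass")
  }

  # stage 3: community profiles -------------------------------------------
  prof <- community_profile(ECC[tab$group == "patient", , drop = FALSE],
                            mesh$community,
                            reference = ECC[tab$group == "control", ,
                                            drop = FALSE])
  data.table::fwrite(prof, pth("community_profile.csv"))

  # stage 4: statistics ----------------------------------------------------
  imap <- fwe_correct(ECC, tab, ~ group * age + sex + head_motion,
                      "group:age", n_perm = config$n_perm,
                      seed = child_seed(config$seed, 4))
  write_stat_map(imap, pth("interaction_map.csv"))
  cmap <- casecontrol_map(ECC, tab)
  write_stat_map(cmap, pth("casecontrol_map.csv"))
  age_con <- fit_glm(ECC[tab$group == "control", , drop = FALSE],
                     tab[tab$group == "control", , drop = FALSE],
                     ~ age + sex + head_motion, "age")
  write_stat_map(age_con, pth("age_effect_controls.csv"))

  icomm <- interaction_map(community_means(ECC, mesh$community), tab)
  icomm$q_fdr <- fdr_correct(icomm$p_uncorrected)
  write_stat_map(icomm, pth("interaction_communities.csv"))
  acomm <- fit_glm(community_means(ECC[tab$group == "control", ,
                                       drop = FALSE], mesh$community),
                   tab[tab$group == "control", , drop = FALSE],
                   ~ age + sex + head_motion, "age")
  ccc <- cross_community_correlation(acomm$t, icomm$t)
  log_msg("stage stats: cross-community r = ", sprintf("%.3f", ccc$r),
          ", p = ", sprintf("%.3g", ccc$p))

  # FCD control and effect-size reduction
  FCD <- t(vapply(cohort$timeseries, function(ts) {
    fcd_map(ts, config$fcd_threshold)$counts
  }, numeric(nrow(mesh$vertices))))
  data.table::fwrite(data.table::as.data.table(FCD), pth("fcd_maps.csv"))
  cov_fit <- covary_model(tab, community_means(ECC, mesh$community),
                          community_means(FCD, mesh$community))
  data.table::fwrite(cov_fit, pth("covary_model.csv"))
  fcd_comm <- community_means(FCD, mesh$community)
  tab_fcd <- tab
  tab_fcd$fcd_mean <- rowMeans(fcd_comm)
  cmap_ctl <- fit_glm(ECC, tab_fcd,
                      ~ group + age + sex + head_motion + fcd_mean, "group")
  clusters <- split(seq_len(ncol(ECC)), mesh$community)
  names(clusters) <- paste0("comm", names(clusters))
  esr <- effect_size_reduction(cmap, cmap_ctl, clusters)
  data.table::fwrite(esr, pth("effect_size_reduction.csv"))

  demo <- demographics_tests(tab)
  data.table::fwrite(demo, pth("demographics.csv"))
  clin <- tryCatch(
    clinical_correlation(ECC, tab, "seizure_free_duration",
                         log_transform = TRUE),
    error = function(e) NULL)
  if (!is.null(clin)) write_stat_map(clin, pth("clinical_seizurefree.csv"))

  # stage 5: spin test -----------------------------------------------------
  spin <- spin_test(imap$t, age_con$t, mesh$vertices,
                    n_spins = config$n_spins,
                    seed = child_seed(config$seed, 5))
  log_msg("stage spin: r = ", sprintf("%.3f", spin$observed),
          ", p_spin = ", sprintf("%.4g", spin$p_spin))

  # stage 6: transcriptomics ------------------------------------------------
  if (is.null(expression)) {
    expression <- simulate_expression(mesh, n_genes = config$n_genes,
                                      n_associated = config$n_associated,
                                      seed = child_seed(config$seed, 6))
  }
  write_expression(expression$expression, pth("expression.tsv"))
  if (!is.null(expression$sets)) {
    write_gene_sets(expression$sets, pth("gene_sets.gmt"))
  }
  y_parc <- parcellate_map(imap$t, mesh$parcel)
  pls <- pls_first_component(expression$expression, y_parc)
  pspin <- pls_spin_significance(expression$expression, y_parc,
                                 parcel_centroids(mesh),
                                 n_spins = min(config$n_spins, 1000L),
                                 seed = child_seed(config$seed, 7))
  boot <- bootstrap_gene_z(expression$expression, y_parc,
                           n_boot = config$n_boot,
                           seed = child_seed(config$seed, 8),
                           fdr_alpha = config$fdr_alpha)
  genes <- data.frame(gene = names(boot$weights), weight = boot$weights,
                      z = boot$z, p = boot$p, q = boot$q,
                      selected = names(boot$weights) %in% boot$selected,
                      row.names = NULL)
  data.table::fwrite(genes, pth("pls_genes.csv"))
  enr <- NULL
  if (!is.null(expression$sets) && length(boot$selected)) {
    enr <- fisher_enrichment(boot$selected, expression$sets)
    data.table::fwrite(enr, pth("enrichment.csv"))
  }
  log_msg("stage pls: variance explained (X) = ",
          sprintf("%.3f", pls$variance_explained_x), ", ",
          length(boot$selected), " genes selected")

  # manifest ----------------------------------------------------------------
  files <- list.files(output_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    package = "gradecc",
    version = as.character(utils::packageVersion("gradecc")),
    r_version = R.version.string,
    config = unclass(config),
    checksums = as.list(tools::md5sum(sort(files)))
  )
  names(manifest$checksums) <- basename(sort(files))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    template_variance_explained = tve,
    eccentricity = ECC,
    community_profile = prof,
    stat_maps = list(interaction = imap, casecontrol = cmap,
                     age_controls = age_con,
                     interaction_communities = icomm),
    cross_community = ccc,
    effect_size_reduction = esr,
    demographics = demo,
    spin = spin,
    pls = pls,
    pls_spin = pspin,
    bootstrap = boot,
    enrichment = enr,
    manifest = manifest
  ))
}
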
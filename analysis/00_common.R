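# Shared study definition for the analysis scripts. Each numbered script
# sources this file and calls load_study(); the study is rebuilt from the
# master seed, so every script is independently runnable.

library(gradecc)

STUDY_SEED <- 20260927L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# Study conditions: 642-vertex single-hemisphere sphere, 7 communities,
# 100 parcels; 40 patients vs 35 controls aged 4-14; graded development
# (coupling slopes 0.02-0.06 per year across communities) with the planted
# disease-by-age interaction proportional to the slope, mirroring faster
# alteration in faster-developing networks.
load_study <- function(seed = STUDY_SEED) {
  sd <- function(k) gradecc:::child_seed(seed, k)
  mesh <- make_sphere_mesh(642, n_communities = 7, n_parcels = 100,
                           seed = sd(3))
  slopes <- seq(0.02, 0.06, length.out = 7)
  truth <- ground_truth(within_coupling_slope = slopes,
                        interaction_effect = 0.6 * slopes)
  cohort <- simulate_cohort(mesh, n_patients = 40, n_controls = 35,
                            truth = truth, n_timepoints = 120,
                            seed = sd(4))
  list(seed = seed, sd = sd, mesh = mesh, truth = truth, cohort = cohort)
}

# gradients + eccentricity for the whole cohort (the expensive step)
derive_eccentricity <- function(study) {
  con <- study$cohort$table$group == "control"
  cg <- cohort_gradients(study$cohort$timeseries,
                         template_subjects = which(con))
  ECC <- gradecc:::ecc_matrix(lapply(cg$gradients, eccentricity))
  dimnames(ECC) <- NULL
  list(template = cg$template, ECC = ECC, controls = con)
}
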
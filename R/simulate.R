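#' Ground truth for a simulated cohort or expression dataset
#'
#' Collects the planted parameters of a simulation so they can be recorded
#' verbatim alongside every output and recovered by downstream tests.
#'
#' @param within_coupling_slope Per-community increase of within-community
#'   signal coupling per year of age (recycled to the number of
#'   communities). Default 0.04/year, i.e. coupling grows by 0.4 across a
#'   4-14 year span, which drives the age-related dispersion of the
#'   gradients.
#' @param interaction_effect Per-community reduction of that slope in
#'   patients (the planted disease-by-age interaction); 0 = no effect.
#' @param base_coupling Within-community coupling at the lower age bound.
#' @param global_coupling Weight of the shared global signal that creates
#'   between-community connectivity.
#' @param noise_sd Per-vertex observation noise standard deviation.
#' @param ar_coef AR(1) coefficient of the latent community signals.
#' @param attention_coupling Optional planted association between a
#'   subject's within-community coupling and the attention score (0 = off);
#'   used to test clinical-correlation recovery.
#' @param border_mixing Maximum fraction by which a vertex at a community
#'   border loads on the neighbouring community's latent signal; decays
#'   with graph distance from the border at rate `mixing_decay`. Smooth
#'   transitions between communities keep the thresholded affinity graph
#'   connected (as in real cortical connectivity); set 0 for exactly
#'   block-structured signals.
#' @param mixing_decay E-folding graph distance of the border mixing.
#' @param associated_genes Integer indices of expression genes planted to
#'   track the spatial axis (filled in by [simulate_expression()]).
#' @param enriched_set_id Name of the annotation set enriched for those
#'   genes (filled in by [simulate_expression()]).
#' @param seed Seed recorded with the truth.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(within_coupling_slope = 0.04,
                         interaction_effect = 0,
                         base_coupling = 0.45,
                         global_coupling = 0.4,
                         noise_sd = 0.8,
                         ar_coef = 0.3,
                         attention_coupling = 0,
                         border_mixing = 0.35,
                         mixing_decay = 1.5,
                         associated_genes = integer(0),
                         enriched_set_id = NA_character_,
                         seed = NA_integer_) {
  structure(list(
    within_coupling_slope = within_coupling_slope,
    interaction_effect = interaction_effect,
    base_coupling = base_coupling,
    global_coupling = global_coupling,
    noise_sd = noise_sd,
    ar_coef = ar_coef,
    attention_coupling = attention_coupling,
    border_mixing = border_mixing,
    mixing_decay = mixing_decay,
    associated_genes = associated_genes,
    enriched_set_id = enriched_set_id,
    seed = seed
  ), class = "ground_truth")
}

# Per-vertex mixing onto the neighbouring community: BFS distance from the
# community border and the identity of the nearest other community.
border_mixing_weights <- function(mesh, border_mixing, mixing_decay) {
  nv <- nrow(mesh$vertices)
  if (border_mixing <= 0) {
    return(list(m = rep(0, nv), second = mesh$community))
  }
  adj <- mesh_adjacency(mesh$faces, nv)
  comm <- mesh$community
  d <- rep(NA_integer_, nv)
  second <- comm
  queue <- integer(0)
  for (v in seq_len(nv)) {
    other <- adj[[v]][comm[adj[[v]]] != comm[v]]
    if (length(other)) {
      d[v] <- 1L
      # most common neighbouring community
      tb <- table(comm[other])
      second[v] <- as.integer(names(tb)[which.max(tb)])
      queue <- c(queue, v)
    }
  }
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (u in adj[[v]]) {
      if (is.na(d[u])) {
        d[u] <- d[v] + 1L
        second[u] <- second[v]
        queue <- c(queue, u)
      }
    }
  }
  list(m = border_mixing * exp(-(d - 1L) / mixing_decay), second = second)
}

# Stationary AR(1) series with unit marginal variance.
ar1_series <- function(n, phi) {
  innov <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1)))
}

#' Simulate a case-control cohort of community-structured time series
#'
#' Each subject's vertex x time matrix is a mixture of one latent AR(1)
#' signal per community plus a shared global signal and white vertex noise.
#' The within-community mixing weight grows linearly with age at
#' `truth$within_coupling_slope`; in patients the slope of designated
#' communities is reduced by `truth$interaction_effect`, planting a
#' disease-by-age interaction in network segregation. The subject table
#' carries demographics, head motion, and clinical/cognitive columns with
#' the distributions documented in the package vignette.
#'
#' @param mesh A `surface_mesh` from [make_sphere_mesh()].
#' @param n_patients,n_controls Group sizes (both must be >= 1).
#' @param age_range Two-element numeric vector inside \[4, 14\] years.
#' @param truth A [ground_truth()] object holding the planted parameters.
#' @param n_timepoints Time series length (>= 50).
#' @param seed Integer seed.
#' @param cog_fraction Fraction of patients with cognitive scores (the rest
#'   get `NA`, exercising listwise deletion downstream).
#' @return A list of class `cohort_sim` with elements `timeseries` (list of
#'   vertex x time matrices, one per subject), `table` (the subject table,
#'   a data.frame), and `truth` (the ground truth with the seed recorded).
#' @export
simulate_cohort <- function(mesh, n_patients, n_controls,
                            age_range = c(4, 14),
                            truth = ground_truth(),
                            n_timepoints = 150L, seed = 1L,
                            cog_fraction = 0.46) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (n_patients < 1L || n_controls < 1L) {
    stop("both groups must be non-empty (n_patients=", n_patients,
         ", n_controls=", n_controls, ")")
  }
  if (n_timepoints < 50L) stop("n_timepoints must be >= 50")
  if (length(age_range) != 2L || age_range[1] >= age_range[2] ||
      age_range[1] < 4 || age_range[2] > 14) {
    stop("age_range must be an increasing interval within [4, 14] years")
  }
  K <- mesh$n_communities
  slope <- rep_len(truth$within_coupling_slope, K)
  inter <- rep_len(truth$interaction_effect, K)
  n <- n_patients + n_controls
  nv <- nrow(mesh$vertices)
  bm <- border_mixing_weights(mesh, truth$border_mixing, truth$mixing_decay)

  out <- with_seed(seed, {
    group <- factor(rep(c("patient", "control"), c(n_patients, n_controls)),
                    levels = c("control", "patient"))
    age <- stats::runif(n, age_range[1], age_range[2])
    sex <- factor(sample(c("male", "female"), n, replace = TRUE),
                  levels = c("male", "female"))
    head_motion <- pmax(0.02, stats::rnorm(n, mean = 0.11, sd = 0.05))
    is_pat <- group == "patient"

    # patient-only clinical columns
    aed <- factor(ifelse(is_pat,
                         sample(c("naive", "medication"), n, replace = TRUE,
                                prob = c(0.55, 0.45)), NA),
                  levels = c("naive", "medication"))
    seizure_free_duration <- ifelse(is_pat,
      pmax(0.5, stats::rlnorm(n, meanlog = log(2.5), sdlog = 1.0)), NA)
    seizure_times <- ifelse(is_pat, 1L + stats::rpois(n, 1.6), NA)
    epilepsy_duration <- ifelse(is_pat,
      pmin(pmax(1, stats::rgamma(n, shape = 1.75, scale = 10.5)),
           pmax(1, (age - 4) * 12)), NA)
    age_at_onset <- ifelse(is_pat, pmax(4, age - epilepsy_duration / 12), NA)

    # per-subject, per-community mixing weights (linear in age)
    a0 <- age - age_range[1]
    W <- matrix(truth$base_coupling, n, K) +
      outer(a0, slope) - outer(a0 * is_pat, inter)
    W <- pmax(W, 0.02)

    has_cog <- is_pat & stats::runif(n) < cog_fraction
    mean_w <- rowMeans(W)
    raven_total <- ifelse(has_cog, round(stats::rnorm(n, 100, 15)), NA)
    response_control <- ifelse(has_cog, round(stats::rnorm(n, 100, 15)), NA)
    attention <- ifelse(has_cog,
      100 + truth$attention_coupling *
        as.numeric(scale(mean_w)) + stats::rnorm(n, 0, 10), NA)

    ts <- vector("list", n)
    for (s in seq_len(n)) {
      Z <- t(vapply(seq_len(K), function(k) ar1_series(n_timepoints,
                                                       truth$ar_coef),
                    numeric(n_timepoints)))
      g <- ar1_series(n_timepoints, truth$ar_coef)
      latent <- Z[mesh$community, , drop = FALSE] * (1 - bm$m) +
        Z[bm$second, , drop = FALSE] * bm$m
      X <- latent * W[s, mesh$community] +
        matrix(truth$global_coupling * g, nv, n_timepoints, byrow = TRUE)
      if (truth$noise_sd > 0) {
        X <- X + matrix(stats::rnorm(nv * n_timepoints, sd = truth$noise_sd),
                        nv, n_timepoints)
      }
      ts[[s]] <- X
    }
    tab <- data.frame(
      subject_id = sprintf("sub%04d", seq_len(n)),
      group = group, age = age, sex = sex, head_motion = head_motion,
      aed = aed, seizure_free_duration = seizure_free_duration,
      seizure_times = seizure_times, epilepsy_duration = epilepsy_duration,
      age_at_onset = age_at_onset, raven_total = raven_total,
      response_control = response_control, attention = attention,
      stringsAsFactors = FALSE
    )
    names(ts) <- tab$subject_id
    list(timeseries = ts, table = tab)
  })
  truth$seed <- as.integer(seed)
  structure(list(timeseries = out$timeseries, table = out$table,
                 truth = truth), class = "cohort_sim")
}

#' Simulate a parcel-by-gene expression matrix with planted spatial genes
#'
#' Associated genes follow the projection of the parcel centroids on a
#' chosen spatial axis plus smooth noise; the remaining genes are smooth
#' spatial noise only. Smoothness is imposed by diffusing vertex-level white
#' noise on the mesh graph before averaging within parcels. An annotation
#' collection with one set enriched for the associated genes plus random
#' sets is generated alongside.
#'
#' @param mesh A `surface_mesh`.
#' @param n_genes Total number of genes.
#' @param n_associated Number of genes planted to track the axis
#'   (`< n_genes`).
#' @param axis 3D direction (normalized internally) of the planted spatial
#'   gradient.
#' @param target_map Optional per-parcel numeric map for the associated
#'   genes to track instead of the geometric axis projection (e.g. a
#'   realized developmental map); standardized internally.
#' @param smoothness Number of mesh-graph diffusion steps applied to the
#'   noise fields (0 = white noise at the vertex level).
#' @param seed Integer seed.
#' @param assoc_noise_sd Noise added to associated genes on top of the axis
#'   projection (0 = perfect tracking).
#' @param make_enriched_set Build the annotation collection (requires
#'   `n_associated > 0`).
#' @param n_random_sets Number of random annotation sets beside the
#'   enriched one.
#' @param set_size Genes per annotation set (default
#'   `max(40, 2 * n_associated)` capped at `n_genes`).
#' @return A list of class `expression_sim` with `expression` (parcel x
#'   gene matrix with dimnames), `sets` (a [gene_set_collection()] or NULL),
#'   and `truth` (a [ground_truth()] recording `associated_genes` and
#'   `enriched_set_id`).
#' @export
simulate_expression <- function(mesh, n_genes = 500L, n_associated = 50L,
                                axis = c(0, 1, 0), smoothness = 2L,
                                seed = 1L, assoc_noise_sd = 0.3,
                                make_enriched_set = TRUE,
                                n_random_sets = 9L, set_size = NULL,
                                target_map = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (n_associated >= n_genes) stop("n_associated must be < n_genes")
  if (make_enriched_set && n_associated == 0L) {
    stop("enrichment requested but n_associated is 0: nothing to enrich")
  }
  axis <- axis / sqrt(sum(axis^2))
  nv <- nrow(mesh$vertices)
  P <- mesh$n_parcels
  cen <- parcel_centroids(mesh)
  if (is.null(target_map)) {
    proj <- as.numeric(cen %*% axis)
  } else {
    if (length(target_map) != P) {
      stop("target_map must have one value per parcel")
    }
    proj <- as.numeric(target_map)
  }
  proj_std <- as.numeric(scale(proj))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  # row-normalized smoothing operator (self + neighbors) on the mesh graph
  adj <- mesh_adjacency(mesh$faces, nv)
  ii <- rep.int(seq_len(nv), lengths(adj))
  jj <- unlist(adj, use.names = FALSE)
  S <- Matrix::sparseMatrix(i = c(ii, seq_len(nv)), j = c(jj, seq_len(nv)),
                            x = 1, dims = c(nv, nv))
  S <- S / Matrix::rowSums(S)

  out <- with_seed(seed, {
    assoc <- sort(sample.int(n_genes, n_associated))
    noise <- matrix(stats::rnorm(nv * n_genes), nv, n_genes)
    sm <- as.integer(smoothness)
    while (sm > 0L) {
      noise <- as.matrix(S %*% noise)
      sm <- sm - 1L
    }
    pn <- rowsum(noise, mesh$parcel) /
      as.vector(table(factor(mesh$parcel, levels = seq_len(P))))
    pn <- scale(pn)
    attr(pn, "scaled:center") <- NULL
    attr(pn, "scaled:scale") <- NULL
    pn[is.nan(pn)] <- 0
    expr <- pn
    expr[, assoc] <- proj_std + assoc_noise_sd * pn[, assoc, drop = FALSE]
    dimnames(expr) <- list(paste0("parcel", seq_len(P)), gene_ids)

    sets <- NULL
    enriched_id <- NA_character_
    if (make_enriched_set) {
      sz <- set_size %||% min(n_genes, max(40L, 2L * n_associated))
      n_from_assoc <- min(n_associated, ceiling(sz * 0.6))
      enr <- c(sample(gene_ids[assoc], n_from_assoc),
               sample(gene_ids[-assoc], sz - n_from_assoc))
      rand_sets <- lapply(seq_len(n_random_sets),
                          function(i) sample(gene_ids, sz))
      all_sets <- c(list(enr), rand_sets)
      ord <- sample.int(length(all_sets))
      all_sets <- all_sets[ord]
      names(all_sets) <- sprintf("set%02d", seq_along(all_sets))
      enriched_id <- names(all_sets)[which(ord == 1L)]
      sets <- gene_set_collection(all_sets, background = gene_ids)
    }
    list(expr = expr, sets = sets, assoc = assoc, enriched_id = enriched_id)
  })

  truth <- ground_truth(associated_genes = out$assoc,
                        enriched_set_id = out$enriched_id,
                        seed = as.integer(seed))
  structure(list(expression = out$expr, sets = out$sets, truth = truth),
            class = "expression_sim")
}

#' Simulate a complete developmental enrichment profile grid
#'
#' Builds a brain-region x developmental-period grid of annotation gene
#' sets (6 regions x 10 periods by default, 60 cells) in which exactly one
#' cell is enriched for a supplied gene list; the other cells are random
#' draws from the background.
#'
#' @param gene_ids Background gene universe.
#' @param associated Genes the enriched cell should over-represent.
#' @param regions,periods Character vectors naming the grid.
#' @param enriched_cell Length-2 character vector `c(region, period)`.
#' @param set_size Genes per cell set.
#' @param enrich_frac Fraction of the enriched cell drawn from `associated`.
#' @param seed Integer seed.
#' @return A list with `profiles` (a [gene_set_collection()] whose set names
#'   are `"region|period"`) and `enriched_cell`.
#' @export
simulate_dev_profiles <- function(gene_ids, associated,
                                  regions = c("cortex", "thalamus",
                                              "striatum", "cerebellum",
                                              "hippocampus", "amygdala"),
                                  periods = c("early_fetal",
                                              "early_mid_fetal",
                                              "late_mid_fetal", "late_fetal",
                                              "neonatal_early_infancy",
                                              "late_infancy",
                                              "early_childhood",
                                              "middle_late_childhood",
                                              "adolescence",
                                              "young_adulthood"),
                                  enriched_cell = c("cortex",
                                                    "middle_late_childhood"),
                                  set_size = 60L, enrich_frac = 0.5,
                                  seed = 1L) {
  stopifnot(all(associated %in% gene_ids),
            enriched_cell[1] %in% regions, enriched_cell[2] %in% periods,
            set_size <= length(gene_ids))
  grid <- expand.grid(region = regions, period = periods,
                      stringsAsFactors = FALSE)
  profiles <- with_seed(seed, {
    sets <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      if (grid$region[i] == enriched_cell[1] &&
          grid$period[i] == enriched_cell[2]) {
        n_a <- min(length(associated), ceiling(set_size * enrich_frac))
        sets[[i]] <- c(sample(associated, n_a),
                       sample(setdiff(gene_ids, associated), set_size - n_a))
      } else {
        sets[[i]] <- sample(gene_ids, set_size)
      }
    }
    names(sets) <- paste(grid$region, grid$period, sep = "|")
    gene_set_collection(sets, background = gene_ids)
  })
  list(profiles = profiles, enriched_cell = enriched_cell)
}
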
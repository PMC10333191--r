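#' Gradient eccentricity map
#'
#' Per-vertex Euclidean distance to the centroid of all vertices in the
#' subject's own aligned low-dimensional gradient space (3D by default).
#' Alignment is part of the definition: individual gradient spaces are only
#' comparable after Procrustes alignment to a common template, so unaligned
#' input is an error.
#'
#' @param g An aligned [gradient_set()] with at least `dims` components.
#' @param dims Number of leading components to use (default 3).
#' @return An object of class `eccentricity_map`: list with `values`
#'   (per-vertex nonnegative distances, `NA` for missing vertices),
#'   `centroid` (length-`dims`), and `dims`.
#' @export
eccentricity <- function(g, dims = 3L) {
  stopifnot(inherits(g, "gradient_set"))
  if (!isTRUE(g$aligned)) {
    stop("gradient set is not aligned; align to a template first ",
         "(eccentricity is defined in the aligned space)")
  }
  dims <- as.integer(dims)
  if (ncol(g$components) < dims) {
    stop("gradient set has ", ncol(g$components),
         " components but dims = ", dims)
  }
  X <- g$components[, seq_len(dims), drop = FALSE]
  ok <- stats::complete.cases(X)
  centroid <- colMeans(X[ok, , drop = FALSE])
  vals <- rep(NA_real_, nrow(X))
  vals[ok] <- sqrt(rowSums((X[ok, , drop = FALSE] -
                              matrix(centroid, sum(ok), dims,
                                     byrow = TRUE))^2))
  structure(list(values = vals, centroid = centroid, dims = dims),
            class = "eccentricity_map")
}

#' @export
print.eccentricity_map <- function(x, ...) {
  cat("eccentricity_map:", length(x$values), "vertices; centroid = (",
      paste(sprintf("%.4g", x$centroid), collapse = ", "), ")\n")
  invisible(x)
}

# Coerce a collection of eccentricity maps (list of eccentricity_map /
# numeric vectors, or a subjects x vertices matrix) to a matrix.
ecc_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  if (inherits(maps, "eccentricity_map")) return(matrix(maps$values, nrow = 1))
  stopifnot(is.list(maps), length(maps) >= 1L)
  rows <- lapply(maps, function(m) {
    if (inherits(m, "eccentricity_map")) m$values else as.numeric(m)
  })
  len <- lengths(rows)
  if (length(unique(len)) != 1L) stop("maps differ in vertex count")
  out <- do.call(rbind, rows)
  rownames(out) <- names(maps)
  out
}

#' Community-level eccentricity profile
#'
#' Summarizes per-vertex eccentricity within functional communities: the
#' mean and standard deviation over all vertices and subjects, and, when a
#' control reference is supplied, a z-score versus controls. The z-score is
#' computed per vertex, `(mean_patients - mean_controls) / sd_controls`,
#' and then averaged over each community's vertices (so n = number of
#' vertices in the community); set `z_level = "subject"` to z-score
#' subject-level community means instead.
#'
#' @param maps Eccentricity maps for the analyzed group: a list of
#'   [eccentricity()] results or a subjects x vertices matrix.
#' @param labels Integer community label per vertex (1..K, all present).
#' @param reference Optional maps of the control group, same forms.
#' @param z_level `"vertex"` (default) or `"subject"`.
#' @return data.frame with one row per community: `community`,
#'   `n_vertices`, `mean`, `sd`, and `z` (NA without a reference).
#' @export
community_profile <- function(maps, labels, reference = NULL,
                              z_level = c("vertex", "subject")) {
  z_level <- match.arg(z_level)
  M <- ecc_matrix(maps)
  labels <- as.integer(labels)
  if (length(labels) != ncol(M)) {
    stop("labels (", length(labels), ") do not cover the ",
         ncol(M), " vertices")
  }
  K <- max(labels)
  counts <- tabulate(labels, nbins = K)
  if (any(counts == 0L)) {
    stop("community with zero vertices: ",
         paste(which(counts == 0L), collapse = ", "))
  }
  comm_mean <- vapply(seq_len(K), function(k) {
    mean(M[, labels == k], na.rm = TRUE)
  }, numeric(1))
  comm_sd <- vapply(seq_len(K), function(k) {
    stats::sd(M[, labels == k], na.rm = TRUE)
  }, numeric(1))
  z <- rep(NA_real_, K)
  if (!is.null(reference)) {
    R <- ecc_matrix(reference)
    if (ncol(R) != ncol(M)) stop("reference maps differ in vertex count")
    if (z_level == "vertex") {
      mu_p <- colMeans(M, na.rm = TRUE)
      mu_c <- colMeans(R, na.rm = TRUE)
      sd_c <- col_sds(R)
      zv <- (mu_p - mu_c) / sd_c
      z <- vapply(seq_len(K), function(k) {
        mean(zv[labels == k], na.rm = TRUE)
      }, numeric(1))
    } else {
      for (k in seq_len(K)) {
        sm_p <- rowMeans(M[, labels == k, drop = FALSE], na.rm = TRUE)
        sm_c <- rowMeans(R[, labels == k, drop = FALSE], na.rm = TRUE)
        z[k] <- (mean(sm_p) - mean(sm_c)) / stats::sd(sm_c)
      }
    }
  }
  data.frame(community = seq_len(K), n_vertices = counts,
             mean = comm_mean, sd = comm_sd, z = z)
}

#' Subject-by-community summary matrix
#'
#' Mean eccentricity (or any per-vertex measure) of each subject within
#' each community; the subject-level input to the covariate-controlled
#' community models.
#'
#' @inheritParams community_profile
#' @return Subjects x communities numeric matrix (columns `comm1`...).
#' @export
community_means <- function(maps, labels) {
  M <- ecc_matrix(maps)
  labels <- as.integer(labels)
  stopifnot(length(labels) == ncol(M))
  K <- max(labels)
  out <- vapply(seq_len(K), function(k) {
    rowMeans(M[, labels == k, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(M)))
  out <- matrix(out, nrow = nrow(M))
  colnames(out) <- paste0("comm", seq_len(K))
  rownames(out) <- rownames(M)
  out
}
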
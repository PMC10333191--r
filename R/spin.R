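# Spherical-rotation (spin) null models for spatial correlation tests.

# One Haar-uniform rotation matrix in SO(3).
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qrd <- qr(M)
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin reassignment indices for locations on a sphere
#'
#' For each spin, draws a uniformly random 3D rotation, rotates the
#' locations, and maps every original location to its nearest rotated
#' location (classic nearest-neighbour spin construction, not guaranteed
#' bijective; duplicated assignments per spin are counted in attribute
#' `"n_collisions"`). When hemisphere tags are supplied, the right
#' hemisphere is rotated by the x-mirrored version of the left-hemisphere
#' rotation and assignments stay within hemisphere.
#'
#' @param coords n x 3 matrix of unit-norm coordinates (vertices or parcel
#'   centroids projected to the sphere).
#' @param n_spins Number of rotations.
#' @param seed Integer seed.
#' @param hemisphere Optional character vector (`"left"`/`"right"`) per
#'   location.
#' @param rotations Optional list of 3 x 3 rotation matrices to use instead
#'   of random ones (testing hook).
#' @return Integer matrix `n_spins` x n: row s maps location i to the
#'   source location whose rotated position is nearest, so a spun map is
#'   `map[idx[s, ]]`. Attributes `n_collisions` and `seed`.
#' @export
spin_indices <- function(coords, n_spins, seed = 1L, hemisphere = NULL,
                         rotations = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 locations")
  nrm <- sqrt(rowSums(coords^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("coordinates must be unit-norm (project parcel centroids to the ",
         "sphere first)")
  }
  dup_groups <- if (is.null(hemisphere)) {
    list(seq_len(n))
  } else {
    split(seq_len(n), hemisphere)
  }
  n_dup <- sum(vapply(dup_groups, function(ii) {
    sum(duplicated(signif(coords[ii, , drop = FALSE], 12)))
  }, numeric(1)))
  if (n_dup > 0) {
    warning("duplicated coordinates: ", n_dup,
            " locations collapse under nearest-neighbour mapping")
  }
  if (is.null(rotations)) {
    rotations <- with_seed(seed, {
      lapply(seq_len(n_spins), function(i) random_rotation())
    })
  } else {
    stopifnot(length(rotations) == n_spins)
  }
  Mir <- diag(c(-1, 1, 1))
  groups <- if (is.null(hemisphere)) {
    list(seq_len(n))
  } else {
    stopifnot(length(hemisphere) == n)
    split(seq_len(n), hemisphere)
  }
  idx <- matrix(NA_integer_, n_spins, n)
  collisions <- integer(n_spins)
  for (s in seq_len(n_spins)) {
    R <- rotations[[s]]
    for (gn in names(groups) %||% "all") {
      ii <- if (is.null(hemisphere)) groups[[1]] else groups[[gn]]
      Rg <- if (!is.null(hemisphere) && gn == "right") Mir %*% R %*% Mir else R
      rot <- coords[ii, , drop = FALSE] %*% t(Rg)
      # nearest on the unit sphere = largest dot product
      D <- coords[ii, , drop = FALSE] %*% t(rot)
      idx[s, ii] <- ii[max.col(D, ties.method = "first")]
    }
    collisions[s] <- n - length(unique(idx[s, ]))
  }
  attr(idx, "n_collisions") <- collisions
  attr(idx, "seed") <- seed
  idx
}

#' Spin permutation test of a spatial correlation
#'
#' Observed statistic is the Pearson correlation of the two maps; the null
#' is built by spherically rotating `map_a` (the statistical map, by the
#' package's convention) `n_spins` times and re-correlating with `map_b`.
#' Two-sided p per the permutation convention
#' `(1 + #\{|null| >= |observed|\}) / (n_spins + 1)`. Missing locations are
#' dropped pairwise, per spin.
#'
#' @param map_a,map_b Numeric vectors on the same locations.
#' @param coords n x 3 unit coordinates of the locations.
#' @param n_spins Number of rotations (default 5000).
#' @param seed Integer seed.
#' @param hemisphere Optional hemisphere tags, see [spin_indices()].
#' @param spins Optional precomputed index matrix from [spin_indices()].
#' @return Object of class `spin_result`: list with `observed`, `nulls`,
#'   `p_spin`, `n_spins`, `seed`.
#' @export
spin_test <- function(map_a, map_b, coords, n_spins = 5000L, seed = 1L,
                      hemisphere = NULL, spins = NULL) {
  stopifnot(length(map_a) == length(map_b),
            length(map_a) == nrow(coords))
  ok <- is.finite(map_a) & is.finite(map_b)
  if (stats::sd(map_a[ok]) == 0 || stats::sd(map_b[ok]) == 0) {
    stop("zero-variance map: spatial correlation undefined")
  }
  if (is.null(spins)) {
    spins <- spin_indices(coords, n_spins, seed = seed,
                          hemisphere = hemisphere)
  } else {
    n_spins <- nrow(spins)
  }
  observed <- stats::cor(map_a[ok], map_b[ok])
  nulls <- vapply(seq_len(n_spins), function(s) {
    a <- map_a[spins[s, ]]
    use <- is.finite(a) & is.finite(map_b)
    if (sum(use) < 3L || stats::sd(a[use]) == 0) return(NA_real_)
    stats::cor(a[use], map_b[use])
  }, numeric(1))
  p <- (1 + sum(abs(nulls) >= abs(observed), na.rm = TRUE)) / (n_spins + 1)
  structure(list(observed = observed, nulls = nulls, p_spin = p,
                 n_spins = n_spins, seed = seed),
            class = "spin_result")
}

#' @export
print.spin_result <- function(x, ...) {
  cat("spin_result: observed =", sprintf("%.4f", x$observed),
      "; p_spin =", sprintf("%.4g", x$p_spin),
      "(", x$n_spins, "spins )\n")
  invisible(x)
}
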
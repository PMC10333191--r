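#' Build a subdivided-icosahedron sphere mesh with community and parcel labels
#'
#' Constructs a triangulated unit sphere by recursive subdivision of an
#' icosahedron and grows `n_communities` contiguous community patches (the
#' functional-network analogue) and `n_parcels` contiguous parcels (the
#' region analogue used for transcriptomic decoding) by seeded region
#' growing on the mesh graph. Communities and parcels are drawn
#' independently, so parcels do not necessarily nest within communities.
#'
#' @param n_vertices Number of vertices; must be a subdivided-icosahedron
#'   count, i.e. one of 12, 42, 162, 642, 2562, 10242.
#' @param n_communities Number of community labels (default 7, mirroring the
#'   seven canonical functional networks).
#' @param n_parcels Number of parcels; must satisfy
#'   `n_parcels >= n_communities` and `n_vertices >= 4 * n_parcels`.
#' @param seed Integer seed; identical seeds give identical meshes.
#' @param hemisphere Hemisphere tag applied to every vertex (`"left"` or
#'   `"right"`).
#' @return An object of class `surface_mesh`: a list with `vertices`
#'   (n x 3 unit coordinates), `faces` (m x 3 vertex indices), `community`,
#'   `parcel` (integer labels), `hemisphere` (character vector),
#'   `n_communities`, `n_parcels`.
#' @examples
#' mesh <- make_sphere_mesh(162, n_communities = 7, n_parcels = 20, seed = 1)
#' table(mesh$community)
#' @export
make_sphere_mesh <- function(n_vertices, n_communities = 7L, n_parcels,
                             seed = 1L, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  valid <- 10L * 4L^(0:5) + 2L
  if (!n_vertices %in% valid) {
    stop("n_vertices must be a subdivided-icosahedron count (one of ",
         paste(valid, collapse = ", "), "); got ", n_vertices)
  }
  n_communities <- as.integer(n_communities)
  n_parcels <- as.integer(n_parcels)
  if (n_parcels < n_communities) {
    stop("infeasible sizes: n_parcels (", n_parcels,
         ") must be >= n_communities (", n_communities, ")")
  }
  if (n_vertices < 4L * n_parcels) {
    stop("infeasible sizes: n_vertices (", n_vertices,
         ") must be >= 4 * n_parcels (", 4L * n_parcels, ")")
  }
  level <- which(valid == n_vertices) - 1L
  ico <- icosphere(level)
  adj <- mesh_adjacency(ico$faces, nrow(ico$vertices))
  labs <- with_seed(seed, {
    comm <- grow_labels(adj, n_communities, ico$vertices)
    parc <- grow_labels(adj, n_parcels, ico$vertices)
    list(comm = comm, parc = parc)
  })
  mesh <- structure(list(
    vertices = ico$vertices,
    faces = ico$faces,
    community = labs$comm,
    parcel = labs$parc,
    hemisphere = rep(hemisphere, nrow(ico$vertices)),
    n_communities = n_communities,
    n_parcels = n_parcels
  ), class = "surface_mesh")
  validate_mesh(mesh)
  mesh
}

#' Mirror a surface mesh across the midsagittal plane
#'
#' Returns a copy of the mesh with the x coordinate negated and the opposite
#' hemisphere tag, keeping labels; used to assemble two-hemisphere fixtures
#' for mirrored spin rotations.
#'
#' @param mesh A `surface_mesh`.
#' @return A `surface_mesh` with flipped x coordinates and hemisphere tags.
#' @export
mirror_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  out <- mesh
  out$vertices[, 1] <- -out$vertices[, 1]
  out$hemisphere <- ifelse(mesh$hemisphere == "left", "right", "left")
  # flip face orientation so outward normals are preserved
  out$faces <- out$faces[, c(1L, 3L, 2L)]
  out
}

#' Parcel centroids projected back onto the unit sphere
#'
#' @param mesh A `surface_mesh`.
#' @return `n_parcels` x 3 matrix of unit-norm centroid coordinates, row
#'   names the parcel ids.
#' @export
parcel_centroids <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  cen <- rowsum(mesh$vertices, mesh$parcel) /
    as.vector(table(factor(mesh$parcel, levels = seq_len(mesh$n_parcels))))
  cen <- cen / sqrt(rowSums(cen^2))
  rownames(cen) <- paste0("parcel", seq_len(mesh$n_parcels))
  cen
}

validate_mesh <- function(mesh) {
  nrm <- sqrt(rowSums(mesh$vertices^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("mesh vertices are not on the unit sphere")
  if (anyNA(mesh$community) || any(mesh$community < 1L)) {
    stop("every vertex needs a community label")
  }
  if (anyNA(mesh$parcel) || any(mesh$parcel < 1L)) {
    stop("every vertex needs a parcel label")
  }
  if (length(unique(mesh$community)) != mesh$n_communities) {
    stop("empty community label")
  }
  if (length(unique(mesh$parcel)) != mesh$n_parcels) {
    stop("empty parcel label")
  }
  invisible(mesh)
}

# Base icosahedron; vertices on the unit sphere.
icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1,  p,  0,   1,  p,  0,  -1, -p,  0,   1, -p,  0,
     0, -1,  p,   0,  1,  p,   0, -1, -p,   0,  1, -p,
     p,  0, -1,   p,  0,  1,  -p,  0, -1,  -p,  0,  1
  ), ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(
    1, 12, 6,  1, 6, 2,  1, 2, 8,  1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3,  11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,  4, 3, 7,  4, 7, 9,  4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,  10, 9, 2
  ), ncol = 3, byrow = TRUE)
  list(vertices = v, faces = f)
}

# Subdivide each triangle into four, projecting midpoints to the sphere.
icosphere <- function(level) {
  m <- icosahedron()
  for (i in seq_len(level)) m <- subdivide_once(m)
  m
}

subdivide_once <- function(m) {
  v <- m$vertices
  f <- m$faces
  midkey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  e1 <- midkey(f[, 1], f[, 2])
  e2 <- midkey(f[, 2], f[, 3])
  e3 <- midkey(f[, 3], f[, 1])
  keys <- unique(c(e1, e2, e3))
  idx <- setNames(seq_along(keys) + nrow(v), keys)
  ends <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  a <- as.integer(ends[, 1]); b <- as.integer(ends[, 2])
  mid <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  v2 <- rbind(v, mid)
  m1 <- idx[e1]; m2 <- idx[e2]; m3 <- idx[e3]
  f2 <- rbind(
    cbind(f[, 1], m1, m3),
    cbind(f[, 2], m2, m1),
    cbind(f[, 3], m3, m2),
    cbind(m1, m2, m3)
  )
  dimnames(f2) <- NULL
  list(vertices = v2, faces = f2)
}

# Adjacency list from triangle faces.
mesh_adjacency <- function(faces, n) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2], factor(e[, 1], levels = seq_len(n)))
}

# Size-balanced multi-source region growing from farthest-point seeds:
# contiguous patches of near-equal size, no empty label. Needs the vertex
# coordinates to spread the seeds.
grow_labels <- function(adj, n_labels, coords = NULL) {
  n <- length(adj)
  lab <- integer(n)
  if (is.null(coords)) {
    seeds <- sample.int(n, n_labels)
  } else {
    seeds <- integer(n_labels)
    seeds[1] <- sample.int(n, 1L)
    mind <- colSums((t(coords) - coords[seeds[1], ])^2)
    for (i in seq_len(n_labels - 1L)) {
      seeds[i + 1L] <- which.max(mind)
      mind <- pmin(mind, colSums((t(coords) - coords[seeds[i + 1L], ])^2))
    }
  }
  lab[seeds] <- seq_len(n_labels)
  frontier <- vector("list", n_labels)
  size <- rep.int(1L, n_labels)
  for (i in seq_len(n_labels)) {
    nb <- adj[[seeds[i]]]
    frontier[[i]] <- nb[lab[nb] == 0L]
  }
  while (any(lab == 0L)) {
    live <- vapply(frontier, length, 0L) > 0L
    if (!any(live)) {
      # disconnected leftovers should not happen on a sphere mesh, but keep
      # the loop total: attach an unlabeled vertex to a random label
      v <- which(lab == 0L)[1L]
      lab[v] <- sample.int(n_labels, 1L)
      next
    }
    # grow the currently smallest live patch
    l <- which(live)[which.min(size[live])]
    cand <- frontier[[l]]
    pick <- if (length(cand) == 1L) 1L else sample.int(length(cand), 1L)
    v <- cand[pick]
    frontier[[l]] <- cand[-pick]
    if (lab[v] != 0L) next
    lab[v] <- l
    size[l] <- size[l] + 1L
    nb <- adj[[v]]
    nb <- nb[lab[nb] == 0L]
    if (length(nb)) frontier[[l]] <- c(frontier[[l]], nb)
  }
  lab
}

# Number of connected components each label forms on the mesh graph
# (1 everywhere = all patches contiguous). Used by validation and tests.
label_components <- function(adj, lab) {
  vapply(sort(unique(lab)), function(l) {
    keep <- which(lab == l)
    sub <- lapply(adj[keep], function(nb) intersect(nb, keep))
    comp <- integer(length(keep))
    cur <- 0L
    pos <- setNames(seq_along(keep), keep)
    for (s in seq_along(keep)) {
      if (comp[s] != 0L) next
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        u <- queue[[1L]]; queue <- queue[-1L]
        nb <- pos[as.character(sub[[u]])]
        nb <- nb[comp[nb] == 0L]
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    cur
  }, integer(1))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces,",
      x$n_communities, "communities,", x$n_parcels, "parcels,",
      unique(x$hemisphere), "hemisphere\n")
  invisible(x)
}
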
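#' Pairwise Pearson functional connectivity
#'
#' Correlates every pair of vertex time series. Vertices with zero temporal
#' variance are flagged (attribute `"flagged"`), given correlation 0 to all
#' others, and excluded from downstream embeddings.
#'
#' @param ts Vertex x time numeric matrix (>= 2 vertices, >= 2 timepoints,
#'   all finite).
#' @return Vertex x vertex correlation matrix with unit diagonal and an
#'   integer attribute `flagged` listing zero-variance vertices.
#' @export
compute_fc <- function(ts) {
  stopifnot(is.matrix(ts), is.numeric(ts))
  if (ncol(ts) < 2L) stop("need at least 2 timepoints")
  if (nrow(ts) < 2L) stop("need at least 2 vertices")
  if (any(!is.finite(ts))) stop("time series contain non-finite values")
  v <- rowSums((ts - rowMeans(ts))^2)
  flagged <- which(v <= .Machine$double.eps * ncol(ts))
  if (length(flagged) == nrow(ts)) {
    stop("all vertices are constant: ",
         paste(utils::head(flagged, 10), collapse = ", "),
         if (length(flagged) > 10) ", ..." else "")
  }
  n <- nrow(ts)
  C <- matrix(0, n, n)
  ok <- setdiff(seq_len(n), flagged)
  C[ok, ok] <- stats::cor(t(ts[ok, , drop = FALSE]))
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  attr(C, "flagged") <- flagged
  C
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Per row, keeps the `ceiling(density * (N - 1))` largest off-diagonal
#' values (signed order) and zeroes the rest; the diagonal is kept. The
#' result is generally asymmetric.
#'
#' @param C Square numeric matrix.
#' @param density Fraction of off-diagonal entries to retain per row, in
#'   (0, 1\]. Default 0.10 (top 10 percent of edges).
#' @return Thresholded matrix of the same dimensions.
#' @export
sparsify_rows <- function(C, density = 0.10) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  n <- nrow(C)
  keep <- as.integer(ceiling(density * (n - 1L)))
  if (keep >= n - 1L) return(C)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- C[i, ]
    row[i] <- -Inf
    thr <- -sort(-row, partial = keep)[keep]  # keep-th largest off-diagonal
    sel <- which(row >= thr)
    if (length(sel) > keep) {  # ties at the threshold: first-come order
      sel <- sel[order(row[sel], decreasing = TRUE)[seq_len(keep)]]
    }
    S[i, sel] <- row[sel]
  }
  diag(S) <- diag(C)
  S
}

#' Cosine-similarity affinity between connectivity rows
#'
#' Entry (i, j) is the cosine similarity of rows i and j of the (typically
#' sparsified) connectivity matrix; negative similarities are clipped to 0
#' so the affinity is valid for diffusion normalization, and the diagonal is
#' set to 1. The output is symmetric even when the input is not.
#'
#' @param S Square numeric matrix with no all-zero rows.
#' @return Nonnegative symmetric affinity matrix with unit diagonal.
#' @export
cosine_affinity <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  nrm <- sqrt(rowSums(S^2))
  zero <- which(nrm == 0)
  if (length(zero)) {
    stop("all-zero rows at vertices: ",
         paste(utils::head(zero, 10), collapse = ", "))
  }
  A <- tcrossprod(S / nrm)
  A <- (A + t(A)) / 2
  A[A < 0] <- 0
  A[A > 1] <- 1
  diag(A) <- 1
  A
}

#' Gradient set container
#'
#' @param components Vertex x k matrix of embedding components.
#' @param eigenvalues Length-k nonnegative eigenvalues (descending).
#' @param variance_explained Length-k fractions (nonincreasing, sum <= 1).
#' @param alpha Diffusion normalization exponent used.
#' @param aligned Whether the components have been Procrustes-aligned.
#' @return An object of class `gradient_set`.
#' @export
gradient_set <- function(components, eigenvalues, variance_explained,
                         alpha, aligned = FALSE) {
  stopifnot(ncol(components) == length(eigenvalues),
            length(eigenvalues) == length(variance_explained))
  structure(list(components = components, eigenvalues = eigenvalues,
                 variance_explained = variance_explained, alpha = alpha,
                 aligned = isTRUE(aligned)), class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat("gradient_set:", nrow(x$components), "vertices x",
      ncol(x$components), "components; alpha =", x$alpha,
      "; aligned =", x$aligned, "\n")
  cat("variance explained:",
      paste(sprintf("%.3f", x$variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' Diffusion map embedding of an affinity matrix
#'
#' Applies the anisotropic normalization `W = D^-alpha A D^-alpha`, forms
#' the Markov operator by row normalization, and embeds with the top
#' nontrivial eigenvectors (the constant eigenvector at eigenvalue 1 is
#' discarded). Components are scaled by `lambda / (1 - lambda)` under the
#' default diffusion-time-agnostic convention, or returned as plain
#' unit-norm eigenvectors with `scaling = "eigenvector"`. The variance
#' explained of component i is `lambda_i / sum(lambda_j)` over all retained
#' nontrivial positive eigenvalues.
#'
#' @param A Nonnegative symmetric affinity matrix whose graph is connected.
#' @param alpha Density-normalization exponent (default 0.5).
#' @param k Number of components to return (>= 3, `< nrow(A)`).
#' @param scaling `"diffusion"` (default) or `"eigenvector"`.
#' @return A [gradient_set()] with `aligned = FALSE`.
#' @export
diffusion_embedding <- function(A, alpha = 0.5, k = 10L,
                                scaling = c("diffusion", "eigenvector")) {
  scaling <- match.arg(scaling)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  k <- as.integer(k)
  if (k >= n) stop("k must be smaller than the number of vertices")
  if (any(A < 0)) stop("affinity must be nonnegative")
  comp <- graph_components(A > 0)
  nc <- max(comp)
  if (nc > 1L) {
    stop("affinity graph is disconnected (", nc, " components); ",
         "diffusion embedding requires a single component")
  }
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  dw <- rowSums(W)
  isq <- 1 / sqrt(dw)
  Sm <- W * outer(isq, isq)
  Sm <- (Sm + t(Sm)) / 2
  e <- eigen(Sm, symmetric = TRUE)
  lam <- e$values[-1L]              # drop the trivial unit eigenvalue
  psi <- e$vectors * isq            # back-transform to Markov eigenvectors
  psi <- psi[, -1L, drop = FALSE]
  psi <- sweep(psi, 2, sqrt(colSums(psi^2)), "/")
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(psi))) {
    if (psi[which.max(abs(psi[, j])), j] < 0) psi[, j] <- -psi[, j]
  }
  pos_sum <- sum(lam[lam > 0])
  ve <- lam / pos_sum
  kk <- seq_len(k)
  compo <- psi[, kk, drop = FALSE]
  if (scaling == "diffusion") {
    compo <- compo * rep(lam[kk] / (1 - lam[kk]), each = n)
  }
  gradient_set(compo, eigenvalues = lam[kk], variance_explained = ve[kk],
               alpha = alpha, aligned = FALSE)
}

#' Group-template gradients from averaged connectivity
#'
#' Element-wise mean of the supplied connectivity matrices, then the
#' standard sparsify / cosine-affinity / diffusion-embedding pipeline.
#'
#' @param fc_matrices List of same-sized connectivity matrices (>= 2, or 1
#'   which trivially equals the single-subject embedding).
#' @inheritParams diffusion_embedding
#' @param density Row sparsification density.
#' @return A [gradient_set()] with `aligned = FALSE`.
#' @export
group_template <- function(fc_matrices, density = 0.10, alpha = 0.5,
                           k = 10L, scaling = c("diffusion", "eigenvector")) {
  scaling <- match.arg(scaling)
  stopifnot(is.list(fc_matrices), length(fc_matrices) >= 1L)
  dims <- vapply(fc_matrices, function(m) dim(m), integer(2))
  if (any(dims != dims[, 1])) {
    stop("connectivity matrices differ in shape across subjects")
  }
  Cbar <- Reduce(`+`, fc_matrices) / length(fc_matrices)
  diffusion_embedding(cosine_affinity(sparsify_rows(Cbar, density)),
                      alpha = alpha, k = k, scaling = scaling)
}

#' Procrustes alignment of a gradient set to a template
#'
#' Finds the orthogonal transform (rotation/reflection, no scaling) that
#' minimizes the Frobenius distance of the components to the template and
#' applies it. Vertices with missing components in either set are ignored
#' when estimating the transform but are transformed in the output.
#'
#' @param g A [gradient_set()] to align.
#' @param template A [gradient_set()] with the same vertex count and k.
#' @return The aligned [gradient_set()] (`aligned = TRUE`) with the
#'   orthogonal matrix stored in attribute `"rotation"`.
#' @export
procrustes_align <- function(g, template) {
  stopifnot(inherits(g, "gradient_set"), inherits(template, "gradient_set"))
  G <- g$components
  Tc <- template$components
  if (!all(dim(G) == dim(Tc))) {
    stop("gradient set and template differ in vertex count or k (",
         paste(dim(G), collapse = "x"), " vs ",
         paste(dim(Tc), collapse = "x"), ")")
  }
  ok <- stats::complete.cases(G) & stats::complete.cases(Tc)
  M <- crossprod(G[ok, , drop = FALSE], Tc[ok, , drop = FALSE])
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  out <- g
  out$components <- G %*% R
  out$aligned <- TRUE
  attr(out, "rotation") <- R
  out
}

#' Functional connectivity density map
#'
#' Per vertex, counts the connections whose Pearson correlation exceeds the
#' threshold.
#'
#' @inheritParams compute_fc
#' @param r_threshold Correlation cutoff in (0, 1); default 0.3.
#' @return A list of class `fcd_map` with integer `counts` (length =
#'   vertices) and `r_threshold`.
#' @export
fcd_map <- function(ts, r_threshold = 0.3) {
  if (!(r_threshold > 0 && r_threshold < 1)) {
    stop("r_threshold must be in (0, 1)")
  }
  C <- compute_fc(ts)
  counts <- as.integer(rowSums(C > r_threshold) - 1L)  # diagonal removed
  structure(list(counts = counts, r_threshold = r_threshold),
            class = "fcd_map")
}

#' Per-subject gradients through the full connectome pipeline
#'
#' Convenience wrapper: Pearson connectivity, row sparsification, cosine
#' affinity, diffusion embedding, optional Procrustes alignment to a
#' template. Zero-variance vertices are excluded from the embedding and
#' reinserted as missing rows in the components.
#'
#' @inheritParams compute_fc
#' @inheritParams group_template
#' @param template Optional [gradient_set()] to align to.
#' @return A [gradient_set()].
#' @export
subject_gradients <- function(ts, density = 0.10, alpha = 0.5, k = 10L,
                              template = NULL,
                              scaling = c("diffusion", "eigenvector")) {
  scaling <- match.arg(scaling)
  C <- compute_fc(ts)
  flagged <- attr(C, "flagged")
  ok <- setdiff(seq_len(nrow(C)), flagged)
  g <- diffusion_embedding(
    cosine_affinity(sparsify_rows(C[ok, ok, drop = FALSE], density)),
    alpha = alpha, k = k, scaling = scaling)
  if (length(flagged)) {
    full <- matrix(NA_real_, nrow(C), ncol(g$components))
    full[ok, ] <- g$components
    g$components <- full
  }
  if (!is.null(template)) g <- procrustes_align(g, template)
  g
}

#' Template and aligned gradients for a whole cohort
#'
#' Computes per-subject connectivity once, builds the group template from
#' the mean connectivity of `template_subjects` (typically the controls),
#' embeds every subject, and aligns each embedding to the template.
#'
#' @param ts_list List of vertex x time matrices.
#' @param template_subjects Indices of the subjects averaged into the
#'   template (default: all).
#' @inheritParams group_template
#' @return A list with `template` (unaligned [gradient_set()]) and
#'   `gradients` (list of aligned [gradient_set()]s, named as `ts_list`).
#' @export
cohort_gradients <- function(ts_list, template_subjects = NULL,
                             density = 0.10, alpha = 0.5, k = 10L,
                             scaling = c("diffusion", "eigenvector")) {
  scaling <- match.arg(scaling)
  stopifnot(is.list(ts_list), length(ts_list) >= 1L)
  template_subjects <- template_subjects %||% seq_along(ts_list)
  fc <- lapply(ts_list, compute_fc)
  template <- group_template(fc[template_subjects], density = density,
                             alpha = alpha, k = k, scaling = scaling)
  grads <- lapply(fc, function(C) {
    flagged <- attr(C, "flagged")
    ok <- setdiff(seq_len(nrow(C)), flagged)
    g <- diffusion_embedding(
      cosine_affinity(sparsify_rows(C[ok, ok, drop = FALSE], density)),
      alpha = alpha, k = k, scaling = scaling)
    if (length(flagged)) {
      full <- matrix(NA_real_, nrow(C), ncol(g$components))
      full[ok, ] <- g$components
      g$components <- full
    }
    procrustes_align(g, template)
  })
  names(grads) <- names(ts_list)
  list(template = template, gradients = grads)
}
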
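# Parcel-level PLS decoding of a statistical map against gene expression.

#' Average a vertex map within parcels
#'
#' @param vertex_map Numeric per-vertex values (`NA` vertices are excluded
#'   from the means).
#' @param parcel_label Integer parcel label per vertex (1..P, all present).
#' @return Named numeric vector of parcel means (`parcel1`...`parcelP`).
#' @export
parcellate_map <- function(vertex_map, parcel_label) {
  stopifnot(length(vertex_map) == length(parcel_label))
  parcel_label <- as.integer(parcel_label)
  P <- max(parcel_label)
  counts <- tabulate(parcel_label, nbins = P)
  if (any(counts == 0L)) {
    stop("empty parcel: ", paste(which(counts == 0L), collapse = ", "))
  }
  out <- vapply(seq_len(P), function(p) {
    mean(vertex_map[parcel_label == p], na.rm = TRUE)
  }, numeric(1))
  names(out) <- paste0("parcel", seq_len(P))
  out
}

standardize_expression <- function(X, standardize, center = TRUE) {
  sds <- col_sds(X)
  zero <- which(sds == 0)
  if (length(zero)) {
    stop("zero-variance gene columns: ",
         paste(utils::head(colnames(X)[zero] %||% zero, 10), collapse = ", "))
  }
  out <- scale(X, center = center, scale = if (standardize) sds else FALSE)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' First partial-least-squares component for a univariate response
#'
#' For a single response map the PLS1 weight vector has the closed form
#' `w = X'y / ||X'y||` (normalized cross-covariance); scores are `t = Xw`.
#' Gene columns are z-scored by default before fitting (the usual
#' convention for regional expression matrices). The fraction of expression
#' variance captured is `||t (t't)^-1 t' X||_F^2 / ||X||_F^2`.
#'
#' @param X Parcel x gene expression matrix (>= 10 parcels, no zero
#'   variance columns).
#' @param y Per-parcel response map (centered internally, non-constant).
#' @param standardize Z-score gene columns (default TRUE; FALSE centers
#'   only).
#' @param center Center gene columns (default TRUE; set FALSE only for
#'   matrices already processed upstream).
#' @return Object of class `pls_result`: `weights` (per gene, unit norm),
#'   `scores` (per parcel), `variance_explained_x`, `spatial_r`
#'   (correlation of scores with `y`), `gene_ids`, `standardize`.
#' @export
pls_first_component <- function(X, y, standardize = TRUE, center = TRUE) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (nrow(X) < 10L) stop("need at least 10 parcels")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(y) == 0) stop("zero-variance response map")
  Xs <- standardize_expression(X, standardize, center)
  yc <- y - mean(y)
  cv <- as.numeric(crossprod(Xs, yc))
  w <- cv / sqrt(sum(cv^2))
  scores <- as.numeric(Xs %*% w)
  ve <- sum(as.numeric(crossprod(Xs, scores))^2) / sum(scores^2) /
    sum(Xs^2)
  names(w) <- colnames(X)
  structure(list(weights = w, scores = scores,
                 variance_explained_x = ve,
                 spatial_r = stats::cor(scores, y),
                 gene_ids = colnames(X), standardize = standardize),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat("pls_result:", length(x$weights), "genes,", length(x$scores),
      "parcels; variance explained (X) =",
      sprintf("%.3f", x$variance_explained_x),
      "; spatial r =", sprintf("%.3f", x$spatial_r), "\n")
  invisible(x)
}

#' Spin significance of the PLS1 association
#'
#' Tests whether PLS1 captures more covariance between the map and the
#' expression matrix than expected under spatially constrained chance. The
#' statistic is the squared covariance captured by the first component,
#' which for a univariate response is proportional to `||X'y||^2`; the map
#' is spun over parcel centroids and the statistic recomputed per spin.
#' One-sided upper p per the permutation convention.
#'
#' @inheritParams pls_first_component
#' @param coords Parcel centroid coordinates on the unit sphere.
#' @param n_spins,seed,hemisphere,spins As in [spin_test()].
#' @return A `spin_result` whose `observed`/`nulls` hold the covariance
#'   statistic.
#' @export
pls_spin_significance <- function(X, y, coords, n_spins = 1000L, seed = 1L,
                                  standardize = TRUE, hemisphere = NULL,
                                  spins = NULL) {
  stopifnot(nrow(coords) == nrow(X))
  Xs <- standardize_expression(X, standardize)
  stat <- function(yy) {
    yc <- yy - mean(yy)
    sum(as.numeric(crossprod(Xs, yc))^2)
  }
  if (is.null(spins)) {
    spins <- spin_indices(coords, n_spins, seed = seed,
                          hemisphere = hemisphere)
  } else {
    n_spins <- nrow(spins)
  }
  observed <- stat(y)
  nulls <- vapply(seq_len(n_spins), function(s) stat(y[spins[s, ]]),
                  numeric(1))
  p <- (1 + sum(nulls >= observed)) / (n_spins + 1)
  structure(list(observed = observed, nulls = nulls, p_spin = p,
                 n_spins = n_spins, seed = seed),
            class = "spin_result")
}

#' Bootstrap gene ranking of PLS1 weights
#'
#' Resamples parcels with replacement, recomputes the PLS1 weight vector
#' (sign-aligned to the original component to prevent sign-flip inflation
#' of the spread), and forms per-gene Z scores as the original weight over
#' its bootstrap standard error. Two-sided normal p-values are FDR
#' corrected and genes with `q < fdr_alpha` are selected.
#'
#' @inheritParams pls_first_component
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param fdr_alpha Selection threshold on the BH q-value.
#' @return List of class `pls_bootstrap`: `weights`, `z`, `p`, `q`,
#'   `selected` (gene ids), `n_boot`, `seed`.
#' @export
bootstrap_gene_z <- function(X, y, n_boot = 1000L, seed = 1L,
                             standardize = TRUE, fdr_alpha = 0.05) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  base <- pls_first_component(X, y, standardize = standardize)
  Xs <- standardize_expression(X, standardize)
  P <- nrow(Xs)
  w0 <- base$weights
  W <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        ix <- sample.int(P, replace = TRUE)
        if (stats::sd(y[ix]) > 0) break
      }
      Xb <- Xs[ix, , drop = FALSE]
      yb <- y[ix]
      cv <- as.numeric(crossprod(Xb, yb - mean(yb)))
      nb <- sqrt(sum(cv^2))
      wb <- if (nb > 0) cv / nb else cv
      s <- sign(sum(wb * w0))
      if (s == 0) s <- 1
      s * wb
    }, numeric(length(w0)))
  })
  se <- row_sds(W)
  z <- ifelse(se > 0, w0 / se, NA_real_)
  if (anyNA(z)) {
    warning(sum(is.na(z)), " genes with zero bootstrap SE: Z reported as NA")
  }
  p <- 2 * stats::pnorm(-abs(z))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- fdr_correct(p[ok])
  selected <- base$gene_ids[which(q < fdr_alpha)]
  structure(list(weights = w0, z = z, p = p, q = q, selected = selected,
                 n_boot = n_boot, seed = seed),
            class = "pls_bootstrap")
}
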
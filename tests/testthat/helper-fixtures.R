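# Shared fixtures and independent oracles. Fixtures are built in code and
# memoized per session; oracles are deliberately written as direct
# formulas/enumeration, independent of the implementation they check.

.fixtures <- new.env(parent = emptyenv())

small_mesh <- function(n = 162, K = 7, P = 20, seed = 1) {
  key <- paste("mesh", n, K, P, seed, sep = "_")
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_sphere_mesh(n, K, P, seed = seed)
  }
  .fixtures[[key]]
}

small_cohort <- function(n_pat = 15, n_con = 15, seed = 7,
                         truth = ground_truth(), n_t = 100) {
  key <- paste("cohort", n_pat, n_con, seed, n_t,
               paste(unlist(truth[1:2]), collapse = "_"), sep = "_")
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_cohort(small_mesh(), n_pat, n_con,
                                        truth = truth, n_timepoints = n_t,
                                        seed = seed)
  }
  .fixtures[[key]]
}

# spatially smooth scalar map on a mesh (neighbourhood averaging of noise)
smooth_map <- function(mesh, steps = 3, seed = 1) {
  adj <- gradecc:::mesh_adjacency(mesh$faces, nrow(mesh$vertices))
  x <- gradecc:::with_seed(seed, rnorm(nrow(mesh$vertices)))
  for (i in seq_len(steps)) {
    x <- vapply(seq_along(adj), function(v) mean(x[c(v, adj[[v]])]),
                numeric(1))
  }
  x
}

# Haar-ish random orthogonal matrix (sign-fixed QR)
rand_orth <- function(k, seed = 1) {
  gradecc:::with_seed(seed, {
    M <- matrix(rnorm(k * k), k, k)
    qrd <- qr(M)
    qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))), k)
  })
}

rand_rotation3 <- function(seed = 1) {
  Q <- rand_orth(3, seed)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# element-wise Pearson correlation by the direct formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# OLS t-statistic by explicit normal equations
glm_oracle <- function(y, X, ccol) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  tt <- beta[ccol] / sqrt(sigma2 * XtXi[ccol, ccol])
  list(beta = beta[ccol], t = tt, df = df,
       p = 2 * pt(-abs(tt), df))
}

# Benjamini-Hochberg step-up by the hand formula
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Two-sided Fisher p by exhaustive enumeration with choose() products
# (independent of dhyper): sums P(k) over all k whose probability does not
# exceed the observed one.
hyper_oracle <- function(a, n, K, N) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  k <- lo:hi
  pr <- choose(K, k) * choose(N - K, n - k) / choose(N, n)
  min(1, sum(pr[pr <= pr[k == a] * (1 + 1e-7)]))
}
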
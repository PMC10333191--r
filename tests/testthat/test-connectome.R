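# Connectivity, affinity, diffusion embedding, template, alignment, FCD.

test_that("compute_fc matches the direct Pearson formula and handles
           degenerate rows", {
  set.seed(1)
  ts <- matrix(rnorm(24), 4, 6)
  C <- compute_fc(ts)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(C[i, j], pearson_oracle(ts[i, ], ts[j, ]),
                 tolerance = 1e-12)
  }
  # identical and negated rows
  ts2 <- rbind(ts[1, ], ts[1, ], -ts[1, ])
  C2 <- compute_fc(ts2)
  expect_equal(C2[1, 2], 1)
  expect_equal(C2[1, 3], -1)
  # zero-variance vertex flagged with correlation 0
  ts3 <- rbind(ts, 5)
  C3 <- compute_fc(ts3)
  expect_identical(attr(C3, "flagged"), 5L)
  expect_true(all(C3[5, -5] == 0))
  expect_equal(C3[5, 5], 1)
  expect_error(compute_fc(matrix(1, 3, 10)), "constant")
})

test_that("sparsify_rows keeps exactly the top off-diagonal values per row", {
  set.seed(2)
  C <- compute_fc(matrix(rnorm(20 * 40), 20, 40))
  S <- sparsify_rows(C, 0.10)
  keep <- ceiling(0.10 * 19)  # = 2
  for (i in 1:20) {
    off <- S[i, -i]
    expect_equal(sum(off != 0), keep)
    # kept set equals brute-force top-k selection by signed value
    expect_setequal(which(S[i, ] != 0 & seq_len(20) != i),
                    setdiff(order(C[i, ] - 2 * (seq_len(20) == i),
                                  decreasing = TRUE)[seq_len(keep)], i))
  }
  expect_identical(sparsify_rows(C, 1), C)
  # N = 11, density 0.10: each row keeps exactly its row maximum
  C11 <- compute_fc(matrix(rnorm(11 * 30), 11, 30))
  S11 <- sparsify_rows(C11, 0.10)
  for (i in 1:11) {
    off <- S11[i, -i]
    expect_equal(sum(off != 0), 1)
    expect_equal(max(off), max(C11[i, -i]))
  }
  expect_error(sparsify_rows(C, 0), "density")
})

test_that("cosine_affinity matches hand-computed cosines and is symmetric", {
  S <- rbind(c(1, 2, 0, 0),
             c(2, 4, 0, 0),   # parallel to row 1
             c(0, 0, 3, 0),   # orthogonal to rows 1-2
             c(1, 0, 1, 1))
  A <- cosine_affinity(S)
  expect_equal(A[1, 2], 1, tolerance = 1e-12)
  expect_equal(A[1, 3], 0)
  expect_equal(A[1, 4], (1 * 1 + 2 * 0) / (sqrt(5) * sqrt(3)),
               tolerance = 1e-12)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 1))
  # negative similarity clipped
  B <- cosine_affinity(rbind(c(1, 0), c(-1, 0.01)))
  expect_equal(B[1, 2], 0)
  expect_error(cosine_affinity(rbind(c(1, 1), c(0, 0))), "all-zero")
  # symmetric output even for asymmetric sparsified input
  set.seed(3)
  Sp <- sparsify_rows(compute_fc(matrix(rnorm(15 * 40), 15, 40)), 0.2)
  expect_gt(max(abs(Sp - t(Sp))), 0)  # input really is asymmetric
  Ap <- cosine_affinity(Sp)
  expect_lt(max(abs(Ap - t(Ap))), 1e-10)
})

test_that("diffusion embedding agrees with a dense eigendecomposition of
           the normalized Markov operator", {
  set.seed(4)
  ts <- matrix(rnorm(50 * 80), 50, 80)
  A <- cosine_affinity(sparsify_rows(compute_fc(ts), 0.2))
  g <- diffusion_embedding(A, alpha = 0.5, k = 5)
  # oracle: plain (non-symmetric) eigendecomposition of P = D^-1 W
  d <- rowSums(A)
  W <- A / outer(d^0.5, d^0.5)
  P <- W / rowSums(W)
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  expect_equal(Re(e$values[ord[1]]), 1, tolerance = 1e-10)
  for (j in 1:5) {
    expect_gt(abs(cor(Re(e$vectors[, ord[j + 1]]), g$components[, j])),
              0.999)
    expect_equal(g$eigenvalues[j], Re(e$values[ord[j + 1]]),
                 tolerance = 1e-8)
  }
})

test_that("embedding separates a two-block affinity by the sign of
           component 1", {
  n <- 20
  eps <- 0.01
  A <- matrix(eps, n, n)
  A[1:10, 1:10] <- 1
  A[11:20, 11:20] <- 1
  g <- diffusion_embedding(A, k = 3)
  s <- sign(g$components[, 1])
  expect_true(all(s[1:10] == s[1]) && all(s[11:20] == -s[1]))
})

test_that("variance explained is nonincreasing, positive, and sums below 1", {
  set.seed(5)
  for (r in 1:5) {
    A <- cosine_affinity(sparsify_rows(
      compute_fc(matrix(rnorm(30 * 60), 30, 60)), 0.3))
    g <- diffusion_embedding(A, k = 8)
    ve <- g$variance_explained
    expect_true(all(diff(ve) <= 1e-12))
    expect_true(all(ve > 0 & ve <= 1))
    expect_lte(sum(ve), 1)
  }
})

test_that("embedding commutes with vertex relabeling up to component sign", {
  set.seed(6)
  A <- cosine_affinity(sparsify_rows(
    compute_fc(matrix(rnorm(25 * 60), 25, 60)), 0.3))
  g <- diffusion_embedding(A, k = 4)
  perm <- sample(25)
  gp <- diffusion_embedding(A[perm, perm], k = 4)
  for (j in 1:4) {
    expect_equal(abs(cor(gp$components[, j], g$components[perm, j])), 1,
                 tolerance = 1e-6)
  }
})

test_that("disconnected affinity graphs are refused with a component count", {
  A <- diag(4)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  expect_error(diffusion_embedding(A, k = 2), "2 components")
})

test_that("group template equals the single-subject embedding for identical
           subjects and averages connectivity element-wise", {
  set.seed(7)
  ts <- matrix(rnorm(30 * 60), 30, 60)
  C <- compute_fc(ts)
  g1 <- diffusion_embedding(cosine_affinity(sparsify_rows(C, 0.2)), k = 4)
  gt <- group_template(list(C, C, C), density = 0.2, k = 4)
  expect_equal(gt$components, g1$components, tolerance = 1e-10)
  expect_false(gt$aligned)
  # element-wise mean oracle on 3 distinct subjects
  Cs <- lapply(1:3, function(i) compute_fc(matrix(rnorm(10 * 30), 10, 30)))
  Cbar <- (Cs[[1]] + Cs[[2]] + Cs[[3]]) / 3
  attr(Cbar, "flagged") <- NULL
  g_direct <- diffusion_embedding(
    cosine_affinity(sparsify_rows(Cbar, 0.5)), k = 3)
  g_tmpl <- group_template(Cs, density = 0.5, k = 3)
  expect_equal(g_tmpl$components, g_direct$components, tolerance = 1e-12)
  expect_error(group_template(list(Cs[[1]], matrix(0, 4, 4))), "shape")
})

test_that("procrustes alignment recovers a known orthogonal transform and
           never increases the distance to the template", {
  set.seed(8)
  tmpl <- gradient_set(matrix(rnorm(40 * 5), 40, 5), rep(0.5, 5),
                       rep(0.1, 5), alpha = 0.5)
  # self-alignment: identity transform, zero residual
  self <- procrustes_align(tmpl, tmpl)
  expect_equal(attr(self, "rotation"), diag(5), tolerance = 1e-10)
  expect_equal(self$components, tmpl$components, tolerance = 1e-10)
  expect_true(self$aligned)
  for (r in 1:5) {
    Q <- rand_orth(5, seed = 20 + r)
    g <- tmpl
    g$components <- tmpl$components %*% Q
    al <- procrustes_align(g, tmpl)
    expect_lt(norm(al$components - tmpl$components, "F"), 1e-8)
    # optimality: aligned distance <= unaligned distance
    expect_lte(norm(al$components - tmpl$components, "F"),
               norm(g$components - tmpl$components, "F"))
  }
  g_bad <- gradient_set(matrix(0, 40, 3), rep(1, 3), rep(0.1, 3), 0.5)
  expect_error(procrustes_align(g_bad, tmpl), "vertex count or k")
})

test_that("fcd_map equals the exhaustive double-loop count", {
  set.seed(9)
  ts <- matrix(rnorm(30 * 100), 30, 100)
  fm <- fcd_map(ts, 0.3)
  C <- cor(t(ts))
  oracle <- vapply(1:30, function(i) {
    sum(vapply(setdiff(1:30, i), function(j) C[i, j] > 0.3, logical(1)))
  }, integer(1))
  expect_identical(fm$counts, oracle)
  # shared signal: every count = N - 1
  shared <- matrix(rep(rnorm(50), each = 10), 10, 50) +
    matrix(rnorm(500), 10, 50) * 1e-6
  expect_true(all(fcd_map(shared, 0.3)$counts == 9L))
  # independent long series: counts near zero
  long <- matrix(rnorm(20 * 2000), 20, 2000)
  expect_lte(max(fcd_map(long, 0.3)$counts), 1L)
  expect_error(fcd_map(ts, 1.2), "r_threshold")
})

test_that("zero-variance vertices are excluded from the embedding and
           reinserted as missing", {
  set.seed(10)
  co <- small_cohort(4, 4, seed = 31)
  ts <- co$timeseries[[1]]
  ts[7, ] <- 3  # constant vertex
  g <- subject_gradients(ts, k = 5)
  expect_true(all(is.na(g$components[7, ])))
  expect_false(anyNA(g$components[-7, ]))
})
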
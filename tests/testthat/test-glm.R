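# Linear-model statistics: oracles, symmetries, calibration, corrections.

make_table <- function(n, seed = 1) {
  gradecc:::with_seed(seed, data.frame(
    subject_id = sprintf("s%03d", 1:n),
    group = factor(rep(c("patient", "control"), length.out = n),
                   levels = c("control", "patient")),
    age = runif(n, 4, 14),
    sex = factor(sample(c("male", "female"), n, replace = TRUE)),
    head_motion = pmax(0.02, rnorm(n, 0.11, 0.05))
  ))
}

test_that("fit_glm matches the closed-form simple regression and the
           normal-equations oracle on random designs", {
  set.seed(1)
  n <- 40
  tab <- make_table(n)
  x <- tab$age
  y <- matrix(0.5 * x + rnorm(n), ncol = 1)
  sm <- fit_glm(y, tab, ~ age, "age")
  # closed-form simple-regression t
  r <- cor(x, y[, 1])
  t_closed <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(sm$t, t_closed, tolerance = 1e-10)
  # normal-equations oracle on the full covariate model, random Y
  f <- ~ group * age + sex + head_motion
  X <- gradecc:::build_design(tab, f)
  for (r in 1:5) {
    Y <- matrix(rnorm(n * 3), n, 3)
    sm2 <- fit_glm(Y, tab, f, "group:age")
    ccol <- gradecc:::contrast_column(X, f, "group:age")
    for (v in 1:3) {
      orc <- glm_oracle(Y[, v], X, ccol)
      expect_equal(sm2$t[v], orc$t, tolerance = 1e-8)
      expect_equal(sm2$beta[v], orc$beta, tolerance = 1e-8)
      expect_equal(sm2$p_uncorrected[v], orc$p, tolerance = 1e-6)
    }
  }
})

test_that("constant response yields t = 0 and p = 1", {
  tab <- make_table(20)
  sm <- fit_glm(matrix(2, 20, 2), tab, ~ age, "age")
  expect_true(all(sm$t == 0))
  expect_true(all(sm$p_uncorrected == 1))
})

test_that("parameter recovery: age slope CI covers the truth at nominal
           rate", {
  n <- 50
  hits <- 0L
  for (r in 1:100) {
    tab <- make_table(n, seed = 300 + r)
    y <- matrix(0.5 * tab$age + rnorm(n), ncol = 1)
    sm <- fit_glm(y, tab, ~ age + sex, "age")
    se <- sm$beta / sm$t
    ci <- sm$beta + c(-1, 1) * qt(0.975, attr(sm, "df")) * se
    if (ci[1] <= 0.5 && 0.5 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  tab <- make_table(20)
  tab$age2 <- tab$age
  expect_error(fit_glm(matrix(rnorm(20), ncol = 1), tab, ~ age + age2,
                       "age"), "collinear.*age2")
})

test_that("interaction and case-control t flip sign exactly under group
           relabeling", {
  set.seed(2)
  tab <- make_table(30)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  tab_fl <- tab
  tab_fl$group <- factor(ifelse(tab$group == "patient", "control",
                                "patient"), levels = c("control", "patient"))
  im <- interaction_map(Y, tab)
  im_fl <- interaction_map(Y, tab_fl)
  expect_equal(im_fl$t, -im$t, tolerance = 1e-10)
  cc <- casecontrol_map(Y, tab)
  cc_fl <- casecontrol_map(Y, tab_fl)
  expect_equal(cc_fl$t, -cc$t, tolerance = 1e-10)
  # one group empty -> error
  tab_one <- tab
  tab_one$group <- factor("patient", levels = c("control", "patient"))
  expect_error(interaction_map(Y, tab_one), "non-empty")
})

test_that("covary_model: orthogonal covariate leaves the coefficient
           unchanged, duplicate covariate errors, oracle matches", {
  set.seed(3)
  n <- 40
  tab <- make_table(n)
  ecc <- matrix(rnorm(n * 2), n, 2)
  # construct covariate orthogonal to every other design column
  f <- ~ ecc + sex + head_motion
  for (k in 1:2) {
    d <- data.frame(ecc = ecc[, k], sex = tab$sex,
                    head_motion = tab$head_motion)
    X <- gradecc:::build_design(d, f)
    raw <- rnorm(n)
    orth <- raw - X %*% solve(crossprod(X), crossprod(X, raw))
    if (k == 1) cov1 <- orth else cov2 <- orth
  }
  cova <- cbind(cov1, cov2)
  fit <- covary_model(tab, ecc, cova)
  # marginal model without the covariate
  for (k in 1:2) {
    d <- data.frame(age = tab$age, ecc = ecc[, k], sex = tab$sex,
                    head_motion = tab$head_motion)
    Xm <- gradecc:::build_design(d, ~ ecc + sex + head_motion)
    marg <- glm_oracle(tab$age, Xm, which(colnames(Xm) == "ecc"))
    expect_equal(fit$beta[k], marg$beta, tolerance = 1e-8)
    # full oracle with the covariate included
    Xf <- cbind(Xm, cov = cova[, k])
    orc <- glm_oracle(tab$age, Xf, which(colnames(Xf) == "ecc"))
    expect_equal(fit$t[k], orc$t, tolerance = 1e-8)
  }
  expect_error(covary_model(tab, ecc, ecc), "collinear")
  expect_error(covary_model(tab, ecc, cova[, 1, drop = FALSE]), "aligned")
  # robust variant runs and returns finite statistics per community
  frob <- covary_model(tab, ecc, cova, method = "rlm")
  expect_true(all(is.finite(frob$t)) && nrow(frob) == 2)
})

test_that("effect-size reduction reproduces a constructed 25% attenuation", {
  set.seed(4)
  n <- 60
  tab <- make_table(n)
  g <- as.numeric(tab$group == "patient")
  g <- g - mean(g)
  reds <- vapply(1:50, function(r) {
    e <- rnorm(n)
    e <- e - g * sum(e * g) / sum(g^2)  # orthogonalize
    y <- g + e + rnorm(n, sd = 0.05)
    m <- 0.25 * g + e                   # mediator: controlled beta = 0.75
    tb <- tab
    tb$m <- m
    base <- fit_glm(matrix(y, ncol = 1), tb, ~ group, "group")
    ctrl <- fit_glm(matrix(y, ncol = 1), tb, ~ group + m, "group")
    effect_size_reduction(base, ctrl, list(all = 1),
                          measure = "beta")$reduction_pct
  }, numeric(1))
  expect_equal(mean(reds), 25, tolerance = 0.1)
  # controlled == base -> 0%
  y <- matrix(rnorm(n), ncol = 1)
  base <- fit_glm(y, tab, ~ group, "group")
  expect_equal(effect_size_reduction(base, base,
                                     list(all = 1))$reduction_pct, 0)
  # covariate independent of response and group -> reduction near 0
  tabi <- tab
  tabi$ind <- rnorm(n)
  ctrl_i <- fit_glm(y, tabi, ~ group + ind, "group")
  expect_lt(abs(effect_size_reduction(base, ctrl_i,
                                      list(all = 1))$reduction_pct), 30)
  # zero base effect -> NA
  base0 <- base
  base0$t <- rep(0, 1)
  expect_true(is.na(effect_size_reduction(base0, base,
                                          list(all = 1))$reduction_pct))
})

test_that("permutation FWE: dominance over uncorrected p, monotonicity in
           |t|, and exchangeability of the observed map", {
  set.seed(5)
  n <- 30
  tab <- make_table(n)
  Y <- matrix(rnorm(n * 20), n, 20)
  Y[, 1] <- Y[, 1] + 0.8 * as.numeric(tab$group == "patient") * tab$age / 10
  f <- ~ group * age + sex + head_motion
  fw <- fwe_correct(Y, tab, f, "group:age", n_perm = 199, seed = 9)
  expect_true(all(fw$p_fwe >= fw$p_uncorrected - 1 / 200))
  expect_equal(which.min(fw$p_fwe), which.max(abs(fw$t)))
  # permuting subject order leaves the observed statistics unchanged
  perm <- sample(n)
  fw2 <- fwe_correct(Y[perm, ], tab[perm, ], f, "group:age",
                     n_perm = 199, seed = 9)
  expect_equal(fw2$t, fw$t, tolerance = 1e-10)
  # determinism
  fw3 <- fwe_correct(Y, tab, f, "group:age", n_perm = 199, seed = 9)
  expect_identical(fw$p_fwe, fw3$p_fwe)
  expect_error(fwe_correct(Y, tab, f, "group:age", n_perm = 10), "99")
})

test_that("fdr_correct equals the hand step-up formula and is
           order-invariant", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.5, 0.9)
  q <- fdr_correct(p)
  expect_equal(q, bh_oracle(p), tolerance = 1e-12)
  expect_equal(min(q), 7 * 0.01 / 1)  # = 0.07
  expect_true(all(fdr_correct(rep(1, 5)) == 1))
  set.seed(6)
  pr <- runif(20)
  o <- sample(20)
  expect_equal(fdr_correct(pr)[o], fdr_correct(pr[o]), tolerance = 1e-12)
  expect_error(fdr_correct(numeric(0)), "empty")
})

test_that("cross-community correlation matches the direct formula and
           rejects degenerate input", {
  a <- c(1.2, -0.5, 2.2, 0.1, -1.8, 0.9, 1.1)
  expect_equal(cross_community_correlation(a, -a)$r, -1, tolerance = 1e-12)
  set.seed(7)
  b <- rnorm(7)
  cc <- cross_community_correlation(a, b)
  expect_equal(cc$r, pearson_oracle(a, b), tolerance = 1e-12)
  rr <- cc$r
  expect_equal(cc$p, 2 * pt(-abs(rr * sqrt(5 / (1 - rr^2))), 5),
               tolerance = 1e-12)
  expect_error(cross_community_correlation(a, rep(1, 7)), "zero variance")
  expect_error(cross_community_correlation(a[1:2], b[1:2]), "at least 3")
  expect_error(cross_community_correlation(a, b[1:5]), "length")
})

test_that("clinical correlation drops missing subjects, logs durations,
           and recovers a planted association", {
  set.seed(8)
  n <- 80
  tab <- make_table(n)
  tab$attention <- NA_real_
  ecc <- matrix(rnorm(n * 10), n, 10)
  has <- which(tab$group == "patient")[1:30]
  # planted: attention tracks mean ecc of vertices 1:3
  sig <- rowMeans(ecc[has, 1:3])
  tab$attention[has] <- 100 + 12 * scale(sig) + rnorm(30, 0, 2)
  cl <- clinical_correlation(ecc, tab, "attention")
  expect_equal(attr(cl, "n_used"), 30L)
  expect_equal(attr(cl, "n_dropped"), 50L)
  expect_gt(mean(cl$t[1:3]), 2.5)
  expect_lt(mean(abs(cl$t[6:10])), 1.5)
  # log transform: duration 1 contributes 0 on the log scale
  tab$dur <- NA_real_
  tab$dur[has] <- exp(rnorm(length(has)))
  tab$dur[has[1]] <- 1
  cl2 <- clinical_correlation(ecc, tab, "dur", log_transform = TRUE)
  expect_s3_class(cl2, "stat_map")
  tab$dur[has[2]] <- -2
  expect_error(clinical_correlation(ecc, tab, "dur", log_transform = TRUE),
               tab$subject_id[has[2]])
  expect_error(clinical_correlation(ecc, tab, "nosuch"), "not found")
})

test_that("demographics: chi-square without continuity correction and
           summary-t equals full-data t", {
  # identical group proportions -> chi-square 0
  tb <- data.frame(
    group = factor(rep(c("patient", "control"), each = 20),
                   levels = c("control", "patient")),
    sex = factor(rep(rep(c("male", "female"), each = 10), 2)),
    age = runif(40, 4, 14),
    head_motion = runif(40, 0.05, 0.2)
  )
  d <- demographics_tests(tb)
  expect_equal(d$statistic[d$variable == "sex"], 0, tolerance = 1e-12)
  # t from summary stats equals t from the full sample
  set.seed(9)
  x1 <- rnorm(25, 9, 2); x2 <- rnorm(18, 10, 2)
  ps <- pooled_t_summary(mean(x1), sd(x1), 25, mean(x2), sd(x2), 18)
  tt <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(ps$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ps$p, tt$p.value, tolerance = 1e-10)
  expect_error(pooled_t_summary(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("bootstrap stability: full-sample correlation is 1, deterministic,
           and grows with sample size on planted-effect data", {
  set.seed(10)
  n <- 60
  tab <- make_table(n)
  g <- as.numeric(tab$group == "patient")
  Y <- matrix(rnorm(n * 15), n, 15)
  Y[, 1:5] <- Y[, 1:5] + outer(0.6 * g * (tab$age - 4), rep(1, 5))
  bs <- bootstrap_stability(Y, tab, c(24, 40, 60), n_boot = 30, seed = 3)
  expect_equal(bs$mean_r[3], 1, tolerance = 1e-10)
  expect_true(all(diff(bs$mean_r) > 0))
  bs2 <- bootstrap_stability(Y, tab, c(24, 40, 60), n_boot = 30, seed = 3)
  expect_identical(bs, bs2)
  expect_error(bootstrap_stability(Y, tab, c(6), n_boot = 5, seed = 1),
               "below predictors")
  expect_error(bootstrap_stability(Y, tab, c(100), n_boot = 5, seed = 1),
               "exceeds")
})
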
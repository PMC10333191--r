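# Vertex- and community-level linear models: mass-univariate OLS with a
# single-df contrast, permutation FWE, FDR, demographics, clinical
# correlations, and bootstrap stability.

# Design matrix with the package's factor coding: treatment contrasts for
# `group` (so the contrast column is the patient-vs-control difference) and
# sum-to-zero contrasts for `sex` (main effects interpretable at the factor
# mean).
build_design <- function(table, formula) {
  mf <- stats::model.frame(formula, table, na.action = stats::na.fail)
  carg <- list()
  for (nm in names(mf)) {
    if (is.factor(mf[[nm]])) {
      carg[[nm]] <- if (nm == "sex") "contr.sum" else "contr.treatment"
    }
  }
  if (!length(carg)) carg <- NULL
  X <- stats::model.matrix(formula, mf, contrasts.arg = carg)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

# Column index of the single-df contrast term in a design matrix.
contrast_column <- function(X, formula, contrast) {
  tl <- attr(stats::terms(formula), "term.labels")
  norm <- function(s) paste(sort(strsplit(s, ":", fixed = TRUE)[[1]]),
                            collapse = ":")
  hit <- which(vapply(tl, norm, "") == norm(contrast))
  if (!length(hit)) {
    stop("contrast term '", contrast, "' is not in the model (terms: ",
         paste(tl, collapse = ", "), ")")
  }
  cols <- which(attr(X, "assign") == hit)
  if (length(cols) != 1L) {
    stop("contrast term '", contrast, "' spans ", length(cols),
         " design columns; only single-df contrasts are supported")
  }
  cols
}

# Mass-univariate OLS: Y is n x V, X is n x p (full rank), ccol the
# contrast column. Returns beta, t, p (two-sided), df for each column of Y.
# Constant-y degenerate case: sigma = 0 and beta = 0 yields t = 0, p = 1.
glm_tmaps <- function(Y, X, ccol) {
  n <- nrow(X); p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  XtY <- crossprod(X, Y)
  B <- XtXi %*% XtY
  yss <- colSums(Y^2)
  rss <- pmax(yss - colSums(B * XtY), 0)
  # guard against catastrophic cancellation for (near-)perfect fits
  degenerate <- rss <= 1e-13 * pmax(yss, .Machine$double.xmin)
  rss[degenerate] <- 0
  df <- n - p
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXi[ccol, ccol])
  beta <- B[ccol, ]
  scale <- sqrt(yss / n) + .Machine$double.xmin
  tstat <- ifelse(se > 0, beta / se,
                  ifelse(abs(beta) <= 1e-8 * scale, 0, sign(beta) * Inf))
  pval <- 2 * stats::pt(-abs(tstat), df)
  list(beta = unname(beta), t = unname(tstat), p = unname(pval), df = df)
}

stat_map <- function(fit, contrast, formula, n) {
  out <- data.frame(vertex = seq_along(fit$beta), beta = fit$beta,
                    t = fit$t, p_uncorrected = fit$p,
                    p_fwe = NA_real_, q_fdr = NA_real_)
  attr(out, "df") <- fit$df
  attr(out, "contrast") <- contrast
  attr(out, "formula") <- deparse(formula)
  attr(out, "n") <- n
  class(out) <- c("stat_map", "data.frame")
  out
}

#' Vertex-wise linear model with a single-df contrast
#'
#' Ordinary least squares at every vertex; t = beta/SE for the requested
#' contrast, two-sided p from the t distribution on n - p degrees of
#' freedom.
#'
#' @param y Per-subject maps: subjects x vertices matrix, or a list of
#'   [eccentricity()] maps.
#' @param table Subject table (data.frame) supplying the predictors.
#' @param formula Right-hand-side formula over columns of `table`, e.g.
#'   `~ group * age + sex + head_motion`.
#' @param contrast Name of the model term to test (e.g. `"group:age"`);
#'   must resolve to a single design column.
#' @return A `stat_map` data.frame with columns `vertex`, `beta`, `t`,
#'   `p_uncorrected`, `p_fwe` (NA until [fwe_correct()]), `q_fdr` (NA until
#'   [fdr_correct()]); attributes `df`, `contrast`, `formula`, `n`.
#' @export
fit_glm <- function(y, table, formula, contrast) {
  Y <- ecc_matrix(y)
  stopifnot(nrow(Y) == nrow(table))
  X <- build_design(table, formula)
  if (nrow(table) <= ncol(X) + 2L) {
    stop("need more subjects (", nrow(table), ") than predictors + 2 (",
         ncol(X) + 2L, ")")
  }
  ccol <- contrast_column(X, formula, contrast)
  stat_map(glm_tmaps(Y, X, ccol), contrast, formula, nrow(Y))
}

#' Disease-by-age interaction map
#'
#' Vertex-wise model with group, age, their interaction, and the standard
#' covariates; the contrast is the group x age interaction (the group
#' difference in the age slope).
#'
#' @inheritParams fit_glm
#' @param ecc Per-subject eccentricity maps (matrix or list).
#' @param covariates Additional covariate column names (default sex and
#'   head motion).
#' @return A `stat_map` (see [fit_glm()]).
#' @export
interaction_map <- function(ecc, table,
                            covariates = c("sex", "head_motion")) {
  check_two_groups(table)
  rng <- tapply(table$age, table$group, range)
  if (max(vapply(rng, `[`, 0, 1)) >= min(vapply(rng, `[`, 0, 2))) {
    stop("group age ranges do not overlap; interaction slope is not ",
         "identified")
  }
  f <- stats::reformulate(c("group * age", covariates))
  fit_glm(ecc, table, f, "group:age")
}

#' Case-control contrast map
#'
#' Vertex-wise group difference covarying age and the standard covariates.
#'
#' @inheritParams interaction_map
#' @return A `stat_map` (see [fit_glm()]).
#' @export
casecontrol_map <- function(ecc, table,
                            covariates = c("age", "sex", "head_motion")) {
  check_two_groups(table)
  f <- stats::reformulate(c("group", covariates))
  fit_glm(ecc, table, f, "group")
}

check_two_groups <- function(table) {
  if (!"group" %in% names(table)) stop("table needs a 'group' column")
  tab <- table(table$group)
  if (length(tab) < 2L || any(tab == 0L)) {
    stop("both groups must be non-empty; got counts: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  invisible(NULL)
}

#' Community-level model of age on eccentricity with a controlled covariate
#'
#' Per community, regresses age on the community eccentricity plus a
#' competing imaging covariate (functional connectivity density or cortical
#' thickness) plus sex and head motion, and reports the eccentricity
#' partial coefficient — the unique contribution of eccentricity to age
#' beyond the covariate. Note the regression direction (age as response)
#' follows the covariate-control formulation used in this analysis family.
#'
#' @param table Subject table with `age`, `sex`, `head_motion`.
#' @param ecc_summary Subjects x communities eccentricity means
#'   ([community_means()]).
#' @param covariate Subjects x communities matrix of the competing
#'   covariate, aligned to the same communities.
#' @param method `"ols"` (default; matches the closed-form oracle used in
#'   the tests) or `"rlm"` for an M-estimator robust fit.
#' @return data.frame with one row per community: `community`, `beta`, `t`,
#'   `p`, `df` for the eccentricity term.
#' @export
covary_model <- function(table, ecc_summary, covariate,
                         method = c("ols", "rlm")) {
  method <- match.arg(method)
  stopifnot(is.matrix(ecc_summary), is.matrix(covariate),
            nrow(ecc_summary) == nrow(table))
  if (!all(dim(ecc_summary) == dim(covariate))) {
    stop("covariate is not aligned to the same communities (",
         paste(dim(covariate), collapse = "x"), " vs ",
         paste(dim(ecc_summary), collapse = "x"), ")")
  }
  K <- ncol(ecc_summary)
  out <- data.frame(community = seq_len(K), beta = NA_real_, t = NA_real_,
                    p = NA_real_, df = NA_real_)
  for (k in seq_len(K)) {
    d <- data.frame(age = table$age, ecc = ecc_summary[, k],
                    cov = covariate[, k], sex = table$sex,
                    head_motion = table$head_motion)
    f <- age ~ ecc + cov + sex + head_motion
    X <- build_design(d, ~ ecc + cov + sex + head_motion)
    if (method == "ols") {
      fit <- glm_tmaps(matrix(d$age, ncol = 1), X, which(colnames(X) == "ecc"))
      out$beta[k] <- fit$beta; out$t[k] <- fit$t
      out$p[k] <- fit$p; out$df[k] <- fit$df
    } else {
      rf <- MASS::rlm(f, data = d, maxit = 100)
      cf <- summary(rf)$coefficients
      out$beta[k] <- cf["ecc", "Value"]
      out$t[k] <- cf["ecc", "t value"]
      out$df[k] <- nrow(d) - ncol(X)
      out$p[k] <- 2 * stats::pt(-abs(out$t[k]), out$df[k])
    }
  }
  out
}

#' Percent effect-size reduction after covariate control
#'
#' Compares a base contrast map with the same contrast recomputed while
#' controlling for one extra covariate, per cluster of vertices. The effect
#' size is the cluster mean of `|t|` (default) or `|beta|`; reduction =
#' `100 * (1 - controlled / base)`. Negative reductions (effect grew) are
#' reported as-is; a zero base effect gives `NA`.
#'
#' @param base,controlled `stat_map`s for the same contrast and subjects;
#'   `controlled` from the model with the added covariate.
#' @param clusters Named list of vertex index vectors.
#' @param measure `"t"` or `"beta"`.
#' @return data.frame: `cluster`, `effect_base`, `effect_controlled`,
#'   `reduction_pct`.
#' @export
effect_size_reduction <- function(base, controlled, clusters,
                                  measure = c("t", "beta")) {
  measure <- match.arg(measure)
  stopifnot(inherits(base, "stat_map"), inherits(controlled, "stat_map"),
            nrow(base) == nrow(controlled), is.list(clusters))
  if (is.null(names(clusters))) {
    names(clusters) <- paste0("cluster", seq_along(clusters))
  }
  eb <- vapply(clusters, function(ix) mean(abs(base[[measure]][ix])),
               numeric(1))
  ec <- vapply(clusters, function(ix) mean(abs(controlled[[measure]][ix])),
               numeric(1))
  red <- ifelse(eb > 0, 100 * (1 - ec / eb), NA_real_)
  data.frame(cluster = names(clusters), effect_base = eb,
             effect_controlled = ec, reduction_pct = red,
             row.names = NULL)
}

#' Max-statistic permutation family-wise error correction
#'
#' Freedman-Lane permutation of reduced-model residuals: the model without
#' the contrast term is fitted, its residuals are permuted and added back
#' to the reduced fit, the full model is refitted, and the maximum `|t|`
#' over vertices forms the null distribution. `p_fwe` at each vertex is
#' `(1 + #\{max-null >= |t|\}) / (n_perm + 1)`, an exact FWE-controlling
#' p-value under exchangeability.
#'
#' @inheritParams fit_glm
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return A `stat_map` with `p_fwe` filled and the null maxima in
#'   attribute `"max_null"`.
#' @export
fwe_correct <- function(y, table, formula, contrast, n_perm = 999L,
                        seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  Y <- ecc_matrix(y)
  stopifnot(nrow(Y) == nrow(table))
  X <- build_design(table, formula)
  ccol <- contrast_column(X, formula, contrast)
  n <- nrow(X)
  obs <- glm_tmaps(Y, X, ccol)
  X0 <- X[, -ccol, drop = FALSE]
  H0 <- X0 %*% chol2inv(chol(crossprod(X0))) %*% t(X0)
  F0 <- H0 %*% Y
  R0 <- Y - F0
  XtXi <- chol2inv(chol(crossprod(X)))
  cvar <- XtXi[ccol, ccol]
  df <- n - ncol(X)
  max_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Yp <- F0 + R0[sample.int(n), , drop = FALSE]
      XtY <- crossprod(X, Yp)
      B <- XtXi %*% XtY
      rss <- pmax(colSums(Yp^2) - colSums(B * XtY), 0)
      se <- sqrt(rss / df * cvar)
      max(abs(ifelse(se > 0, B[ccol, ] / se, 0)))
    }, numeric(1))
  })
  out <- stat_map(obs, contrast, formula, n)
  out$p_fwe <- vapply(abs(out$t), function(tv) {
    (1 + sum(max_null >= tv)) / (n_perm + 1)
  }, numeric(1))
  attr(out, "max_null") <- max_null
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Benjamini-Hochberg false discovery rate q-values
#'
#' Step-up BH q-values, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Correlation between two community-level t-maps
#'
#' Pearson correlation over communities with a two-sided p on n - 2
#' degrees of freedom; used to relate typical age effects to
#' disease-by-age alterations across networks.
#'
#' @param tmap_a,tmap_b Numeric vectors of per-community t-values (same
#'   length, >= 3, non-constant).
#' @return List with `r`, `p`, `df`.
#' @export
cross_community_correlation <- function(tmap_a, tmap_b) {
  if (length(tmap_a) != length(tmap_b)) stop("t-maps differ in length")
  n <- length(tmap_a)
  if (n < 3L) stop("need at least 3 communities")
  if (stats::sd(tmap_a) == 0 || stats::sd(tmap_b) == 0) {
    stop("constant t-map: correlation undefined (zero variance)")
  }
  ct <- stats::cor.test(tmap_a, tmap_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, df = n - 2L)
}

#' Clinical / cognitive correlation map
#'
#' Vertex-wise partial regression of eccentricity on a clinical or
#' cognitive variable, covarying age and sex. Subjects missing the variable
#' are dropped listwise and counted (attribute `"n_dropped"`). The
#' seizure-free-duration convention of log-normalizing positive durations
#' is supported via `log_transform`.
#'
#' @inheritParams interaction_map
#' @param variable Column name in `table`.
#' @param log_transform Take the natural log of the variable first
#'   (requires strictly positive values).
#' @param covariates Covariate columns (default age and sex).
#' @return A `stat_map` for the variable's coefficient, with attributes
#'   `n_used` and `n_dropped`.
#' @export
clinical_correlation <- function(ecc, table, variable,
                                 log_transform = FALSE,
                                 covariates = c("age", "sex")) {
  if (!variable %in% names(table)) {
    stop("variable '", variable, "' not found in the subject table")
  }
  Y <- ecc_matrix(ecc)
  stopifnot(nrow(Y) == nrow(table))
  v <- table[[variable]]
  keep <- !is.na(v)
  n_dropped <- sum(!keep)
  v <- v[keep]
  if (log_transform) {
    if (any(v <= 0)) {
      stop("log transform requested but '", variable,
           "' is non-positive for subjects: ",
           paste(table$subject_id[keep][v <= 0], collapse = ", "))
    }
    v <- log(v)
  }
  tab <- table[keep, , drop = FALSE]
  tab$clinvar <- v
  f <- stats::reformulate(c("clinvar", covariates))
  out <- fit_glm(Y[keep, , drop = FALSE], tab, f, "clinvar")
  attr(out, "variable") <- variable
  attr(out, "n_used") <- sum(keep)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Per-group mean, SD, and size.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
pooled_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2 for the t-test")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Demographic comparison table
#'
#' Group comparisons in the style of a cohort demographics table: Pearson
#' chi-square without continuity correction for categorical rows (sex) and
#' pooled-variance two-sample t-tests for continuous rows (age, head
#' motion), with two-sided p-values.
#'
#' @param table Subject table with `group`, `sex`, `age`, `head_motion`.
#' @param continuous Continuous columns to compare (default age and head
#'   motion).
#' @return data.frame: `variable`, `test`, `statistic`, `p`,
#'   `patient_summary`, `control_summary`.
#' @export
demographics_tests <- function(table,
                               continuous = c("age", "head_motion")) {
  check_two_groups(table)
  g <- factor(table$group)
  counts <- table(table$sex, g)
  if (any(dim(counts) < 2L)) stop("sex by group table is degenerate")
  # Pearson chi-square without continuity correction; the small-count
  # approximation warning is expected on small synthetic cohorts
  cs <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  fmt_counts <- function(col) paste(counts[, col], collapse = "/")
  rows <- list(data.frame(
    variable = "sex", test = "chisq",
    statistic = unname(cs$statistic), p = cs$p.value,
    patient_summary = fmt_counts("patient"),
    control_summary = fmt_counts("control")))
  for (v in continuous) {
    x <- table[[v]]
    ns <- tapply(x, g, function(z) sum(!is.na(z)))
    if (any(ns < 2)) {
      stop("group with n < 2 for continuous variable '", v, "'")
    }
    tt <- stats::t.test(x ~ g, var.equal = TRUE)
    fmt <- function(lv) sprintf("%.2f ± %.2f",
                                mean(x[g == lv], na.rm = TRUE),
                                stats::sd(x[g == lv], na.rm = TRUE))
    rows <- c(rows, list(data.frame(
      variable = v, test = "t", statistic = unname(tt$statistic),
      p = tt$p.value, patient_summary = fmt("patient"),
      control_summary = fmt("control"))))
  }
  do.call(rbind, rows)
}

#' Bootstrap stability of the interaction map across sample sizes
#'
#' For each requested size, repeatedly subsamples subjects without
#' replacement (preserving the group ratio), recomputes the disease-by-age
#' interaction map, and correlates its t-map with the full-sample map.
#'
#' @inheritParams interaction_map
#' @param sample_sizes Integer vector of subsample sizes.
#' @param n_boot Resamples per size.
#' @param seed Integer seed.
#' @return data.frame: `size`, `mean_r`, `sd_r`, `n_boot`.
#' @export
bootstrap_stability <- function(ecc, table, sample_sizes, n_boot = 100L,
                                seed = 1L,
                                covariates = c("sex", "head_motion")) {
  Y <- ecc_matrix(ecc)
  full <- interaction_map(Y, table, covariates)$t
  n <- nrow(table)
  idx_pat <- which(table$group == "patient")
  idx_con <- which(table$group == "control")
  min_n <- ncol(build_design(table,
                             stats::reformulate(c("group * age",
                                                  covariates)))) + 3L
  out <- data.frame(size = as.integer(sample_sizes), mean_r = NA_real_,
                    sd_r = NA_real_, n_boot = as.integer(n_boot))
  with_seed(seed, {
    for (i in seq_along(sample_sizes)) {
      sz <- sample_sizes[i]
      if (sz > n) stop("sample size ", sz, " exceeds available n = ", n)
      if (sz < min_n) {
        stop("sample size ", sz, " is below predictors + 2 (need >= ",
             min_n, ")")
      }
      n_pat <- max(2L, round(sz * length(idx_pat) / n))
      n_con <- max(2L, sz - n_pat)
      rs <- vapply(seq_len(n_boot), function(b) {
        take <- c(sample(idx_pat, min(n_pat, length(idx_pat))),
                  sample(idx_con, min(n_con, length(idx_con))))
        sub <- interaction_map(Y[take, , drop = FALSE],
                               table[take, , drop = FALSE], covariates)
        stats::cor(sub$t, full)
      }, numeric(1))
      out$mean_r[i] <- mean(rs)
      out$sd_r[i] <- stats::sd(rs)
    }
  })
  out
}
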
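# Gene set collections and Fisher-exact over-representation analysis.

#' Gene set collection
#'
#' Named gene sets over a common background universe; every set must be a
#' subset of the background.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param background Character vector: the gene universe.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)),
            all(nzchar(names(sets))), is.character(background))
  background <- unique(background)
  sets <- lapply(sets, unique)
  bad <- names(sets)[!vapply(sets, function(s) all(s %in% background),
                             logical(1))]
  if (length(bad)) {
    stop("sets contain genes outside the background: ",
         paste(bad, collapse = ", "))
  }
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets over",
      length(x$background), "background genes\n")
  invisible(x)
}

# Two-sided hypergeometric (Fisher exact) p for a 2x2 table: overlap `a`
# between a selected list of size n and a set of size K in a background of
# size N. Sums all tail probabilities not exceeding the observed one, with
# the same relative-error guard as stats::fisher.test.
hyper_p2 <- function(a, n, K, N) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  k <- lo:hi
  pr <- stats::dhyper(k, K, N - K, n)
  p_obs <- pr[k == a]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Fisher exact over-representation of a gene list in annotation sets
#'
#' Per set, forms the 2x2 table of list membership by set membership over
#' the background, computes the two-sided Fisher exact p (all
#' hypergeometric outcomes no more probable than the observed one), the
#' sample odds ratio (Haldane 0.5 correction when a cell is zero, flagged),
#' and BH q-values over the sets.
#'
#' @param selected Character vector of selected genes (non-empty, subset of
#'   the background).
#' @param sets A [gene_set_collection()].
#' @return data.frame: `set`, `set_size`, `overlap`, `odds_ratio`, `p`,
#'   `q`, `haldane`.
#' @export
fisher_enrichment <- function(selected, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  selected <- unique(selected)
  if (!length(selected)) stop("empty selected gene list")
  if (!all(selected %in% sets$background)) {
    stop("selected genes outside the background: ",
         paste(utils::head(setdiff(selected, sets$background), 5),
               collapse = ", "))
  }
  N <- length(sets$background)
  n <- length(selected)
  res <- lapply(names(sets$sets), function(nm) {
    s <- sets$sets[[nm]]
    K <- length(s)
    a <- length(intersect(selected, s))
    b <- n - a
    cc <- K - a
    d <- N - n - cc
    hald <- any(c(a, b, cc, d) == 0)
    or <- if (hald) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      (a * d) / (b * cc)
    }
    data.frame(set = nm, set_size = K, overlap = a, odds_ratio = or,
               p = hyper_p2(a, n, K, N), haldane = hald)
  })
  out <- do.call(rbind, res)
  out$q <- fdr_correct(out$p)
  out[, c("set", "set_size", "overlap", "odds_ratio", "p", "q", "haldane")]
}

#' Developmental enrichment over a region-by-period profile grid
#'
#' Applies [fisher_enrichment()] to every cell of a complete brain-region x
#' developmental-period grid of annotation sets (named `"region|period"`)
#' and corrects across all cells with BH.
#'
#' @param selected Character vector of selected genes.
#' @param profiles A [gene_set_collection()] whose set names are
#'   `"region|period"` and which forms a complete grid.
#' @return data.frame: `region`, `period`, `set_size`, `overlap`,
#'   `odds_ratio`, `p`, `q`.
#' @export
developmental_enrichment <- function(selected, profiles) {
  stopifnot(inherits(profiles, "gene_set_collection"))
  parts <- strsplit(names(profiles$sets), "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("profile set names must be 'region|period'")
  }
  region <- vapply(parts, `[`, "", 1L)
  period <- vapply(parts, `[`, "", 2L)
  regions <- unique(region)
  periods <- unique(period)
  want <- as.vector(outer(regions, periods, paste, sep = "|"))
  missing <- setdiff(want, names(profiles$sets))
  if (length(missing)) {
    stop("incomplete profile grid; missing cells: ",
         paste(missing, collapse = ", "))
  }
  fe <- fisher_enrichment(selected, profiles)
  fe$q <- fdr_correct(fe$p)  # BH across all grid cells
  out <- data.frame(region = region[match(fe$set, names(profiles$sets))],
                    period = period[match(fe$set, names(profiles$sets))],
                    set_size = fe$set_size, overlap = fe$overlap,
                    odds_ratio = fe$odds_ratio, p = fe$p, q = fe$q)
  out[order(match(out$region, regions), match(out$period, periods)), ,
      drop = FALSE]
}
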
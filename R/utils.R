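# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed that stays inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483647)
}

row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1L))
}

col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  m <- colMeans(x)
  sqrt(colSums((t(t(x) - m))^2) / (n - 1L))
}

# Connected components of an undirected graph given a logical/numeric
# adjacency matrix; returns an integer membership vector.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] != 0 & comp == 0L)
      if (length(nb)) {
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
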
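# Internal helpers: seeding, edge bookkeeping, dataset validation.

# Deterministically fold a master seed and an arbitrary number of integer
# tags into a child seed < 2^31. All randomness in the package flows through
# seeds derived this way; no function touches the global RNG without
# restoring it afterwards.
.mixSeed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) {
    h <- (h * 69069 + (abs(as.numeric(k)) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state on exit.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# A cheap, deterministic fingerprint of a numeric dataset, used so that
# resampling streams are tied to the dataset itself rather than to argument
# position (this is what makes diff(i,j) == -diff(j,i) exact).
.datasetSeed <- function(seed, d) {
  n <- nrow(d)
  p <- ncol(d)
  probe <- c(d[1L, 1L], d[n, p], sum(d[1L, ]) / p)
  folded <- floor(abs(probe) * 1e6) %% 1e6
  .mixSeed(seed, n, p, folded[1L], folded[2L], folded[3L])
}

# Kahn's algorithm; errors if the edge set is cyclic.
.topologicalOrder <- function(p, edges) {
  indeg <- integer(p)
  if (nrow(edges)) {
    tab <- tabulate(edges[, 2L], nbins = p)
    indeg <- tab
  }
  childrenOf <- vector("list", p)
  for (k in seq_len(nrow(edges))) {
    t <- edges[k, 1L]
    childrenOf[[t]] <- c(childrenOf[[t]], edges[k, 2L])
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in childrenOf[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != p) stop("graph is cyclic: no topological order exists")
  as.integer(ord)
}

.asEdgeMatrix <- function(edges, variables = NULL) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L)) {
    m <- matrix(integer(0), ncol = 2L)
  } else if (is.character(edges)) {
    stopifnot(!is.null(variables))
    m <- matrix(match(edges, variables), ncol = 2L)
    if (anyNA(m)) stop("edge refers to an unknown variable name")
  } else {
    m <- matrix(as.integer(edges), ncol = 2L)
  }
  colnames(m) <- c("tail", "head")
  m
}

# Row-wise "tail>head" keys for set operations on edge matrices.
.edgeKeys <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  paste(edges[, 1L], edges[, 2L], sep = ">")
}

# Validate a dataset (numeric matrix with unique column names, no NAs).
# Returns the matrix, coercing data.frames.
.checkDataset <- function(d, what = "dataset") {
  if (is.data.frame(d)) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) {
    stop(what, " must be a numeric matrix or data frame")
  }
  if (is.null(colnames(d)) || anyDuplicated(colnames(d))) {
    stop(what, " must have unique column (variable) names")
  }
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s contains a missing value at row %d, column '%s'",
                 what, bad[1L], colnames(d)[bad[2L]]))
  }
  if (nrow(d) < 1L) stop(what, " must contain at least one row")
  d
}

# All subsets of size k of an integer vector, as a list (k = 0 gives the
# empty set).
.subsetsOfSize <- function(x, k) {
  if (k == 0L) return(list(integer(0)))
  if (length(x) < k) return(list())
  if (length(x) == k) return(list(x))
  cols <- utils::combn(x, k)
  lapply(seq_len(ncol(cols)), function(j) cols[, j])
}
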
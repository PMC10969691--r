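# Score-based structure discovery: greedy hill climbing over DAGs with a
# Gaussian BIC score (penalty discount configurable), followed by
# conversion of the selected DAG to its CPDAG.

# Local Gaussian BIC of node y given a parent set, from the ML covariance
# matrix S of the (centred) data.
.localBic <- function(S, n, y, pa, penaltyDiscount) {
  if (length(pa) == 0L) {
    sigma2 <- S[y, y]
  } else {
    Spp <- S[pa, pa, drop = FALSE]
    Spy <- S[pa, y]
    sigma2 <- S[y, y] - drop(crossprod(Spy, solve(Spp, Spy)))
  }
  sigma2 <- max(sigma2, 1e-12)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  ll - 0.5 * penaltyDiscount * log(n) * (length(pa) + 1)
}

# TRUE if a directed path from `from` to `to` exists in the parent-list
# representation (children traversal).
.hasDirectedPath <- function(childrenOf, from, to) {
  stack <- childrenOf[[from]]
  seen <- logical(length(childrenOf))
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, childrenOf[[v]])
  }
  FALSE
}

# Greedy hill climbing: add / delete / reverse moves, best-first,
# deterministic tie-breaking by scan order. Returns the parent list of the
# selected DAG.
.hillClimb <- function(data, penaltyDiscount = 1) {
  n <- nrow(data)
  p <- ncol(data)
  X <- scale(data, center = TRUE, scale = FALSE)
  S <- crossprod(X) / n
  cache <- new.env(parent = emptyenv())
  score <- function(y, pa) {
    key <- paste0(y, "|", paste(sort(pa), collapse = ","))
    v <- cache[[key]]
    if (is.null(v)) {
      v <- .localBic(S, n, y, pa, penaltyDiscount)
      cache[[key]] <- v
    }
    v
  }
  parentsOf <- rep(list(integer(0)), p)
  childrenOf <- rep(list(integer(0)), p)
  current <- vapply(seq_len(p), function(y) score(y, parentsOf[[y]]), numeric(1))
  repeat {
    bestDelta <- 1e-10
    bestMove <- NULL
    for (x in seq_len(p)) {
      for (y in seq_len(p)) {
        if (x == y) next
        hasXY <- x %in% parentsOf[[y]]
        hasYX <- y %in% parentsOf[[x]]
        if (!hasXY && !hasYX) {
          # add x -> y (acyclic iff no directed path y ~> x)
          if (!.hasDirectedPath(childrenOf, y, x)) {
            delta <- score(y, c(parentsOf[[y]], x)) - current[y]
            if (delta > bestDelta) {
              bestDelta <- delta
              bestMove <- list(op = "add", x = x, y = y)
            }
          }
        } else if (hasXY) {
          delDelta <- score(y, setdiff(parentsOf[[y]], x)) - current[y]
          if (delDelta > bestDelta) {
            bestDelta <- delDelta
            bestMove <- list(op = "delete", x = x, y = y)
          }
          # reverse x -> y to y -> x: remove, then check y ~> ... ~> x? The
          # reversed arrow is y -> x, illegal iff another path x ~> y remains.
          childrenNoXY <- childrenOf
          childrenNoXY[[x]] <- setdiff(childrenNoXY[[x]], y)
          if (!.hasDirectedPath(childrenNoXY, x, y)) {
            revDelta <- delDelta +
              score(x, c(parentsOf[[x]], y)) - current[x]
            if (revDelta > bestDelta) {
              bestDelta <- revDelta
              bestMove <- list(op = "reverse", x = x, y = y)
            }
          }
        }
      }
    }
    if (is.null(bestMove)) break
    x <- bestMove$x; y <- bestMove$y
    if (bestMove$op == "add") {
      parentsOf[[y]] <- c(parentsOf[[y]], x)
      childrenOf[[x]] <- c(childrenOf[[x]], y)
    } else if (bestMove$op == "delete") {
      parentsOf[[y]] <- setdiff(parentsOf[[y]], x)
      childrenOf[[x]] <- setdiff(childrenOf[[x]], y)
    } else {
      parentsOf[[y]] <- setdiff(parentsOf[[y]], x)
      childrenOf[[x]] <- setdiff(childrenOf[[x]], y)
      parentsOf[[x]] <- c(parentsOf[[x]], y)
      childrenOf[[y]] <- c(childrenOf[[y]], x)
    }
    current[y] <- score(y, parentsOf[[y]])
    current[x] <- score(x, parentsOf[[x]])
  }
  parentsOf
}

#' Convert a DAG to its CPDAG
#'
#' Keeps the arrows of v-structures (two nonadjacent parents of a common
#' child) directed, leaves all other edges undirected, and closes under the
#' Meek orientation rules; the result represents the DAG's Markov
#' equivalence class.
#'
#' @param dag a [CausalDag-class].
#' @return An [EstimatedGraph-class].
#' @export
dagToCpdag <- function(dag) {
  stopifnot(is(dag, "CausalDag"))
  p <- length(dag@variables)
  edges <- dag@edges
  dir <- matrix(FALSE, p, p)
  if (nrow(edges)) dir[edges] <- TRUE
  adj <- dir | t(dir)
  amat <- matrix(0L, p, p)
  amat[adj] <- 1L
  for (k in seq_len(p)) {
    pa <- which(dir[, k])
    if (length(pa) < 2L) next
    for (a in seq_along(pa)) {
      for (b in seq_along(pa)) {
        if (a >= b) next
        i <- pa[a]; j <- pa[b]
        if (!adj[i, j]) {
          amat[k, i] <- 0L
          amat[k, j] <- 0L
        }
      }
    }
  }
  EstimatedGraph(dag@variables, .meekClosure(amat))
}

# Full score-based run on a dataset; returns the amat of the CPDAG of the
# selected DAG.
.gesSearch <- function(data, penaltyDiscount = 1) {
  parentsOf <- .hillClimb(data, penaltyDiscount)
  edges <- do.call(rbind, lapply(seq_along(parentsOf), function(y) {
    if (length(parentsOf[[y]])) cbind(parentsOf[[y]], y) else NULL
  }))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  dag <- CausalDag(colnames(data), edges)
  dagToCpdag(dag)@amat
}
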
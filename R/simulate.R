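# Paired-network simulator: random DAGs, linear-Gaussian parameterisation
# with unit marginal variances, controlled-difference network pairs, and
# dataset sampling.

# Draw edge coefficients beta = b * u with P(b = 1) = 0.6, P(b = -1) = 0.4
# and u ~ Uniform(0.1, 0.35). Caller owns the RNG state.
.drawCoefficients <- function(m) {
  u <- stats::runif(m, 0.1, 0.35)
  b <- ifelse(stats::runif(m) < 0.6, 1, -1)
  b * u
}

# Walk the DAG in topological order, setting each node's noise variance so
# its marginal variance is exactly 1, and propagating the implied
# covariance. Fails (ok = FALSE) when a node's pre-noise variance exceeds 1.
.noiseFromCoefficients <- function(dag, coefficients) {
  p <- length(dag@variables)
  edges <- dag@edges
  Sigma <- matrix(0, p, p)
  noiseVar <- numeric(p)
  for (v in dag@topoOrder) {
    rows <- which(edges[, 2L] == v)
    if (!length(rows)) {
      noiseVar[v] <- 1
      Sigma[v, v] <- 1
      next
    }
    pa <- edges[rows, 1L]
    beta <- coefficients[rows]
    preVar <- drop(crossprod(beta, Sigma[pa, pa, drop = FALSE] %*% beta))
    if (preVar > 1 + 1e-12) {
      return(list(ok = FALSE, badNode = dag@variables[v], preVar = preVar))
    }
    noiseVar[v] <- max(1 - preVar, 0)
    rowv <- drop(crossprod(beta, Sigma[pa, , drop = FALSE]))
    Sigma[v, ] <- rowv
    Sigma[, v] <- rowv
    Sigma[v, v] <- 1
  }
  list(ok = TRUE, noiseSd = sqrt(noiseVar))
}

#' Generate a random DAG with a fixed number of edges
#'
#' Draws a uniformly random topological order of the variables, then samples
#' the requested number of edges uniformly without replacement from the
#' order-respecting pairs, so the edge count is met exactly and acyclicity
#' holds by construction.
#'
#' @param nVars number of variables (named \code{V1}, \code{V2}, ...).
#' @param nEdges number of edges; at most \code{nVars * (nVars - 1) / 2}.
#' @param seed integer seed; the same seed reproduces the same DAG.
#' @return A [CausalDag-class].
#' @examples
#' randomDag(10, 15, seed = 1)
#' @export
randomDag <- function(nVars, nEdges, seed) {
  stopifnot(nVars >= 1, nEdges >= 0)
  maxEdges <- nVars * (nVars - 1) / 2
  if (nEdges > maxEdges) {
    stop(sprintf("nEdges = %d exceeds the maximum %d for a DAG on %d variables",
                 nEdges, maxEdges, nVars))
  }
  vars <- sprintf("V%d", seq_len(nVars))
  .withSeed(seed, {
    ord <- sample.int(nVars)
    if (nEdges == 0L) {
      edges <- matrix(integer(0), ncol = 2L)
    } else {
      idx <- which(upper.tri(matrix(NA, nVars, nVars)), arr.ind = TRUE)
      pick <- idx[sample.int(nrow(idx), nEdges), , drop = FALSE]
      edges <- cbind(ord[pick[, 1L]], ord[pick[, 2L]])
    }
    CausalDag(vars, edges, topoOrder = ord)
  })
}

#' Parameterise a DAG as a unit-marginal-variance linear-Gaussian SEM
#'
#' Each edge coefficient is drawn as the product of a Bernoulli sign
#' (P(+1) = 0.6) and a Uniform(0.1, 0.35) magnitude; noise standard
#' deviations are then set in topological order so every marginal variance
#' equals one. If some node's pre-noise variance exceeds one, the whole
#' coefficient draw is discarded and redrawn, up to \code{maxAttempts}
#' times. (Regenerating the DAG itself on failure is the job of
#' [simulateNetwork()].)
#'
#' @param dag a [CausalDag-class].
#' @param seed integer seed.
#' @param maxAttempts number of fresh coefficient draws before giving up.
#' @return A [LinearGaussianNetwork-class].
#' @export
parameterizeSem <- function(dag, seed, maxAttempts = 100) {
  lastBad <- NULL
  for (attempt in seq_len(maxAttempts)) {
    coef <- .withSeed(.mixSeed(seed, attempt),
                      .drawCoefficients(nrow(dag@edges)))
    res <- .noiseFromCoefficients(dag, coef)
    if (res$ok) return(LinearGaussianNetwork(dag, coef, res$noiseSd))
    lastBad <- res$badNode
  }
  stop(sprintf(paste0("could not reach unit marginal variances in %d attempts; ",
                      "last offending node: %s"), maxAttempts, lastBad))
}

#' Simulate a random linear-Gaussian network
#'
#' Generates a random DAG and parameterises it; when the unit-variance
#' constraint fails, a fresh DAG is generated and a new parameterisation is
#' attempted.
#'
#' @inheritParams randomDag
#' @param maxAttempts number of DAG + parameterisation attempts.
#' @return A [LinearGaussianNetwork-class].
#' @examples
#' net <- simulateNetwork(10, 15, seed = 1)
#' @export
simulateNetwork <- function(nVars, nEdges, seed, maxAttempts = 100) {
  lastBad <- NULL
  for (attempt in seq_len(maxAttempts)) {
    dag <- randomDag(nVars, nEdges, seed = .mixSeed(seed, attempt, 1))
    coef <- .withSeed(.mixSeed(seed, attempt, 2),
                      .drawCoefficients(nrow(dag@edges)))
    res <- .noiseFromCoefficients(dag, coef)
    if (res$ok) return(LinearGaussianNetwork(dag, coef, res$noiseSd))
    lastBad <- res$badNode
  }
  stop(sprintf(paste0("could not simulate a unit-variance network in %d ",
                      "attempts; last offending node: %s"), maxAttempts, lastBad))
}

#' Exact covariance matrix implied by a linear-Gaussian network
#'
#' Closed form \eqn{\Sigma = (I - B)^{-1} \Omega (I - B)^{-T}} where B holds
#' the edge coefficients and \eqn{\Omega} the noise variances. The diagonal
#' is 1 by construction of the simulator.
#'
#' @param net a [LinearGaussianNetwork-class].
#' @return A symmetric positive-definite matrix with variable dimnames.
#' @export
impliedCovariance <- function(net) {
  stopifnot(is(net, "LinearGaussianNetwork"))
  p <- length(net@dag@variables)
  S <- .impliedCov(p, net@dag@edges, net@coefficients, net@noiseSd^2)
  dimnames(S) <- list(net@dag@variables, net@dag@variables)
  S
}

#' Derive a second network differing from the first in a controlled edge set
#'
#' Deletes \code{ceiling(nDiff / 2)} edges chosen uniformly from g1 and adds
#' \code{floor(nDiff / 2)} edges chosen uniformly from the order-respecting
#' non-adjacent pairs (using g1's generation order, so g2 is acyclic by
#' construction). Added-edge coefficients follow the same sign-times-uniform
#' law; shared edges keep g1's coefficients bitwise; all noise standard
#' deviations of g2 are recomputed so its marginal variances are one. On
#' variance overflow the added-edge coefficients are resampled up to
#' \code{maxAttempts} times, then the addition set itself is regenerated.
#'
#' @param g1 a [LinearGaussianNetwork-class].
#' @param nDiff total number of differing edges (deleted + added).
#' @param seed integer seed.
#' @param maxAttempts retry budget for coefficient draws and addition sets.
#' @return A [NetworkPair-class] with the deleted/added sets recorded.
#' @examples
#' g1 <- simulateNetwork(10, 15, seed = 1)
#' pair <- derivePair(g1, 4, seed = 2)
#' deletedEdges(pair)
#' @export
derivePair <- function(g1, nDiff, seed, maxAttempts = 100) {
  stopifnot(is(g1, "LinearGaussianNetwork"), nDiff >= 1)
  dag1 <- g1@dag
  p <- length(dag1@variables)
  edges1 <- dag1@edges
  m <- nrow(edges1)
  nDel <- ceiling(nDiff / 2)
  nAdd <- nDiff - nDel
  if (nDel > m) stop("nDiff too large: not enough edges in g1 to delete")

  pos <- integer(p)
  pos[dag1@topoOrder] <- seq_len(p)
  idx <- which(upper.tri(matrix(NA, p, p)), arr.ind = TRUE)
  allPairs <- cbind(dag1@topoOrder[idx[, 1L]], dag1@topoOrder[idx[, 2L]])
  candidates <- allPairs[!(.edgeKeys(allPairs) %in% .edgeKeys(edges1)), ,
                         drop = FALSE]
  if (nAdd > nrow(candidates)) {
    stop("nDiff too large: not enough order-respecting non-edges to add")
  }

  delIdx <- .withSeed(.mixSeed(seed, 1), sample.int(m, nDel))
  deleted <- edges1[delIdx, , drop = FALSE]
  keptIdx <- setdiff(seq_len(m), delIdx)

  for (outer in seq_len(maxAttempts)) {
    added <- .withSeed(.mixSeed(seed, 2, outer), {
      candidates[sample.int(nrow(candidates), nAdd), , drop = FALSE]
    })
    edges2 <- rbind(edges1[keptIdx, , drop = FALSE], added)
    dag2 <- CausalDag(dag1@variables, edges2, topoOrder = dag1@topoOrder)
    for (inner in seq_len(maxAttempts)) {
      addedCoef <- .withSeed(.mixSeed(seed, 3, outer, inner),
                             .drawCoefficients(nAdd))
      coef2 <- c(g1@coefficients[keptIdx], addedCoef)
      res <- .noiseFromCoefficients(dag2, coef2)
      if (res$ok) {
        g2 <- LinearGaussianNetwork(dag2, coef2, res$noiseSd)
        return(new("NetworkPair", g1 = g1, g2 = g2,
                   deletedEdges = deleted, addedEdges = added,
                   metadata = list(seed = seed, nDiff = nDiff,
                                   nDeleted = nDel, nAdded = nAdd)))
      }
    }
  }
  stop("could not derive a unit-variance paired network: retry budget exhausted")
}

#' Sample i.i.d. rows from a linear-Gaussian network
#'
#' Evaluates the structural equations in topological order with independent
#' Gaussian noise.
#'
#' @param net a [LinearGaussianNetwork-class].
#' @param n number of rows (at least 1).
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @return An \code{n} x \code{nVars} numeric matrix with variable
#'   column names.
#' @examples
#' net <- simulateNetwork(5, 6, seed = 1)
#' d <- sampleData(net, 100, seed = 2)
#' @export
sampleData <- function(net, n, seed) {
  stopifnot(is(net, "LinearGaussianNetwork"))
  if (n < 1) stop("n must be at least 1")
  dag <- net@dag
  p <- length(dag@variables)
  edges <- dag@edges
  .withSeed(seed, {
    X <- matrix(0, n, p, dimnames = list(NULL, dag@variables))
    for (v in dag@topoOrder) {
      eps <- stats::rnorm(n, 0, net@noiseSd[v])
      rows <- which(edges[, 2L] == v)
      if (length(rows)) {
        pa <- edges[rows, 1L]
        X[, v] <- X[, pa, drop = FALSE] %*% net@coefficients[rows] + eps
      } else {
        X[, v] <- eps
      }
    }
    X
  })
}
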
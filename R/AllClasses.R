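#' @import methods
NULL

# Closed-form covariance of a linear-Gaussian SEM given as a coefficient
# matrix and noise variances; shared by the class validity check and the
# exported impliedCovariance().
.impliedCov <- function(p, edges, coefficients, noiseVar) {
  B <- matrix(0, p, p)
  if (nrow(edges)) B[cbind(edges[, 2L], edges[, 1L])] <- coefficients
  A <- solve(diag(p) - B)
  A %*% (noiseVar * t(A))
}

#' CausalDag: a directed acyclic graph over named variables
#'
#' Stores an ordered variable list, an edge set as an integer matrix of
#' (tail, head) index pairs, and a topological order. Acyclicity, absence of
#' self-loops and duplicate edges are enforced by the validity method.
#'
#' @slot variables character vector of variable names.
#' @slot edges integer matrix with columns \code{tail} and \code{head}.
#' @slot topoOrder integer permutation of \code{seq_along(variables)} such
#'   that every edge points from an earlier to a later position.
#' @export
setClass("CausalDag",
  slots = c(variables = "character", edges = "matrix", topoOrder = "integer"))

setValidity("CausalDag", function(object) {
  msg <- character(0)
  p <- length(object@variables)
  if (p < 1L) msg <- c(msg, "at least one variable is required")
  if (anyDuplicated(object@variables)) msg <- c(msg, "duplicate variable names")
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must be a two-column matrix")
  if (nrow(e)) {
    if (any(e < 1L | e > p)) msg <- c(msg, "edge index out of range")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (anyDuplicated(.edgeKeys(e))) msg <- c(msg, "duplicated edges")
  }
  if (length(object@topoOrder) != p ||
      anyDuplicated(object@topoOrder) ||
      any(sort(object@topoOrder) != seq_len(p))) {
    msg <- c(msg, "topoOrder must be a permutation of the variable indices")
  } else if (nrow(e)) {
    pos <- integer(p)
    pos[object@topoOrder] <- seq_len(p)
    if (any(pos[e[, 1L]] >= pos[e[, 2L]])) {
      msg <- c(msg, "edges must respect the topological order (acyclicity)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CausalDag
#'
#' @param variables character vector of variable names.
#' @param edges either an integer matrix of (tail, head) index pairs or a
#'   character matrix of variable names; may be empty.
#' @param topoOrder optional topological order; computed (and acyclicity
#'   thereby verified) when omitted.
#' @return A [CausalDag-class] object.
#' @examples
#' CausalDag(c("X", "Y"), rbind(c(1L, 2L)))
#' @export
CausalDag <- function(variables, edges = NULL, topoOrder = NULL) {
  edges <- .asEdgeMatrix(edges, variables)
  if (is.null(topoOrder)) topoOrder <- .topologicalOrder(length(variables), edges)
  new("CausalDag", variables = as.character(variables), edges = edges,
      topoOrder = as.integer(topoOrder))
}

#' LinearGaussianNetwork: a DAG parameterised as a linear-Gaussian SEM
#'
#' Each variable is a linear function of its parents plus independent
#' Gaussian noise; coefficients have magnitude in \[0.1, 0.35\] and noise
#' scales are chosen so that every marginal variance equals one (checked to
#' 1e-8 by the validity method). Parentless variables are standard normal.
#'
#' @slot dag the [CausalDag-class] structure.
#' @slot coefficients numeric vector, one per edge row of the DAG.
#' @slot noiseSd named numeric vector of noise standard deviations.
#' @export
setClass("LinearGaussianNetwork",
  slots = c(dag = "CausalDag", coefficients = "numeric", noiseSd = "numeric"))

setValidity("LinearGaussianNetwork", function(object) {
  msg <- character(0)
  dag <- object@dag
  p <- length(dag@variables)
  if (length(object@coefficients) != nrow(dag@edges)) {
    msg <- c(msg, "one coefficient per edge is required")
  }
  if (length(object@noiseSd) != p) {
    msg <- c(msg, "one noise standard deviation per variable is required")
  }
  if (length(msg)) return(msg)
  if (any(object@noiseSd < 0)) msg <- c(msg, "noise standard deviations must be nonnegative")
  a <- abs(object@coefficients)
  if (length(a) && (any(a < 0.1 - 1e-9) || any(a > 0.35 + 1e-9))) {
    msg <- c(msg, "coefficient magnitudes must lie in [0.1, 0.35]")
  }
  hasParent <- rep(FALSE, p)
  if (nrow(dag@edges)) hasParent[dag@edges[, 2L]] <- TRUE
  if (any(abs(object@noiseSd[!hasParent] - 1) > 1e-8)) {
    msg <- c(msg, "parentless variables must have unit noise standard deviation")
  }
  S <- .impliedCov(p, dag@edges, object@coefficients, object@noiseSd^2)
  if (any(abs(diag(S) - 1) > 1e-8)) {
    msg <- c(msg, "implied marginal variances must equal 1 (tolerance 1e-8)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LinearGaussianNetwork
#'
#' @param dag a [CausalDag-class].
#' @param coefficients numeric vector parallel to the DAG's edge rows.
#' @param noiseSd named or unnamed numeric vector of per-variable noise
#'   standard deviations (in variable order).
#' @return A [LinearGaussianNetwork-class] object.
#' @examples
#' dag <- CausalDag(c("X", "Y"), rbind(c(1L, 2L)))
#' LinearGaussianNetwork(dag, 0.3, c(1, sqrt(0.91)))
#' @export
LinearGaussianNetwork <- function(dag, coefficients, noiseSd) {
  noiseSd <- as.numeric(noiseSd)
  names(noiseSd) <- dag@variables
  new("LinearGaussianNetwork", dag = dag,
      coefficients = as.numeric(coefficients), noiseSd = noiseSd)
}

#' NetworkPair: two linear-Gaussian networks differing in a known edge set
#'
#' Holds the ground truth for simulation experiments: \code{g2} equals
#' \code{g1} with \code{deletedEdges} removed and \code{addedEdges} added;
#' shared edges carry bitwise-identical coefficients.
#'
#' @slot g1,g2 [LinearGaussianNetwork-class] objects over the same variables.
#' @slot deletedEdges integer edge matrix (present in g1, absent from g2).
#' @slot addedEdges integer edge matrix (absent from g1, present in g2).
#' @slot metadata list of provenance fields (seed, requested nDiff, split).
#' @export
setClass("NetworkPair",
  slots = c(g1 = "LinearGaussianNetwork", g2 = "LinearGaussianNetwork",
            deletedEdges = "matrix", addedEdges = "matrix", metadata = "list"))

setValidity("NetworkPair", function(object) {
  msg <- character(0)
  v1 <- object@g1@dag@variables
  v2 <- object@g2@dag@variables
  if (!identical(v1, v2)) msg <- c(msg, "g1 and g2 must share the variable list")
  k1 <- .edgeKeys(object@g1@dag@edges)
  k2 <- .edgeKeys(object@g2@dag@edges)
  kd <- .edgeKeys(object@deletedEdges)
  ka <- .edgeKeys(object@addedEdges)
  if (!all(kd %in% k1) || any(kd %in% k2)) {
    msg <- c(msg, "deletedEdges must be in g1 and not in g2")
  }
  if (!all(ka %in% k2) || any(ka %in% k1)) {
    msg <- c(msg, "addedEdges must be in g2 and not in g1")
  }
  if (!setequal(k2, union(setdiff(k1, kd), ka))) {
    msg <- c(msg, "edges(g2) must equal (edges(g1) minus deleted) plus added")
  }
  shared <- intersect(k1, k2)
  c1 <- object@g1@coefficients[match(shared, k1)]
  c2 <- object@g2@coefficients[match(shared, k2)]
  if (length(shared) && !identical(unname(c1), unname(c2))) {
    msg <- c(msg, "shared edges must carry identical coefficients")
  }
  if (length(msg)) msg else TRUE
})

#' EstimatedGraph: the (partially directed) output of structure discovery
#'
#' A CPDAG/pattern over the data's variables. The adjacency matrix uses the
#' coding \code{amat[i, j] == 1 && amat[j, i] == 0} for a directed edge
#' i -> j, both entries 1 for an undirected edge, both 0 for no edge. The
#' coding makes "directed both ways" unrepresentable.
#'
#' @slot variables character vector of variable names.
#' @slot amat integer adjacency matrix in the coding described above.
#' @export
setClass("EstimatedGraph",
  slots = c(variables = "character", amat = "matrix"))

setValidity("EstimatedGraph", function(object) {
  msg <- character(0)
  p <- length(object@variables)
  a <- object@amat
  if (nrow(a) != p || ncol(a) != p) msg <- c(msg, "amat must be p x p")
  else {
    if (!all(a %in% c(0L, 1L))) msg <- c(msg, "amat entries must be 0 or 1")
    if (any(diag(a) != 0L)) msg <- c(msg, "amat diagonal must be zero")
  }
  if (length(msg)) msg else TRUE
})

EstimatedGraph <- function(variables, amat) {
  storage.mode(amat) <- "integer"
  dimnames(amat) <- list(variables, variables)
  new("EstimatedGraph", variables = as.character(variables), amat = amat)
}

#' EdgeIndicatorMap: binary per-pair edge presence indicators
#'
#' @slot mode \code{"orientation"} (ordered pairs) or \code{"skeleton"}
#'   (unordered pairs; matrix kept symmetric).
#' @slot indicators integer 0/1 matrix with variable dimnames.
#' @export
setClass("EdgeIndicatorMap",
  slots = c(mode = "character", indicators = "matrix"))

#' EdgeScoreMap: per-pair edge frequencies in \[0, 1\]
#'
#' Produced by resampling (bootstrap or without-replacement subsampling);
#' every value is an integer multiple of 1/B.
#'
#' @slot mode \code{"orientation"} or \code{"skeleton"}.
#' @slot scores numeric matrix in \[0, 1\] with variable dimnames.
#' @slot B integer resample count.
#' @export
setClass("EdgeScoreMap",
  slots = c(mode = "character", scores = "matrix", B = "integer"))

setValidity("EdgeScoreMap", function(object) {
  s <- object@scores
  msg <- character(0)
  if (any(s < -1e-12 | s > 1 + 1e-12)) msg <- c(msg, "scores must lie in [0, 1]")
  if (object@mode == "skeleton" && !isSymmetric(unname(s))) {
    msg <- c(msg, "skeleton score matrices must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

EdgeScoreMap <- function(mode, scores, B) {
  new("EdgeScoreMap", mode = mode, scores = scores, B = as.integer(B))
}

#' DiffScoreMap: per-pair scores estimating membership in Ei - Ej
#'
#' @slot mode \code{"orientation"} or \code{"skeleton"}.
#' @slot method \code{"naive"}, \code{"bs"} or \code{"rsbs"}.
#' @slot scores numeric matrix in \[-1, 1\] (\{0, 1\} for naive).
#' @slot direction length-2 character tag naming the (i, j) order.
#' @export
setClass("DiffScoreMap",
  slots = c(mode = "character", method = "character", scores = "matrix",
            direction = "character"))

setValidity("DiffScoreMap", function(object) {
  s <- object@scores
  msg <- character(0)
  if (any(s < -1 - 1e-12 | s > 1 + 1e-12)) msg <- c(msg, "scores must lie in [-1, 1]")
  if (object@method == "naive" && !all(s %in% c(0, 1))) {
    msg <- c(msg, "naive scores must be 0 or 1")
  }
  if (length(object@direction) != 2L) msg <- c(msg, "direction must have length 2")
  if (length(msg)) msg else TRUE
})

DiffScoreMap <- function(mode, method, scores, direction = c("i", "j")) {
  new("DiffScoreMap", mode = mode, method = method, scores = scores,
      direction = as.character(direction))
}

#' DiffLabels: ground-truth edge-difference labels
#'
#' Positives are exactly the pairs present in network i but absent from
#' network j, over the ordered-pair universe (orientation) or unordered-pair
#' universe (skeleton).
#'
#' @slot mode \code{"orientation"} or \code{"skeleton"}.
#' @slot labels integer 0/1 matrix with variable dimnames.
#' @slot direction length-2 character tag naming the (i, j) order.
#' @export
setClass("DiffLabels",
  slots = c(mode = "character", labels = "matrix", direction = "character"))

DiffLabels <- function(mode, labels, direction = c("i", "j")) {
  storage.mode(labels) <- "integer"
  new("DiffLabels", mode = mode, labels = labels,
      direction = as.character(direction))
}
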
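# Accessor and show methods.

# Edges of a DAG as a data.frame of variable names.
.edgeFrame <- function(variables, edges, coefficients = NULL) {
  df <- data.frame(tail = variables[edges[, 1L]],
                   head = variables[edges[, 2L]],
                   stringsAsFactors = FALSE)
  if (!is.null(coefficients)) df$coefficient <- as.numeric(coefficients)
  df
}

#' @rdname accessors
#' @export
setMethod("variables", "CausalDag", function(object) object@variables)

#' @rdname accessors
#' @export
setMethod("variables", "LinearGaussianNetwork",
          function(object) object@dag@variables)

#' @rdname accessors
#' @export
setMethod("variables", "EstimatedGraph", function(object) object@variables)

#' @rdname accessors
#' @export
setMethod("variables", "NetworkPair", function(object) object@g1@dag@variables)

#' @rdname accessors
#' @export
setMethod("edgeTable", "CausalDag",
          function(object) .edgeFrame(object@variables, object@edges))

#' @rdname accessors
#' @export
setMethod("edgeTable", "LinearGaussianNetwork", function(object) {
  .edgeFrame(object@dag@variables, object@dag@edges, object@coefficients)
})

#' @rdname accessors
#' @export
setMethod("nEdges", "CausalDag", function(object) nrow(object@edges))

#' @rdname accessors
#' @export
setMethod("nEdges", "LinearGaussianNetwork",
          function(object) nrow(object@dag@edges))

#' @rdname accessors
#' @export
setMethod("noiseSd", "LinearGaussianNetwork", function(object) object@noiseSd)

#' @rdname accessors
#' @export
setMethod("dagOf", "LinearGaussianNetwork", function(object) object@dag)

#' @rdname accessors
#' @export
setMethod("graph1", "NetworkPair", function(object) object@g1)

#' @rdname accessors
#' @export
setMethod("graph2", "NetworkPair", function(object) object@g2)

#' @rdname accessors
#' @export
setMethod("deletedEdges", "NetworkPair", function(object) {
  .edgeFrame(object@g1@dag@variables, object@deletedEdges)
})

#' @rdname accessors
#' @export
setMethod("addedEdges", "NetworkPair", function(object) {
  .edgeFrame(object@g1@dag@variables, object@addedEdges)
})

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "EdgeScoreMap", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "DiffScoreMap", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "EdgeIndicatorMap", function(object) object@indicators)

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "DiffLabels", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("scoreMode", "EdgeScoreMap", function(object) object@mode)

#' @rdname accessors
#' @export
setMethod("scoreMode", "DiffScoreMap", function(object) object@mode)

#' @rdname accessors
#' @export
setMethod("scoreMode", "EdgeIndicatorMap", function(object) object@mode)

#' @rdname accessors
#' @export
setMethod("scoreMode", "DiffLabels", function(object) object@mode)

#' @rdname accessors
#' @export
setMethod("scoreMethod", "DiffScoreMap", function(object) object@method)

#' @rdname accessors
#' @export
setMethod("resampleCount", "EdgeScoreMap", function(object) object@B)

setMethod("show", "CausalDag", function(object) {
  cat(sprintf("CausalDag: %d variables, %d edges\n",
              length(object@variables), nrow(object@edges)))
})

setMethod("show", "LinearGaussianNetwork", function(object) {
  cat(sprintf("LinearGaussianNetwork: %d variables, %d edges (unit marginal variances)\n",
              length(object@dag@variables), nrow(object@dag@edges)))
})

setMethod("show", "NetworkPair", function(object) {
  cat(sprintf("NetworkPair: %d variables; g1 %d edges, g2 %d edges; %d deleted + %d added\n",
              length(object@g1@dag@variables), nrow(object@g1@dag@edges),
              nrow(object@g2@dag@edges), nrow(object@deletedEdges),
              nrow(object@addedEdges)))
})

setMethod("show", "EstimatedGraph", function(object) {
  a <- object@amat
  und <- sum(a == 1L & t(a) == 1L) / 2L
  dir <- sum(a == 1L & t(a) == 0L)
  cat(sprintf("EstimatedGraph: %d variables, %d directed + %d undirected edges\n",
              length(object@variables), dir, und))
})

setMethod("show", "EdgeScoreMap", function(object) {
  cat(sprintf("EdgeScoreMap (%s mode, B = %d): %d pairs with frequency > 0\n",
              object@mode, object@B, .countPositive(object@scores, object@mode)))
})

setMethod("show", "DiffScoreMap", function(object) {
  cat(sprintf("DiffScoreMap (%s, %s mode, direction %s - %s): %d pairs with score > 0\n",
              object@method, object@mode, object@direction[1L],
              object@direction[2L], .countPositive(object@scores, object@mode)))
})

setMethod("show", "DiffLabels", function(object) {
  cat(sprintf("DiffLabels (%s mode, direction %s - %s): %d positives\n",
              object@mode, object@direction[1L], object@direction[2L],
              .countPositive(object@labels, object@mode)))
})

.countPositive <- function(m, mode) {
  if (mode == "skeleton") sum(m[upper.tri(m)] > 0) else {
    sum(m[row(m) != col(m)] > 0)
  }
}
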
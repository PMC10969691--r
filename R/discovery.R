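# Uniform interface to the structure discovery backends and normalisation
# of their partially directed outputs into per-pair edge indicators.

#' Run causal structure discovery on a dataset
#'
#' Dispatches to one of the built-in backends and normalises the result to
#' an [EstimatedGraph-class] (a CPDAG/pattern). Both backends are
#' deterministic given the data and parameters.
#'
#' \describe{
#'   \item{\code{"pc"}}{PC-stable with Fisher-z partial-correlation tests;
#'     parameter \code{alpha} (default 0.05) and optional \code{maxCond}
#'     capping the conditioning-set size.}
#'   \item{\code{"ges"}}{score-based greedy search: BIC hill climbing over
#'     DAGs followed by CPDAG conversion; parameter
#'     \code{penaltyDiscount} (default 1) scales the BIC penalty.}
#' }
#'
#' @param data numeric matrix or data frame with at least two named columns.
#' @param algorithm \code{"pc"} or \code{"ges"}.
#' @param params named list of backend settings (see Details).
#' @return An [EstimatedGraph-class].
#' @examples
#' net <- simulateNetwork(5, 6, seed = 1)
#' g <- runDiscovery(sampleData(net, 500, seed = 2), "pc")
#' @export
runDiscovery <- function(data, algorithm = c("pc", "ges"), params = list()) {
  data <- .checkDataset(data)
  if (ncol(data) < 2L) stop("discovery requires at least two variables")
  algorithm <- match.arg(algorithm)
  amat <- if (algorithm == "pc") {
    alpha <- if (is.null(params$alpha)) 0.05 else params$alpha
    maxCond <- if (is.null(params$maxCond)) Inf else params$maxCond
    .pcSearch(data, alpha = alpha, maxCond = maxCond)
  } else {
    pd <- if (is.null(params$penaltyDiscount)) 1 else params$penaltyDiscount
    .gesSearch(data, penaltyDiscount = pd)
  }
  EstimatedGraph(colnames(data), amat)
}

#' Convert an estimated graph to per-pair edge indicators
#'
#' Skeleton mode sets the indicator of an unordered pair to 1 when any edge
#' (directed or undirected) joins the pair. Orientation mode sets the
#' indicator of the ordered pair (X, Y) to 1 for a directed edge X -> Y;
#' an undirected edge X - Y contributes 1 to both orderings under
#' \code{undirectedPolicy = "both"} (an undirected CPDAG edge rules out
#' neither direction) and 0 to both under \code{"none"}.
#'
#' @param g an [EstimatedGraph-class].
#' @param mode \code{"orientation"} or \code{"skeleton"}.
#' @param undirectedPolicy \code{"both"} (default) or \code{"none"}.
#' @return An [EdgeIndicatorMap-class].
#' @export
graphToIndicators <- function(g, mode = c("orientation", "skeleton"),
                              undirectedPolicy = c("both", "none")) {
  stopifnot(is(g, "EstimatedGraph"))
  mode <- match.arg(mode)
  undirectedPolicy <- match.arg(undirectedPolicy)
  a <- g@amat
  und <- a == 1L & t(a) == 1L
  dir <- a == 1L & t(a) == 0L
  ind <- if (mode == "skeleton") {
    (a | t(a)) * 1L
  } else if (undirectedPolicy == "both") {
    (dir | und) * 1L
  } else {
    dir * 1L
  }
  storage.mode(ind) <- "integer"
  dimnames(ind) <- list(g@variables, g@variables)
  new("EdgeIndicatorMap", mode = mode, indicators = ind)
}

#' Serialise an estimated graph as TSV
#'
#' One row per edge with a \code{state} column: \code{-->} for a directed
#' edge from \code{node1} to \code{node2}, \code{---} for an undirected
#' edge. A header comment records the variable list so isolated nodes
#' round-trip.
#'
#' @param g an [EstimatedGraph-class].
#' @param path output file path.
#' @export
writeEstimatedGraph <- function(g, path) {
  stopifnot(is(g, "EstimatedGraph"))
  a <- g@amat
  vars <- g@variables
  rows <- character(0)
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (a[i, j] == 1L && a[j, i] == 0L) {
        rows <- c(rows, paste(vars[i], vars[j], "-->", sep = "\t"))
      } else if (i < j && a[i, j] == 1L && a[j, i] == 1L) {
        rows <- c(rows, paste(vars[i], vars[j], "---", sep = "\t"))
      }
    }
  }
  writeLines(c(paste0("# variables: ", paste(vars, collapse = ",")),
               paste("node1", "node2", "state", sep = "\t"), rows), path)
  invisible(path)
}

#' Read an estimated graph written by [writeEstimatedGraph()]
#'
#' @param path file path.
#' @return An [EstimatedGraph-class].
#' @export
readEstimatedGraph <- function(path) {
  lines <- readLines(path)
  varLine <- grep("^# variables: ", lines, value = TRUE)
  if (!length(varLine)) stop("missing '# variables:' header in ", path)
  vars <- strsplit(sub("^# variables: ", "", varLine[1L]), ",")[[1L]]
  body <- lines[!grepl("^#", lines)]
  p <- length(vars)
  amat <- matrix(0L, p, p)
  if (length(body) > 1L) {
    tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(tab))) {
      i <- match(tab$node1[k], vars)
      j <- match(tab$node2[k], vars)
      if (is.na(i) || is.na(j)) stop("edge refers to unknown variable in ", path)
      if (tab$state[k] == "-->") {
        amat[i, j] <- 1L
      } else if (tab$state[k] == "---") {
        amat[i, j] <- 1L
        amat[j, i] <- 1L
      } else {
        stop("unknown edge state '", tab$state[k], "' in ", path)
      }
    }
  }
  EstimatedGraph(vars, amat)
}
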
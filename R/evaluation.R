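# Evaluation of edge-difference estimates as a binary classification
# problem: ground-truth labels, ranking/calibration metrics, F1-optimised
# threshold metrics, and effect sizes.

# Indicator matrix of a graph-like object for a given mode. Networks and
# DAGs are fully directed; estimated graphs obey the undirected policy.
.graphIndicator <- function(g, mode, undirectedPolicy = "both") {
  if (is(g, "LinearGaussianNetwork")) g <- g@dag
  if (is(g, "CausalDag")) {
    p <- length(g@variables)
    ind <- matrix(0L, p, p, dimnames = list(g@variables, g@variables))
    if (nrow(g@edges)) ind[g@edges] <- 1L
    if (mode == "skeleton") ind <- (ind | t(ind)) * 1L
    storage.mode(ind) <- "integer"
    return(ind)
  }
  if (is(g, "EstimatedGraph")) {
    return(graphToIndicators(g, mode, undirectedPolicy)@indicators)
  }
  stop("unsupported graph type: ", class(g)[1L])
}

# Flatten a per-pair matrix over the evaluation universe: all ordered pairs
# X != Y (orientation) or all unordered pairs (skeleton). The extraction
# order is fixed so labels and scores stay aligned.
.flattenPairs <- function(m, mode) {
  if (mode == "skeleton") m[upper.tri(m)] else m[row(m) != col(m)]
}

#' Ground-truth edge-difference labels for a pair of graphs
#'
#' Labels the ordered pair (X, Y) (orientation mode) or unordered pair
#' (skeleton mode) 1 exactly when the edge is present in \code{gI} and
#' absent from \code{gJ}, and 0 otherwise; this is the positive class of
#' the binary classification problem. Accepts
#' [LinearGaussianNetwork-class], [CausalDag-class] or
#' [EstimatedGraph-class] inputs (the latter for reference graphs learned
#' from full real datasets).
#'
#' @param gI,gJ the two graphs, over identical variable lists.
#' @param mode \code{"orientation"} or \code{"skeleton"}.
#' @param undirectedPolicy policy for undirected edges of estimated graphs
#'   in orientation mode, see [graphToIndicators()].
#' @param direction length-2 character tag naming the (i, j) order.
#' @return A [DiffLabels-class].
#' @export
trueEdgeDiff <- function(gI, gJ, mode = c("orientation", "skeleton"),
                         undirectedPolicy = c("both", "none"),
                         direction = c("i", "j")) {
  mode <- match.arg(mode)
  undirectedPolicy <- match.arg(undirectedPolicy)
  eI <- .graphIndicator(gI, mode, undirectedPolicy)
  eJ <- .graphIndicator(gJ, mode, undirectedPolicy)
  if (!identical(dimnames(eI), dimnames(eJ))) {
    stop("the two graphs must share identical variable lists")
  }
  DiffLabels(mode, (eI == 1L & eJ == 0L) * 1L, direction)
}

# Trapezoidal AUCROC from the ranking of scores (tie groups collapsed).
.aucroc <- function(y, s) {
  o <- order(s, decreasing = TRUE)
  ys <- y[o]
  ss <- s[o]
  idx <- cumsum(rle(ss)$lengths)
  tp <- c(0, cumsum(ys)[idx])
  fp <- c(0, cumsum(1 - ys)[idx])
  tpr <- tp / max(tp)
  fpr <- fp / max(fp)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Step-wise (interpolation-free) area under the precision-recall curve.
.aupr <- function(y, s) {
  o <- order(s, decreasing = TRUE)
  ys <- y[o]
  ss <- s[o]
  idx <- cumsum(rle(ss)$lengths)
  tp <- cumsum(ys)[idx]
  prec <- tp / idx
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

# Mean binary cross-entropy after mapping a diff score in \[-1, 1\] to a
# predicted probability. "clip": p = clip(max(s, 0), eps, 1 - eps) --
# negative scores count as evidence against membership. "shift":
# p = clip((s + 1) / 2, eps, 1 - eps).
.crossEntropy <- function(y, s, mapping = "clip", eps = 1e-6) {
  p <- if (mapping == "clip") pmax(s, 0) else (s + 1) / 2
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Classification metrics for an edge-difference score map
#'
#' Treats the ground-truth labels as a binary classification problem over
#' the pair universe. Reports AUCROC (trapezoidal rule over the score
#' ranking), AUPR (step-wise summation), cross-entropy (score-to-
#' probability mapping as described below), and the confusion metrics at
#' the F1-optimal threshold (scanned over score midpoints; ties broken
#' toward the higher threshold, i.e. fewer predicted positives).
#'
#' Cross-entropy needs probabilities while diff scores live in \[-1, 1\]:
#' the default \code{ceMapping = "clip"} treats negative scores as evidence
#' against membership in Ei - Ej and maps s to clip(max(s, 0), eps, 1-eps);
#' \code{"shift"} maps s to (s + 1) / 2 instead.
#'
#' With no positives or no negatives the ranking metrics are reported as
#' \code{NA} (not 0) and \code{degenerate} is set. Zero-denominator
#' PPV/NPV/F1 are reported as 0 with \code{zeroDenominator} set.
#'
#' @param labels a [DiffLabels-class].
#' @param scores a [DiffScoreMap-class] on the same variables and mode.
#' @param ceMapping \code{"clip"} (default) or \code{"shift"}.
#' @param eps clipping constant for the probability mapping.
#' @return A one-row \code{data.frame}: method, direction, mode, aucroc,
#'   aupr, crossEntropy, ceMapping, threshold, sensitivity, specificity,
#'   ppv, npv, f1, accuracy, nPos, nNeg, degenerate, zeroDenominator.
#' @export
classificationMetrics <- function(labels, scores,
                                  ceMapping = c("clip", "shift"),
                                  eps = 1e-6) {
  stopifnot(is(labels, "DiffLabels"), is(scores, "DiffScoreMap"))
  ceMapping <- match.arg(ceMapping)
  if (!identical(labels@mode, scores@mode)) {
    stop("labels and scores must use the same mode")
  }
  if (!identical(dimnames(labels@labels), dimnames(scores@scores))) {
    stop("labels and scores must be defined on the same variables")
  }
  y <- .flattenPairs(labels@labels, labels@mode)
  s <- .flattenPairs(scores@scores, scores@mode)
  nPos <- sum(y == 1L)
  nNeg <- sum(y == 0L)
  degenerate <- nPos == 0L || nNeg == 0L

  aucroc <- if (degenerate) NA_real_ else .aucroc(y, s)
  aupr <- if (degenerate) NA_real_ else .aupr(y, s)
  ce <- .crossEntropy(y, s, ceMapping, eps)

  # F1-optimal threshold over score midpoints (predict positive when
  # score > threshold); extreme candidates cover all-positive and
  # all-negative rules.
  u <- sort(unique(s))
  cand <- c(u[1L] - 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
            u[length(u)])
  f1At <- function(t) {
    pred <- s > t
    tp <- sum(pred & y == 1L)
    den <- 2 * tp + sum(pred & y == 0L) + sum(!pred & y == 1L)
    if (den == 0) 0 else 2 * tp / den
  }
  f1s <- vapply(cand, f1At, numeric(1))
  threshold <- cand[max(which(f1s == max(f1s)))]
  pred <- s > threshold
  tp <- sum(pred & y == 1L)
  fp <- sum(pred & y == 0L)
  fn <- sum(!pred & y == 1L)
  tn <- sum(!pred & y == 0L)
  safe <- function(num, den) if (den == 0) 0 else num / den
  zeroDen <- (tp + fp) == 0L || (tn + fn) == 0L
  data.frame(
    method = scores@method,
    direction = paste(scores@direction, collapse = "-"),
    mode = scores@mode,
    aucroc = aucroc,
    aupr = aupr,
    crossEntropy = ce,
    ceMapping = ceMapping,
    threshold = threshold,
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    f1 = max(f1s),
    accuracy = (tp + tn) / length(y),
    nPos = nPos,
    nNeg = nNeg,
    degenerate = degenerate,
    zeroDenominator = zeroDen,
    stringsAsFactors = FALSE
  )
}

# Population R^2 of the regression of y on the variable set S, from the
# implied covariance (unit marginal variances).
.popR2 <- function(Sigma, y, S) {
  if (length(S) == 0L) return(0)
  Sss <- Sigma[S, S, drop = FALSE]
  Ssy <- Sigma[S, y]
  drop(crossprod(Ssy, solve(Sss, Ssy))) / Sigma[y, y]
}

#' Effect size (Cohen's f-squared) of an edge in a linear-Gaussian network
#'
#' For the edge X -> Y, \eqn{f^2 = (R^2(Pa(Y)) - R^2(Pa(Y) \setminus X)) /
#' (1 - R^2(Pa(Y)))}, the additional information in X about Y given Y's
#' other parents. The R-squared terms are population values computed in
#' closed form from [impliedCovariance()], since the generating network is
#' known in simulation.
#'
#' @param net a [LinearGaussianNetwork-class].
#' @param tail,head variable names of the edge (which must be present).
#' @return A nonnegative scalar.
#' @examples
#' dag <- CausalDag(c("X", "Y"), rbind(c(1L, 2L)))
#' net <- LinearGaussianNetwork(dag, 0.3, c(1, sqrt(0.91)))
#' effectSize(net, "X", "Y")  # 0.09 / 0.91
#' @export
effectSize <- function(net, tail, head) {
  stopifnot(is(net, "LinearGaussianNetwork"))
  vars <- net@dag@variables
  ti <- match(tail, vars)
  hi <- match(head, vars)
  if (is.na(ti) || is.na(hi)) stop("unknown variable name")
  edges <- net@dag@edges
  onEdge <- edges[, 1L] == ti & edges[, 2L] == hi
  if (!any(onEdge)) stop(sprintf("edge %s -> %s is not in the network", tail, head))
  Sigma <- impliedCovariance(net)
  pa <- edges[edges[, 2L] == hi, 1L]
  r2Full <- .popR2(Sigma, hi, pa)
  r2Minus <- .popR2(Sigma, hi, setdiff(pa, ti))
  max((r2Full - r2Minus) / (1 - r2Full), 0)
}

#' Effect sizes of every edge in a network
#'
#' @param net a [LinearGaussianNetwork-class].
#' @return A \code{data.frame} with columns tail, head, f2.
#' @export
effectSizeTable <- function(net) {
  stopifnot(is(net, "LinearGaussianNetwork"))
  df <- edgeTable(net)
  df$f2 <- vapply(seq_len(nrow(df)),
                  function(k) effectSize(net, df$tail[k], df$head[k]),
                  numeric(1))
  df$coefficient <- NULL
  df
}

#' Correlate edge effect sizes with edge-difference scores
#'
#' Rank (Spearman) correlation between the effect sizes of a set of edges
#' (typically the true-different edges of a simulated pair) and the scores
#' a resampling estimator assigned to them, plus the paired values for
#' plotting.
#'
#' @param table \code{data.frame} with columns tail, head, f2 (e.g. from
#'   [effectSizeTable()] restricted to the deleted edges).
#' @param scores a [DiffScoreMap-class].
#' @return A list with elements \code{correlation} (NA when fewer than 3
#'   edges are supplied or the scores are constant, with \code{flag}
#'   saying why), \code{method} ("spearman"), and \code{pairs} (the paired
#'   f2/score values).
#' @export
correlateEffectSizeScores <- function(table, scores) {
  stopifnot(is(scores, "DiffScoreMap"),
            all(c("tail", "head", "f2") %in% names(table)))
  m <- scores@scores
  vars <- rownames(m)
  ti <- match(table$tail, vars)
  hi <- match(table$head, vars)
  if (anyNA(ti) || anyNA(hi)) stop("edge refers to a variable absent from the score map")
  sc <- if (scores@mode == "skeleton") {
    m[cbind(pmin(ti, hi), pmax(ti, hi))]
  } else {
    m[cbind(ti, hi)]
  }
  pairs <- data.frame(tail = table$tail, head = table$head,
                      f2 = table$f2, score = sc, stringsAsFactors = FALSE)
  if (nrow(pairs) < 3L) {
    return(list(correlation = NA_real_, method = "spearman",
                flag = "fewer than 3 edges", pairs = pairs))
  }
  if (stats::sd(pairs$score) == 0 || stats::sd(pairs$f2) == 0) {
    return(list(correlation = NA_real_, method = "spearman",
                flag = "zero variance", pairs = pairs))
  }
  list(correlation = stats::cor(pairs$f2, pairs$score, method = "spearman"),
       method = "spearman", flag = NA_character_, pairs = pairs)
}
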
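# The three estimators of the structural difference Ei - Ej between two
# networks given two datasets: naive, bootstrap, and equal-sample-size
# resampling (RSBS).

# Check that two datasets share a variable set and return dJ with columns
# reordered to match dI.
.alignDatasets <- function(dI, dJ) {
  if (!setequal(colnames(dI), colnames(dJ))) {
    stop("the two datasets must share the same variable set")
  }
  dJ[, colnames(dI), drop = FALSE]
}

# Run discovery on B resamples of `data` (indices produced by indexFun(b))
# and accumulate per-pair indicator counts for both evaluation modes from
# the same runs. Counts are kept integral so frequencies are exact
# multiples of 1/B.
.resampleFrequencies <- function(data, B, indexFun, algorithm, params,
                                 undirectedPolicy) {
  p <- ncol(data)
  vars <- colnames(data)
  countO <- matrix(0L, p, p)
  countS <- matrix(0L, p, p)
  for (b in seq_len(B)) {
    idx <- indexFun(b)
    g <- runDiscovery(data[idx, , drop = FALSE], algorithm, params)
    countO <- countO + graphToIndicators(g, "orientation", undirectedPolicy)@indicators
    countS <- countS + graphToIndicators(g, "skeleton")@indicators
  }
  dimnames(countO) <- dimnames(countS) <- list(vars, vars)
  list(orientation = EdgeScoreMap("orientation", countO / B, B),
       skeleton = EdgeScoreMap("skeleton", countS / B, B))
}

# Bootstrap resampling streams are derived from the seed plus the dataset
# fingerprint, so the same dataset gets the same frequencies regardless of
# argument position.
.bootstrapBoth <- function(d, algorithm, params, B, seed, undirectedPolicy) {
  d <- .checkDataset(d)
  n <- nrow(d)
  base <- .datasetSeed(seed, d)
  .resampleFrequencies(d, B, function(b) {
    .withSeed(.mixSeed(base, 101, b), sample.int(n, n, replace = TRUE))
  }, algorithm, params, undirectedPolicy)
}

.subsampleBoth <- function(dLarge, nTarget, algorithm, params, B, seed,
                           undirectedPolicy) {
  dLarge <- .checkDataset(dLarge)
  n <- nrow(dLarge)
  if (nTarget >= n) {
    stop("nTarget must be smaller than the dataset's sample size ",
         "(use the bootstrap for equal sizes)")
  }
  base <- .datasetSeed(seed, dLarge)
  .resampleFrequencies(dLarge, B, function(b) {
    .withSeed(.mixSeed(base, 202, b), sample.int(n, nTarget, replace = FALSE))
  }, algorithm, params, undirectedPolicy)
}

#' Bootstrap edge frequencies for one dataset
#'
#' Runs the discovery backend on \code{B} with-replacement resamples of the
#' data and returns, per pair of variables, the fraction of resamples in
#' which the corresponding edge was reported (a confidence proxy for the
#' edge). All values are integer multiples of 1/B.
#'
#' @param d dataset (numeric matrix or data frame with named columns).
#' @param algorithm,params discovery backend, see [runDiscovery()].
#' @param B number of bootstrap resamples (default 50).
#' @param mode \code{"skeleton"} or \code{"orientation"}.
#' @param seed integer seed; the resample stream also depends on the
#'   dataset itself, so the same data yield the same frequencies wherever
#'   they appear in a comparison.
#' @param undirectedPolicy how undirected CPDAG edges enter orientation
#'   indicators, see [graphToIndicators()].
#' @return An [EdgeScoreMap-class].
#' @export
bootstrapEdgeFrequencies <- function(d, algorithm = c("pc", "ges"),
                                     params = list(), B = 50,
                                     mode = c("skeleton", "orientation"),
                                     seed = 1,
                                     undirectedPolicy = c("both", "none")) {
  stopifnot(B >= 1)
  mode <- match.arg(mode)
  .bootstrapBoth(d, match.arg(algorithm), params, B, seed,
                 match.arg(undirectedPolicy))[[mode]]
}

#' Equal-sample-size subsample frequencies for one dataset
#'
#' Runs the discovery backend on \code{B} without-replacement subsamples of
#' exactly \code{nTarget} rows each (typically the smaller dataset's sample
#' size) and returns the per-pair discovery frequency.
#'
#' @inheritParams bootstrapEdgeFrequencies
#' @param dLarge the larger dataset.
#' @param nTarget subsample size, strictly smaller than \code{nrow(dLarge)}.
#' @return An [EdgeScoreMap-class].
#' @export
subsampleFrequencies <- function(dLarge, nTarget, algorithm = c("pc", "ges"),
                                 params = list(), B = 50,
                                 mode = c("skeleton", "orientation"),
                                 seed = 1,
                                 undirectedPolicy = c("both", "none")) {
  stopifnot(B >= 1)
  mode <- match.arg(mode)
  .subsampleBoth(dLarge, nTarget, match.arg(algorithm), params, B, seed,
                 match.arg(undirectedPolicy))[[mode]]
}

#' Difference of two edge-frequency maps
#'
#' Per-pair difference \code{scoreMatrix(fI) - scoreMatrix(fJ)}; the larger
#' the value for a pair, the more likely the edge is present in network i
#' but not network j. This is the scoring step shared by the bootstrap and
#' equal-sample-size resampling estimators.
#'
#' @param fI,fJ [EdgeScoreMap-class] objects with matching mode and
#'   variables.
#' @param method label stored on the result (\code{"bs"} or \code{"rsbs"}).
#' @param direction length-2 character tag naming the (i, j) order.
#' @return A [DiffScoreMap-class] with values in \[-1, 1\].
#' @export
edgeScoreDiff <- function(fI, fJ, method = c("bs", "rsbs"),
                          direction = c("i", "j")) {
  stopifnot(is(fI, "EdgeScoreMap"), is(fJ, "EdgeScoreMap"))
  method <- match.arg(method)
  if (!identical(fI@mode, fJ@mode)) stop("score map modes differ")
  if (!identical(dimnames(fI@scores), dimnames(fJ@scores))) {
    stop("score maps are defined over different variables")
  }
  DiffScoreMap(fI@mode, method, fI@scores - fJ@scores, direction)
}

#' Naive edge-difference estimator
#'
#' Applies the discovery backend once to each dataset and scores a pair 1
#' exactly when the edge indicator from \code{dI} is 1 and from \code{dJ}
#' is 0 (and 0 otherwise, including the reversed case).
#'
#' @inheritParams bootstrapEdgeFrequencies
#' @param dI,dJ the two datasets (shared variable set).
#' @param direction length-2 character tag naming the (i, j) order.
#' @return A [DiffScoreMap-class] with values in \{0, 1\}.
#' @export
naiveDiff <- function(dI, dJ, algorithm = c("pc", "ges"), params = list(),
                      mode = c("skeleton", "orientation"),
                      undirectedPolicy = c("both", "none"),
                      direction = c("i", "j")) {
  dI <- .checkDataset(dI, "dI")
  dJ <- .alignDatasets(dI, .checkDataset(dJ, "dJ"))
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  undirectedPolicy <- match.arg(undirectedPolicy)
  eI <- graphToIndicators(runDiscovery(dI, algorithm, params), mode,
                          undirectedPolicy)@indicators
  eJ <- graphToIndicators(runDiscovery(dJ, algorithm, params), mode,
                          undirectedPolicy)@indicators
  DiffScoreMap(mode, "naive", (eI == 1L & eJ == 0L) * 1, direction)
}

#' Bootstrap edge-difference estimator
#'
#' Computes bootstrap edge frequencies for each dataset separately and
#' takes the per-pair difference in (i, j) order. Because the resample
#' streams are tied to each dataset, swapping the argument order negates
#' every score exactly.
#'
#' @inheritParams naiveDiff
#' @param B number of bootstrap resamples per dataset (default 50).
#' @param seed integer seed.
#' @return A [DiffScoreMap-class] with values in \[-1, 1\].
#' @export
bootstrapDiff <- function(dI, dJ, algorithm = c("pc", "ges"), params = list(),
                          B = 50, mode = c("skeleton", "orientation"),
                          seed = 1, undirectedPolicy = c("both", "none"),
                          direction = c("i", "j")) {
  dI <- .checkDataset(dI, "dI")
  dJ <- .alignDatasets(dI, .checkDataset(dJ, "dJ"))
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  undirectedPolicy <- match.arg(undirectedPolicy)
  fI <- .bootstrapBoth(dI, algorithm, params, B, seed, undirectedPolicy)[[mode]]
  fJ <- .bootstrapBoth(dJ, algorithm, params, B, seed, undirectedPolicy)[[mode]]
  edgeScoreDiff(fI, fJ, "bs", direction)
}

#' Equal-sample-size resampling (RSBS) edge-difference estimator
#'
#' The dataset with the larger sample size is scored by without-replacement
#' subsamples at the smaller dataset's size (equalising statistical power);
#' the smaller dataset is scored by the bootstrap; the difference is taken
#' in (i, j) order. Errors when the sample sizes are equal, where the
#' method is not applicable.
#'
#' @inheritParams bootstrapDiff
#' @return A [DiffScoreMap-class] with values in \[-1, 1\].
#' @export
rsbsDiff <- function(dI, dJ, algorithm = c("pc", "ges"), params = list(),
                     B = 50, mode = c("skeleton", "orientation"), seed = 1,
                     undirectedPolicy = c("both", "none"),
                     direction = c("i", "j")) {
  dI <- .checkDataset(dI, "dI")
  dJ <- .alignDatasets(dI, .checkDataset(dJ, "dJ"))
  if (nrow(dI) == nrow(dJ)) {
    stop("equal sample size resampling is not applicable when the two ",
         "datasets have equal sample sizes (N1 = N2)")
  }
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  undirectedPolicy <- match.arg(undirectedPolicy)
  nSmall <- min(nrow(dI), nrow(dJ))
  freqFor <- function(d) {
    if (nrow(d) > nSmall) {
      .subsampleBoth(d, nSmall, algorithm, params, B, seed,
                     undirectedPolicy)[[mode]]
    } else {
      .bootstrapBoth(d, algorithm, params, B, seed, undirectedPolicy)[[mode]]
    }
  }
  edgeScoreDiff(freqFor(dI), freqFor(dJ), "rsbs", direction)
}
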
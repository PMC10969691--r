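# Real-data protocol: manufacture a ground-truth network pair from a
# single tabular dataset by variable permutation, then benchmark the
# estimators on subsamples.

#' Permute two variable sets to manufacture a dataset pair
#'
#' Randomly selects two disjoint variable sets of size \code{nPermute} and
#' returns two full-sample copies of the data, each with its own set's
#' columns independently row-shuffled (one shuffle per variable). In the
#' large sample, permuting a variable destroys every dependence involving
#' it, so the networks learned from the two copies differ around the
#' permuted variables; those learned networks serve as the reference pair.
#'
#' @param d0 dataset (numeric matrix or data frame with named columns).
#' @param nPermute size of each permuted variable set (2 and 6 are the
#'   protocol defaults); \code{2 * nPermute} must not exceed the number of
#'   variables.
#' @param seed integer seed.
#' @return A list with \code{d1Full}, \code{d2Full}, \code{permuted1},
#'   \code{permuted2}.
#' @export
permuteAndSplit <- function(d0, nPermute, seed = 1) {
  d0 <- .checkDataset(d0)
  p <- ncol(d0)
  if (2 * nPermute > p) {
    stop("2 * nPermute exceeds the number of variables")
  }
  .withSeed(.mixSeed(seed, 1), {
    chosen <- sample.int(p, 2 * nPermute)
    set1 <- colnames(d0)[chosen[seq_len(nPermute)]]
    set2 <- colnames(d0)[chosen[nPermute + seq_len(nPermute)]]
    d1 <- d0
    for (v in set1) d1[, v] <- d1[sample.int(nrow(d1)), v]
    d2 <- d0
    for (v in set2) d2[, v] <- d2[sample.int(nrow(d2)), v]
    list(d1Full = d1, d2Full = d2, permuted1 = set1, permuted2 = set2)
  })
}

#' Run the real-data benchmarking protocol for one dataset pair
#'
#' Learns reference graphs from the two full-sample datasets, then draws
#' D1 as a 60% without-replacement subsample of \code{d1Full}
#' (N1 = ceiling(0.6 n)) and D2 as a subsample of \code{d2Full} at each
#' requested ratio of N1 (ceiling applied), runs the estimators, and
#' evaluates both directions against the reference-graph difference.
#' RSBS is skipped where N2 = N1.
#'
#' @param d1Full,d2Full full-sample datasets from [permuteAndSplit()].
#' @param ratios N2 as fractions of N1 (default the protocol's
#'   \{0.1, 0.2, 0.5, 1\}).
#' @param spec a [gridSpec()] supplying algorithm, methods, modes, B and
#'   policies (its grid fields are ignored here).
#' @param seed integer seed.
#' @return A \code{data.frame} of metrics rows, one per ratio x method x
#'   direction x mode, with N1/N2 columns.
#' @export
realdataCondition <- function(d1Full, d2Full, ratios = c(0.1, 0.2, 0.5, 1),
                              spec = smokeGridSpec(), seed = 1) {
  d1Full <- .checkDataset(d1Full, "d1Full")
  d2Full <- .alignDatasets(d1Full, .checkDataset(d2Full, "d2Full"))
  ref1 <- runDiscovery(d1Full, spec$algorithm, spec$params)
  ref2 <- runDiscovery(d2Full, spec$algorithm, spec$params)
  n1 <- as.integer(ceiling(0.6 * nrow(d1Full)))
  d1 <- .withSeed(.mixSeed(seed, 11),
                  d1Full[sample.int(nrow(d1Full), n1), , drop = FALSE])
  rows <- list()
  for (ratio in ratios) {
    n2 <- as.integer(ceiling(ratio * n1))
    if (n2 > nrow(d2Full)) {
      stop(sprintf("ratio %.2f requires %d rows but d2Full has %d",
                   ratio, n2, nrow(d2Full)))
    }
    d2 <- .withSeed(.mixSeed(seed, 12, round(1000 * ratio)),
                    d2Full[sample.int(nrow(d2Full), n2), , drop = FALSE])
    maps <- .pairDiffMaps(d1, d2, spec, seed = .mixSeed(seed, 13))
    for (mode in spec$modes) {
      lab12 <- trueEdgeDiff(ref1, ref2, mode, spec$undirectedPolicy,
                            direction = c("D1", "D2"))
      lab21 <- trueEdgeDiff(ref2, ref1, mode, spec$undirectedPolicy,
                            direction = c("D2", "D1"))
      for (nm in names(maps)) {
        parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
        if (parts[2L] != mode) next
        lab <- if (parts[3L] == "12") lab12 else lab21
        met <- classificationMetrics(lab, maps[[nm]], spec$ceMapping)
        met$n1 <- n1
        met$n2 <- n2
        met$ratio <- ratio
        rows[[length(rows) + 1L]] <- met
      }
    }
  }
  do.call(rbind, rows)
}
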
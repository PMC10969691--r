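# Shared fixtures and independent oracles, all built in code.

# Build a skeleton-mode EdgeScoreMap over the given variables from a named
# list of unordered-pair frequencies ("A|C" = 0.86, ...).
makeSkeletonMap <- function(values, vars, B = 50) {
  p <- length(vars)
  m <- matrix(0, p, p, dimnames = list(vars, vars))
  for (key in names(values)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    m[ab[1], ab[2]] <- m[ab[2], ab[1]] <- values[[key]]
  }
  EdgeScoreMap("skeleton", m, B)
}

# The worked-example frequency maps for the five-variable network pair
# whose only true skeleton difference is D-E: per-dataset bootstrap
# frequencies (B = 50) and the equal-sample-size subsample frequencies of
# the larger dataset.
exampleFrequencyMaps <- function() {
  vars <- c("A", "B", "C", "D", "E")
  list(
    bs1 = makeSkeletonMap(list("D|E" = 0.94, "A|C" = 0.86, "B|C" = 1,
                               "C|D" = 1, "A|D" = 0.04, "B|E" = 0.24), vars),
    bs2 = makeSkeletonMap(list("A|C" = 0.10, "B|C" = 1, "C|D" = 1,
                               "A|D" = 0.02), vars),
    rs1 = makeSkeletonMap(list("D|E" = 0.42, "A|C" = 0.16, "B|C" = 1,
                               "C|D" = 1, "A|D" = 0.04, "B|E" = 0.04), vars)
  )
}

# The corresponding true structures: g2 equals g1 without the D -> E edge.
examplePairDags <- function() {
  vars <- c("A", "B", "C", "D", "E")
  g1 <- CausalDag(vars, rbind(c(1L, 3L), c(2L, 3L), c(3L, 4L), c(4L, 5L)))
  g2 <- CausalDag(vars, rbind(c(1L, 3L), c(2L, 3L), c(3L, 4L)))
  list(g1 = g1, g2 = g2)
}

# Brute-force AUCROC oracle: the probability that a random positive
# outscores a random negative, ties counting one half.
aucOracle <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (sp in pos) tot <- tot + sum(sp > neg) + 0.5 * sum(sp == neg)
  tot / (length(pos) * length(neg))
}

# Two-variable network X -> Y with a given coefficient.
twoVarNet <- function(beta = 0.3) {
  dag <- CausalDag(c("X", "Y"), rbind(c(1L, 2L)))
  LinearGaussianNetwork(dag, beta, c(1, sqrt(1 - beta^2)))
}

# A network pair whose single deleted edge has a large effect size
# (f2 about 0.53); used by the consistency-at-scale checks.
strongDiffPair <- function() {
  derivePair(simulateNetwork(10, 20, seed = 38), 2, seed = 138)
}

# Independent-noise dataset on which both backends return an edgeless
# graph.
noiseData <- function(n = 2000, p = 5, seed = 2) {
  cbnDiff:::.withSeed(seed, {
    matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("N", seq_len(p))))
  })
}
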
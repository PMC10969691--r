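# The three difference estimators: worked-example arithmetic, resampling
# invariants, antisymmetry, and behaviour at scale.

test_that("frequency-map differences reproduce the worked-example arithmetic", {
  maps <- exampleFrequencyMaps()
  bs <- edgeScoreDiff(maps$bs1, maps$bs2, "bs")
  expect_equal(scoreMatrix(bs)["A", "C"], 0.76)
  expect_equal(scoreMatrix(bs)["D", "E"], 0.94)
  rs <- edgeScoreDiff(maps$rs1, maps$bs2, "rsbs")
  expect_equal(scoreMatrix(rs)["A", "C"], 0.06)
  expect_equal(scoreMatrix(rs)["D", "E"], 0.42)
  # swapping the maps negates every score
  expect_equal(scoreMatrix(edgeScoreDiff(maps$bs2, maps$bs1, "bs")),
               -scoreMatrix(bs))
})

test_that("bootstrap frequencies are multiples of 1/B and degenerate cleanly at B = 1", {
  net <- simulateNetwork(8, 12, seed = 71)
  d <- sampleData(net, 300, seed = 72)
  f <- bootstrapEdgeFrequencies(d, "pc", B = 10, mode = "skeleton", seed = 73)
  v <- scoreMatrix(f)
  expect_true(all(abs(v * 10 - round(v * 10)) < 1e-9))
  expect_identical(resampleCount(f), 10L)
  f1 <- bootstrapEdgeFrequencies(d, "pc", B = 1, mode = "skeleton", seed = 73)
  expect_true(all(scoreMatrix(f1) %in% c(0, 1)))
})

test_that("subsampling validates its target size and keeps 1/B granularity", {
  net <- simulateNetwork(8, 12, seed = 74)
  d <- sampleData(net, 400, seed = 75)
  expect_error(subsampleFrequencies(d, 400, "pc", B = 5, seed = 1),
               "smaller than")
  expect_error(subsampleFrequencies(d, 500, "pc", B = 5, seed = 1),
               "smaller than")
  f <- subsampleFrequencies(d, 150, "pc", B = 8, mode = "skeleton", seed = 76)
  v <- scoreMatrix(f)
  expect_true(all(abs(v * 8 - round(v * 8)) < 1e-9))
  # boundary sanity run: nTarget = n - 1 executes without error
  expect_s4_class(subsampleFrequencies(d, 399, "pc", B = 2, seed = 1),
                  "EdgeScoreMap")
})

test_that("bootstrap and rsbs diffs are exactly antisymmetric and vanish on identical data", {
  pair <- derivePair(simulateNetwork(10, 15, seed = 81), 4, seed = 82)
  d1 <- sampleData(graph1(pair), 400, seed = 83)
  d2 <- sampleData(graph2(pair), 150, seed = 84)
  for (mode in c("skeleton", "orientation")) {
    bs12 <- bootstrapDiff(d1, d2, "pc", B = 10, mode = mode, seed = 85)
    bs21 <- bootstrapDiff(d2, d1, "pc", B = 10, mode = mode, seed = 85)
    expect_identical(scoreMatrix(bs12) + scoreMatrix(bs21),
                     scoreMatrix(bs12) * 0)
    rs12 <- rsbsDiff(d1, d2, "pc", B = 10, mode = mode, seed = 85)
    rs21 <- rsbsDiff(d2, d1, "pc", B = 10, mode = mode, seed = 85)
    expect_identical(scoreMatrix(rs12) + scoreMatrix(rs21),
                     scoreMatrix(rs12) * 0)
    # scores are multiples of 1/B
    v <- abs(scoreMatrix(bs12))
    expect_true(all(abs(v * 10 - round(v * 10)) < 1e-9))
  }
  # same data on both sides: frequency maps coincide, diff is identically 0
  bsSame <- bootstrapDiff(d1, d1, "pc", B = 10, mode = "skeleton", seed = 86)
  expect_true(all(scoreMatrix(bsSame) == 0))
})

test_that("rsbs rejects equal sample sizes as not applicable", {
  net <- simulateNetwork(6, 8, seed = 91)
  d1 <- sampleData(net, 200, seed = 92)
  d2 <- sampleData(net, 200, seed = 93)
  expect_error(rsbsDiff(d1, d2, "pc", B = 5, seed = 1), "not applicable")
})

test_that("naive equals the thresholded difference of single-run indicators", {
  pair <- derivePair(simulateNetwork(10, 15, seed = 94), 4, seed = 95)
  d1 <- sampleData(graph1(pair), 400, seed = 96)
  d2 <- sampleData(graph2(pair), 150, seed = 97)
  for (mode in c("skeleton", "orientation")) {
    nv <- naiveDiff(d1, d2, "pc", mode = mode)
    e1 <- scoreMatrix(graphToIndicators(runDiscovery(d1, "pc"), mode))
    e2 <- scoreMatrix(graphToIndicators(runDiscovery(d2, "pc"), mode))
    expect_equal(scoreMatrix(nv), (e1 == 1L & e2 == 0L) * 1)
    expect_true(all(scoreMatrix(nv) %in% c(0, 1)))
    # no -1 where the edge is only in the second network
    expect_true(all(scoreMatrix(nv)[e2 == 1L & e1 == 0L] == 0))
  }
})

test_that("a strong deleted edge outscores unchanged pairs at large n", {
  pair <- strongDiffPair()
  del <- cbnDiff::deletedEdges(pair)
  expect_gte(effectSize(graph1(pair), del$tail[1], del$head[1]), 0.15)
  d1 <- sampleData(graph1(pair), 5000, seed = 101)
  d2 <- sampleData(graph2(pair), 5000, seed = 102)
  bd <- bootstrapDiff(d1, d2, "pc", B = 10, mode = "skeleton", seed = 103)
  m <- scoreMatrix(bd)
  lab <- scoreMatrix(trueEdgeDiff(graph1(pair), graph2(pair), "skeleton"))
  unchanged <- m[upper.tri(m) & lab == 0]
  expect_gt(m[del$tail[1], del$head[1]], median(unchanged))
})
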
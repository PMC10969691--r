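# Evaluation: ground-truth labels, classification metrics against hand
# computations and a pairwise-comparison oracle, effect sizes, and the
# effect-size/score correlation.

test_that("edge-difference labels cover the pair universe with the right positives", {
  dags <- examplePairDags()
  # skeleton: the only difference is D - E
  labS <- trueEdgeDiff(dags$g1, dags$g2, "skeleton")
  mS <- scoreMatrix(labS)
  expect_identical(sum(mS[upper.tri(mS)]), 1L)
  expect_identical(mS["D", "E"], 1L)
  # universe cardinalities: Nv(Nv-1) ordered, half that unordered
  labO <- trueEdgeDiff(dags$g1, dags$g2, "orientation")
  expect_length(cbnDiff:::.flattenPairs(scoreMatrix(labO), "orientation"), 20L)
  expect_length(cbnDiff:::.flattenPairs(mS, "skeleton"), 10L)
  # identical graphs: all-zero labels
  expect_identical(sum(scoreMatrix(trueEdgeDiff(dags$g1, dags$g1, "skeleton"))), 0L)
  # the two directions have disjoint positive sets
  pair <- derivePair(simulateNetwork(20, 40, seed = 111), 8, seed = 112)
  l12 <- scoreMatrix(trueEdgeDiff(graph1(pair), graph2(pair), "orientation"))
  l21 <- scoreMatrix(trueEdgeDiff(graph2(pair), graph1(pair), "orientation"))
  expect_identical(sum(l12 & l21), 0L)
  expect_identical(sum(l12), nrow(cbnDiff::deletedEdges(pair)))
  expect_identical(sum(l21), nrow(cbnDiff::addedEdges(pair)))
})

test_that("classification metrics match hand-derived values", {
  vars <- paste0("V", 1:4)  # skeleton universe: 6 unordered pairs
  lab <- matrix(0L, 4, 4, dimnames = list(vars, vars))
  lab["V1", "V2"] <- lab["V2", "V1"] <- 1L
  sc <- matrix(0.1, 4, 4, dimnames = list(vars, vars))
  sc["V1", "V2"] <- sc["V2", "V1"] <- 0.9
  sc["V1", "V3"] <- sc["V3", "V1"] <- 0.8
  labels <- cbnDiff:::DiffLabels("skeleton", lab)
  scores <- cbnDiff:::DiffScoreMap("skeleton", "bs", sc)
  m <- classificationMetrics(labels, scores)
  # hand enumeration: the single positive tops the ranking
  expect_equal(m$aucroc, 1)
  expect_equal(m$aupr, 1)
  expect_gt(m$threshold, 0.8)
  expect_lte(m$threshold, 0.9)
  expect_equal(m$f1, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  # perfect scores equal to labels
  perfect <- cbnDiff:::DiffScoreMap("skeleton", "bs", lab * 1)
  mp <- classificationMetrics(labels, perfect)
  expect_equal(mp$aucroc, 1)
  expect_equal(mp$aupr, 1)
  expect_equal(mp$f1, 1)
  # constant scores: uninformative ranking
  const <- cbnDiff:::DiffScoreMap("skeleton", "bs", sc * 0 + 0.5)
  expect_equal(classificationMetrics(labels, const)$aucroc, 0.5)
  # degenerate labels: ranking metrics are missing, not zero
  none <- cbnDiff:::DiffLabels("skeleton", lab * 0L)
  md <- classificationMetrics(none, scores)
  expect_true(is.na(md$aucroc))
  expect_true(is.na(md$aupr))
  expect_true(md$degenerate)
})

test_that("AUCROC equals the pairwise-comparison probability on random cases", {
  vars <- paste0("V", 1:15)  # orientation universe: 210 ordered pairs
  for (rep in 1:5) {
    gen <- cbnDiff:::.withSeed(300 + rep, {
      lab <- matrix(rbinom(225, 1, 0.15), 15, 15, dimnames = list(vars, vars))
      diag(lab) <- 0L
      sc <- matrix(round(runif(225, -1, 1), 1), 15, 15,
                   dimnames = list(vars, vars))  # rounding forces ties
      diag(sc) <- 0
      list(lab = lab, sc = sc)
    })
    labels <- cbnDiff:::DiffLabels("orientation", gen$lab)
    scores <- cbnDiff:::DiffScoreMap("orientation", "bs", gen$sc)
    y <- cbnDiff:::.flattenPairs(scoreMatrix(labels), "orientation")
    s <- cbnDiff:::.flattenPairs(gen$sc, "orientation")
    if (sum(y) == 0 || sum(y) == length(y)) next
    expect_equal(classificationMetrics(labels, scores)$aucroc,
                 aucOracle(y, s))
  }
})

test_that("ranking metrics are invariant to monotone score transforms", {
  pair <- strongDiffPair()
  d1 <- sampleData(graph1(pair), 800, seed = 121)
  d2 <- sampleData(graph2(pair), 300, seed = 122)
  bd <- bootstrapDiff(d1, d2, "pc", B = 10, mode = "skeleton", seed = 123)
  lab <- trueEdgeDiff(graph1(pair), graph2(pair), "skeleton")
  m1 <- classificationMetrics(lab, bd)
  cubed <- cbnDiff:::DiffScoreMap("skeleton", "bs", scoreMatrix(bd)^3)
  m2 <- classificationMetrics(lab, cubed)
  expect_equal(m1$aucroc, m2$aucroc)
  expect_equal(m1$aupr, m2$aupr)
})

test_that("effect sizes match the closed form and its boundary cases", {
  expect_equal(effectSize(twoVarNet(0.3), "X", "Y"), 0.09 / 0.91,
               tolerance = 1e-12)
  expect_equal(effectSize(twoVarNet(0.1), "X", "Y"), 0.01 / 0.99,
               tolerance = 1e-12)
  expect_error(effectSize(twoVarNet(0.3), "Y", "X"), "not in the network")
  tab <- effectSizeTable(simulateNetwork(10, 20, seed = 131))
  expect_identical(nrow(tab), 20L)
  expect_true(all(tab$f2 >= 0))
})

test_that("effect-size/score correlation handles monotone, constant and tiny inputs", {
  tab <- data.frame(tail = c("A", "B", "C"), head = c("B", "C", "D"),
                    f2 = c(0.05, 0.15, 0.30))
  vars <- c("A", "B", "C", "D")
  sc <- matrix(0, 4, 4, dimnames = list(vars, vars))
  sc["A", "B"] <- 0.2; sc["B", "C"] <- 0.5; sc["C", "D"] <- 0.9
  scores <- cbnDiff:::DiffScoreMap("orientation", "bs", sc)
  res <- correlateEffectSizeScores(tab, scores)
  expect_equal(res$correlation, 1)
  constScores <- cbnDiff:::DiffScoreMap("orientation", "bs", sc * 0 + 0.5)
  resC <- correlateEffectSizeScores(tab, constScores)
  expect_true(is.na(resC$correlation))
  expect_identical(resC$flag, "zero variance")
  resT <- correlateEffectSizeScores(tab[1:2, ], scores)
  expect_true(is.na(resT$correlation))
  expect_match(resT$flag, "fewer than 3")
})
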
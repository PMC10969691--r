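# Experiment runner: grid enumeration arithmetic, condition execution and
# determinism, the best-method rule, and the real-data permutation
# protocol.

test_that("condition enumeration matches an explicit nested-loop oracle", {
  spec <- gridSpec()
  cond <- enumerateConditions(spec)
  # oracle: count the Cartesian product by explicit loops
  count <- 0L
  rsbsCount <- 0L
  for (nv in spec$nVars) for (mult in spec$neMultipliers) {
    for (frac in spec$ndFractions) for (n1 in spec$n1) {
      for (ratio in spec$n2Ratios) {
        count <- count + 1L
        if (ceiling(ratio * n1) != n1) rsbsCount <- rsbsCount + 1L
      }
    }
  }
  expect_identical(nrow(cond), count)
  expect_identical(attr(cond, "nPairs"), as.integer(count * spec$repeats))
  expect_identical(attr(cond, "nRsbsApplicable"), rsbsCount)
  # the Nd and N2 columns carry the ceiling of the fractional settings
  expect_true(all(cond$nd == ceiling(rep(spec$ndFractions, each = 16) *
                                       rep(round(spec$neMultipliers * 100),
                                           each = 80))))
  # a custom spec obeys the same arithmetic
  small <- gridSpec(nVars = 20, neMultipliers = 2, ndFractions = c(0.1, 0.5),
                    n1 = c(100, 200), n2Ratios = c(0.5, 1), repeats = 3)
  cs <- enumerateConditions(small)
  expect_identical(nrow(cs), 8L)
  expect_identical(attr(cs, "nPairs"), 24L)
  expect_identical(attr(cs, "nRsbsApplicable"), 4L)
  expect_error(gridSpec(n1 = numeric(0)), "empty")
})

test_that("running a condition yields per-repeat reports for every applicable method", {
  spec <- gridSpec(nVars = 10, neMultipliers = 1.5, ndFractions = 0.25,
                   n1 = 200, n2Ratios = 0.5, repeats = 2, algorithm = "pc",
                   B = 5)
  cond <- enumerateConditions(spec)
  expect_identical(cond$n2, 100L)
  res <- runCondition(cond[1, ], spec, masterSeed = 7)
  pr <- res$perRepeat
  # 3 methods x 2 directions x 2 modes x 2 repeats
  expect_identical(nrow(pr), 24L)
  expect_setequal(unique(pr$method), c("naive", "bs", "rsbs"))
  expect_setequal(unique(pr$direction), c("D1-D2", "D2-D1"))
  expect_setequal(unique(pr$mode), c("orientation", "skeleton"))
  # determinism: identical aggregates on a rerun
  res2 <- runCondition(cond[1, ], spec, masterSeed = 7)
  expect_identical(res$aggregate, res2$aggregate)
  # equal sample sizes: rsbs must be absent
  specEq <- gridSpec(nVars = 10, neMultipliers = 1.5, ndFractions = 0.25,
                     n1 = 200, n2Ratios = 1, repeats = 1, algorithm = "pc",
                     B = 5)
  condEq <- enumerateConditions(specEq)
  resEq <- runCondition(condEq[1, ], specEq, masterSeed = 7)
  expect_false("rsbs" %in% resEq$perRepeat$method)
})

test_that("the one-standard-deviation best-method rule matches hand computations", {
  base <- data.frame(id = 1, direction = "D1-D2", mode = "skeleton")
  # means 0.9 (sd 0.05) vs 0.84: 0.84 < 0.85, so only the first is best
  agg <- rbind(cbind(base, method = "bs", aucroc_mean = 0.90, aucroc_sd = 0.05),
               cbind(base, method = "naive", aucroc_mean = 0.84, aucroc_sd = 0.05))
  tab <- bestMethodTable(agg, "aucroc")
  expect_equal(tab$percentBest[tab$method == "bs"], 100)
  expect_equal(tab$percentBest[tab$method == "naive"], 0)
  # identical means: both marked best
  aggTie <- rbind(cbind(base, method = "bs", aucroc_mean = 0.9, aucroc_sd = 0.02),
                  cbind(base, method = "naive", aucroc_mean = 0.9, aucroc_sd = 0.02))
  tabTie <- bestMethodTable(aggTie, "aucroc")
  expect_equal(tabTie$percentBest, c(100, 100))
  # cross-entropy: lower is better, rule mirrored
  aggCe <- rbind(cbind(base, method = "bs", crossEntropy_mean = 0.08,
                       crossEntropy_sd = 0.04),
                 cbind(base, method = "naive", crossEntropy_mean = 0.30,
                       crossEntropy_sd = 0.04))
  tabCe <- bestMethodTable(aggCe, "crossEntropy")
  expect_equal(tabCe$percentBest[tabCe$method == "bs"], 100)
  expect_equal(tabCe$percentBest[tabCe$method == "naive"], 0)
  # percentages computed over each method's applicable conditions only
  agg2 <- rbind(agg,
                cbind(base[0, ], method = character(0),
                      aucroc_mean = numeric(0), aucroc_sd = numeric(0)))
  agg2b <- rbind(cbind(data.frame(id = 2, direction = "D1-D2",
                                  mode = "skeleton"), method = "bs",
                       aucroc_mean = 0.7, aucroc_sd = 0.1))
  tab2 <- bestMethodTable(rbind(agg, agg2b), "aucroc")
  expect_identical(tab2$nApplicable[tab2$method == "bs"], 2L)
  expect_identical(tab2$nApplicable[tab2$method == "naive"], 1L)
})

test_that("variable permutation preserves marginals and destroys dependence", {
  net <- simulateNetwork(14, 25, seed = 141)
  d0 <- sampleData(net, 2000, seed = 142)
  for (np in c(2L, 6L)) {
    split <- permuteAndSplit(d0, np, seed = 143)
    expect_length(split$permuted1, np)
    expect_length(split$permuted2, np)
    expect_length(intersect(split$permuted1, split$permuted2), 0L)
    # marginal multiset of a permuted column is unchanged
    v <- split$permuted1[1]
    expect_identical(sort(split$d1Full[, v]), sort(d0[, v]))
    # permuted columns decorrelate from everything else
    others <- setdiff(colnames(d0), v)
    cors <- abs(cor(split$d1Full[, v], split$d1Full[, others]))
    expect_lt(max(cors), 0.08)
  }
  expect_error(permuteAndSplit(d0, 8, seed = 1), "exceeds")
})

test_that("the real-data protocol sizes its subsamples and skips rsbs at equal n", {
  net <- simulateNetwork(8, 14, seed = 151)
  d0 <- sampleData(net, 400, seed = 152)
  split <- permuteAndSplit(d0, 2, seed = 153)
  spec <- gridSpec(nVars = 8, neMultipliers = 1, ndFractions = 0.1, n1 = 100,
                   repeats = 1, algorithm = "pc", B = 5)
  res <- realdataCondition(split$d1Full, split$d2Full, ratios = c(0.5, 1),
                           spec = spec, seed = 154)
  expect_true(all(res$n1 == ceiling(0.6 * 400)))
  expect_identical(sort(unique(res$n2)), c(120L, 240L))
  expect_false("rsbs" %in% res$method[res$n2 == res$n1])
  expect_true("rsbs" %in% res$method[res$n2 != res$n1])
  expect_true(all(c("naive", "bs") %in% res$method))
})
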
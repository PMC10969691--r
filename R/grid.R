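# Simulation-grid experiment runner: condition enumeration, per-condition
# execution with repeats, aggregation, and the best-method tabulation rule.

#' Simulation grid specification
#'
#' The defaults reproduce the full simulation design: Nv = 100;
#' Ne = \{1.5, 2, 2.5\} x Nv; Nd = ceiling(\{0.05, 0.1, 0.2, 0.5, 1\} x Ne);
#' N1 = \{500, 1000, 2000, 5000\}; N2 = ceiling(\{0.1, 0.2, 0.5, 1\} x N1);
#' 50 repeats per condition (240 conditions, 12,000 dataset pairs). Running
#' that grid is cluster-scale work; see [smokeGridSpec()] for a desk-scale
#' preset.
#'
#' @param nVars vector of network sizes.
#' @param neMultipliers edge counts as multiples of \code{nVars}.
#' @param ndFractions differing-edge counts as fractions of Ne (ceiling
#'   applied).
#' @param n1 sample sizes for the first dataset.
#' @param n2Ratios sample sizes for the second dataset as ratios of N1
#'   (ceiling applied).
#' @param repeats dataset pairs per condition.
#' @param algorithm,params discovery backend, see [runDiscovery()].
#' @param methods estimators to run; \code{"rsbs"} is skipped where
#'   N1 = N2.
#' @param modes evaluation modes.
#' @param B resample count for the resampling estimators.
#' @param undirectedPolicy see [graphToIndicators()].
#' @param ceMapping see [classificationMetrics()].
#' @return A \code{GridSpec} list.
#' @export
gridSpec <- function(nVars = 100,
                     neMultipliers = c(1.5, 2, 2.5),
                     ndFractions = c(0.05, 0.1, 0.2, 0.5, 1),
                     n1 = c(500, 1000, 2000, 5000),
                     n2Ratios = c(0.1, 0.2, 0.5, 1),
                     repeats = 50,
                     algorithm = "pc",
                     params = list(),
                     methods = c("naive", "bs", "rsbs"),
                     modes = c("orientation", "skeleton"),
                     B = 50,
                     undirectedPolicy = "both",
                     ceMapping = "clip") {
  spec <- list(nVars = nVars, neMultipliers = neMultipliers,
               ndFractions = ndFractions, n1 = n1, n2Ratios = n2Ratios,
               repeats = repeats, algorithm = algorithm, params = params,
               methods = methods, modes = modes, B = B,
               undirectedPolicy = undirectedPolicy, ceMapping = ceMapping)
  if (!length(spec$nVars) || !length(spec$neMultipliers) ||
      !length(spec$ndFractions) || !length(spec$n1) ||
      !length(spec$n2Ratios) || spec$repeats < 1) {
    stop("empty grid specification")
  }
  class(spec) <- "GridSpec"
  spec
}

#' Desk-scale smoke preset of the simulation grid
#'
#' A deliberately small grid (Nv = 10 by default) for plumbing checks and
#' examples; never a silent substitute for the full design.
#'
#' @param ... overrides passed to [gridSpec()].
#' @export
smokeGridSpec <- function(...) {
  defaults <- list(nVars = 10, neMultipliers = 1.5, ndFractions = 0.2,
                   n1 = 200, n2Ratios = c(0.5, 1), repeats = 2,
                   algorithm = "ges", B = 10)
  args <- utils::modifyList(defaults, list(...))
  do.call(gridSpec, args)
}

#' Enumerate the conditions of a simulation grid
#'
#' Deterministically ordered Cartesian product of the structure and sample
#' size settings. Ceiling is applied to fractional Nd and N2 values.
#'
#' @param spec a [gridSpec()].
#' @return A \code{data.frame} with one row per condition (columns id, nv,
#'   ne, nd, n1, n2) and attributes \code{nPairs} (conditions x repeats)
#'   and \code{nRsbsApplicable} (conditions with N1 != N2).
#' @examples
#' nrow(enumerateConditions(gridSpec()))  # 240
#' @export
enumerateConditions <- function(spec) {
  stopifnot(inherits(spec, "GridSpec"))
  g <- expand.grid(n2Ratio = spec$n2Ratios, n1 = spec$n1,
                   ndFraction = spec$ndFractions,
                   neMultiplier = spec$neMultipliers,
                   nv = spec$nVars, KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    id = seq_len(nrow(g)),
    nv = as.integer(g$nv),
    ne = as.integer(round(g$neMultiplier * g$nv)),
    nd = as.integer(ceiling(g$ndFraction * round(g$neMultiplier * g$nv))),
    n1 = as.integer(g$n1),
    n2 = as.integer(ceiling(g$n2Ratio * g$n1))
  )
  attr(out, "nPairs") <- as.integer(nrow(out) * spec$repeats)
  attr(out, "nRsbsApplicable") <- sum(out$n1 != out$n2)
  out
}

# All requested diff maps for one dataset pair, computed with per-dataset
# frequency maps shared across modes and directions.
.pairDiffMaps <- function(d1, d2, spec, seed) {
  res <- list()
  freq1 <- freq2 <- sub1 <- sub2 <- NULL
  needBs <- any(c("bs", "rsbs") %in% spec$methods)
  if (needBs) {
    freq1 <- .bootstrapBoth(d1, spec$algorithm, spec$params, spec$B, seed,
                            spec$undirectedPolicy)
    freq2 <- .bootstrapBoth(d2, spec$algorithm, spec$params, spec$B, seed,
                            spec$undirectedPolicy)
  }
  rsbsOk <- "rsbs" %in% spec$methods && nrow(d1) != nrow(d2)
  if (rsbsOk) {
    nSmall <- min(nrow(d1), nrow(d2))
    if (nrow(d1) > nSmall) {
      sub1 <- .subsampleBoth(d1, nSmall, spec$algorithm, spec$params, spec$B,
                             seed, spec$undirectedPolicy)
      sub2 <- freq2
    } else {
      sub1 <- freq1
      sub2 <- .subsampleBoth(d2, nSmall, spec$algorithm, spec$params, spec$B,
                             seed, spec$undirectedPolicy)
    }
  }
  ind1 <- ind2 <- NULL
  if ("naive" %in% spec$methods) {
    g1hat <- runDiscovery(d1, spec$algorithm, spec$params)
    g2hat <- runDiscovery(d2, spec$algorithm, spec$params)
    ind1 <- lapply(c(orientation = "orientation", skeleton = "skeleton"),
                   function(m) graphToIndicators(g1hat, m, spec$undirectedPolicy)@indicators)
    ind2 <- lapply(c(orientation = "orientation", skeleton = "skeleton"),
                   function(m) graphToIndicators(g2hat, m, spec$undirectedPolicy)@indicators)
  }
  for (mode in spec$modes) {
    for (dir in c("12", "21")) {
      a <- if (dir == "12") 1L else 2L
      b <- 3L - a
      tag <- c(paste0("D", a), paste0("D", b))
      if ("naive" %in% spec$methods) {
        eI <- (if (a == 1L) ind1 else ind2)[[mode]]
        eJ <- (if (a == 1L) ind2 else ind1)[[mode]]
        res[[paste("naive", mode, dir, sep = ".")]] <-
          DiffScoreMap(mode, "naive", (eI == 1L & eJ == 0L) * 1, tag)
      }
      if ("bs" %in% spec$methods) {
        fI <- (if (a == 1L) freq1 else freq2)[[mode]]
        fJ <- (if (a == 1L) freq2 else freq1)[[mode]]
        res[[paste("bs", mode, dir, sep = ".")]] <-
          edgeScoreDiff(fI, fJ, "bs", tag)
      }
      if (rsbsOk) {
        fI <- (if (a == 1L) sub1 else sub2)[[mode]]
        fJ <- (if (a == 1L) sub2 else sub1)[[mode]]
        res[[paste("rsbs", mode, dir, sep = ".")]] <-
          edgeScoreDiff(fI, fJ, "rsbs", tag)
      }
    }
  }
  res
}

#' Run one simulation condition
#'
#' For each repeat: simulate a network pair at the condition's structure
#' settings, sample D1 and D2 at the condition's sample sizes, run every
#' applicable estimator, and evaluate both directions (E1 - E2 and
#' E2 - E1) in every requested mode against the ground-truth labels. Fully
#' deterministic given \code{masterSeed}.
#'
#' @param condition one row of [enumerateConditions()].
#' @param spec the [gridSpec()].
#' @param masterSeed integer master seed; per-repeat seeds are derived from
#'   it and the condition id.
#' @return A list with \code{perRepeat} (one metrics row per repeat x
#'   method x direction x mode), \code{aggregate} (mean and sd per metric
#'   over repeats), and \code{condition}.
#' @export
runCondition <- function(condition, spec, masterSeed = 1) {
  stopifnot(inherits(spec, "GridSpec"), nrow(condition) == 1L)
  rows <- list()
  for (r in seq_len(spec$repeats)) {
    sd0 <- .mixSeed(masterSeed, condition$id, r)
    g1 <- simulateNetwork(condition$nv, condition$ne, seed = .mixSeed(sd0, 1))
    pair <- derivePair(g1, condition$nd, seed = .mixSeed(sd0, 2))
    d1 <- sampleData(pair@g1, condition$n1, seed = .mixSeed(sd0, 3))
    d2 <- sampleData(pair@g2, condition$n2, seed = .mixSeed(sd0, 4))
    maps <- .pairDiffMaps(d1, d2, spec, seed = .mixSeed(sd0, 5))
    for (mode in spec$modes) {
      lab12 <- trueEdgeDiff(pair@g1, pair@g2, mode, direction = c("D1", "D2"))
      lab21 <- trueEdgeDiff(pair@g2, pair@g1, mode, direction = c("D2", "D1"))
      for (nm in names(maps)) {
        parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
        if (parts[2L] != mode) next
        lab <- if (parts[3L] == "12") lab12 else lab21
        met <- classificationMetrics(lab, maps[[nm]], spec$ceMapping)
        met$repeatIndex <- r
        rows[[length(rows) + 1L]] <- met
      }
    }
  }
  perRepeat <- do.call(rbind, rows)
  perRepeat <- cbind(condition[rep(1L, nrow(perRepeat)),
                               c("id", "nv", "ne", "nd", "n1", "n2")],
                     perRepeat, row.names = NULL)
  metricCols <- c("aucroc", "aupr", "crossEntropy", "sensitivity",
                  "specificity", "ppv", "npv", "f1", "accuracy")
  agg <- stats::aggregate(perRepeat[metricCols],
                          perRepeat[c("id", "nv", "ne", "nd", "n1", "n2",
                                      "method", "direction", "mode")],
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  flat <- agg[, 1:9]
  for (mc in metricCols) {
    flat[[paste0(mc, "_mean")]] <- agg[[mc]][, "mean"]
    flat[[paste0(mc, "_sd")]] <- agg[[mc]][, "sd"]
  }
  list(perRepeat = perRepeat, aggregate = flat,
       condition = condition)
}

#' Run a grid of simulation conditions
#'
#' @param spec a [gridSpec()].
#' @param masterSeed integer master seed.
#' @param conditions optional subset of [enumerateConditions()] rows to run.
#' @param verbose print per-condition timing.
#' @return A list with \code{perRepeat} and \code{aggregate} data frames
#'   covering all executed conditions.
#' @export
runGrid <- function(spec, masterSeed = 1, conditions = NULL, verbose = FALSE) {
  if (is.null(conditions)) conditions <- enumerateConditions(spec)
  per <- list()
  agg <- list()
  for (k in seq_len(nrow(conditions))) {
    t0 <- Sys.time()
    res <- runCondition(conditions[k, , drop = FALSE], spec, masterSeed)
    per[[k]] <- res$perRepeat
    agg[[k]] <- res$aggregate
    if (verbose) {
      message(sprintf("condition %d/%d (id %d) done in %.1fs",
                      k, nrow(conditions), conditions$id[k],
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  list(perRepeat = do.call(rbind, per), aggregate = do.call(rbind, agg))
}

#' Best-method tabulation over simulation conditions
#'
#' Per condition (and direction and mode), the method with the best mean
#' metric is found; every method whose mean lies within one standard
#' deviation of the best method's mean (the best method's SD) is also
#' marked best. Higher is better for AUCROC/AUPR/F1-type metrics, lower
#' for cross-entropy. Percentages are reported over each method's
#' applicable conditions (RSBS is absent where N1 = N2).
#'
#' @param aggregate the \code{aggregate} data frame from [runGrid()] or
#'   rbound [runCondition()] aggregates.
#' @param metric base metric name, e.g. \code{"aucroc"}, \code{"aupr"},
#'   \code{"crossEntropy"}.
#' @param direction,mode optional filters (e.g. \code{"D1-D2"},
#'   \code{"orientation"}).
#' @return A \code{data.frame} with one row per method: nApplicable,
#'   nBest, percentBest.
#' @examples
#' agg <- data.frame(id = 1, method = c("bs", "naive"),
#'                   direction = "D1-D2", mode = "skeleton",
#'                   aucroc_mean = c(0.9, 0.84), aucroc_sd = c(0.05, 0.05))
#' bestMethodTable(agg, "aucroc")  # only "bs" marked best
#' @export
bestMethodTable <- function(aggregate, metric = "aucroc",
                            direction = NULL, mode = NULL) {
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  stopifnot(all(c(mcol, scol, "id", "method") %in% names(aggregate)))
  df <- aggregate
  if (!is.null(direction)) df <- df[df$direction == direction, ]
  if (!is.null(mode)) df <- df[df$mode == mode, ]
  df <- df[!is.na(df[[mcol]]), ]
  if (!nrow(df)) stop("no usable rows for metric ", metric)
  lowerBetter <- metric == "crossEntropy"
  groupKey <- interaction(df$id,
                          if (!is.null(df$direction)) df$direction else "",
                          if (!is.null(df$mode)) df$mode else "",
                          drop = TRUE)
  df$best <- FALSE
  for (gkey in levels(groupKey)) {
    sel <- which(groupKey == gkey)
    if (length(sel) < 1L) next
    means <- df[[mcol]][sel]
    sds <- df[[scol]][sel]
    sds[is.na(sds)] <- 0
    bi <- if (lowerBetter) which.min(means) else which.max(means)
    cut <- if (lowerBetter) means[bi] + sds[bi] else means[bi] - sds[bi]
    df$best[sel] <- if (lowerBetter) means <= cut else means >= cut
  }
  methods <- sort(unique(df$method))
  out <- do.call(rbind, lapply(methods, function(m) {
    sel <- df$method == m
    data.frame(method = m, nApplicable = sum(sel), nBest = sum(df$best[sel]),
               percentBest = 100 * sum(df$best[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Long-running full-scale spot check
#'
#' Runs the bootstrap and equal-sample-size resampling estimators at the
#' full simulation scale for a single structure/sample-size setting
#' (Nv = 100, Ne = 200, Nd = 40, N1 = 500, N2 = 250 by default) and
#' reports mean AUPR and cross-entropy for the orientation E1 - E2
#' outcome. At the design's 50 repeats this is hours of computation on one
#' core; it exists for users with cluster time, not for routine test runs.
#'
#' @param masterSeed integer master seed.
#' @param repeats number of repeats (50 at full scale).
#' @param algorithm discovery backend.
#' @param B resample count.
#' @return The \code{aggregate} data frame of [runCondition()].
#' @export
runFullScaleCheck <- function(masterSeed = 1, repeats = 50,
                              algorithm = "ges", B = 50) {
  spec <- gridSpec(nVars = 100, neMultipliers = 2, ndFractions = 0.2,
                   n1 = 500, n2Ratios = 0.5, repeats = repeats,
                   algorithm = algorithm, B = B, modes = "orientation")
  cond <- enumerateConditions(spec)
  stopifnot(cond$ne == 200, cond$nd == 40, cond$n2 == 250)
  runCondition(cond[1L, , drop = FALSE], spec, masterSeed)$aggregate
}
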
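# Constraint-based structure discovery: PC-stable with Fisher-z
# partial-correlation tests, v-structure orientation, and Meek rules.

# Partial correlation of variables i and j given the set S, from the
# correlation matrix C.
.partialCor <- function(C, i, j, S) {
  if (length(S) == 0L) return(C[i, j])
  if (length(S) == 1L) {
    k <- S
    den <- (1 - C[i, k]^2) * (1 - C[j, k]^2)
    if (den <= 0) return(0)
    return((C[i, j] - C[i, k] * C[j, k]) / sqrt(den))
  }
  sub <- C[c(i, j, S), c(i, j, S)]
  P <- tryCatch(solve(sub), error = function(e) NULL)
  if (is.null(P)) return(0)
  -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
}

# Fisher-z p-value for zero partial correlation; NA when the sample is too
# small to test (the edge is then retained).
.fisherZ <- function(r, n, condSize) {
  df <- n - condSize - 3
  if (df < 1) return(NA_real_)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  stat <- sqrt(df) * abs(atanh(r))
  2 * stats::pnorm(stat, lower.tail = FALSE)
}

# PC-stable skeleton phase. Returns the adjacency matrix and the separating
# sets found (indexed (i - 1) * p + j, both orders filled).
.pcSkeleton <- function(C, n, alpha, maxCond = Inf) {
  p <- ncol(C)
  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  seps <- vector("list", p * p)
  l <- 0L
  repeat {
    snapshot <- adj
    testable <- FALSE
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i == j || !adj[i, j]) next
        nb <- which(snapshot[i, ])
        nb <- nb[nb != j]
        if (length(nb) < l) next
        testable <- TRUE
        for (S in .subsetsOfSize(nb, l)) {
          pval <- .fisherZ(.partialCor(C, i, j, S), n, l)
          if (!is.na(pval) && pval > alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            seps[[(i - 1L) * p + j]] <- S
            seps[[(j - 1L) * p + i]] <- S
            break
          }
        }
      }
    }
    l <- l + 1L
    if (!testable || l > maxCond) break
  }
  list(adj = adj, seps = seps)
}

# Orient v-structures from separating sets, then close under Meek rules.
.pcOrient <- function(adj, seps) {
  p <- nrow(adj)
  amat <- matrix(0L, p, p)
  amat[adj] <- 1L
  # v-structures: unshielded i - k - j with k not in sepset(i, j)
  for (k in seq_len(p)) {
    nbk <- which(adj[k, ])
    if (length(nbk) < 2L) next
    for (a in seq_along(nbk)) {
      for (b in seq_along(nbk)) {
        if (a >= b) next
        i <- nbk[a]; j <- nbk[b]
        if (adj[i, j]) next
        S <- seps[[(i - 1L) * p + j]]
        if (is.null(S)) S <- integer(0)
        if (!(k %in% S)) {
          # orient i -> k and j -> k unless an opposite arrow already exists
          if (amat[i, k] == 1L) amat[k, i] <- 0L
          if (amat[j, k] == 1L) amat[k, j] <- 0L
        }
      }
    }
  }
  .meekClosure(amat)
}

# Meek rules R1-R3 applied to a pattern until fixpoint. amat coding:
# amat[i, j] = 1, amat[j, i] = 0 is i -> j; both 1 undirected.
.meekClosure <- function(amat) {
  p <- nrow(amat)
  adjacent <- function(x, y) amat[x, y] == 1L || amat[y, x] == 1L
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) {
      for (b in seq_len(p)) {
        if (a == b || !(amat[a, b] == 1L && amat[b, a] == 1L)) next
        # can we orient a -> b?
        orient <- FALSE
        # R1: exists c -> a with c, b nonadjacent
        for (cc in seq_len(p)) {
          if (amat[cc, a] == 1L && amat[a, cc] == 0L && cc != b &&
              !adjacent(cc, b)) { orient <- TRUE; break }
        }
        # R2: exists directed path a -> c -> b
        if (!orient) {
          for (cc in seq_len(p)) {
            if (cc == a || cc == b) next
            if (amat[a, cc] == 1L && amat[cc, a] == 0L &&
                amat[cc, b] == 1L && amat[b, cc] == 0L) { orient <- TRUE; break }
          }
        }
        # R3: two nonadjacent c, d with a - c, a - d undirected and
        # c -> b, d -> b
        if (!orient) {
          cand <- which(vapply(seq_len(p), function(cc) {
            cc != a && cc != b &&
              amat[a, cc] == 1L && amat[cc, a] == 1L &&
              amat[cc, b] == 1L && amat[b, cc] == 0L
          }, logical(1)))
          if (length(cand) >= 2L) {
            for (x in seq_along(cand)) {
              for (y in seq_along(cand)) {
                if (x >= y) next
                if (!adjacent(cand[x], cand[y])) { orient <- TRUE; break }
              }
              if (orient) break
            }
          }
        }
        if (orient) {
          amat[b, a] <- 0L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  amat
}

# Full PC run on a dataset; returns the amat of the estimated pattern.
.pcSearch <- function(data, alpha = 0.05, maxCond = Inf) {
  C <- stats::cor(data)
  sk <- .pcSkeleton(C, nrow(data), alpha, maxCond)
  .pcOrient(sk$adj, sk$seps)
}
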
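## Independent oracles used across the suite. These deliberately avoid the
## package's own alignment/clustering/matching code paths.

## Plain-R affine-gap Smith-Waterman: O(nm) three-matrix recursion.
swOracle <- function(q, s, match = 1, mismatch = -2, gapOpen = -5, gapExt = -2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)   # best ending in match/mismatch
  E <- matrix(-Inf, n + 1, m + 1) # gap in s (query consumed)
  F <- matrix(-Inf, n + 1, m + 1) # gap in q
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i - 1L, j] + gapOpen, E[i - 1L, j] + gapExt)
      F[i, j] <- max(H[i, j - 1L] + gapOpen, F[i, j - 1L] + gapExt)
      sub <- if (qc[i - 1L] == sc[j - 1L]) match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

## best oracle score across a library (both strands)
swOracleLibrary <- function(q, library) {
  revc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  best <- 0
  for (r in seq_along(consensusSeqs(library))) {
    s <- as.character(consensusSeqs(library)[[r]])
    best <- max(best, swOracle(q, s), swOracle(q, revc(s)))
  }
  best
}

## interval-graph connected-components clustering oracle (igraph)
clusterOracle <- function(evidence, stats, cfg) {
  iv <- MEIdetect:::predictedIntervals(evidence, stats)
  chrom <- as.character(GenomicRanges::seqnames(evidence))
  n <- length(evidence)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- chrom[i] == chrom[j] && iv$lo[i] < iv$hi[j] && iv$lo[j] < iv$hi[i]
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  lapply(sort(unique(comp)), function(k) sort(which(comp == k)))
}

## exhaustive minimum-cost bipartite matcher (small inputs only)
matchOracle <- function(callPos, truthPos, tol) {
  nc <- length(callPos); nt <- length(truthPos)
  bestCount <- -1; bestCost <- Inf
  recurse <- function(i, usedT, count, cost) {
    if (i > nc) {
      if (count > bestCount || (count == bestCount && cost < bestCost)) {
        bestCount <<- count; bestCost <<- cost
      }
      return(invisible())
    }
    recurse(i + 1L, usedT, count, cost)           # leave call i unmatched
    for (j in seq_len(nt)) {
      if (usedT[j]) next
      d <- abs(callPos[i] - truthPos[j])
      if (d <= tol) {
        usedT[j] <- TRUE
        recurse(i + 1L, usedT, count + 1L, cost + d)
        usedT[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nt), 0L, 0)
  list(tp = bestCount)
}
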
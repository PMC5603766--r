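## hand-built evidence GRanges for clustering tests
mkEvidence <- function(chrom, start, side, clipPos = NA_integer_,
                       family = "Alu", category = "RAM_PAIR", width = 100L) {
  n <- length(start)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, start + width))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    category = rep(category, length.out = n), qname = sprintf("q%03d", seq_len(n)),
    anchorSide = rep(side, length.out = n), anchorMapq = 60L,
    anchorIsReverse = rep(side, length.out = n) == "right",
    clipPos = rep(clipPos, length.out = n),
    clippedSeq = NA_character_, teSeq = NA_character_,
    family = rep(family, length.out = n), subfamily = NA_character_,
    teStrand = "+", teStart = 0L, teEnd = 50L, score = 50, identity = 1)
  ord <- order(as.character(GenomicRanges::seqnames(gr)), BiocGenerics::start(gr))
  gr[ord]
}

fixedStats <- list(mean = 500, sd = 50, readLen = 100L)  # ext = 650

test_that("insert-size estimation matches closed forms", {
  set.seed(21)
  mk <- function(tlens) {
    recs <- unlist(lapply(seq_along(tlens), function(i) {
      p1 <- 1000L + 37L * i
      p2 <- p1 + tlens[i] - 100L
      c(samLine(sprintf("t%04d", i), 99, "chr1", p1, 60, "100M", "=", p2, tlens[i], randDna(100)),
        samLine(sprintf("t%04d", i), 147, "chr1", p2, 60, "100M", "=", p1, -tlens[i], randDna(100)))
    }))
    makeBam(recs, c(chr1 = 100000L))
  }
  s1 <- estimateInsertSize(mk(rep(500L, 120)))
  expect_equal(s1$mean, 500)
  expect_equal(s1$sd, 0)
  expect_equal(s1$readLen, 100L)
  s2 <- estimateInsertSize(mk(rep(c(400L, 600L), 60)))
  expect_equal(s2$mean, 500)
  expect_equal(s2$sd, 100)   # population form, exactly 100
  expect_error(estimateInsertSize(mk(rep(500L, 10))), "too few")
})

test_that("insert-size parameters are recovered from simulated data", {
  fx <- smallSimFixture()
  st <- estimateInsertSize(fx$ds$bam)
  n <- 10000
  expect_lt(abs(st$mean - fx$scfg$insertMean), 3 * fx$scfg$insertSd / sqrt(n))
  expect_lt(abs(st$sd - fx$scfg$insertSd), 5)
  expect_equal(st$readLen, fx$scfg$readLen)
})

test_that("cluster validity requires support and two flanks or clips", {
  ## a single record never clusters at minSupport 2
  cfg <- meiConfig(minSupport = 2L)
  ev1 <- mkEvidence("chr1", 5000L, "left")
  expect_equal(length(clusterEvidence(ev1, fixedStats, cfg)), 0L)

  ## 3 left + 3 right anchored records at one locus: one cluster of all 6
  ev6 <- mkEvidence("chr1", c(4500L, 4600L, 4700L, 5300L, 5400L, 5500L),
                    c("left", "left", "left", "right", "right", "right"))
  cl <- clusterEvidence(ev6, fixedStats, cfg)
  expect_equal(length(cl), 1L)
  expect_equal(S4Vectors::mcols(cl)$nSupport, 6L)
  expect_equal(S4Vectors::mcols(cl)$leftSupport, 3L)
  expect_equal(S4Vectors::mcols(cl)$rightSupport, 3L)
  expect_equal(S4Vectors::mcols(cl)$familyVote, "Alu")

  ## left-only support is rescued by clip evidence
  evClip <- mkEvidence("chr1", c(4500L, 4600L, 4700L), "left",
                       clipPos = c(5000L, 5000L, NA), category = "CLIP_PAIR")
  S4Vectors::mcols(evClip)$clippedSeq <- c(strrep("G", 25), strrep("G", 25), NA)
  clc <- clusterEvidence(evClip, fixedStats, meiConfig(minSupport = 3L,
                                                       minClipSupport = 2L))
  expect_equal(length(clc), 1L)

  ## unsorted evidence is rejected
  expect_error(clusterEvidence(rev(ev6), fixedStats, cfg), "sorted")
})

test_that("family votes tie to 'ambiguous'", {
  ev <- mkEvidence("chr1", c(4500L, 4600L, 5300L, 5400L),
                   c("left", "left", "right", "right"),
                   family = c("Alu", "Alu", "L1", "L1"))
  cl <- clusterEvidence(ev, fixedStats, meiConfig(minSupport = 2L))
  expect_equal(S4Vectors::mcols(cl)$familyVote, "ambiguous")
})

test_that("clustering equals the interval-graph connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(33)
  ## ~50 records at 4 well-separated loci on a toy chromosome
  loci <- c(10000L, 18000L, 30000L, 52000L)
  starts <- integer(0); sides <- character(0)
  for (p in loci) {
    nl <- sample(4:8, 1); nr <- sample(4:8, 1)
    starts <- c(starts, p - sample(100:600, nl, TRUE), p + sample(1:500, nr, TRUE))
    sides <- c(sides, rep("left", nl), rep("right", nr))
  }
  ord <- order(starts)
  ev <- mkEvidence("chr1", starts[ord], sides[ord])
  cfg <- meiConfig(minSupport = 1L, minClipSupport = 1L)
  cl <- clusterEvidence(ev, fixedStats, cfg, allClusters = TRUE)
  got <- lapply(S4Vectors::mcols(cl)$members, sort)
  want <- clusterOracle(ev, fixedStats, cfg)
  expect_equal(length(got), length(want))
  expect_equal(got[order(vapply(got, min, 0L))], want[order(vapply(want, min, 0L))],
               ignore_attr = TRUE)
})

test_that("finalization releases a cluster only when out of reach", {
  cl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9001, 10000))
  st <- list(mean = 500, sd = 50, readLen = 100L)
  expect_false(finalizeReady(cl, 10200L, st))    # 10200 <= 10000 + 650
  expect_false(finalizeReady(cl, 10650L, st))
  expect_true(finalizeReady(cl, 10651L, st))
  expect_equal(finalizeReady(cl[0], 1L, st), logical(0))
})

test_that("streaming clustering equals batch clustering", {
  fx <- smallSimFixture()
  ev <- scanDiscordant(fx$ds$bam, fx$lib, meiConfig())
  st <- estimateInsertSize(fx$ds$bam)
  batch <- clusterEvidence(ev, st, meiConfig())
  for (chunk in c(7L, 50L)) {
    stream <- clusterEvidenceStream(ev, st, meiConfig(), chunkSize = chunk)
    expect_equal(length(stream), length(batch))
    expect_equal(BiocGenerics::start(stream), BiocGenerics::start(batch))
    expect_equal(BiocGenerics::end(stream), BiocGenerics::end(batch))
    expect_equal(lapply(S4Vectors::mcols(stream)$members, sort),
                 lapply(S4Vectors::mcols(batch)$members, sort))
  }
})

test_that("valid cluster windows do not overlap and contain their members", {
  fx <- smallSimFixture()
  ev <- scanDiscordant(fx$ds$bam, fx$lib, meiConfig())
  st <- estimateInsertSize(fx$ds$bam)
  cl <- clusterEvidence(ev, st, meiConfig())
  bychr <- split(seq_along(cl), as.character(GenomicRanges::seqnames(cl)))
  for (ii in bychr) {
    if (length(ii) < 2L) next
    s <- BiocGenerics::start(cl)[ii]; e <- BiocGenerics::end(cl)[ii]
    o <- order(s)
    expect_true(all(s[o][-1] > e[o][-length(e)]))
  }
  ## members' anchor positions lie within (or at) the cluster window
  for (i in seq_along(cl)) {
    mem <- S4Vectors::mcols(cl)$members[[i]]
    expect_true(all(as.character(GenomicRanges::seqnames(ev))[mem] ==
                    as.character(GenomicRanges::seqnames(cl))[i]))
  }
})
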
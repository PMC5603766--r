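## shared scaffolding: a fixed reference window
bpWin <- function(seed = 61, len = 3000L) {
  set.seed(seed)
  refStr <- randDna(len)
  list(chrom = "chr1", offset = 0L, seq = refStr)
}

refAt <- function(win, lo, hi) substr(win$seq, lo + 1L, hi)  # 0-based half-open

mkReads <- function(pos, cigar, seq) {
  data.frame(qname = sprintf("r%03d", seq_along(pos)), chrom = "chr1",
             pos = pos, mapq = 60L, cigar = cigar, seq = seq,
             isReverse = FALSE, stringsAsFactors = FALSE)
}

test_that("region read collection follows the overlap rule", {
  set.seed(62)
  recs <- c(
    samLine("a", 99, "chr1", 151, 60, "100M", "=", 151, 0, randDna(100)),  # [150,250)
    samLine("b", 99, "chr1", 951, 60, "100M", "=", 951, 0, randDna(100)),  # outside
    samLine("c", 99, "chr1", 81, 60, "100M", "=", 81, 0, randDna(100)))    # [80,180)
  bam <- makeBam(recs, c(chr1 = 5000L))
  cluster <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  got <- collectRegionReads(bam, cluster)
  expect_setequal(got$qname, c("a", "c"))
  empty <- collectRegionReads(bam, GenomicRanges::GRanges("chr1", IRanges::IRanges(3001, 3100)))
  expect_equal(nrow(empty), 0L)
  ## counts equal an independent whole-file overlap scan
  all <- MEIdetect:::readBamRecords(bam, NULL)
  manual <- sum(all$pos < 200L & all$pos + 100L > 100L)
  expect_equal(nrow(got), manual)
})

test_that("co-located soft clips aggregate into one supported clip point", {
  win <- bpWin()
  set.seed(63)
  clipSeq <- randDna(40)
  reads <- mkReads(rep(940L, 5),
                   rep("60M40S", 5),
                   paste0(refAt(win, 940L, 1000L), clipSeq))
  cp <- recalibrateClips(reads, win, meiConfig())
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$pos, 1000L)
  expect_equal(cp$side, "R")
  expect_equal(cp$support, 5L)
  expect_equal(cp$clippedSeqs[[1]], rep(clipSeq, 5))
})

test_that("mostly-mismatching read terminals are rescued as synthetic clips", {
  win <- bpWin()
  ## read aligned 100M at 900, last 10 bases carry 7 mismatches
  refPart <- refAt(win, 900L, 1000L)
  ch <- strsplit(refPart, "")[[1]]
  mmAt <- c(91, 92, 94, 95, 97, 98, 100)            # 7 of the last 10
  for (p in mmAt) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  reads <- mkReads(900L, "100M", paste(ch, collapse = ""))
  cp <- recalibrateClips(reads, win, meiConfig())
  resc <- cp[cp$side == "R", , drop = FALSE]
  expect_equal(nrow(resc), 1L)
  ## synthetic clip at the first mismatch of the terminal run: base 91
  expect_equal(resc$pos, 900L + 90L)
  ## a clean read end is not rescued
  clean <- mkReads(900L, "100M", refPart)
  expect_equal(nrow(recalibrateClips(clean, win, meiConfig())), 0L)
})

test_that("small deletions collapse to the breakpoint found by realignment", {
  win <- bpWin()
  ## true clip at 1080: 80 reference bases, then 20 TE-derived bases the
  ## aligner forced into 3D + 20M
  refPart <- refAt(win, 1000L, 1080L)
  set.seed(64)
  tail <- strsplit(randDna(20), "")[[1]]
  refCont <- strsplit(refAt(win, 1083L, 1103L), "")[[1]]
  for (k in 1:20) if (tail[k] == refCont[k])
    tail[k] <- setdiff(c("A", "C", "G", "T"), refCont[k])[1]
  readSeq <- paste0(refPart, paste(tail, collapse = ""))
  reads <- mkReads(1000L, "80M3D20M", readSeq)
  cp <- recalibrateClips(reads, win, meiConfig())
  expect_equal(cp$side, "R")
  ## independent oracle: local realignment of the read to the window; the
  ## alignment ends where the reference-derived part of the read ends
  pa <- Biostrings::pairwiseAlignment(
    readSeq, refAt(win, 1000L, 1200L), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
    gapOpening = 5, gapExtension = 2)
  oracleEnd <- 1000L + BiocGenerics::end(Biostrings::subject(pa))
  expect_equal(cp$pos, oracleEnd)
  expect_equal(cp$pos, 1080L)
})

test_that("clip validation needs a discordant majority", {
  win <- bpWin()
  set.seed(65)
  refCont <- refAt(win, 1000L, 1030L)
  disc <- replicate(6, randDna(30))
  conc <- rep(refCont, 4)
  cp6 <- list(pos = 1000L, side = "R", clippedSeqs = c(disc, conc),
              alignedFlank = refAt(win, 990L, 1000L))
  expect_true(validateClipPoint(cp6, win, meiConfig()))
  cp5 <- list(pos = 1000L, side = "R", clippedSeqs = c(disc[1:5], conc, refCont),
              alignedFlank = refAt(win, 990L, 1000L))
  expect_false(validateClipPoint(cp5, win, meiConfig()))   # 5 of 10: not > half
})

test_that("a sloppy junction fails unless the clip is a poly-A/T tail", {
  win <- bpWin()
  set.seed(66)
  badFlank <- paste(vapply(strsplit(refAt(win, 990L, 1000L), "")[[1]],
                           function(b) setdiff(c("A", "C", "G", "T"), b)[1], ""),
                    collapse = "")   # 10 junction-adjacent mismatches
  disc <- replicate(4, randDna(30))
  cp <- list(pos = 1000L, side = "R", clippedSeqs = disc, alignedFlank = badFlank)
  expect_false(validateClipPoint(cp, win, meiConfig()))
  polyA <- replicate(4, paste0(strrep("A", 25), randDna(5)))
  cpA <- list(pos = 1000L, side = "R", clippedSeqs = polyA, alignedFlank = badFlank)
  expect_true(validateClipPoint(cpA, win, meiConfig()))
})

test_that("rule one is monotone in discordant support", {
  win <- bpWin()
  set.seed(67)
  seqs <- replicate(6, randDna(30))
  cp <- list(pos = 1200L, side = "R", clippedSeqs = seqs,
             alignedFlank = refAt(win, 1190L, 1200L))
  expect_true(validateClipPoint(cp, win, meiConfig()))
  for (k in 1:4) {
    cp$clippedSeqs <- c(cp$clippedSeqs, randDna(30))
    expect_true(validateClipPoint(cp, win, meiConfig()))
  }
})

test_that("breakpoints and TSD follow the two-clip geometry", {
  win <- bpWin()
  clips <- data.frame(pos = c(1012L, 1000L), side = c("R", "L"),
                      support = c(5L, 4L), stringsAsFactors = FALSE)
  clips$clippedSeqs <- list(rep("G", 5), rep("C", 4))
  clips$alignedFlank <- c("", "")
  bp <- callBreakpointsTsd(clips, win, meiConfig())
  expect_equal(bp$bpLeft, 1012L)
  expect_equal(bp$bpRight, 1000L)
  expect_equal(bp$insertionPos, 1000L)
  expect_equal(bp$tsdSeq, refAt(win, 1000L, 1012L))
  expect_equal(nchar(bp$tsdSeq), 12L)

  ## blunt insertion: both clips at the same point, empty TSD
  clips2 <- clips; clips2$pos <- c(1000L, 1000L)
  bp2 <- callBreakpointsTsd(clips2, win, meiConfig())
  expect_equal(bp2$tsdSeq, "")

  ## separation beyond tsdMax keeps the call but drops the TSD
  clips3 <- clips; clips3$pos <- c(1100L, 1000L)
  bp3 <- callBreakpointsTsd(clips3, win, meiConfig())
  expect_true(bp3$flag)
  expect_true(is.na(bp3$tsdSeq))
})

test_that("genotyping thresholds the reference-allele fraction", {
  cfg <- meiConfig()
  expect_equal(genotypeCall(0L, 12L, cfg), "HOM")
  expect_equal(genotypeCall(10L, 10L, cfg), "HET")
  expect_equal(genotypeCall(1L, 9L, cfg), "HOM")     # ref fraction 0.10 <= 0.15
  expect_equal(genotypeCall(3L, 9L, cfg), "HET")     # ref fraction 0.25
  expect_error(genotypeCall(0L, 0L, cfg), "undefined")
})

test_that("recovered TSDs are reference substrings and breakpoints are near truth", {
  fx <- smallCallsFixture()
  calls <- fx$calls
  m <- S4Vectors::mcols(calls)
  expect_true(length(calls) > 0L)
  for (i in seq_along(calls)) {
    if (is.na(m$tsdSeq[i]) || is.na(m$bpLeft[i]) || is.na(m$bpRight[i])) next
    ch <- as.character(GenomicRanges::seqnames(calls))[i]
    want <- as.character(Biostrings::subseq(fx$ref[[ch]], m$bpRight[i] + 1L, m$bpLeft[i]))
    expect_equal(m$tsdSeq[i], want)
  }
  ## each matched call's left breakpoint is within 5 bp of the planted point
  rep <- matchCalls(calls, fx$ds$truth)
  tm <- S4Vectors::mcols(fx$ds$truth)
  for (k in seq_len(nrow(rep$pairs))) {
    i <- rep$pairs$call[k]; j <- rep$pairs$truth[k]
    if (is.na(m$bpLeft[i])) next
    expect_lte(abs(m$bpLeft[i] - tm$pos0[j]), 5L)
  }
})
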
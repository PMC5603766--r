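simLib <- function() bundledTELibrary()

test_that("planting is seed-deterministic and length-conserving", {
  lib <- simLib()
  ref <- makeReference(2e5, 1, seed = 3)
  cfg <- simConfig(nInsertions = 3L, seed = 9)
  s1 <- plantInsertions(ref, lib, cfg)
  s2 <- plantInsertions(ref, lib, cfg)
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  expect_identical(as.character(s1$haplotypes$hap1), as.character(s2$haplotypes$hap1))
  expect_equal(length(s1$truth), 3L)

  m <- S4Vectors::mcols(s1$truth)
  novel <- m$lengthBp + m$polyALen + m$tsdLen
  expect_equal(sum(Biostrings::width(s1$haplotypes$hap1)),
               sum(Biostrings::width(ref)) + sum(novel))
  expect_equal(sum(Biostrings::width(s1$haplotypes$hap2)),
               sum(Biostrings::width(ref)) + sum(novel[m$zygosity == "HOM"]))
})

test_that("each planted block reconstructs exactly from its truth record", {
  lib <- simLib()
  ref <- makeReference(3e5, 2, seed = 4)
  cfg <- simConfig(nInsertions = 6L, seed = 10)
  s <- plantInsertions(ref, lib, cfg)
  m <- S4Vectors::mcols(s$truth)
  for (ch in names(ref)) {
    ii <- which(as.character(GenomicRanges::seqnames(s$truth)) == ch)
    if (!length(ii)) next
    hap <- as.character(s$haplotypes$hap1[[ch]])
    shift <- 0L
    for (i in ii) {
      cons <- as.character(consensusSeqs(lib)[[paste0(m$family[i], "#", m$subfamily[i])]])
      te <- substr(cons, nchar(cons) - m$lengthBp[i] + 1L, nchar(cons))
      core <- paste0(te, strrep("A", m$polyALen[i]))
      if (m$orientation[i] == "-")
        core <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(core)))
      tsd <- substr(as.character(ref[[ch]]), m$pos0[i] - m$tsdLen[i] + 1L, m$pos0[i])
      expectBlock <- paste0(core, tsd)
      got <- substr(hap, m$pos0[i] + shift + 1L, m$pos0[i] + shift + nchar(expectBlock))
      expect_identical(got, expectBlock)
      shift <- shift + nchar(expectBlock)
    }
  }
})

test_that("read sampling matches the configured coverage and error rate", {
  lib <- simLib()
  ref <- makeReference(2e5, 1, seed = 5)
  cfg <- simConfig(nInsertions = 2L, depth = 10, errorRate = 0, seed = 11)
  s <- plantInsertions(ref, lib, cfg)
  reads <- generateReads(s, cfg)
  hapBases <- sum(Biostrings::width(s$haplotypes$hap1)) +
              sum(Biostrings::width(s$haplotypes$hap2))
  expect_lt(abs(nrow(reads) - 10 * hapBases / (2 * 2 * 100)) / nrow(reads), 0.01)

  ## error-free reads are exact haplotype substrings
  set.seed(1)
  for (k in sample(nrow(reads), 25)) {
    hap <- as.character(s$haplotypes[[reads$hap[k]]][[reads$chrom[k]]])
    expect_identical(reads$seqLeft[k],
                     substr(hap, reads$fragStart[k] + 1L, reads$fragStart[k] + 100L))
    expect_identical(reads$seqRight[k],
                     substr(hap, reads$fragEnd[k] - 99L, reads$fragEnd[k]))
  }

  ## empirical mismatch rate at errorRate 0.001 within its binomial 99% CI
  cfgE <- simConfig(nInsertions = 2L, depth = 10, errorRate = 0.001, seed = 11)
  sE <- plantInsertions(ref, lib, cfgE)
  rE <- generateReads(sE, cfgE)
  take <- seq_len(min(4000L, nrow(rE)))
  mm <- 0L; tot <- 0L
  for (k in take) {
    hap <- as.character(sE$haplotypes[[rE$hap[k]]][[rE$chrom[k]]])
    a <- strsplit(rE$seqLeft[k], "")[[1]]
    b <- strsplit(substr(hap, rE$fragStart[k] + 1L, rE$fragStart[k] + 100L), "")[[1]]
    mm <- mm + sum(a != b); tot <- tot + 100L
  }
  p <- mm / tot
  ci <- 2.58 * sqrt(0.001 * 0.999 / tot)
  expect_lt(abs(p - 0.001), ci + 1e-9)
})

test_that("FASTQ and truth outputs are byte-identical across runs of one seed", {
  lib <- simLib()
  ref <- makeReference(1.5e5, 1, seed = 6)
  cfg <- simConfig(nInsertions = 2L, depth = 4, seed = 12)
  out <- replicate(2, {
    s <- plantInsertions(ref, lib, cfg)
    reads <- generateReads(s, cfg)
    pre <- tempfile()
    writeFastq(reads, pre)
    tr <- tempfile()
    writeTruth(s$truth, tr)
    list(fq1 = readLines(paste0(pre, "_1.fq")), fq2 = readLines(paste0(pre, "_2.fq")),
         truth = readLines(tr))
  }, simplify = FALSE)
  expect_identical(out[[1]], out[[2]])
})

test_that("truth tables round-trip through the BED writer", {
  lib <- simLib()
  ref <- makeReference(2e5, 1, seed = 7)
  s <- plantInsertions(ref, lib, simConfig(nInsertions = 3L, seed = 13))
  path <- tempfile()
  writeTruth(s$truth, path)
  back <- readTruth(path)
  keep <- c("pos0", "family", "subfamily", "orientation", "lengthBp", "tsdLen", "zygosity")
  expect_equal(as.data.frame(S4Vectors::mcols(back)[, keep]),
               as.data.frame(S4Vectors::mcols(s$truth)[, keep]))
  ## an empty truth set writes a header-only file
  p0 <- tempfile()
  writeTruth(s$truth[0], p0)
  expect_equal(length(readLines(p0)), 1L)
  expect_equal(length(readTruth(p0)), 0L)
})

test_that("the provenance aligner emits junction soft clips and TSD-aware placement", {
  fx <- smallSimFixture()
  b <- MEIdetect:::readBamRecords(fx$ds$bam, NULL)
  m <- S4Vectors::mcols(fx$ds$truth)
  tChrom <- as.character(GenomicRanges::seqnames(fx$ds$truth))
  clipped <- grepl("S", b$cigar)
  expect_true(any(clipped))
  ## right-end clips sit exactly at insertion points; left-end clips at the
  ## TSD-shifted point
  rc <- MEIdetect:::rightClipLen(b$cigar) > 0L
  ends <- b$pos + MEIdetect:::refSpanWidth(b$cigar)
  for (i in seq_along(fx$ds$truth)) {
    here <- rc & b$chrom == tChrom[i] & abs(ends - m$pos0[i]) < 3L
    expect_true(any(ends[here] == m$pos0[i]))
    lc <- MEIdetect:::leftClipLen(b$cigar) > 0L & b$chrom == tChrom[i] &
      abs(b$pos - (m$pos0[i] - m$tsdLen[i])) < 3L
    expect_true(any(b$pos[lc] == m$pos0[i] - m$tsdLen[i]))
  }
  ## mapped reads away from insertions are perfect reference copies
  refStr <- lapply(fx$ref, as.character)
  full <- which(b$cigar == "100M" & !b$isUnmapped)
  set.seed(2)
  ok <- 0L
  for (k in sample(full, 50)) {
    nearIns <- any(tChrom == b$chrom[k] & abs(m$pos0 - b$pos[k]) < 800)
    if (nearIns) next
    want <- substr(refStr[[b$chrom[k]]], b$pos[k] + 1L, b$pos[k] + 100L)
    mm <- sum(strsplit(b$seq[k], "")[[1]] != strsplit(want, "")[[1]])
    expect_lte(mm, 3L)   # only sequencing errors
    ok <- ok + 1L
  }
  expect_gt(ok, 10L)
})
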
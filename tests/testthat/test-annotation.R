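test_that("greedy assembly merges overlaps and reconstructs tilings", {
  expect_equal(assembleContigs("ACGTACGT")$seq, "ACGTACGT")
  got <- assembleContigs(c("ACGTAC", "GTACGG"), minOverlap = 4L)
  expect_equal(got$seq, "ACGTACGG")
  expect_equal(got$nReads, 2L)

  ## contained sequences are absorbed
  got2 <- assembleContigs(c("ACGTACGTACGTACGTACGTACGT", "TACGTACG"), minOverlap = 4L)
  expect_equal(got2$seq, "ACGTACGTACGTACGTACGTACGT")

  ## 20 error-free 100-mers tiling a 400 bp sequence reassemble it exactly
  set.seed(71)
  te <- randDna(400)
  starts <- sort(c(1L, sample(2:300, 18), 301L))
  reads <- substring(te, starts, starts + 99L)
  out <- assembleContigs(reads, minOverlap = 20L)
  expect_equal(out$seq[1], te)
})

test_that("assembly is deterministic under input permutation", {
  set.seed(72)
  te <- randDna(300)
  starts <- c(1, 60, 120, 180, 201)
  reads <- substring(te, starts, starts + 99L)
  a <- assembleContigs(reads, 20L)
  b <- assembleContigs(rev(reads), 20L)
  expect_identical(a, b)
})

test_that("subfamily assignment uses diagnostic sites with score tie-breaks", {
  lib <- bundledTELibrary()
  diag <- as.data.frame(diagnostics(lib))
  ya5 <- diag[diag$subfamily == "AluYa5", ]
  cons <- as.character(consensusSeqs(lib)[["Alu#AluYa5"]])
  ## a substring covering at least three AluYa5 diagnostic sites
  lo <- min(ya5$consensus_pos[1:3]) + 1L
  hi <- max(ya5$consensus_pos[1:3]) + 1L
  frag <- substr(cons, max(1L, lo - 20L), min(nchar(cons), hi + 20L))
  ann <- annotateSubfamily(frag, lib)
  expect_equal(ann$family, "Alu")
  expect_equal(ann$subfamily, "AluYa5")
  expect_gte(ann$matchedDiagnostics, 3L)
  expect_equal(ann$matchedDiagnostics, ann$totalDiagnostics)
})

test_that("a fragment covering no diagnostic column is family-level only", {
  set.seed(73)
  ## a family with diagnostics far from the probe region
  base <- randDna(400)
  mut <- function(s, pos, to) { x <- strsplit(s, "")[[1]]; x[pos] <- to; paste(x, collapse = "") }
  lib <- makeLibrary(list("Alu#u" = mut(base, 10, "A"), "Alu#v" = mut(base, 20, "C")))
  frag <- substr(base, 101, 300)   # clear of columns 10/20
  ann <- annotateSubfamily(frag, lib)
  expect_equal(ann$family, "Alu")
  expect_equal(ann$subfamily, "unresolved")
  ## and an unalignable contig is unknown
  expect_equal(annotateSubfamily(randDna(80), lib)$family, "unknown")
})

test_that("one off-diagnostic substitution does not change the subfamily call", {
  lib <- bundledTELibrary()
  diag <- as.data.frame(diagnostics(lib))
  yb8 <- diag[diag$subfamily == "AluYb8", ]
  cons <- as.character(consensusSeqs(lib)[["Alu#AluYb8"]])
  set.seed(74)
  for (rep in 1:4) {
    frag <- substr(cons, 1, 250)
    at <- sample(setdiff(seq_len(250), diag$consensus_pos + 1L), 1)
    ch <- strsplit(frag, "")[[1]]
    ch[at] <- sample(setdiff(c("A", "C", "G", "T"), ch[at]), 1)
    frag <- paste(ch, collapse = "")
    ann <- annotateSubfamily(frag, lib)
    ## oracle: exhaustive per-subfamily diagnostic check over the fragment
    expect_equal(ann$subfamily, "AluYb8")
    expect_equal(ann$matchedDiagnostics, sum(yb8$consensus_pos < 250))
  }
})

test_that("subfamily identification works for any diagnostic-covering substring", {
  lib <- bundledTELibrary()
  diag <- as.data.frame(diagnostics(lib))
  set.seed(75)
  for (sub in c("AluSx1", "L1PA2", "SVA_F")) {
    d <- diag[diag$subfamily == sub, ]
    fam <- d$family[1]
    cons <- as.character(consensusSeqs(lib)[[paste0(fam, "#", sub)]])
    p <- d$consensus_pos[sample(nrow(d), 1)] + 1L
    frag <- substr(cons, max(1, p - 60L), min(nchar(cons), p + 60L))
    expect_equal(annotateSubfamily(frag, lib)$subfamily, sub)
  }
})

test_that("orientation voting honors ties and tail contradiction", {
  expect_equal(annotateOrientation(rep("+", 5),
                                   rightJunctionSeq = paste0(randDna(10), strrep("A", 10))),
               "+")
  expect_equal(annotateOrientation(c("+", "+", "+", "-", "-", "-")), "unknown")
  expect_equal(annotateOrientation(c("-", "-", "-")), "-")
  ## a single-vote margin with a contradicting tail collapses to unknown
  set.seed(76)
  expect_equal(annotateOrientation(c("+", "+", "-"),
                                   leftJunctionSeq = paste0(strrep("T", 12), randDna(10))),
               "unknown")
  ## with a strong margin the vote stands
  expect_equal(annotateOrientation(rep("+", 6),
                                   leftJunctionSeq = paste0(strrep("T", 12), randDna(10))),
               "+")
})

test_that("inserted length is the consensus span, not the coverage", {
  l1 <- annotateLength(1L, 280L)
  expect_equal(l1$lRetro, 280L)
  l2 <- annotateLength(c(1L, 181L), c(100L, 280L))
  expect_equal(l2$lRetro, 280L)   # span across a coverage gap
  expect_error(annotateLength(NA_integer_, NA_integer_))
})

test_that("orientation flips when all evidence is reverse-complemented", {
  fx <- smallCallsFixture()
  m <- S4Vectors::mcols(fx$calls)
  tm <- S4Vectors::mcols(fx$ds$truth)
  rep <- matchCalls(fx$calls, fx$ds$truth)
  expect_true(nrow(rep$pairs) > 0L)
  ## simulated insertions of both orientations are annotated correctly,
  ## which exercises both strand directions of the same voting rule
  oriCalled <- m$orientation[rep$pairs$call]
  oriTrue <- tm$orientation[rep$pairs$truth]
  ok <- oriCalled != "unknown"
  expect_true(all(oriCalled[ok] == oriTrue[ok]))
  expect_true(any(oriTrue == "+") && any(oriTrue == "-"))
})

test_that("annotated lengths track planted truncations and never exceed the consensus", {
  fx <- smallCallsFixture()
  lib <- fx$lib
  m <- S4Vectors::mcols(fx$calls)
  tm <- S4Vectors::mcols(fx$ds$truth)
  rep <- matchCalls(fx$calls, fx$ds$truth)
  consLen <- stats::setNames(Biostrings::width(consensusSeqs(lib)), teSubfamilies(lib))
  for (k in seq_len(nrow(rep$pairs))) {
    i <- rep$pairs$call[k]; j <- rep$pairs$truth[k]
    if (is.na(m$lengthBp[i])) next
    expect_lte(m$lengthBp[i], consLen[[tm$subfamily[j]]])
    ## dense error-free-ish evidence: recovered length within 35 bp of truth
    ## (junction clips bound both ends; the poly-A tail blurs the 3' end)
    expect_lte(abs(m$lengthBp[i] - tm$lengthBp[j]), 35L)
  }
})
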
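## TE-insertion read simulator: plants insertions (TSD, poly-A tail,
## 5'-truncation, zygosity) into a reference, samples paired-end fragments
## with substitution errors, and emits FASTQ plus a ground-truth table.
## A built-in provenance aligner turns the simulated reads into a
## soft-clip-aware coordinate-sorted BAM without any external binary.

#' Simulation configuration
#'
#' Defaults encode the simulated study conditions: paired-end 100 bp reads,
#' insert size 500 +/- 50 bp, 0.1\% substitution error, TSDs of 5-20 bp,
#' poly-A tails of 8-30 bp on the non-LTR families, Alu/SVA/LTR inserted
#' full-length with probability 0.7 (else uniformly 5'-truncated), L1
#' 5'-truncated with probability 0.8, and half of the insertions
#' heterozygous.
#'
#' @param nInsertions Number of insertions to plant.
#' @param depth Total fold-coverage (split over the two haplotypes).
#' @param readLen Read length in bp.
#' @param insertMean,insertSd Fragment-length distribution (bp).
#' @param errorRate Per-base substitution error rate.
#' @param hetFraction Fraction of insertions that are heterozygous
#'   (assigned exactly: \code{round(hetFraction * n)} loci).
#' @param tsdRange,polyARange Uniform ranges (bp).
#' @param fullLengthProb Probability an Alu/SVA/LTR insertion is
#'   full-length.
#' @param l1FullLengthProb Probability an L1 insertion is full-length.
#' @param minTeLen Minimum inserted TE length after truncation.
#' @param minGap Minimum distance between planted insertions.
#' @param seed Integer seed; every downstream step derives from it.
#' @return A list of class \code{simConfig}.
#' @export
simConfig <- function(nInsertions = 150L, depth = 30, readLen = 100L,
                      insertMean = 500, insertSd = 50, errorRate = 0.001,
                      hetFraction = 0.5, tsdRange = c(5L, 20L),
                      polyARange = c(8L, 30L), fullLengthProb = 0.7,
                      l1FullLengthProb = 0.2, minTeLen = 50L,
                      minGap = 2000L, seed = 1L) {
  stopifnot(depth > 0, readLen <= insertMean, errorRate >= 0, errorRate < 0.1)
  structure(list(nInsertions = as.integer(nInsertions), depth = depth,
                 readLen = as.integer(readLen), insertMean = insertMean,
                 insertSd = insertSd, errorRate = errorRate,
                 hetFraction = hetFraction, tsdRange = as.integer(tsdRange),
                 polyARange = as.integer(polyARange),
                 fullLengthProb = fullLengthProb,
                 l1FullLengthProb = l1FullLengthProb,
                 minTeLen = as.integer(minTeLen), minGap = as.integer(minGap),
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Generate a random synthetic reference genome
#'
#' @param totalLen Total length in bp.
#' @param nChrom Number of chromosomes (equal sizes).
#' @param seed Integer seed.
#' @return A named \code{DNAStringSet} (chr1, chr2, ...).
#' @export
makeReference <- function(totalLen = 5e6, nChrom = 2L, seed = 1L) {
  set.seed(seed)
  per <- as.integer(ceiling(totalLen / nChrom))
  seqs <- vapply(seq_len(nChrom), function(i)
    paste(sample(c("A", "C", "G", "T"), per, replace = TRUE), collapse = ""), "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(nChrom))
  out
}

revcompStr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Plant TE insertions into a reference
#'
#' Positions are uniform, at least \code{minGap} apart and clear of the
#' chromosome ends. Each inserted block is the (possibly 5'-truncated,
#' possibly reverse-complemented) TE sequence plus its poly-A tail plus a
#' copy of the reference bases immediately left of the insertion point (the
#' TSD). Heterozygous insertions go into haplotype 1 only, homozygous into
#' both. Deterministic for a given seed.
#'
#' @param reference Named \code{DNAStringSet}.
#' @param library A \code{\link{TELibrary}}.
#' @param cfg A \code{\link{simConfig}}.
#' @return List: \code{haplotypes} (list of two \code{DNAStringSet}s),
#'   \code{truth} (\code{GRanges}, 0-based insertion point in
#'   \code{mcols()$pos0}), \code{maps} (per-haplotype liftover tables used
#'   by \code{\link{perfectAlign}}).
#' @export
plantInsertions <- function(reference, library, cfg = simConfig()) {
  if (length(library) == 0L) stop("TE library is empty")
  if (sum(Biostrings::width(reference)) < 1e5)
    stop("reference too short for simulation (need >= 100 kb)")
  set.seed(cfg$seed)
  n <- cfg$nInsertions
  chromLens <- Biostrings::width(reference)
  names(chromLens) <- names(reference)
  edge <- 1000L
  ## rejection-sample positions >= minGap apart
  posChrom <- character(n); posRef <- integer(n)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 200L * n) stop("could not place ", n, " insertions >= ",
                               cfg$minGap, " bp apart on this reference")
    ch <- sample(names(chromLens), 1L, prob = chromLens)
    p <- sample.int(chromLens[[ch]] - 2L * edge, 1L) + edge  # 0-based point
    same <- posChrom[seq_len(placed)] == ch
    if (any(same) && min(abs(posRef[seq_len(placed)][same] - p)) < cfg$minGap) next
    placed <- placed + 1L
    posChrom[placed] <- ch; posRef[placed] <- p
  }
  ord <- order(posChrom, posRef)
  posChrom <- posChrom[ord]; posRef <- posRef[ord]

  recs <- sample.int(length(library), n, replace = TRUE)
  fams <- teFamilies(library)[recs]
  subs <- teSubfamilies(library)[recs]
  consLen <- Biostrings::width(consensusSeqs(library))[recs]
  fullProb <- ifelse(fams == "L1", cfg$l1FullLengthProb, cfg$fullLengthProb)
  isFull <- stats::runif(n) < fullProb
  lengthBp <- integer(n)
  for (i in seq_len(n)) {
    lengthBp[i] <- if (isFull[i]) consLen[i]
      else sample(seq(cfg$minTeLen, consLen[i]), 1L)
  }
  orientation <- sample(c("+", "-"), n, replace = TRUE)
  tsdLen <- sample(seq(cfg$tsdRange[1], cfg$tsdRange[2]), n, replace = TRUE)
  polyALen <- ifelse(fams == "LTR", 0L,
                     sample(seq(cfg$polyARange[1], cfg$polyARange[2]), n, replace = TRUE))
  nHet <- round(cfg$hetFraction * n)
  zygosity <- sample(c(rep("HET", nHet), rep("HOM", n - nHet)))

  novel <- character(n)
  for (i in seq_len(n)) {
    cons <- as.character(consensusSeqs(library)[[recs[i]]])
    L <- consLen[i]
    te <- substr(cons, L - lengthBp[i] + 1L, L)      # 5'-truncation keeps the 3' end
    core <- paste0(te, strrep("A", polyALen[i]))
    if (orientation[i] == "-") core <- revcompStr(core)
    tsdSeq <- if (tsdLen[i] > 0L)
      as.character(Biostrings::subseq(reference[[posChrom[i]]],
                                      posRef[i] - tsdLen[i] + 1L, posRef[i]))
      else ""
    novel[i] <- paste0(core, tsdSeq)
  }
  novelLen <- nchar(novel)

  buildHap <- function(sel) {
    out <- lapply(names(reference), function(ch) {
      refStr <- as.character(reference[[ch]])
      ii <- which(sel & posChrom == ch)
      if (!length(ii)) return(refStr)
      p <- posRef[ii]
      pieces <- character(2L * length(ii) + 1L)
      prev <- 0L
      for (k in seq_along(ii)) {
        pieces[2L * k - 1L] <- substr(refStr, prev + 1L, p[k])
        pieces[2L * k] <- novel[ii[k]]
        prev <- p[k]
      }
      pieces[2L * length(ii) + 1L] <- substr(refStr, prev + 1L, nchar(refStr))
      paste(pieces, collapse = "")
    })
    hs <- Biostrings::DNAStringSet(unlist(out))
    names(hs) <- names(reference)
    hs
  }
  sel1 <- rep(TRUE, n)              # haplotype 1 carries every insertion
  sel2 <- zygosity == "HOM"
  mapOf <- function(sel) {
    lapply(stats::setNames(names(reference), names(reference)), function(ch) {
      ii <- which(sel & posChrom == ch)
      data.frame(refPos = posRef[ii], novelLen = novelLen[ii],
                 tsdLen = tsdLen[ii])
    })
  }
  truth <- GenomicRanges::GRanges(posChrom, IRanges::IRanges(posRef + 1L, posRef + 1L))
  S4Vectors::mcols(truth) <- S4Vectors::DataFrame(
    pos0 = posRef, family = fams, subfamily = subs, orientation = orientation,
    lengthBp = lengthBp, tsdLen = tsdLen, polyALen = polyALen,
    zygosity = zygosity)
  list(haplotypes = list(hap1 = buildHap(sel1), hap2 = buildHap(sel2)),
       truth = truth,
       maps = list(hap1 = mapOf(sel1), hap2 = mapOf(sel2)),
       reference = reference)
}

.mutateSeqs <- function(seqs, errorRate) {
  if (errorRate <= 0) return(seqs)
  n <- nchar(seqs[1L])
  nerr <- stats::rbinom(length(seqs), n, errorRate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    ch <- strsplit(seqs[i], "")[[1]]
    at <- sample.int(n, nerr[i])
    for (p in at) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Sample paired-end reads from the planted haplotypes
#'
#' Fragments are uniform per haplotype (half the total depth each);
#' fragment lengths are Normal(insertMean, insertSd) truncated to
#' [2 readLen, insertMean + 4 insertSd]; the two reads are the fragment
#' ends, read 2 on the opposite strand; substitution errors are independent
#' per base. Deterministic for a given seed.
#'
#' @param sim Output of \code{\link{plantInsertions}}.
#' @param cfg A \code{\link{simConfig}}.
#' @param depth Override the configured depth (used by depth sweeps).
#' @param seedOffset Added to \code{cfg$seed} for the read-sampling stream.
#' @return A data.frame with one row per pair: qname, hap, chrom,
#'   fragStart/fragEnd (0-based half-open on the haplotype), orient
#'   ("F": read 1 is the left fragment end), seqLeft/seqRight
#'   (haplotype-forward sequences of the left and right read).
#' @export
generateReads <- function(sim, cfg = simConfig(), depth = NULL, seedOffset = 1L) {
  set.seed(cfg$seed + seedOffset)
  depth <- if (is.null(depth)) cfg$depth else depth
  rl <- cfg$readLen
  out <- list()
  for (h in seq_along(sim$haplotypes)) {
    hap <- sim$haplotypes[[h]]
    hapLens <- Biostrings::width(hap)
    nFrag <- as.integer(round(depth / length(sim$haplotypes) *
                              sum(hapLens) / (2 * rl)))
    if (nFrag < 1L) next
    ch <- sample(seq_along(hap), nFrag, replace = TRUE, prob = hapLens)
    fragLen <- as.integer(round(stats::rnorm(nFrag, cfg$insertMean, cfg$insertSd)))
    fragLen <- pmin(pmax(fragLen, 2L * rl),
                    as.integer(cfg$insertMean + 4 * cfg$insertSd))
    maxStart <- hapLens[ch] - fragLen
    ok <- maxStart >= 0L
    ch <- ch[ok]; fragLen <- fragLen[ok]; maxStart <- maxStart[ok]
    start0 <- as.integer(floor(stats::runif(length(ch)) * (maxStart + 1L)))
    orient <- sample(c("F", "R"), length(ch), replace = TRUE)
    seqLeft <- character(length(ch)); seqRight <- character(length(ch))
    for (c2 in unique(ch)) {
      sel <- ch == c2
      hs <- as.character(hap[[c2]])
      seqLeft[sel] <- substring(hs, start0[sel] + 1L, start0[sel] + rl)
      seqRight[sel] <- substring(hs, start0[sel] + fragLen[sel] - rl + 1L,
                                 start0[sel] + fragLen[sel])
    }
    out[[h]] <- data.frame(
      qname = sprintf("sim_h%d_%07d", h, seq_along(ch)),
      hap = h, chrom = names(hap)[ch],
      fragStart = start0, fragEnd = start0 + fragLen,
      orient = orient, seqLeft = seqLeft, seqRight = seqRight,
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  reads$seqLeft <- .mutateSeqs(reads$seqLeft, cfg$errorRate)
  reads$seqRight <- .mutateSeqs(reads$seqRight, cfg$errorRate)
  reads
}

#' Write simulated pairs as FASTQ
#'
#' Four-line FASTQ, Phred+33 with constant Q30. Read 1/2 assignment follows
#' the fragment orientation; sequences are emitted as sequenced (the right
#' fragment end reverse-complemented).
#'
#' @param reads Data.frame from \code{\link{generateReads}}.
#' @param prefix Output prefix; writes \code{<prefix>_1.fq} and
#'   \code{<prefix>_2.fq}.
#' @return The two file paths, invisibly.
#' @export
writeFastq <- function(reads, prefix) {
  rcAll <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  rawRight <- rcAll(reads$seqRight)
  r1 <- ifelse(reads$orient == "F", reads$seqLeft, rawRight)
  r2 <- ifelse(reads$orient == "F", rawRight, reads$seqLeft)
  q <- strrep("?", nchar(r1[1L]))
  f1 <- paste0(prefix, "_1.fq"); f2 <- paste0(prefix, "_2.fq")
  writeLines(paste0("@", reads$qname, "/1\n", r1, "\n+\n", q), f1)
  writeLines(paste0("@", reads$qname, "/2\n", r2, "\n+\n", q), f2)
  invisible(c(f1, f2))
}

#' Truth table writer/reader (BED6+)
#'
#' Columns: chrom, pos, pos+1, family:subfamily, lengthBp, orientation,
#' tsdLen, zygosity; sorted by (chrom, pos).
#'
#' @param truth Truth \code{GRanges} from \code{\link{plantInsertions}}.
#' @param path Output path.
#' @export
writeTruth <- function(truth, path) {
  m <- S4Vectors::mcols(truth)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(truth)),
                   start = m$pos0, end = m$pos0 + 1L,
                   name = paste(m$family, m$subfamily, sep = ":"),
                   score = m$lengthBp, strand = m$orientation,
                   tsdLen = m$tsdLen, zygosity = m$zygosity)
  df <- df[order(df$chrom, df$start), ]
  con <- file(path, "w")
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand\ttsdLen\tzygosity", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("chrom", "start", "end", "name", "score",
                                        "strand", "tsdLen", "zygosity"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character",
                                         "integer", "character"))
  fam <- sub(":.*$", "", df$name); sub_ <- sub("^[^:]*:", "", df$name)
  truth <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  S4Vectors::mcols(truth) <- S4Vectors::DataFrame(
    pos0 = df$start, family = fam, subfamily = sub_, orientation = df$strand,
    lengthBp = df$score, tsdLen = df$tsdLen,
    polyALen = rep(NA_integer_, nrow(df)), zygosity = df$zygosity)
  truth
}

## ---- provenance ("perfect") aligner -----------------------------------

## map one haplotype's read intervals back to reference coordinates given
## that chromosome's liftover table; vectorized over reads
.liftReads <- function(s, e, map, tsdAware = TRUE, minAnchor = 20L) {
  n <- length(s)
  if (!nrow(map)) {
    return(data.frame(mapped = rep(TRUE, n), pos = s, mLen = e - s,
                      leadS = 0L, trailS = 0L))
  }
  cumBefore <- c(0L, cumsum(map$novelLen))        # novel bases before block i
  novStart <- map$refPos + cumBefore[-length(cumBefore)]
  novEnd <- novStart + map$novelLen
  ## relevant novel block: the one starting at or before the read end
  k <- findInterval(e - 1L, novStart)
  k[k == 0L] <- 1L
  nS <- novStart[k]; nE <- novEnd[k]
  refLeft <- pmax(0L, pmin(e, nS) - pmin(s, nS))
  refRight <- pmax(0L, pmax(e, nE) - pmax(s, nE))
  novelOver <- pmax(0L, pmin(e, nE) - pmax(s, nS))
  shiftBefore <- cumBefore[k]                      # novel bases left of block k
  inRef <- novelOver == 0L
  ## fully in reference: subtract the novel bases to the left
  posFull <- s - ifelse(s >= nE, cumBefore[k + 1L], shiftBefore)
  useLeft <- !inRef & refLeft >= minAnchor & refLeft >= refRight
  useRight <- !inRef & !useLeft & refRight >= minAnchor
  ext <- pmin(map$tsdLen[k], novelOver)            # TSD-aware extension
  len <- e - s
  out <- data.frame(mapped = inRef | useLeft | useRight,
                    pos = NA_integer_, mLen = NA_integer_,
                    leadS = 0L, trailS = 0L)
  out$pos[inRef] <- posFull[inRef]
  out$mLen[inRef] <- len[inRef]
  out$pos[useLeft] <- (s - shiftBefore)[useLeft]
  out$mLen[useLeft] <- refLeft[useLeft]
  out$trailS[useLeft] <- (len - refLeft)[useLeft]
  out$pos[useRight] <- (map$refPos[k] - ext)[useRight]
  out$mLen[useRight] <- (refRight + ext)[useRight]
  out$leadS[useRight] <- (len - refRight - ext)[useRight]
  out
}

#' Place simulated reads at their true positions (provenance aligner)
#'
#' Writes a coordinate-sorted, indexed BAM in which every read is placed
#' where its fragment came from: reads over reference sequence get full
#' matches, reads crossing an insertion junction get the correct soft
#' clips (extending through the duplicated TSD copy as a real aligner
#' would), and reads fully inside inserted sequence are emitted unmapped at
#' their mate's position. No external aligner binary is involved.
#'
#' @param reads Data.frame from \code{\link{generateReads}}.
#' @param sim Output of \code{\link{plantInsertions}}.
#' @param cfg A \code{\link{simConfig}}.
#' @param bamPrefix Output prefix (files \code{<prefix>.bam(.bai)}).
#' @param minAnchor Minimum aligned bases for a junction read to be placed.
#' @return Path to the BAM.
#' @export
perfectAlign <- function(reads, sim, cfg = simConfig(), bamPrefix = tempfile(),
                         minAnchor = 20L) {
  rl <- cfg$readLen
  n <- nrow(reads)
  ## left read: [fragStart, fragStart+rl); right read: [fragEnd-rl, fragEnd)
  lift <- data.frame(mapped = logical(2L * n), pos = NA_integer_,
                     mLen = NA_integer_, leadS = 0L, trailS = 0L)
  for (h in unique(reads$hap)) {
    maps <- sim$maps[[h]]
    for (ch in unique(reads$chrom[reads$hap == h])) {
      sel <- which(reads$hap == h & reads$chrom == ch)
      map <- maps[[ch]]
      lift[sel, ] <- .liftReads(reads$fragStart[sel], reads$fragStart[sel] + rl,
                                map, minAnchor = minAnchor)
      lift[n + sel, ] <- .liftReads(reads$fragEnd[sel] - rl, reads$fragEnd[sel],
                                    map, minAnchor = minAnchor)
    }
  }
  liftL <- lift[seq_len(n), ]; liftR <- lift[n + seq_len(n), ]
  keep <- liftL$mapped | liftR$mapped          # drop pairs fully inside novel
  reads <- reads[keep, , drop = FALSE]
  liftL <- liftL[keep, , drop = FALSE]; liftR <- liftR[keep, , drop = FALSE]
  n <- nrow(reads)

  cigarOf <- function(lf) ifelse(!lf$mapped, "*",
    paste0(ifelse(lf$leadS > 0L, paste0(lf$leadS, "S"), ""),
           lf$mLen, "M",
           ifelse(lf$trailS > 0L, paste0(lf$trailS, "S"), "")))
  rcAll <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))

  flagL <- 1L + 32L +
    ifelse(reads$orient == "F", 64L, 128L) +
    ifelse(liftL$mapped, 0L, 4L) + ifelse(liftR$mapped, 0L, 8L)
  flagR <- 1L + 16L +
    ifelse(reads$orient == "F", 128L, 64L) +
    ifelse(liftR$mapped, 0L, 4L) + ifelse(liftL$mapped, 0L, 8L)
  ## unmapped reads keep no strand bit and sit at the mate's position
  flagR[!liftR$mapped] <- flagR[!liftR$mapped] - 16L
  bothMapped <- liftL$mapped & liftR$mapped
  flagL[bothMapped] <- flagL[bothMapped] + 2L
  flagR[bothMapped] <- flagR[bothMapped] + 2L

  posL <- ifelse(liftL$mapped, liftL$pos, liftR$pos)
  posR <- ifelse(liftR$mapped, liftR$pos, liftL$pos)
  tlen <- ifelse(bothMapped, (posR + liftR$mLen + liftR$leadS + liftR$trailS) - posL, 0L)
  ## SEQ is reference-oriented when mapped; as sequenced when unmapped
  seqL <- reads$seqLeft
  seqR <- reads$seqRight
  seqR[!liftR$mapped] <- rcAll(seqR[!liftR$mapped])
  mapqL <- ifelse(liftL$mapped, 60L, 0L)
  mapqR <- ifelse(liftR$mapped, 60L, 0L)
  qual <- strrep("?", rl)

  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(sim$reference),
                  "\tLN:", Biostrings::width(sim$reference)))
  lineOf <- function(qn, flag, ch, pos, mapq, cig, mpos, tl, seq)
    paste(qn, flag, ch, pos + 1L, mapq, cig, "=", mpos + 1L, tl, seq, qual,
          sep = "\t")
  lines <- c(lineOf(reads$qname, flagL, reads$chrom, posL, mapqL,
                    cigarOf(liftL), posR, tlen, seqL),
             lineOf(reads$qname, flagR, reads$chrom, posR, mapqR,
                    cigarOf(liftR), posL, -tlen, seqR))
  samPath <- paste0(bamPrefix, ".sam")
  writeLines(c(hdr, lines), samPath)
  bam <- Rsamtools::asBam(samPath, destination = bamPrefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(samPath)
  bam
}

#' Simulate, plant, sequence and align in one call
#'
#' @param reference Named \code{DNAStringSet} (e.g. \code{\link{makeReference}}).
#' @param library A \code{\link{TELibrary}}.
#' @param cfg A \code{\link{simConfig}}.
#' @param bamPrefix Output BAM prefix.
#' @param depth Optional depth override.
#' @return List: \code{bam}, \code{truth}, \code{sim}, \code{reads}.
#' @export
simulateDataset <- function(reference, library, cfg = simConfig(),
                            bamPrefix = tempfile(), depth = NULL) {
  sim <- plantInsertions(reference, library, cfg)
  reads <- generateReads(sim, cfg, depth = depth)
  bam <- perfectAlign(reads, sim, cfg, bamPrefix)
  list(bam = bam, truth = sim$truth, sim = sim, reads = reads)
}
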
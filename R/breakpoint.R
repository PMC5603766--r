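## Breakpoint resolution: collect all reads over a cluster window, gather
## and recalibrate soft-clip boundaries, validate candidate clip points,
## call the two breakpoints and the target site duplication between them,
## and genotype the insertion from the allele balance.
##
## Geometry: an insertion with a TSD produces two clip points. Reads from
## the left flank run into the inserted sequence and are clipped at their
## right (3') end at the insertion point ("R" clips, the higher coordinate,
## bp_left). Reads from the right flank align starting at the first TSD
## base and are clipped at their left (5') end ("L" clips, bp_right =
## bp_left - TSD length). The TSD is the reference between the two.

#' Collect all primary reads overlapping a cluster window
#'
#' Includes fully reference-concordant reads, which genotyping needs.
#'
#' @param bamPath Indexed BAM.
#' @param cluster A single cluster (\code{GRanges} of length 1).
#' @param pad Extra reference bases fetched on each side.
#' @return A data.frame of read records (0-based \code{pos}).
#' @export
collectRegionReads <- function(bamPath, cluster, pad = 0L) {
  stopifnot(length(cluster) == 1L)
  chrom <- as.character(GenomicRanges::seqnames(cluster))
  lo <- max(1L, BiocGenerics::start(cluster) - pad)
  hi <- BiocGenerics::end(cluster) + pad
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(what = what, flag = flag,
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi)))
  b <- Rsamtools::scanBam(bamPath, param = param)[[1]]
  data.frame(qname = b$qname, chrom = as.character(b$rname), pos = b$pos - 1L,
             mapq = b$mapq, cigar = b$cigar, seq = as.character(b$seq),
             isReverse = bitwAnd(b$flag, 16L) > 0L,
             stringsAsFactors = FALSE)
}

## ---- clip-point collection and recalibration --------------------------

## refWindow: list(chrom, offset (0-based start), seq (character))
refWindowFromSeq <- function(refSeq, chrom, lo, hi) {
  seq <- as.character(Biostrings::subseq(refSeq[[chrom]], lo + 1L, hi))
  list(chrom = chrom, offset = lo, seq = seq)
}

refBaseAt <- function(win, pos0) {
  i <- pos0 - win$offset + 1L
  ifelse(i >= 1L & i <= nchar(win$seq), substring(win$seq, i, i), "N")
}

refSliceStr <- function(win, lo0, hi0) {
  i <- max(1L, lo0 - win$offset + 1L); j <- min(nchar(win$seq), hi0 - win$offset)
  if (j < i) "" else substr(win$seq, i, j)
}

## per-read parsed cigar: ops and lengths
.parseCigar <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1]]
  list(ops = ops, len = len)
}

## walk one read against the reference window; returns per-read clip events
## plus aligned-block info used for spanning counts and mismatch rescue
.readClips <- function(pos, cigar, seq, win, cfg) {
  pc <- .parseCigar(cigar)
  events <- list()
  qpos <- 1L; rpos <- pos          # query 1-based, reference 0-based
  nOps <- length(pc$ops)
  alnStart <- pos
  matchedRef <- character(0); matchedRead <- character(0)
  for (k in seq_len(nOps)) {
    op <- pc$ops[k]; L <- pc$len[k]
    if (op == "S") {
      clipSeq <- substr(seq, qpos, qpos + L - 1L)
      side <- if (k == 1L) "L" else "R"
      flank <- if (side == "R") substr(seq, max(1L, qpos - 10L), qpos - 1L)
               else substr(seq, qpos + L, min(nchar(seq), qpos + L + 9L))
      if (L >= cfg$recalMinClip)
        events[[length(events) + 1L]] <- list(pos = rpos, side = side, seq = clipSeq,
                                              flank = flank, kind = "softclip")
      qpos <- qpos + L
    } else if (op %in% c("M", "=", "X")) {
      matchedRef <- c(matchedRef, refSliceStr(win, rpos, rpos + L))
      matchedRead <- c(matchedRead, substr(seq, qpos, qpos + L - 1L))
      qpos <- qpos + L; rpos <- rpos + L
    } else if (op == "D") {
      ## small deletion: candidate for collapse during recalibration
      if (L < cfg$smallDelMax && k < nOps) {
        ## bases aligned beyond the deletion; if they disagree with the
        ## reference, the deletion marks the true clip boundary
        tailRead <- substr(seq, qpos, nchar(seq))
        tailRef <- refSliceStr(win, rpos + L, rpos + L + nchar(tailRead))
        n <- min(nchar(tailRead), nchar(tailRef))
        if (n > 0L) {
          mm <- sum(strsplit(substr(tailRead, 1L, n), "")[[1]] !=
                    strsplit(substr(tailRef, 1L, n), "")[[1]])
          if (mm > n / 2) {
            events[[length(events) + 1L]] <- list(pos = rpos, side = "R",
              seq = tailRead, flank = substr(seq, max(1L, qpos - 10L), qpos - 1L),
              kind = "recal_del")
            break
          }
        }
      }
      rpos <- rpos + L
    } else if (op == "I") {
      qpos <- qpos + L
    } else if (op %in% c("N")) {
      rpos <- rpos + L
    } else if (op == "H") {
      ## hard clips carry no sequence; ignore
    }
  }
  refStr <- paste(matchedRef, collapse = "")
  readStr <- paste(matchedRead, collapse = "")
  ## terminal-mismatch rescue on clean ends: if more than half of the last
  ## (first) w aligned bases mismatch the reference, a synthetic clip is
  ## placed at the first mismatch of that terminal run
  w <- cfg$terminalWindow
  n <- min(nchar(refStr), nchar(readStr))
  if (n >= w) {
    refC <- strsplit(refStr, "")[[1]][seq_len(n)]
    readC <- strsplit(readStr, "")[[1]][seq_len(n)]
    mism <- refC != readC
    noRightClip <- !(pc$ops[nOps] == "S")
    noLeftClip <- !(pc$ops[1L] == "S")
    if (noRightClip && sum(mism[(n - w + 1L):n]) > w / 2) {
      first <- (n - w) + min(which(mism[(n - w + 1L):n]))
      events[[length(events) + 1L]] <- list(pos = pos + first - 1L, side = "R",
        seq = substr(readStr, first, n),
        flank = substr(readStr, max(1L, first - 10L), first - 1L), kind = "rescue")
    }
    if (noLeftClip && sum(mism[1:w]) > w / 2) {
      last <- max(which(mism[1:w]))
      events[[length(events) + 1L]] <- list(pos = pos + last, side = "L",
        seq = substr(readStr, 1L, last),
        flank = substr(readStr, last + 1L, min(n, last + 10L)), kind = "rescue")
    }
  }
  spanOk <- all(pc$ops %in% c("M", "=", "X", "I", "D")) &&
    sum(pc$len[pc$ops == "S"]) == 0L
  list(events = events, alnStart = alnStart, alnEnd = rpos,
       clean = spanOk && !any(vapply(events, function(e) e$kind == "rescue", TRUE)))
}

#' Collect and recalibrate clip points over a cluster region
#'
#' Three sources feed the clip-point table: (a) soft-clip boundaries from
#' the CIGARs; (b) reads whose CIGAR carries a small deletion followed by
#' aligned bases that mostly disagree with the reference - the deletion is
#' collapsed and the boundary moved to the deletion start; (c) terminal-
#' mismatch rescue - an unclipped read end whose last \code{terminalWindow}
#' aligned bases are more than half mismatches contributes a synthetic clip
#' at the first mismatch of that run.
#'
#' @param reads Read data.frame from \code{\link{collectRegionReads}}.
#' @param win Reference window (list with \code{offset} and \code{seq})
#'   covering the cluster plus a read length on each side.
#' @param cfg Pipeline configuration.
#' @return A data.frame of clip points: \code{pos} (0-based), \code{side}
#'   ("R" = clip at read 3' end, left of the insertion; "L" = clip at read
#'   5' end, right of the insertion), \code{support}, and the member
#'   clipped sequences (list column), plus per-read spanning info in
#'   attributes \code{spanStarts}/\code{spanEnds} for genotyping.
#' @export
recalibrateClips <- function(reads, win, cfg = meiConfig()) {
  events <- list()
  spanStarts <- integer(0); spanEnds <- integer(0)
  for (i in seq_len(nrow(reads))) {
    res <- .readClips(reads$pos[i], reads$cigar[i], reads$seq[i], win, cfg)
    events <- c(events, res$events)
    if (res$clean) {
      spanStarts <- c(spanStarts, res$alnStart)
      spanEnds <- c(spanEnds, res$alnEnd)
    }
  }
  if (!length(events)) {
    out <- data.frame(pos = integer(0), side = character(0), support = integer(0))
    out$clippedSeqs <- list()
    out$alignedFlank <- character(0)
  } else {
    pos <- vapply(events, `[[`, 0L, "pos")
    side <- vapply(events, `[[`, "", "side")
    seqs <- vapply(events, `[[`, "", "seq")
    flanks <- vapply(events, `[[`, "", "flank")
    key <- paste(pos, side)
    grp <- split(seq_along(events), key)
    out <- data.frame(
      pos = vapply(grp, function(ii) pos[ii[1L]], 0L),
      side = vapply(grp, function(ii) side[ii[1L]], ""),
      support = vapply(grp, length, 0L),
      stringsAsFactors = FALSE)
    out$clippedSeqs <- lapply(grp, function(ii) seqs[ii])
    ## junction-adjacent aligned-flank consensus (junction sits at the clip,
    ## so flanks of an "R" clip are right-anchored and vice versa)
    out$alignedFlank <- vapply(seq_along(grp), function(g) {
      f <- flanks[grp[[g]]]; f <- f[nzchar(f)]
      if (!length(f)) return("")
      .clipConsensus(f, if (out$side[g] == "R") "L" else "R")
    }, "")
    out <- out[order(out$pos, out$side), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "spanStarts") <- spanStarts
  attr(out, "spanEnds") <- spanEnds
  out
}

## identity of a clipped sequence against the reference continuation at the
## junction (gap-free positional comparison, junction-anchored)
.clipVsRef <- function(clipSeq, pos, side, win) {
  L <- nchar(clipSeq)
  refC <- if (side == "R") refSliceStr(win, pos, pos + L)
          else refSliceStr(win, pos - L, pos)
  n <- min(nchar(refC), L)
  if (n == 0L) return(0)
  a <- if (side == "R") substr(clipSeq, 1L, n) else substr(clipSeq, L - n + 1L, L)
  b <- if (side == "R") substr(refC, 1L, n) else substr(refC, nchar(refC) - n + 1L, nchar(refC))
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

## majority-base consensus of clipped sequences, junction-anchored
.clipConsensus <- function(seqs, side) {
  L <- max(nchar(seqs))
  mat <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (side == "R") c(ch, rep(NA, L - length(ch)))
    else c(rep(NA, L - length(ch)), ch)
  }, character(L))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = L)
  cons <- apply(mat, 1L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_character_)
    tb <- table(col)
    names(tb)[which.max(tb)]
  })
  paste(cons[!is.na(cons)], collapse = "")
}

#' Does a sequence start with a poly-A or poly-T run?
#'
#' At least \code{minRun} consecutive A (or T) allowing one interruption.
#' @param seq DNA string.
#' @param minRun Minimum run length (default 8).
#' @param fromEnd Check the end of the sequence instead of the start.
#' @export
isPolyAT <- function(seq, minRun = 8L, fromEnd = FALSE) {
  if (is.na(seq) || nchar(seq) < minRun) return(FALSE)
  probe <- if (fromEnd) substr(seq, nchar(seq) - minRun, nchar(seq))
           else substr(seq, 1L, minRun + 1L)
  ch <- strsplit(probe, "")[[1]]
  any(vapply(c("A", "T"), function(b) sum(ch != b) <= 1L, TRUE))
}

#' Validate a candidate clip point
#'
#' Three rules, all required: (1) more than half of the member clipped
#' sequences are discordant with the reference continuation at the point
#' (identity below \code{discordantIdentityMax}); (2) in a local alignment
#' of the clipped-sequence consensus against the reference continuation the
#' gapped fraction is below 30\%; (3) the junction is crisp - the run of
#' consecutive mismatches on the aligned flank immediately adjacent to the
#' junction (majority base over member reads vs the reference) is shorter
#' than 5 bp - unless the clipped consensus starts (junction side) with a
#' poly-A/T run, which excuses rule (3).
#'
#' @param cp One clip-point row from \code{\link{recalibrateClips}} (or a
#'   list with \code{pos}, \code{side}, \code{clippedSeqs},
#'   \code{alignedFlank} optionally giving the junction-adjacent aligned
#'   consensus).
#' @param win Reference window.
#' @param cfg Pipeline configuration.
#' @return Logical.
#' @export
validateClipPoint <- function(cp, win, cfg = meiConfig()) {
  seqs <- if (is.list(cp$clippedSeqs) && !is.character(cp$clippedSeqs))
    cp$clippedSeqs[[1]] else cp$clippedSeqs
  if (!length(seqs)) return(FALSE)
  ## rule 1: majority discordant
  ident <- vapply(seqs, .clipVsRef, 0, pos = cp$pos, side = cp$side, win = win)
  if (!(mean(ident < cfg$discordantIdentityMax) > 0.5)) return(FALSE)
  ## rule 2: gap fraction < 30% in local alignment of the clipped consensus
  ## against the reference continuation
  cons <- .clipConsensus(seqs, cp$side)
  L <- nchar(cons)
  refC <- if (cp$side == "R") refSliceStr(win, cp$pos, cp$pos + L + 10L)
          else refSliceStr(win, cp$pos - L - 10L, cp$pos)
  if (nchar(refC) >= 1L && L >= 1L) {
    pa <- Biostrings::pairwiseAlignment(cons, refC, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
      gapOpening = 5, gapExtension = 2)
    alnLen <- nchar(as.character(Biostrings::alignedPattern(pa)))
    if (alnLen > 0L) {
      gaps <- Biostrings::nindel(pa)
      gapFrac <- (sum(Biostrings::insertion(gaps)[, "WidthSum"]) +
                  sum(Biostrings::deletion(gaps)[, "WidthSum"])) / alnLen
      if (gapFrac >= cfg$gapFractionMax) return(FALSE)
    }
  }
  ## rule 3: crisp junction on the aligned flank, or poly-A/T escape
  polyEscape <- if (cp$side == "R") isPolyAT(cons, cfg$polyMinRun)
                else isPolyAT(cons, cfg$polyMinRun, fromEnd = TRUE)
  if (polyEscape) return(TRUE)
  flank <- cp$alignedFlank
  if (is.null(flank) || is.na(flank) || !nzchar(flank)) return(TRUE)
  w <- nchar(flank)
  refF <- if (cp$side == "R") refSliceStr(win, cp$pos - w, cp$pos)
          else refSliceStr(win, cp$pos, cp$pos + w)
  n <- min(nchar(refF), w)
  if (n == 0L) return(TRUE)
  fC <- if (cp$side == "R") rev(strsplit(flank, "")[[1]])[seq_len(n)]
        else strsplit(flank, "")[[1]][seq_len(n)]
  rC <- if (cp$side == "R") rev(strsplit(refF, "")[[1]])[seq_len(n)]
        else strsplit(refF, "")[[1]][seq_len(n)]
  mism <- fC != rC
  run <- if (!mism[1L]) 0L else which.min(c(mism, FALSE)) - 1L
  run < cfg$junctionMismatchMax
}

#' Call breakpoints and the target site duplication from validated clips
#'
#' bp_left is the highest-support "R" clip (reads clipped at their 3' end;
#' the insertion point) and bp_right the highest-support "L" clip. When
#' both are present, bp_right at or left of bp_left, and separated by at
#' most \code{tsdMax}, the reference between them is the TSD. A separation
#' beyond \code{tsdMax} keeps the call but flags it and drops the TSD.
#'
#' @param clips Validated clip-point data.frame.
#' @param win Reference window.
#' @param cfg Pipeline configuration.
#' @return List: \code{insertionPos}, \code{bpLeft}, \code{bpRight} (0-based
#'   or NA), \code{tsdSeq} (NA when undefined), \code{supportClip},
#'   \code{flag}.
#' @export
callBreakpointsTsd <- function(clips, win, cfg = meiConfig()) {
  stopifnot(nrow(clips) >= 1L)
  pick <- function(side) {
    sub <- clips[clips$side == side, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub <- sub[order(-sub$support, sub$pos), , drop = FALSE]
    sub[1L, , drop = FALSE]
  }
  R <- pick("R"); L <- pick("L")
  bpLeft <- if (!is.null(R)) R$pos else NA_integer_
  bpRight <- if (!is.null(L)) L$pos else NA_integer_
  tsd <- NA_character_
  flagged <- FALSE
  if (!is.na(bpLeft) && !is.na(bpRight)) {
    if (bpRight > bpLeft) {
      ## inverted geometry: no TSD recoverable
      flagged <- TRUE
    } else if (bpLeft - bpRight <= cfg$tsdMax) {
      tsd <- refSliceStr(win, bpRight, bpLeft)
    } else flagged <- TRUE
  }
  insertionPos <- if (!is.na(bpRight)) bpRight else bpLeft
  supportClip <- sum(c(if (!is.null(R)) R$support, if (!is.null(L)) L$support))
  list(insertionPos = insertionPos, bpLeft = bpLeft, bpRight = bpRight,
       tsdSeq = tsd, supportClip = as.integer(supportClip), flag = flagged)
}

#' Genotype an insertion from allele counts
#'
#' The reference fraction is spanning / (spanning + supporting); at or
#' below \code{homMaxRefFraction} the call is HOM, otherwise HET.
#'
#' @param spanningRefReads Reads cleanly spanning the insertion point on
#'   the reference allele.
#' @param clipAndRamReads Insertion-supporting reads (clips + RAMs).
#' @param cfg Pipeline configuration.
#' @return \code{"HET"} or \code{"HOM"}.
#' @export
genotypeCall <- function(spanningRefReads, clipAndRamReads, cfg = meiConfig()) {
  if (spanningRefReads + clipAndRamReads <= 0L)
    stop("genotype undefined with zero spanning and zero supporting reads")
  refFrac <- spanningRefReads / (spanningRefReads + clipAndRamReads)
  if (refFrac <= cfg$homMaxRefFraction) "HOM" else "HET"
}

## count clean reads spanning [lo, hi] with margin on both sides
.spanningCount <- function(spanStarts, spanEnds, lo, hi, margin) {
  sum(spanStarts <= lo - margin & spanEnds >= hi + margin)
}

#' Resolve one cluster to an insertion call
#'
#' Drives collect-reads, clip recalibration, validation, breakpoint/TSD
#' calling and genotyping for a single cluster. Clusters with no validated
#' clip point still yield a call at the cluster-window midpoint (breakpoints
#' absent, flagged imprecise).
#'
#' @param bamPath Indexed BAM.
#' @param refSeq Reference \code{DNAStringSet}.
#' @param cluster One cluster from \code{\link{clusterEvidence}}.
#' @param evidence The evidence \code{GRanges} the clusters were built from.
#' @param cfg Pipeline configuration.
#' @return A one-row data.frame call.
#' @export
callCluster <- function(bamPath, refSeq, cluster, evidence, cfg = meiConfig()) {
  chrom <- as.character(GenomicRanges::seqnames(cluster))
  readLen <- cfg$readLenHint
  lo <- max(0L, BiocGenerics::start(cluster) - 1L - readLen)
  hi <- min(length(refSeq[[chrom]]), BiocGenerics::end(cluster) + readLen)
  win <- refWindowFromSeq(refSeq, chrom, lo, hi)
  reads <- collectRegionReads(bamPath, cluster, pad = readLen)
  m <- S4Vectors::mcols(cluster)
  memberIdx <- m$members[[1]]
  mev <- S4Vectors::mcols(evidence[memberIdx])
  supportRam <- sum(mev$category == "RAM_PAIR")

  clips <- recalibrateClips(reads, win, cfg)
  spanStarts <- attr(clips, "spanStarts"); spanEnds <- attr(clips, "spanEnds")
  valid <- logical(nrow(clips))
  if (nrow(clips)) {
    for (i in seq_len(nrow(clips))) {
      cp <- list(pos = clips$pos[i], side = clips$side[i],
                 clippedSeqs = clips$clippedSeqs[[i]],
                 alignedFlank = clips$alignedFlank[i])
      valid[i] <- validateClipPoint(cp, win, cfg)
    }
  }
  vclips <- clips[valid, , drop = FALSE]
  if (nrow(vclips)) {
    bp <- callBreakpointsTsd(vclips, win, cfg)
  } else {
    mid <- as.integer((BiocGenerics::start(cluster) - 1L + BiocGenerics::end(cluster)) / 2)
    bp <- list(insertionPos = mid, bpLeft = NA_integer_, bpRight = NA_integer_,
               tsdSeq = NA_character_, supportClip = 0L, flag = TRUE)
  }
  spanLo <- if (!is.na(bp$bpRight)) bp$bpRight else bp$insertionPos
  spanHi <- if (!is.na(bp$bpLeft)) bp$bpLeft else bp$insertionPos
  spanning <- .spanningCount(spanStarts, spanEnds, spanLo, spanHi, cfg$spanMargin)
  ## genotype on junction-local counts: clip support measures the same
  ## junction-overlapping read population as the spanning count, so the
  ## allele fractions are comparable; RAM counts (which scale with the
  ## insert size, not the allele balance) only stand in when no clip
  ## survived validation
  supporting <- if (bp$supportClip > 0L) bp$supportClip else supportRam
  genotype <- if (spanning + supporting > 0L) genotypeCall(spanning, supporting, cfg)
              else NA_character_
  data.frame(chrom = chrom, insertionPos = bp$insertionPos,
             bpLeft = bp$bpLeft, bpRight = bp$bpRight,
             tsdSeq = bp$tsdSeq,
             family = m$familyVote, subfamily = NA_character_,
             orientation = "unknown", lengthBp = NA_integer_,
             genotype = genotype,
             supportRam = supportRam, supportClip = bp$supportClip,
             spanningRefReads = spanning,
             imprecise = bp$flag,
             stringsAsFactors = FALSE)
}
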
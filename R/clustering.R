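## Clustering of discordant evidence into candidate insertion loci
## ("maximal valid clusters") with a streaming release rule that lets
## breakpoint resolution start before the scan finishes.

#' Estimate insert-size statistics from a BAM
#'
#' Mean and standard deviation of template lengths over the first
#' \code{sampleN} proper pairs with |TLEN| below ten read lengths. The
#' standard deviation uses the population (1/n) form so that, e.g.,
#' templates alternating 400/600 give exactly sd 100. Deterministic for a
#' given file.
#'
#' @param bamPath Coordinate-sorted BAM.
#' @param sampleN Number of proper pairs to sample (default 10000).
#' @return A list with \code{mean}, \code{sd} and \code{readLen}.
#' @export
estimateInsertSize <- function(bamPath, sampleN = 10000L) {
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(what = c("isize", "qwidth"), flag = flag)
  b <- Rsamtools::scanBam(bamPath, param = param)[[1]]
  tlen <- b$isize
  keep <- !is.na(tlen) & tlen > 0L
  tlen <- tlen[keep]
  readLen <- as.integer(stats::median(b$qwidth[keep]))
  tlen <- tlen[tlen < 10L * readLen]
  if (length(tlen) < 100L)
    stop("too few proper pairs to estimate insert size (need >= 100, got ",
         length(tlen), ")")
  tlen <- utils::head(tlen, sampleN)
  m <- mean(tlen)
  s <- sqrt(mean((tlen - m)^2))
  list(mean = m, sd = s, readLen = readLen)
}

## predicted insertion interval of one evidence record, 0-based half-open:
## the anchor is extended by mean + 3 sd toward the side the insertion must
## lie on; clip-bearing evidence is centred on its clip position.
predictedIntervals <- function(evidence, stats) {
  ext <- as.integer(ceiling(stats$mean + 3 * stats$sd))
  start0 <- BiocGenerics::start(evidence) - 1L
  end0 <- BiocGenerics::end(evidence)
  side <- S4Vectors::mcols(evidence)$anchorSide
  clip <- S4Vectors::mcols(evidence)$clipPos
  lo <- ifelse(side == "left", end0, start0 - ext)
  hi <- ifelse(side == "left", end0 + ext, start0)
  hasClip <- !is.na(clip)
  lo[hasClip & side == "left"] <- clip[hasClip & side == "left"]
  hi[hasClip & side == "right"] <- clip[hasClip & side == "right"]
  data.frame(lo = pmax(lo, 0L), hi = hi)
}

.newCluster <- function(chrom, lo, hi, idx) list(chrom = chrom, lo = lo, hi = hi, idx = idx)

clustersToGRanges <- function(clusters, evidence, cfg) {
  if (!length(clusters)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      nSupport = integer(0), leftSupport = integer(0), rightSupport = integer(0),
      clipSupport = integer(0), familyVote = character(0),
      members = IRanges::IntegerList())
    return(gr)
  }
  ev <- S4Vectors::mcols(evidence)
  rows <- lapply(clusters, function(cl) {
    m <- ev[cl$idx, , drop = FALSE]
    fams <- table(m$family[!is.na(m$family)])
    vote <- if (!length(fams)) "ambiguous" else {
      top <- names(fams)[fams == max(fams)]
      if (length(top) == 1L) top else "ambiguous"
    }
    list(chrom = cl$chrom, lo = cl$lo, hi = cl$hi,
         n = length(cl$idx),
         left = sum(m$anchorSide == "left"),
         right = sum(m$anchorSide == "right"),
         clip = sum(!is.na(m$clipPos)),
         vote = vote, idx = cl$idx)
  })
  gr <- GenomicRanges::GRanges(
    vapply(rows, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(rows, `[[`, 0L, "lo") + 1L,
                     vapply(rows, `[[`, 0L, "hi")))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    nSupport = vapply(rows, `[[`, 0L, "n"),
    leftSupport = vapply(rows, `[[`, 0L, "left"),
    rightSupport = vapply(rows, `[[`, 0L, "right"),
    clipSupport = vapply(rows, `[[`, 0L, "clip"),
    familyVote = vapply(rows, `[[`, "", "vote"),
    members = IRanges::IntegerList(lapply(rows, `[[`, "idx")))
  gr
}

## validity: enough total support, and either both flanks anchored or
## enough clip-bearing records
.isValidCluster <- function(gr, cfg) {
  m <- S4Vectors::mcols(gr)
  m$nSupport >= cfg$minSupport &
    ((m$leftSupport >= 1L & m$rightSupport >= 1L) |
       m$clipSupport >= cfg$minClipSupport)
}

#' Cluster discordant evidence into candidate insertion loci
#'
#' Single-pass merging of the evidence records' predicted insertion
#' intervals (anchor extended by mean + 3 sd of the insert size toward the
#' insertion side). A record joins the open cluster when its interval
#' overlaps the cluster window and the merged window stays within twice the
#' extension length; otherwise a new cluster opens. A cluster is emitted
#' (valid) when its total support reaches \code{minSupport} and it either
#' has evidence on both flanks or at least \code{minClipSupport}
#' clip-bearing records. The majority family vote is recorded; ties give
#' \code{"ambiguous"}.
#'
#' @param evidence Evidence \code{GRanges} sorted by (chrom, position), as
#'   returned by \code{\link{scanDiscordant}}.
#' @param stats Insert-size statistics from \code{\link{estimateInsertSize}}.
#' @param cfg Pipeline configuration, see \code{\link{meiConfig}}.
#' @param allClusters Return also invalid clusters (used by the streaming
#'   equivalence tests).
#' @return A \code{GRanges} of cluster windows with support counts, the
#'   family vote, and the member evidence indices.
#' @export
clusterEvidence <- function(evidence, stats, cfg = meiConfig(), allClusters = FALSE) {
  if (length(evidence) == 0L) return(clustersToGRanges(list(), evidence, cfg))
  chrom <- as.character(GenomicRanges::seqnames(evidence))
  starts <- BiocGenerics::start(evidence)
  contiguous <- !anyDuplicated(rle(chrom)$values)
  inOrder <- all(vapply(split(starts, factor(chrom, unique(chrom))),
                        function(x) !is.unsorted(x), TRUE))
  if (!contiguous || !inOrder)
    stop("evidence must be sorted by (chrom, position)")
  iv <- predictedIntervals(evidence, stats)
  ext <- ceiling(stats$mean + 3 * stats$sd)
  ## window cap: twice the extension, plus the TSD allowance - the two
  ## flanks of one insertion predict points tsdMax apart at most
  cap <- 2 * ext + cfg$tsdMax
  ord <- order(chrom, iv$lo)
  clusters <- list()
  open <- NULL
  for (k in ord) {
    if (!is.null(open) && identical(open$chrom, chrom[k]) &&
        iv$lo[k] <= open$hi && max(open$hi, iv$hi[k]) - min(open$lo, iv$lo[k]) <= cap) {
      open$lo <- min(open$lo, iv$lo[k]); open$hi <- max(open$hi, iv$hi[k])
      open$idx <- c(open$idx, k)
    } else {
      if (!is.null(open)) clusters[[length(clusters) + 1L]] <- open
      open <- .newCluster(chrom[k], iv$lo[k], iv$hi[k], k)
    }
  }
  if (!is.null(open)) clusters[[length(clusters) + 1L]] <- open
  gr <- clustersToGRanges(clusters, evidence, cfg)
  if (!allClusters) gr <- gr[.isValidCluster(gr, cfg)]
  gr
}

#' Which in-progress clusters can be finalized at a scan position?
#'
#' A cluster is safe to release for breakpoint resolution exactly when the
#' scan position has moved past its window end by more than the window
#' extension (mean + 3 sd): no future read's predicted interval can still
#' reach it. Applied repeatedly along a scan this yields the same cluster
#' set as batch clustering.
#'
#' @param clusters Cluster \code{GRanges} (in progress) on one chromosome.
#' @param scanPos Current 0-based scan position (monotone non-decreasing).
#' @param stats Insert-size statistics.
#' @return Logical vector: ready for release.
#' @export
finalizeReady <- function(clusters, scanPos, stats) {
  if (length(clusters) == 0L) return(logical(0))
  ext <- ceiling(stats$mean + 3 * stats$sd)
  scanPos > BiocGenerics::end(clusters) + ext
}

#' Stream evidence through clustering in position order
#'
#' Emulates the asynchronous scan: evidence is consumed in chunks, clusters
#' whose window can no longer be reached are released immediately, and the
#' concatenated releases equal one batch clustering of everything.
#'
#' @param evidence Sorted evidence \code{GRanges}.
#' @param stats Insert-size statistics.
#' @param cfg Pipeline configuration.
#' @param chunkSize Records per streaming step.
#' @return Same as \code{\link{clusterEvidence}}.
#' @export
clusterEvidenceStream <- function(evidence, stats, cfg = meiConfig(), chunkSize = 25L) {
  if (length(evidence) == 0L) return(clusterEvidence(evidence, stats, cfg))
  n <- length(evidence)
  released <- list()
  pendingIdx <- integer(0)
  emit <- function(gr) if (length(gr)) released[[length(released) + 1L]] <<- gr
  at <- 0L
  while (at < n) {
    take <- seq(at + 1L, min(at + chunkSize, n))
    at <- at + length(take)
    pendingIdx <- c(pendingIdx, take)
    scanChrom <- as.character(GenomicRanges::seqnames(evidence))[at]
    scanPos <- BiocGenerics::start(evidence)[at] - 1L
    cl <- clusterEvidence(evidence[pendingIdx], stats, cfg, allClusters = TRUE)
    sameChrom <- as.character(GenomicRanges::seqnames(cl)) == scanChrom
    ready <- !sameChrom | finalizeReady(cl, scanPos, stats)
    if (any(ready)) {
      done <- cl[ready]
      keep <- .isValidCluster(done, cfg)
      ## remap member indices back to the full evidence set
      S4Vectors::mcols(done)$members <- IRanges::IntegerList(
        lapply(S4Vectors::mcols(done)$members, function(ii) pendingIdx[ii]))
      emit(done[keep])
      used <- unlist(S4Vectors::mcols(cl[ready])$members)
      pendingIdx <- pendingIdx[-used]
    }
  }
  if (length(pendingIdx)) {
    cl <- clusterEvidence(evidence[pendingIdx], stats, cfg, allClusters = TRUE)
    S4Vectors::mcols(cl)$members <- IRanges::IntegerList(
      lapply(S4Vectors::mcols(cl)$members, function(ii) pendingIdx[ii]))
    emit(cl[.isValidCluster(cl, cfg)])
  }
  if (!length(released)) return(clusterEvidence(evidence[0], stats, cfg))
  out <- do.call(c, released)
  out[order(as.character(GenomicRanges::seqnames(out)), BiocGenerics::start(out))]
}

#' Write clusters as BED
#'
#' BED columns: chrom, start, end, name = family vote, score = support.
#' @param clusters Cluster \code{GRanges}.
#' @param path Output path.
#' @export
writeClustersBed <- function(clusters, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(clusters)),
                   start = BiocGenerics::start(clusters) - 1L,
                   end = BiocGenerics::end(clusters),
                   name = S4Vectors::mcols(clusters)$familyVote,
                   score = S4Vectors::mcols(clusters)$nSupport)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
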
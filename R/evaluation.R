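## Evaluation harness: match a call set against truth (or another call
## set) with a positional tolerance and summarize sensitivity, FDR and
## per-true-positive genotype/orientation concordance.

#' Match calls against truth with a positional tolerance
#'
#' Greedy nearest-position matching within \code{toleranceBp} on the same
#' chromosome (and same family unless \code{requireFamily = FALSE}); every
#' call and every truth record is matched at most once. Deterministic:
#' candidate pairs are taken in order of distance, then call index.
#'
#' @param calls Call \code{GRanges} (needs \code{mcols()$insertionPos}).
#' @param truth Truth \code{GRanges} from \code{\link{plantInsertions}}
#'   (needs \code{mcols()$pos0}).
#' @param toleranceBp Matching tolerance (default 100).
#' @param requireFamily Require the family to agree (default TRUE).
#' @return A list of class \code{meiMatchReport}: \code{tp}, \code{fp},
#'   \code{fn}, \code{sensitivity}, \code{fdr}, \code{genotypeConcordance},
#'   \code{orientationConcordance}, and the matched \code{pairs}
#'   data.frame.
#' @export
matchCalls <- function(calls, truth, toleranceBp = 100L, requireFamily = TRUE) {
  cm <- S4Vectors::mcols(calls); tm <- S4Vectors::mcols(truth)
  cChrom <- as.character(GenomicRanges::seqnames(calls))
  tChrom <- as.character(GenomicRanges::seqnames(truth))
  cPos <- cm$insertionPos; tPos <- tm$pos0
  nc <- length(calls); nt <- length(truth)
  cand <- NULL
  if (nc && nt) {
    cand <- do.call(rbind, lapply(seq_len(nc), function(i) {
      ok <- tChrom == cChrom[i] & abs(tPos - cPos[i]) <= toleranceBp
      if (requireFamily) ok <- ok & tm$family == cm$family[i]
      j <- which(ok)
      if (!length(j)) return(NULL)
      data.frame(call = i, truth = j, dist = abs(tPos[j] - cPos[i]))
    }))
  }
  usedC <- logical(nc); usedT <- logical(nt)
  pairs <- NULL
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$dist, cand$call, cand$truth), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand$call[k]; j <- cand$truth[k]
      if (usedC[i] || usedT[j]) next
      usedC[i] <- TRUE; usedT[j] <- TRUE
      pairs <- rbind(pairs, data.frame(call = i, truth = j, dist = cand$dist[k]))
    }
  }
  tp <- sum(usedC); fp <- nc - tp; fn <- nt - tp
  genoConc <- orientConc <- NA_real_
  if (tp > 0L) {
    cz <- cm$genotype[pairs$call]; tz <- tm$zygosity[pairs$truth]
    okG <- !is.na(cz)
    if (any(okG)) genoConc <- mean(cz[okG] == tz[okG])
    co <- cm$orientation[pairs$call]; to <- tm$orientation[pairs$truth]
    okO <- !is.na(co) & co != "unknown"
    if (any(okO)) orientConc <- mean(co[okO] == to[okO])
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
                 fdr = if (tp + fp > 0L) fp / (tp + fp) else NA_real_,
                 genotypeConcordance = genoConc,
                 orientationConcordance = orientConc,
                 pairs = if (is.null(pairs)) data.frame(call = integer(0),
                   truth = integer(0), dist = integer(0)) else pairs),
            class = "meiMatchReport")
}

#' @export
print.meiMatchReport <- function(x, ...) {
  cat(sprintf("meiMatchReport: TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  sensitivity %.4f  FDR %.4f\n", x$sensitivity, x$fdr))
  if (!is.na(x$genotypeConcordance))
    cat(sprintf("  genotype concordance %.4f\n", x$genotypeConcordance))
  if (!is.na(x$orientationConcordance))
    cat(sprintf("  orientation concordance %.4f\n", x$orientationConcordance))
  invisible(x)
}

#' Sensitivity/FDR across sequencing depths
#'
#' Plants one truth set, then for each depth simulates reads, aligns with
#' the provenance aligner, runs full detection and matches against the
#' common truth.
#'
#' @param reference Named \code{DNAStringSet}.
#' @param library A \code{\link{TELibrary}}.
#' @param scfg A \code{\link{simConfig}} (its depth field is ignored).
#' @param depths Numeric vector of at least two depths.
#' @param cfg Pipeline configuration.
#' @param toleranceBp Matching tolerance.
#' @return A data.frame (depth, sensitivity, fdr, tp, fp, fn).
#' @export
depthSweep <- function(reference, library, scfg, depths, cfg = meiConfig(),
                       toleranceBp = 100L) {
  stopifnot(length(depths) >= 2L)
  sim <- plantInsertions(reference, library, scfg)
  rows <- lapply(seq_along(depths), function(k) {
    d <- depths[k]
    if (d <= 0) {
      return(data.frame(depth = d, sensitivity = 0, fdr = NA_real_,
                        tp = 0L, fp = 0L, fn = length(sim$truth)))
    }
    reads <- generateReads(sim, scfg, depth = d, seedOffset = k)
    bam <- perfectAlign(reads, sim, scfg, tempfile())
    calls <- detectInsertions(bam, sim$reference, library, cfg, verbose = FALSE)
    r <- matchCalls(calls, sim$truth, toleranceBp)
    unlink(c(bam, paste0(bam, ".bai")))
    data.frame(depth = d, sensitivity = r$sensitivity, fdr = r$fdr,
               tp = r$tp, fp = r$fp, fn = r$fn)
  })
  do.call(rbind, rows)
}

#' Write a depth-sweep (or any) report table as TSV
#' @param df Data.frame.
#' @param path Output path.
#' @export
writeReport <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
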
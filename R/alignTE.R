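## Local alignment of candidate sequences (clipped parts, repeat-anchored
## mates, evidence contigs) against the TE consensus library.

#' Alignment parameter defaults shared across the pipeline
#'
#' Scoring is match +1 / mismatch -2 / gap open -5 / gap extend -2. A hit is
#' accepted when score >= minScore, identity >= minIdentity and the aligned
#' query span >= minClipLen, so one sequencing error in a 20 bp clip still
#' passes.
#'
#' @keywords internal
alignDefaults <- function() {
  list(minClipLen = 20L, minIdentity = 0.90, minScore = 16,
       match = 1, mismatch = -2, gapOpening = 5, gapExtension = 2)
}

subMatrix <- function(cfg) {
  Biostrings::nucleotideSubstitutionMatrix(match = cfg$match, mismatch = cfg$mismatch)
}

emptyHits <- function(n) {
  data.frame(family = rep(NA_character_, n), subfamily = NA_character_,
             teStrand = NA_character_, teStart = NA_integer_,
             teEnd = NA_integer_, score = NA_real_, identity = NA_real_,
             stringsAsFactors = FALSE)
}

## Exact-substring fast path: concatenated forward and reverse-complement
## library with '+' separators, searched per query. An exact full-length hit
## has identity 1 and the maximal possible score, so it cannot be beaten.
buildLibIndex <- function(library, cfg = alignDefaults()) {
  seqs <- consensusSeqs(library)
  sep <- paste(rep("+", 40L), collapse = "")
  catF <- Biostrings::DNAString(paste(as.character(seqs), collapse = sep))
  catR <- Biostrings::DNAString(paste(as.character(
    Biostrings::reverseComplement(seqs)), collapse = sep))
  w <- Biostrings::width(seqs)
  starts <- cumsum(c(1L, utils::head(w + 40L, -1L)))  # 1-based record starts
  list(library = library, cfg = cfg, catF = catF, catR = catR,
       catFchr = as.character(catF), catRchr = as.character(catR),
       starts = starts, widths = w,
       fwd = seqs, rev = Biostrings::reverseComplement(seqs),
       mat = subMatrix(cfg))
}

## locate which record a concatenated 1-based hit position falls in
.recordOf <- function(pos, idx) findInterval(pos, idx$starts)

## fraction of the dominant single base (A or T) in a sequence
.homopolymerFrac <- function(q) {
  n <- nchar(q)
  max(nchar(gsub("[^A]", "", q)), nchar(gsub("[^T]", "", q))) / n
}

#' Align sequences to the TE library
#'
#' Best local alignment of each query across all consensuses and both
#' strands. A hit is returned only when score, identity and aligned query
#' length pass the thresholds in \code{cfg}; ties are broken by higher
#' identity, then by library record order. Coordinates are 0-based
#' half-open on the forward consensus.
#'
#' @param seqs Character vector (or \code{DNAStringSet}) of query sequences.
#' @param library A \code{\link{TELibrary}} or the index from
#'   \code{buildLibIndex}.
#' @param cfg Alignment parameters (see \code{alignDefaults}).
#' @return A data.frame with one row per query: \code{family},
#'   \code{subfamily}, \code{teStrand}, \code{teStart}, \code{teEnd},
#'   \code{score}, \code{identity}; \code{NA} rows mean no acceptable hit.
#' @export
alignToTE <- function(seqs, library, cfg = alignDefaults()) {
  idx <- if (is(library, "TELibrary")) buildLibIndex(library, cfg) else library
  cfg <- idx$cfg
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  out <- emptyHits(n)
  if (n == 0L) return(out)
  todo <- which(nchar(seqs) >= cfg$minClipLen)

  ## stage 1: exact substring matches (identity 1, score = query length);
  ## near-pure poly-A/T queries are tails, not family-informative sequence,
  ## and are dismissed without alignment (they cannot reach minScore
  ## against the short consensus tails)
  meta <- idx$library@meta
  unresolved <- integer(0)
  for (i in todo) {
    q <- seqs[i]
    nA <- .homopolymerFrac(q)
    if (nA >= 0.8) next
    if (grepl("[^ACGT]", q)) { unresolved <- c(unresolved, i); next }
    pF <- regexpr(q, idx$catFchr, fixed = TRUE)[1L]
    pR <- if (pF > 0L) -1L else regexpr(q, idx$catRchr, fixed = TRUE)[1L]
    if (pF > 0L) {
      r <- .recordOf(pF, idx)
      s0 <- pF - idx$starts[r]                     # 0-based on fwd consensus
      out$family[i] <- meta$family[r]; out$subfamily[i] <- meta$subfamily[r]
      out$teStrand[i] <- "+"; out$teStart[i] <- s0
      out$teEnd[i] <- s0 + nchar(q)
      out$score[i] <- nchar(q) * cfg$match; out$identity[i] <- 1
    } else if (pR > 0L) {
      r <- .recordOf(pR, idx)
      s0 <- pR - idx$starts[r]                     # 0-based on revcomp consensus
      L <- idx$widths[r]
      out$family[i] <- meta$family[r]; out$subfamily[i] <- meta$subfamily[r]
      out$teStrand[i] <- "-"
      out$teStart[i] <- L - (s0 + nchar(q)); out$teEnd[i] <- L - s0
      out$score[i] <- nchar(q) * cfg$match; out$identity[i] <- 1
    } else unresolved <- c(unresolved, i)
  }

  ## stage 2: batched Smith-Waterman against each record and strand
  if (length(unresolved)) {
    pats <- Biostrings::DNAStringSet(seqs[unresolved])
    best <- data.frame(score = rep(-Inf, length(unresolved)), identity = -Inf,
                       rec = NA_integer_, strand = NA_character_,
                       start = NA_integer_, end = NA_integer_)
    for (r in seq_along(idx$widths)) {
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") idx$fwd[[r]] else idx$rev[[r]]
        pa <- Biostrings::pairwiseAlignment(pats, subj, type = "local",
                                            substitutionMatrix = idx$mat,
                                            gapOpening = cfg$gapOpening,
                                            gapExtension = cfg$gapExtension)
        sc <- Biostrings::score(pa)
        ident <- Biostrings::pid(pa, type = "PID1") / 100
        qw <- BiocGenerics::width(Biostrings::pattern(pa))
        sStart <- BiocGenerics::start(Biostrings::subject(pa))
        sEnd <- BiocGenerics::end(Biostrings::subject(pa))
        ok <- sc >= cfg$minScore & ident >= cfg$minIdentity & qw >= cfg$minClipLen
        better <- ok & (sc > best$score | (sc == best$score & ident > best$identity))
        if (any(better)) {
          best$score[better] <- sc[better]
          best$identity[better] <- ident[better]
          best$rec[better] <- r
          best$strand[better] <- strand
          if (strand == "+") {
            best$start[better] <- sStart[better] - 1L
            best$end[better] <- sEnd[better]
          } else {
            L <- idx$widths[r]
            best$start[better] <- L - sEnd[better]
            best$end[better] <- L - (sStart[better] - 1L)
          }
        }
      }
    }
    got <- which(is.finite(best$score))
    ii <- unresolved[got]
    out$family[ii] <- meta$family[best$rec[got]]
    out$subfamily[ii] <- meta$subfamily[best$rec[got]]
    out$teStrand[ii] <- best$strand[got]
    out$teStart[ii] <- best$start[got]
    out$teEnd[ii] <- best$end[got]
    out$score[ii] <- best$score[got]
    out$identity[ii] <- best$identity[got]
  }
  out
}
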
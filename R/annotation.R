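## Annotation of insertion calls: local greedy assembly of the supporting
## evidence into contigs, subfamily assignment via diagnostic nucleotides,
## orientation from strand votes plus poly-A/T tail concordance, and
## inserted length from the consensus span covered by the evidence.

## longest exact suffix(a)/prefix(b) overlap of at least minOverlap;
## containment counts as full-length overlap. Candidate overlap lengths are
## located by the occurrences of b's leading minOverlap-mer inside a, so
## non-overlapping pairs cost a single fixed-string search.
.bestOverlap <- function(a, b, minOverlap) {
  la <- nchar(a); lb <- nchar(b)
  ## containment
  if (lb <= la && grepl(b, a, fixed = TRUE)) return(list(len = lb, merged = a))
  seed <- substr(b, 1L, minOverlap)
  hits <- gregexpr(seed, a, fixed = TRUE)[[1]]
  if (hits[1L] == -1L) return(NULL)
  ks <- la - hits + 1L                       # implied overlap lengths
  ks <- sort(ks[ks >= minOverlap & ks <= min(la, lb)], decreasing = TRUE)
  for (k in ks) {
    if (substr(a, la - k + 1L, la) == substr(b, 1L, k))
      return(list(len = k, merged = paste0(a, substr(b, k + 1L, lb))))
  }
  NULL
}

#' Greedy overlap assembly of evidence sequences into contigs
#'
#' Repeatedly merges the pair with the longest exact suffix/prefix overlap
#' of at least \code{minOverlap} (containments first) until no pair
#' remains; ties are broken by lexicographic order of the sequences, so the
#' result is deterministic.
#'
#' @param seqs Character vector of DNA sequences.
#' @param minOverlap Minimum exact overlap (default 20).
#' @param maxSeqs Densest loci are capped at this many input sequences.
#' @return A data.frame of contigs: \code{seq}, \code{nReads}.
#' @export
assembleContigs <- function(seqs, minOverlap = 20L, maxSeqs = 32L) {
  seqs <- toupper(seqs[!is.na(seqs) & nzchar(seqs)])
  if (!length(seqs)) return(data.frame(seq = character(0), nReads = integer(0)))
  seqs <- sort(seqs)
  if (length(seqs) > maxSeqs) seqs <- seqs[seq_len(maxSeqs)]
  pool <- as.list(seqs)
  counts <- rep(1L, length(pool))
  ovl <- new.env(hash = TRUE)  # cached pairwise overlaps, keyed over stable ids
  ids <- seq_along(pool)
  nextId <- length(pool) + 1L
  getOv <- function(i, j) {
    key <- paste0(i, ":", j)
    v <- get0(key, envir = ovl)
    if (is.null(v)) {
      ov <- .bestOverlap(pool[[which(ids == i)]], pool[[which(ids == j)]], minOverlap)
      v <- if (is.null(ov)) list(none = TRUE) else ov
      assign(key, v, envir = ovl)
    }
    if (!is.null(v$none)) NULL else v
  }
  repeat {
    n <- length(pool)
    if (n < 2L) break
    best <- NULL
    for (ii in seq_len(n)) for (jj in seq_len(n)) {
      if (ii == jj) next
      ov <- getOv(ids[ii], ids[jj])
      if (is.null(ov)) next
      if (is.null(best) || ov$len > best$len ||
          (ov$len == best$len &&
           paste(pool[[ii]], pool[[jj]]) < paste(pool[[best$i]], pool[[best$j]]))) {
        best <- list(len = ov$len, merged = ov$merged, i = ii, j = jj)
      }
    }
    if (is.null(best)) break
    newCount <- counts[best$i] + counts[best$j]
    keep <- setdiff(seq_len(n), c(best$i, best$j))
    pool <- c(pool[keep], best$merged)
    counts <- c(counts[keep], newCount)
    ids <- c(ids[keep], nextId); nextId <- nextId + 1L
  }
  res <- unlist(pool)
  ord <- order(-nchar(res), res)
  data.frame(seq = res[ord], nReads = counts[ord], stringsAsFactors = FALSE)
}

## map a query onto one consensus: returns covered consensus range
## (1-based), matched/covered diagnostic counts, score, identity, strand
.alignForAnnotation <- function(query, consensusSeq, diag, strands = c("+", "-")) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -2)
  best <- NULL
  needCols <- !is.null(diag) && nrow(diag) > 0L
  for (strand in strands) {
    q <- if (strand == "+") query
         else as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
    pa <- Biostrings::pairwiseAlignment(q, consensusSeq, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(pa)
    if (is.null(best) || sc > best$score) {
      ident <- Biostrings::pid(pa, type = "PID1") / 100
      sStart <- BiocGenerics::start(Biostrings::subject(pa))
      sEnd <- BiocGenerics::end(Biostrings::subject(pa))
      consBase <- character(0); consPos <- integer(0)
      if (needCols) {
        ## per-column map: consensus position -> query base
        aQ <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
        aS <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
        sposAll <- sStart - 1L + cumsum(aS != "-")
        keep <- aS != "-" & aQ != "-"
        consPos <- sposAll[keep]
        consBase <- aQ[keep]
      }
      best <- list(score = sc, identity = ident, strand = strand,
                   sStart = sStart, sEnd = sEnd,
                   consPos = consPos, consBase = consBase)
    }
  }
  if (needCols) {
    dpos <- diag$consensus_pos + 1L        # to 1-based
    covered <- dpos %in% best$consPos
    matched <- covered & (best$consBase[match(dpos, best$consPos)] == diag$base)
    best$diagCovered <- sum(covered)
    best$diagMatched <- sum(matched, na.rm = TRUE)
  } else {
    best$diagCovered <- 0L; best$diagMatched <- 0L
  }
  best
}

#' Assign family and subfamily to an evidence contig
#'
#' The family comes from the best local alignment across the library
#' (identity at least \code{minIdentity} required, else \code{"unknown"}).
#' Within that family, the subfamily whose diagnostic sites covered by the
#' alignment are matched by the largest fraction wins; ties go to the
#' higher raw alignment score; a contig covering no diagnostic column gets
#' subfamily \code{"unresolved"}.
#'
#' @param contigSeq Contig DNA string.
#' @param library A \code{\link{TELibrary}} with diagnostics derived.
#' @param minIdentity Minimum alignment identity (default 0.85).
#' @return List: \code{family}, \code{subfamily}, \code{matchedDiagnostics},
#'   \code{totalDiagnostics}, \code{strand}, \code{consStart},
#'   \code{consEnd} (1-based), \code{score}.
#' @export
annotateSubfamily <- function(contigSeq, library, minIdentity = 0.85, libIndex = NULL) {
  fams <- teFamilies(library); subs <- teSubfamilies(library)
  diag <- diagnostics(library)
  noCall <- list(family = "unknown", subfamily = "unknown", record = NA_integer_,
                 matchedDiagnostics = 0L, totalDiagnostics = 0L,
                 strand = NA_character_, consStart = NA_integer_,
                 consEnd = NA_integer_, score = NA_real_)
  ## cheap family pass through the library aligner (exact fast path), then
  ## diagnostic scoring only within that family and on the hit strand
  if (is.null(libIndex)) {
    acfg <- alignDefaults(); acfg$minIdentity <- minIdentity
    libIndex <- buildLibIndex(library, acfg)
  }
  hit <- alignToTE(contigSeq, libIndex)
  if (is.na(hit$family) || hit$identity < minIdentity) return(noCall)
  family <- hit$family
  inFam <- which(fams == family)
  alns <- vector("list", length(library))
  for (r in inFam) {
    d <- diag[diag$subfamily == subs[r], , drop = FALSE]
    alns[[r]] <- .alignForAnnotation(contigSeq, consensusSeqs(library)[[r]], d,
                                     strands = hit$teStrand)
  }
  scores <- rep(-Inf, length(library))
  scores[inFam] <- vapply(inFam, function(r) alns[[r]]$score, 0)
  bestR <- which.max(scores)
  if (alns[[bestR]]$identity < minIdentity) return(noCall)
  covered <- vapply(inFam, function(r) alns[[r]]$diagCovered, 0L)
  ## matched fraction of the covered diagnostics; a subfamily covering no
  ## diagnostic column carries no evidence either way and scores 0
  frac <- vapply(inFam, function(r) {
    a <- alns[[r]]
    if (a$diagCovered == 0L) 0 else a$diagMatched / a$diagCovered
  }, 0)
  if (all(covered == 0L)) {
    pickR <- bestR
    subfamily <- "unresolved"
  } else {
    o <- order(-frac, -scores[inFam])
    pickR <- inFam[o[1L]]
    subfamily <- subs[pickR]
  }
  a <- alns[[pickR]]
  list(family = family, subfamily = subfamily, record = pickR,
       matchedDiagnostics = a$diagMatched, totalDiagnostics = a$diagCovered,
       strand = a$strand, consStart = a$sStart, consEnd = a$sEnd,
       score = a$score)
}

#' Orientation of an insertion from evidence strand votes and tails
#'
#' Majority vote over the TE-hit strands of the reference-oriented
#' supporting sequences; a tie gives \code{"unknown"}. A "+" insertion is
#' expected to show a poly-A run adjacent to its right junction and a "-"
#' insertion a poly-T run at its left junction; a contradicting tail with a
#' vote margin below 2 also gives \code{"unknown"}.
#'
#' @param strandVotes Character vector of "+"/"-" votes.
#' @param rightJunctionSeq Clipped/contig sequence left of the insertion's
#'   right junction (its end abuts the junction), or \code{NA}.
#' @param leftJunctionSeq Sequence right of the left junction (its start
#'   abuts the junction), or \code{NA}.
#' @param polyMinRun Minimum homopolymer run (one interruption allowed).
#' @return \code{"+"}, \code{"-"} or \code{"unknown"}.
#' @export
annotateOrientation <- function(strandVotes, rightJunctionSeq = NA,
                                leftJunctionSeq = NA, polyMinRun = 8L) {
  strandVotes <- strandVotes[!is.na(strandVotes)]
  nF <- sum(strandVotes == "+"); nR <- sum(strandVotes == "-")
  if (nF == nR) return("unknown")
  call <- if (nF > nR) "+" else "-"
  margin <- abs(nF - nR)
  tailSeen <- FALSE; tailContradicts <- FALSE
  hasA <- function(s) !is.na(s) && isPolyAT(s, polyMinRun, fromEnd = TRUE) &&
    grepl("A", substr(s, nchar(s) - 2L, nchar(s)))
  hasT <- function(s) !is.na(s) && isPolyAT(s, polyMinRun) &&
    grepl("T", substr(s, 1L, 3L))
  if (!is.na(rightJunctionSeq) || !is.na(leftJunctionSeq)) {
    polyA <- hasA(rightJunctionSeq)
    polyT <- hasT(leftJunctionSeq)
    tailSeen <- polyA || polyT
    if (tailSeen) {
      tailContradicts <- (call == "+" && !polyA && polyT) ||
                         (call == "-" && !polyT && polyA)
    }
  }
  if (tailContradicts && margin < 2L) return("unknown")
  call
}

#' Inserted length from consensus coverage
#'
#' \code{lMin}/\code{lMax} are the smallest and largest 1-based consensus
#' positions covered by any evidence alignment; the inserted length is
#' their span \code{lMax - lMin + 1} (a span, not a coverage sum).
#'
#' @param consStarts,consEnds 1-based covered ranges on the chosen
#'   subfamily consensus.
#' @return List with \code{lMin}, \code{lMax} and \code{lRetro}.
#' @export
annotateLength <- function(consStarts, consEnds) {
  keep <- !is.na(consStarts) & !is.na(consEnds)
  stopifnot(any(keep))
  lMin <- min(consStarts[keep]); lMax <- max(consEnds[keep])
  list(lMin = lMin, lMax = lMax, lRetro = lMax - lMin + 1L)
}

#' Annotate a set of calls from their supporting evidence
#'
#' For each call the supporting sequences (clipped parts plus
#' reference-oriented repeat-anchored mates) are assembled into contigs,
#' the best contig fixes family/subfamily, all evidence alignments to the
#' chosen consensus give the inserted length, and strand votes plus
#' junction tails give the orientation.
#'
#' @param calls Call data.frame from \code{\link{callCluster}} rows.
#' @param clusters Cluster \code{GRanges} parallel to \code{calls}.
#' @param evidence Evidence \code{GRanges}.
#' @param library A \code{\link{TELibrary}}.
#' @param cfg Pipeline configuration.
#' @return \code{calls} with family, subfamily, orientation, lengthBp,
#'   consStart/consEnd filled in.
#' @export
annotateCalls <- function(calls, clusters, evidence, library, cfg = meiConfig()) {
  if (!nrow(calls)) {
    calls$consStart <- integer(0); calls$consEnd <- integer(0)
    return(calls)
  }
  calls$consStart <- NA_integer_; calls$consEnd <- NA_integer_
  acfg <- alignDefaults(); acfg$minIdentity <- cfg$annotMinIdentity
  libIndex <- buildLibIndex(library, acfg)
  libSubs <- teSubfamilies(library)
  for (i in seq_len(nrow(calls))) {
    memberIdx <- S4Vectors::mcols(clusters)$members[[i]]
    mev <- S4Vectors::mcols(evidence[memberIdx])
    seqs <- unique(c(mev$teSeq[!is.na(mev$teSeq)]))
    contigs <- assembleContigs(seqs, minOverlap = cfg$asmMinOverlap)
    if (!nrow(contigs)) next
    ann <- annotateSubfamily(contigs$seq[1L], library, cfg$annotMinIdentity, libIndex)
    if (ann$family == "unknown") {
      ## fall back to the cluster's family vote
      calls$subfamily[i] <- "unresolved"
      next
    }
    calls$family[i] <- ann$family
    calls$subfamily[i] <- ann$subfamily
    ## length: span over alignments of every contig and evidence hit to the
    ## chosen (or best-aligned, if unresolved) subfamily's consensus
    r <- ann$record
    consChr <- as.character(consensusSeqs(library)[[r]])
    consRC <- revcompStr(consChr)
    Lr <- nchar(consChr)
    starts <- integer(0); ends <- integer(0)
    for (s in contigs$seq) {
      pF <- regexpr(s, consChr, fixed = TRUE)[1L]
      if (pF > 0L) { starts <- c(starts, pF); ends <- c(ends, pF + nchar(s) - 1L); next }
      pR <- regexpr(s, consRC, fixed = TRUE)[1L]
      if (pR > 0L) {
        starts <- c(starts, Lr - (pR + nchar(s) - 1L) + 1L)
        ends <- c(ends, Lr - pR + 1L); next
      }
      a <- .alignForAnnotation(s, consensusSeqs(library)[[r]], NULL)
      if (a$identity >= cfg$annotMinIdentity) {
        starts <- c(starts, a$sStart); ends <- c(ends, a$sEnd)
      }
    }
    ## evidence hits on the same subfamily contribute their consensus span
    sameSub <- !is.na(mev$subfamily) & mev$subfamily == teSubfamilies(library)[r]
    starts <- c(starts, mev$teStart[sameSub] + 1L)
    ends <- c(ends, mev$teEnd[sameSub])
    if (length(starts)) {
      len <- annotateLength(starts, ends)
      calls$lengthBp[i] <- len$lRetro
      calls$consStart[i] <- len$lMin
      calls$consEnd[i] <- len$lMax
    }
    ## orientation: strand votes from evidence hits; junction tails from the
    ## clipped sequences nearest each junction
    votes <- mev$teStrand[!is.na(mev$teStrand)]
    rightJ <- NA_character_; leftJ <- NA_character_
    if (!is.na(calls$bpRight[i])) {
      ## left-end clips sit right of bpRight: their sequence ends at the
      ## right junction of the inserted block
      cand <- !is.na(mev$clipPos) & mev$anchorSide == "right"
      if (any(cand)) rightJ <- mev$clippedSeq[which(cand)[1L]]
    }
    if (!is.na(calls$bpLeft[i])) {
      cand <- !is.na(mev$clipPos) & mev$anchorSide == "left"
      if (any(cand)) leftJ <- mev$clippedSeq[which(cand)[1L]]
    }
    calls$orientation[i] <- annotateOrientation(votes, rightJ, leftJ, cfg$polyMinRun)
  }
  calls
}
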
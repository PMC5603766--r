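## Discordant read-pair detection: classify paired-end reads into the three
## evidence categories that support a non-reference TE insertion:
##   RAM_PAIR  (i)   one mate unique on the reference, the other not unique
##                   there but hitting the TE library (repeat-anchored mate);
##   CLIP_PAIR (ii)  one mate unique and soft-clipped, the clipped part
##                   hitting the TE library;
##   CLIP_ONLY (iii) a soft-clipped read whose clipped part hits the library
##                   while its mate hits the library and is not unique on
##                   the reference.

## vectorized CIGAR helpers (primary alignments; hard clips are not emitted
## by the built-in aligner and supplementary records are skipped upstream)
leftClipLen <- function(cigar) {
  out <- integer(length(cigar))
  hit <- grepl("^[0-9]+S", cigar)
  if (any(hit))
    out[hit] <- as.integer(sub("S.*$", "", cigar[hit]))
  out
}

rightClipLen <- function(cigar) {
  out <- integer(length(cigar))
  hit <- grepl("[0-9]S$", cigar)
  if (any(hit))
    out[hit] <- as.integer(sub("S$", "", regmatches(cigar[hit], regexpr("[0-9]+S$", cigar[hit]))))
  out
}

refSpanWidth <- function(cigar) {
  out <- integer(length(cigar))
  ok <- !is.na(cigar) & nzchar(cigar) & cigar != "*"
  if (!any(ok)) return(out)
  out[ok] <- vapply(cigar[ok], function(cg) {
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    sum(len[ops %in% c("M", "D", "N", "=", "X")])
  }, 0L, USE.NAMES = FALSE)
  out
}

#' Construct an in-memory read record
#'
#' A plain-list stand-in for one BAM record, used by the pair classifier
#' and by tests. Coordinates are 0-based.
#'
#' @param qname Read name shared by both mates.
#' @param chrom Reference name, or \code{NA} when unmapped.
#' @param pos 0-based leftmost aligned position.
#' @param mapq Mapping quality (0-60).
#' @param cigar CIGAR string ("" when unmapped).
#' @param seq Read sequence as stored in the BAM (reference-oriented for
#'   mapped reads, as sequenced for unmapped ones).
#' @param isReverse,isRead1,isUnmapped,mateUnmapped Flags.
#' @param mateChrom,matePos Mate coordinates.
#' @return A list of class \code{readRecord}.
#' @export
readRecord <- function(qname, chrom = NA_character_, pos = NA_integer_,
                       mapq = 0L, cigar = "", seq = "",
                       isReverse = FALSE, isRead1 = TRUE,
                       isUnmapped = FALSE, mateUnmapped = FALSE,
                       mateChrom = NA_character_, matePos = NA_integer_) {
  structure(list(qname = qname, chrom = chrom, pos = as.integer(pos),
                 mapq = as.integer(mapq), cigar = cigar, seq = toupper(seq),
                 isReverse = isReverse, isRead1 = isRead1,
                 isUnmapped = isUnmapped, mateUnmapped = mateUnmapped,
                 mateChrom = mateChrom, matePos = as.integer(matePos)),
            class = "readRecord")
}

#' Is a read uniquely mapped?
#'
#' Uniqueness is operationalized as MAPQ at or above a threshold
#' (boundary inclusive); multi-mappers conventionally carry MAPQ 0.
#'
#' @param read A \code{\link{readRecord}}.
#' @param uniqueMapqMin Threshold (default 30).
#' @return Logical.
#' @export
isUniqueRead <- function(read, uniqueMapqMin = 30L) {
  if (isTRUE(read$isUnmapped)) stop("is_unique is undefined for an unmapped read")
  read$mapq >= uniqueMapqMin
}

## orient a mate sequence to the reference forward strand given its
## anchor's strand: in an FR pair the two reads sit on opposite fragment
## strands, so a forward anchor implies the (unplaced) mate was sequenced
## from the reverse strand.
orientMateSeq <- function(seq, anchorIsReverse) {
  if (anchorIsReverse) seq
  else as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## evidence assembled as plain lists; toEvidenceGRanges() converts
evidenceRow <- function(category, anchor, side, clipPos, clippedSeq, hit) {
  list(chrom = anchor$chrom, start = anchor$pos,
       end = anchor$pos + refSpanWidth(anchor$cigar),
       category = category, qname = anchor$qname,
       anchorSide = side, anchorMapq = anchor$mapq,
       anchorIsReverse = anchor$isReverse,
       clipPos = if (is.null(clipPos)) NA_integer_ else as.integer(clipPos),
       clippedSeq = if (is.null(clippedSeq)) NA_character_ else clippedSeq,
       teSeq = hit$teSeq,
       family = hit$family, subfamily = hit$subfamily,
       teStrand = hit$teStrand, teStart = hit$teStart, teEnd = hit$teEnd,
       score = hit$score, identity = hit$identity)
}

evidenceRowsToDf <- function(rows) {
  if (!length(rows)) return(NULL)
  col <- function(nm, fun, proto) vapply(rows, function(r) fun(r[[nm]]), proto)
  data.frame(
    chrom = col("chrom", as.character, ""),
    start = col("start", as.integer, 0L),
    end = col("end", as.integer, 0L),
    category = col("category", as.character, ""),
    qname = col("qname", as.character, ""),
    anchorSide = col("anchorSide", as.character, ""),
    anchorMapq = col("anchorMapq", as.integer, 0L),
    anchorIsReverse = col("anchorIsReverse", isTRUE, TRUE),
    clipPos = col("clipPos", as.integer, 0L),
    clippedSeq = col("clippedSeq", as.character, ""),
    teSeq = col("teSeq", as.character, ""),
    family = col("family", as.character, ""),
    subfamily = col("subfamily", as.character, ""),
    teStrand = col("teStrand", as.character, ""),
    teStart = col("teStart", as.integer, 0L),
    teEnd = col("teEnd", as.integer, 0L),
    score = col("score", as.numeric, 0),
    identity = col("identity", as.numeric, 0),
    stringsAsFactors = FALSE)
}

.clipInfo <- function(read, minClipLen) {
  lc <- leftClipLen(read$cigar); rc <- rightClipLen(read$cigar)
  res <- list()
  if (rc >= minClipLen) {
    boundary <- read$pos + refSpanWidth(read$cigar)
    res$right <- list(side = "left", clipPos = boundary,
                      seq = substr(read$seq, nchar(read$seq) - rc + 1L, nchar(read$seq)))
  }
  if (lc >= minClipLen) {
    res$left <- list(side = "right", clipPos = read$pos,
                     seq = substr(read$seq, 1L, lc))
  }
  res
}

## single-pair classifier. teHitFun maps a character vector of sequences to
## alignToTE() rows; by default it aligns on the fly.
classifyPairImpl <- function(r1, r2, library, cfg, teHitFun = NULL) {
  if (!identical(r1$qname, r2$qname)) stop("mates have different qnames")
  if (is.null(teHitFun)) {
    idx <- buildLibIndex(library, cfg$align)
    teHitFun <- function(s) alignToTE(s, idx)
  }
  uniq <- function(r) !isTRUE(r$isUnmapped) && r$mapq >= cfg$uniqueMapqMin
  hitOf <- function(s) { h <- teHitFun(s); h$teSeq <- s; h }

  ## criterion (ii): unique, soft-clipped anchor whose clipped part hits the
  ## library, with the mate placed on the reference
  for (ord in list(c(1, 2), c(2, 1))) {
    a <- list(r1, r2)[[ord[1]]]; b <- list(r1, r2)[[ord[2]]]
    if (!uniq(a) || isTRUE(b$isUnmapped)) next
    clips <- .clipInfo(a, cfg$align$minClipLen)
    for (cl in clips) {
      h <- hitOf(cl$seq)
      if (!is.na(h$family)) {
        return(evidenceRow("CLIP_PAIR", a, cl$side, cl$clipPos, cl$seq, h))
      }
    }
  }
  ## criterion (iii): a unique soft-clipped anchor whose clip hits the
  ## library, with the mate not unique on the reference and itself hitting
  ## the library. Under lenientIii the mate's library hit is not required,
  ## only its non-uniqueness.
  for (ord in list(c(1, 2), c(2, 1))) {
    a <- list(r1, r2)[[ord[1]]]; b <- list(r1, r2)[[ord[2]]]
    if (!uniq(a)) next
    mateNonUnique <- isTRUE(b$isUnmapped) || b$mapq < cfg$uniqueMapqMin
    if (!mateNonUnique) next
    clips <- .clipInfo(a, cfg$align$minClipLen)
    for (cl in clips) {
      h <- hitOf(cl$seq)
      if (is.na(h$family)) next
      if (!cfg$lenientIii) {
        mseq <- if (!is.null(b$orientedSeq)) b$orientedSeq
          else if (isTRUE(b$isUnmapped)) orientMateSeq(b$seq, a$isReverse) else b$seq
        mh <- teHitFun(mseq)
        if (is.na(mh$family)) next
      }
      return(evidenceRow("CLIP_ONLY", a, cl$side, cl$clipPos, cl$seq, h))
    }
  }
  ## criterion (i): one mate unique, other not unique on the reference but
  ## hitting the library (repeat-anchored mate)
  for (ord in list(c(1, 2), c(2, 1))) {
    a <- list(r1, r2)[[ord[1]]]; b <- list(r1, r2)[[ord[2]]]
    if (!uniq(a)) next
    mateNonUnique <- isTRUE(b$isUnmapped) || b$mapq < cfg$uniqueMapqMin
    if (!mateNonUnique) next
    mseq <- if (!is.null(b$orientedSeq)) b$orientedSeq
      else if (isTRUE(b$isUnmapped)) orientMateSeq(b$seq, a$isReverse) else b$seq
    h <- hitOf(mseq)
    if (!is.na(h$family)) {
      side <- if (a$isReverse) "right" else "left"
      return(evidenceRow("RAM_PAIR", a, side, NULL, NULL, h))
    }
  }
  NULL
}

#' Classify a read pair into a discordant-evidence category
#'
#' Applies the three criteria with precedence (ii) > (iii) > (i): clip
#' evidence carries a breakpoint and is never downgraded. Concordant pairs
#' return \code{NULL}. The call is symmetric in its two mates.
#'
#' @param r1,r2 \code{\link{readRecord}}s with the same qname.
#' @param library A \code{\link{TELibrary}}.
#' @param cfg Pipeline configuration, see \code{\link{meiConfig}}.
#' @return A one-row evidence data.frame or \code{NULL}.
#' @export
classifyPair <- function(r1, r2, library, cfg = meiConfig()) {
  row <- classifyPairImpl(r1, r2, library, cfg)
  if (is.null(row)) NULL else evidenceRowsToDf(list(row))
}

## ---- whole-BAM scan ---------------------------------------------------

readBamRecords <- function(bamPath, region = NULL) {
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq")
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, flag = flag)
  } else {
    hdr <- Rsamtools::scanBamHeader(bamPath)[[1]]$targets
    if (!region %in% names(hdr)) stop("region not in BAM header: ", region)
    Rsamtools::ScanBamParam(what = what, flag = flag,
      which = GenomicRanges::GRanges(region, IRanges::IRanges(1L, hdr[[region]])))
  }
  res <- Rsamtools::scanBam(bamPath, param = param)
  b <- res[[1]]
  if (length(res) > 1L) for (k in seq_along(b)) b[[k]] <- do.call(c, lapply(res, `[[`, k))
  data.frame(qname = b$qname, flag = b$flag,
             chrom = as.character(b$rname), pos = b$pos - 1L,
             mapq = b$mapq, cigar = ifelse(is.na(b$cigar), "", b$cigar),
             mateChrom = as.character(b$mrnm), matePos = b$mpos - 1L,
             seq = as.character(b$seq),
             isReverse = bitwAnd(b$flag, 16L) > 0L,
             isRead1 = bitwAnd(b$flag, 64L) > 0L,
             isUnmapped = bitwAnd(b$flag, 4L) > 0L,
             mateUnmapped = bitwAnd(b$flag, 8L) > 0L,
             stringsAsFactors = FALSE)
}

.checkBam <- function(bamPath) {
  if (!file.exists(bamPath)) stop("BAM not found: ", bamPath)
  if (!file.exists(paste0(bamPath, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bamPath)))
    stop("BAM index (.bai) missing for ", bamPath)
  hdr <- Rsamtools::scanBamHeader(bamPath)[[1]]$text
  hd <- hdr[names(hdr) == "@HD"]
  if (length(hd) && !any(grepl("SO:coordinate", unlist(hd))))
    stop("BAM is not coordinate-sorted: ", bamPath)
  invisible(TRUE)
}

rowRecord <- function(df, i) {
  r <- readRecord(df$qname[i], df$chrom[i], df$pos[i], df$mapq[i], df$cigar[i],
                  df$seq[i], df$isReverse[i], df$isRead1[i], df$isUnmapped[i],
                  df$mateUnmapped[i], df$mateChrom[i], df$matePos[i])
  if (!is.null(df$orientedSeq) && !is.na(df$orientedSeq[i]))
    r$orientedSeq <- df$orientedSeq[i]
  r
}

#' Scan a BAM for discordant TE-insertion evidence
#'
#' Streams primary alignments, pairs mates by name, and classifies each
#' pair with \code{\link{classifyPair}}. Candidate pairs are pre-filtered
#' vectorized (a pair with both mates uniquely mapped and no soft clip of
#' at least \code{minClipLen} cannot be evidence) and all TE-library
#' alignments are batched. Evidence is returned sorted by (chrom, anchor
#' position); scanning per chromosome and concatenating gives the same
#' result as one whole-file scan.
#'
#' @param bamPath Coordinate-sorted, indexed BAM.
#' @param library A \code{\link{TELibrary}}.
#' @param cfg Pipeline configuration, see \code{\link{meiConfig}}.
#' @param region Optional chromosome name restricting the scan.
#' @return A \link[GenomicRanges]{GRanges} of evidence records (anchor
#'   spans) with metadata columns category, qname, anchorSide, clipPos,
#'   clippedSeq, teSeq, family, subfamily, teStrand, score, identity.
#' @export
scanDiscordant <- function(bamPath, library, cfg = meiConfig(), region = NULL) {
  .checkBam(bamPath)
  df <- readBamRecords(bamPath, region)
  if (nrow(df) == 0L) return(toEvidenceGRanges(NULL))
  ## pair mates by qname
  ord <- order(df$qname, !df$isRead1, method = "radix")
  df <- df[ord, , drop = FALSE]
  qn <- df$qname
  first <- which(c(TRUE, qn[-1L] != qn[-length(qn)]))
  cnt <- diff(c(first, length(qn) + 1L))
  paired <- first[cnt == 2L]
  if (!length(paired)) return(toEvidenceGRanges(NULL))
  i1 <- paired; i2 <- paired + 1L

  minClip <- cfg$align$minClipLen
  uniq <- !df$isUnmapped & df$mapq >= cfg$uniqueMapqMin
  hasClip <- pmax(leftClipLen(df$cigar), rightClipLen(df$cigar)) >= minClip
  candidate <- !(uniq[i1] & uniq[i2] & !hasClip[i1] & !hasClip[i2]) &
               !(df$isUnmapped[i1] & df$isUnmapped[i2])
  i1 <- i1[candidate]; i2 <- i2[candidate]
  if (!length(i1)) return(toEvidenceGRanges(NULL))

  ## batch all TE alignments the classifier may request (clipped parts of
  ## mapped candidate reads; reference-oriented sequences of non-unique mates)
  cand <- unique(c(i1, i2))
  lc <- leftClipLen(df$cigar[cand]); rc <- rightClipLen(df$cigar[cand])
  len <- nchar(df$seq[cand])
  mapped <- !df$isUnmapped[cand]
  clipSeqs <- c(substr(df$seq[cand], 1L, lc)[mapped & lc >= minClip],
                substr(df$seq[cand], len - rc + 1L, len)[mapped & rc >= minClip])
  revcompChar <- function(s) {
    if (!length(s)) return(character(0))
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  }
  mate1 <- !uniq[i1]   # r1 is the non-unique mate; its anchor is r2
  mate2 <- !uniq[i2]
  ## reference-oriented mate sequences, stored on the record so the
  ## classifier never re-orients: mapped multi-mappers are already
  ## reference-oriented; unmapped mates of a forward anchor were sequenced
  ## from the opposite strand
  df$orientedSeq <- NA_character_
  fillOrient <- function(sel, i, j) {
    ii <- i[sel]
    unm <- df$isUnmapped[ii]
    anchRev <- df$isReverse[j[sel]]
    out <- df$seq[ii]
    flip <- unm & !anchRev
    out[flip] <- revcompChar(out[flip])
    df$orientedSeq[ii] <<- out
    out
  }
  mateSeqs <- c(fillOrient(mate1, i1, i2), fillOrient(mate2, i2, i1))
  needSeq <- unique(c(clipSeqs, mateSeqs))
  idx <- buildLibIndex(library, cfg$align)
  hits <- alignToTE(needSeq, idx)
  hashEnv <- new.env(hash = TRUE, size = length(needSeq) * 2L)
  for (j in seq_along(needSeq)) assign(needSeq[j], j, envir = hashEnv)
  lookup <- function(s) {
    j <- mget(s, envir = hashEnv, ifnotfound = NA_integer_)[[1L]]
    if (!is.na(j)) hits[j, , drop = FALSE] else alignToTE(s, idx)
  }

  ev <- vector("list", length(i1))
  for (k in seq_along(i1)) {
    ev[[k]] <- classifyPairImpl(rowRecord(df, i1[k]), rowRecord(df, i2[k]),
                                library, cfg, teHitFun = lookup)
  }
  ev <- ev[!vapply(ev, is.null, TRUE)]
  toEvidenceGRanges(evidenceRowsToDf(ev))
}

#' @keywords internal
toEvidenceGRanges <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      category = character(0), qname = character(0), anchorSide = character(0),
      anchorMapq = integer(0), anchorIsReverse = logical(0),
      clipPos = integer(0), clippedSeq = character(0), teSeq = character(0),
      family = character(0), subfamily = character(0), teStrand = character(0),
      teStart = integer(0), teEnd = integer(0),
      score = numeric(0), identity = numeric(0))
    return(gr)
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[, !(names(df) %in% c("chrom", "start", "end")), drop = FALSE])
  gr
}

#' Write evidence to the sorted tab-separated intermediate format
#'
#' Mirrors the two-step architecture: the scan step can spill its evidence
#' and the clustering step can reload it.
#'
#' @param evidence Evidence \code{GRanges} from \code{\link{scanDiscordant}}.
#' @param path Output path.
#' @export
writeEvidence <- function(evidence, path) {
  df <- as.data.frame(evidence)
  df$start <- df$start - 1L  # back to 0-based
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
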
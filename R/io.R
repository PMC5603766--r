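## Call-set writers: BED6+ and a minimal VCF 4.2 with symbolic mobile
## element ALT alleles.

#' Write insertion calls as BED6+
#'
#' Columns: chrom, start, end (the insertion point), family:subfamily,
#' support, orientation, then tsdSeq, genotype, lengthBp, supportRam,
#' supportClip, spanningRefReads.
#'
#' @param calls Call \code{GRanges} from \code{\link{detectInsertions}}.
#' @param path Output path.
#' @export
writeCallsBed <- function(calls, path) {
  m <- S4Vectors::mcols(calls)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(calls)),
                   start = m$insertionPos, end = m$insertionPos + 1L,
                   name = paste(m$family, m$subfamily, sep = ":"),
                   score = m$supportRam + m$supportClip,
                   strand = ifelse(m$orientation == "unknown", ".", m$orientation),
                   tsdSeq = ifelse(is.na(m$tsdSeq), ".", m$tsdSeq),
                   genotype = m$genotype,
                   lengthBp = ifelse(is.na(m$lengthBp), ".", m$lengthBp),
                   supportRam = m$supportRam, supportClip = m$supportClip,
                   spanningRefReads = m$spanningRefReads)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6+ call file back into a call GRanges
#'
#' @param path BED6+ file written by \code{\link{writeCallsBed}}.
#' @return A call \code{GRanges}.
#' @export
readCallsBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name", "score",
                                        "strand", "tsdSeq", "genotype", "lengthBp",
                                        "supportRam", "supportClip",
                                        "spanningRefReads"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character",
                                         "character", "character", "character",
                                         "integer", "integer", "integer"))
  calls <- data.frame(chrom = df$chrom, insertionPos = df$start,
                      bpLeft = NA_integer_, bpRight = NA_integer_,
                      tsdSeq = ifelse(df$tsdSeq == ".", NA_character_, df$tsdSeq),
                      family = sub(":.*$", "", df$name),
                      subfamily = sub("^[^:]*:", "", df$name),
                      orientation = ifelse(df$strand == ".", "unknown", df$strand),
                      lengthBp = suppressWarnings(as.integer(df$lengthBp)),
                      genotype = df$genotype,
                      supportRam = df$supportRam, supportClip = df$supportClip,
                      spanningRefReads = df$spanningRefReads,
                      imprecise = NA, stringsAsFactors = FALSE)
  callsToGRanges(calls)
}

#' Write insertion calls as minimal VCF 4.2
#'
#' Symbolic \code{ALT=<INS:ME:FAMILY>} records with INFO keys TSD, MEINFO
#' (subfamily, consensus start/end, strand), SVLEN and IMPRECISE, and a
#' single-sample GT column. Positions are 1-based per VCF.
#'
#' @param calls Call \code{GRanges}.
#' @param refSeq Reference \code{DNAStringSet} (for the REF base).
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @export
writeCallsVcf <- function(calls, refSeq, path, sample = "SAMPLE") {
  m <- S4Vectors::mcols(calls)
  chrom <- as.character(GenomicRanges::seqnames(calls))
  pos1 <- m$insertionPos + 1L
  refBase <- vapply(seq_along(calls), function(i)
    as.character(Biostrings::subseq(refSeq[[chrom[i]]], pos1[i], pos1[i])), "")
  gt <- ifelse(is.na(m$genotype), "./.",
               ifelse(m$genotype == "HOM", "1/1", "0/1"))
  info <- vapply(seq_along(calls), function(i) {
    parts <- c(
      if (!is.na(m$tsdSeq[i]) && nzchar(m$tsdSeq[i])) paste0("TSD=", m$tsdSeq[i]),
      paste0("MEINFO=", m$subfamily[i], ",",
             if (!is.null(m$consStart) && !is.na(m$consStart[i])) m$consStart[i] else ".",
             ",",
             if (!is.null(m$consEnd) && !is.na(m$consEnd[i])) m$consEnd[i] else ".",
             ",", m$orientation[i]),
      if (!is.na(m$lengthBp[i])) paste0("SVLEN=", m$lengthBp[i]),
      if (isTRUE(m$imprecise[i])) "IMPRECISE")
    paste(parts, collapse = ";")
  }, "")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=MEIdetect",
           paste0("##contig=<ID=", names(refSeq), ",length=",
                  Biostrings::width(refSeq), ">"),
           "##ALT=<ID=INS:ME:ALU,Description=\"Alu element insertion\">",
           "##ALT=<ID=INS:ME:L1,Description=\"L1 element insertion\">",
           "##ALT=<ID=INS:ME:SVA,Description=\"SVA element insertion\">",
           "##ALT=<ID=INS:ME:LTR,Description=\"LTR element insertion\">",
           "##INFO=<ID=TSD,Number=1,Type=String,Description=\"Target site duplication\">",
           "##INFO=<ID=MEINFO,Number=4,Type=String,Description=\"Mobile element info: NAME,START,END,POLARITY\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Inserted length\">",
           "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoint\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- paste(chrom, pos1, ".", refBase,
                paste0("<INS:ME:", toupper(m$family), ">"),
                ".", "PASS", info, "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Merge per-sample call sets into a multi-sample genotype matrix
#'
#' Loci are unified greedily across samples with a positional tolerance
#' (same chromosome and family). Genotype codes: 0 absent, 1 HET, 2 HOM.
#'
#' @param callSets Named list of call \code{GRanges}.
#' @param toleranceBp Locus-unification tolerance (default 100).
#' @return A list: \code{loci} (\code{GRanges}) and \code{genotypes}
#'   (matrix loci x samples).
#' @export
mergeCallSets <- function(callSets, toleranceBp = 100L) {
  stopifnot(length(callSets) >= 1L)
  if (is.null(names(callSets)))
    names(callSets) <- paste0("S", seq_along(callSets))
  lociChrom <- character(0); lociPos <- integer(0); lociFam <- character(0)
  geno <- NULL
  for (s in seq_along(callSets)) {
    cs <- callSets[[s]]
    m <- S4Vectors::mcols(cs)
    col <- integer(0)
    gcol <- rep(0L, length(lociPos))
    for (i in seq_along(cs)) {
      ch <- as.character(GenomicRanges::seqnames(cs))[i]
      p <- m$insertionPos[i]
      fam <- m$family[i]
      hit <- which(lociChrom == ch & lociFam == fam &
                   abs(lociPos - p) <= toleranceBp)
      if (length(hit)) {
        j <- hit[which.min(abs(lociPos[hit] - p))]
      } else {
        lociChrom <- c(lociChrom, ch); lociPos <- c(lociPos, p)
        lociFam <- c(lociFam, fam)
        if (!is.null(geno)) geno <- rbind(geno, matrix(0L, 1L, ncol(geno)))
        gcol <- c(gcol, 0L)
        j <- length(lociPos)
      }
      gcol[j] <- if (!is.na(m$genotype[i]) && m$genotype[i] == "HOM") 2L else 1L
    }
    geno <- if (is.null(geno)) matrix(gcol, ncol = 1L)
            else cbind(geno, gcol[seq_len(nrow(geno))])
  }
  colnames(geno) <- names(callSets)
  ord <- order(lociChrom, lociPos)
  loci <- GenomicRanges::GRanges(lociChrom[ord],
                                 IRanges::IRanges(lociPos[ord] + 1L,
                                                  lociPos[ord] + 1L))
  S4Vectors::mcols(loci)$family <- lociFam[ord]
  list(loci = loci, genotypes = geno[ord, , drop = FALSE])
}
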
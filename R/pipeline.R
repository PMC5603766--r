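#' Pipeline configuration
#'
#' Every tunable threshold of the caller in one validated list. Unknown
#' names are rejected.
#'
#' @param uniqueMapqMin MAPQ at or above which a read counts as uniquely
#'   mapped (default 30).
#' @param minClipLen Minimum soft-clip length considered as TE evidence
#'   (default 20 bp).
#' @param minIdentity Minimum identity of a TE-library hit (default 0.90).
#' @param minScore Minimum local alignment score of a TE-library hit
#'   (match +1 / mismatch -2 / gap open -5 / gap extend -2; default 16).
#' @param minSupport Minimum total evidence records for a valid cluster
#'   (default 3).
#' @param minClipSupport Clip-bearing records that alone validate a
#'   cluster (default 2).
#' @param recalMinClip Minimum soft-clip length contributing a clip point
#'   during breakpoint recalibration (default 8 bp).
#' @param smallDelMax Deletions shorter than this are collapsed during
#'   recalibration (default 10 bp).
#' @param terminalWindow Window for terminal-mismatch rescue (default 10 bp).
#' @param discordantIdentityMax Clipped sequence vs reference identity
#'   below which the clip is discordant (default 0.8).
#' @param gapFractionMax Maximum gapped fraction in the clip-consensus
#'   alignment (default 0.3).
#' @param junctionMismatchMax Maximum junction mismatch run (default 5 bp).
#' @param polyMinRun Minimum poly-A/T run, one interruption allowed
#'   (default 8).
#' @param tsdMax Maximum breakpoint separation still called a TSD
#'   (default 50 bp).
#' @param homMaxRefFraction Reference-allele fraction at or below which a
#'   call is homozygous (default 0.15).
#' @param spanMargin Bases a spanning read must reach past each breakpoint
#'   (default 5).
#' @param asmMinOverlap Minimum exact overlap in contig assembly
#'   (default 20 bp).
#' @param annotMinIdentity Minimum contig-to-consensus identity for
#'   annotation (default 0.85).
#' @param lenientIii Relax criterion (iii): do not require the mate's
#'   library hit, only its non-uniqueness.
#' @param readLenHint Read length used to pad breakpoint windows (reset
#'   from the BAM during \code{\link{detectInsertions}}).
#' @param seed Seed for any randomized step.
#' @return A list of class \code{meiConfig}.
#' @export
meiConfig <- function(uniqueMapqMin = 30L, minClipLen = 20L,
                      minIdentity = 0.90, minScore = 16,
                      minSupport = 3L, minClipSupport = 2L,
                      recalMinClip = 8L, smallDelMax = 10L,
                      terminalWindow = 10L, discordantIdentityMax = 0.8,
                      gapFractionMax = 0.3, junctionMismatchMax = 5L,
                      polyMinRun = 8L, tsdMax = 50L,
                      homMaxRefFraction = 0.15, spanMargin = 5L,
                      asmMinOverlap = 20L, annotMinIdentity = 0.85,
                      lenientIii = FALSE, readLenHint = 100L, seed = 1L) {
  cfg <- list(uniqueMapqMin = as.integer(uniqueMapqMin),
              align = list(minClipLen = as.integer(minClipLen),
                           minIdentity = minIdentity, minScore = minScore,
                           match = 1, mismatch = -2,
                           gapOpening = 5, gapExtension = 2),
              minSupport = as.integer(minSupport),
              minClipSupport = as.integer(minClipSupport),
              recalMinClip = as.integer(recalMinClip),
              smallDelMax = as.integer(smallDelMax),
              terminalWindow = as.integer(terminalWindow),
              discordantIdentityMax = discordantIdentityMax,
              gapFractionMax = gapFractionMax,
              junctionMismatchMax = as.integer(junctionMismatchMax),
              polyMinRun = as.integer(polyMinRun),
              tsdMax = as.integer(tsdMax),
              homMaxRefFraction = homMaxRefFraction,
              spanMargin = as.integer(spanMargin),
              asmMinOverlap = as.integer(asmMinOverlap),
              annotMinIdentity = annotMinIdentity,
              lenientIii = isTRUE(lenientIii),
              readLenHint = as.integer(readLenHint),
              seed = as.integer(seed))
  class(cfg) <- "meiConfig"
  cfg
}

#' Read a configuration from a YAML-like key: value file
#'
#' Flat \code{key: value} lines; unknown keys are rejected; omitted keys
#' keep their defaults.
#'
#' @param path Config file path.
#' @return A \code{\link{meiConfig}}.
#' @export
readMeiConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*:\\s*(\\S+)\\s*$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  known <- names(formals(meiConfig))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- lapply(stats::setNames(vals, keys), function(v) {
    if (v %in% c("TRUE", "FALSE", "true", "false")) as.logical(toupper(v))
    else as.numeric(v)
  })
  do.call(meiConfig, args)
}

#' End-to-end insertion detection
#'
#' Runs scan, insert-size estimation, clustering, breakpoint resolution and
#' annotation, logging per-stage counts. Deterministic for identical
#' inputs and configuration.
#'
#' @param bamPath Coordinate-sorted, indexed BAM.
#' @param refSeq Named \code{DNAStringSet} of the reference (or a FASTA
#'   path).
#' @param library A \code{\link{TELibrary}} (diagnostics derived for
#'   subfamily annotation).
#' @param cfg Pipeline configuration.
#' @param annotate Run the annotation stage (default TRUE).
#' @param verbose Log stage counts with \code{message()}.
#' @return A \code{GRanges} of insertion calls (1-based start = insertion
#'   point + 1) with call fields in \code{mcols()}.
#' @export
detectInsertions <- function(bamPath, refSeq, library, cfg = meiConfig(),
                             annotate = TRUE, verbose = TRUE) {
  if (is.character(refSeq)) refSeq <- Biostrings::readDNAStringSet(refSeq)
  names(refSeq) <- sub("\\s.*$", "", names(refSeq))
  say <- function(...) if (verbose) message("[MEIdetect] ", ...)
  evidence <- scanDiscordant(bamPath, library, cfg)
  say("scan: ", length(evidence), " evidence record(s)")
  stats <- estimateInsertSize(bamPath)
  cfg$readLenHint <- stats$readLen
  say(sprintf("insert size: mean %.1f sd %.1f readLen %d",
              stats$mean, stats$sd, stats$readLen))
  clusters <- clusterEvidence(evidence, stats, cfg)
  say("clustering: ", length(clusters), " valid cluster(s)")
  calls <- lapply(seq_along(clusters), function(i)
    callCluster(bamPath, refSeq, clusters[i], evidence, cfg))
  calls <- if (length(calls)) do.call(rbind, calls)
           else callCluster(bamPath, refSeq, clusters, evidence, cfg)[0, ]
  say("breakpoints: ", nrow(calls), " call(s), ",
      sum(!is.na(calls$tsdSeq)), " with TSD")
  if (annotate && nrow(calls)) {
    calls <- annotateCalls(calls, clusters, evidence, library, cfg)
    say("annotation: ", sum(calls$subfamily != "unresolved", na.rm = TRUE),
        " subfamily-resolved")
  }
  callsToGRanges(calls)
}

#' @keywords internal
callsToGRanges <- function(calls) {
  if (is.null(calls) || !nrow(calls)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      insertionPos = integer(0), bpLeft = integer(0), bpRight = integer(0),
      tsdSeq = character(0), family = character(0), subfamily = character(0),
      orientation = character(0), lengthBp = integer(0), genotype = character(0),
      supportRam = integer(0), supportClip = integer(0),
      spanningRefReads = integer(0), imprecise = logical(0))
    return(gr)
  }
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$insertionPos + 1L,
                                                calls$insertionPos + 1L))
  keep <- setdiff(names(calls), c("chrom", "consStart", "consEnd"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(calls[, keep, drop = FALSE])
  if (!is.null(calls$consStart)) {
    S4Vectors::mcols(gr)$consStart <- calls$consStart
    S4Vectors::mcols(gr)$consEnd <- calls$consEnd
  }
  gr
}
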
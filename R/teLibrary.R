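#' Read a retrotransposon consensus library from FASTA
#'
#' Each FASTA header must encode the record's family and subfamily as
#' \code{family#subfamily} (RepeatMasker-style naming); the pattern is
#' configurable through \code{headerRegex}, whose two capture groups are
#' taken as family and subfamily.
#'
#' @param fastaPath Path to the library FASTA.
#' @param headerRegex Regular expression with exactly two capture groups.
#' @return A \code{\link{TELibrary}} with empty diagnostics.
#' @examples
#' fa <- system.file("extdata", "te_consensus_synthetic.fa", package = "MEIdetect")
#' lib <- readTELibrary(fa)
#' lib
#' @export
readTELibrary <- function(fastaPath, headerRegex = "^([^#]+)#(.+)$") {
  if (!file.exists(fastaPath)) stop("FASTA not found: ", fastaPath)
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  if (length(seqs) == 0L) stop("no records in library FASTA: ", fastaPath)
  hdr <- sub("\\s.*$", "", names(seqs))
  m <- regmatches(hdr, regexec(headerRegex, hdr))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed library header (expected family#subfamily): ",
         paste(hdr[bad], collapse = ", "))
  fam <- vapply(m, `[`, "", 2L)
  sub <- vapply(m, `[`, "", 3L)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- paste(fam, sub, sep = "#")
  new("TELibrary",
      consensus = seqs,
      meta = S4Vectors::DataFrame(family = fam, subfamily = sub),
      diagnostics = emptyDiagnostics())
}

emptyDiagnostics <- function() {
  S4Vectors::DataFrame(family = character(0), subfamily = character(0),
                       column = integer(0), base = character(0),
                       consensus_pos = integer(0))
}

## ---- multiple alignment of subfamily consensuses ----------------------

## Center-star progressive alignment: every sequence is globally aligned to
## the longest one (match +1, mismatch -1, gap -2) and the pairwise gap
## patterns are merged into one set of columns. Subfamily consensuses are
## >95% identical, so any reasonable MSA agrees on the columns.
alignSubfamilies <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  center <- which.max(nchar(seqs))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  rows <- list()
  rows[[center]] <- strsplit(seqs[[center]], "")[[1]]
  master <- rows[[center]]             # gapped center row, grows as gaps merge
  for (i in seq_len(n)[-center]) {
    pa <- Biostrings::pairwiseAlignment(seqs[[center]], seqs[[i]],
                                        type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 2)
    cg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    rg <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ## project this pairwise alignment onto the master center row by
    ## walking both gapped center representations simultaneously
    j <- 1L   # index into cg/rg
    k <- 1L   # index into master
    outRow <- character(0)
    masterMap <- integer(0)  # for each output column, source master column or NA
    while (j <= length(cg) || k <= length(master)) {
      mIsGap <- k <= length(master) && master[k] == "-"
      cIsGap <- j <= length(cg) && cg[j] == "-"
      if (k <= length(master) && j <= length(cg) && !mIsGap && !cIsGap) {
        outRow <- c(outRow, rg[j]); masterMap <- c(masterMap, k)
        j <- j + 1L; k <- k + 1L
      } else if (mIsGap) {
        ## column inserted by an earlier sequence; this one gets a gap
        outRow <- c(outRow, "-"); masterMap <- c(masterMap, k)
        k <- k + 1L
      } else if (cIsGap) {
        ## new column inserted by sequence i
        outRow <- c(outRow, rg[j]); masterMap <- c(masterMap, NA_integer_)
        j <- j + 1L
      } else if (j > length(cg)) {
        outRow <- c(outRow, "-"); masterMap <- c(masterMap, k); k <- k + 1L
      } else {
        outRow <- c(outRow, rg[j]); masterMap <- c(masterMap, NA_integer_)
        j <- j + 1L
      }
    }
    ## rebuild master and pad existing rows where new columns appeared
    newMasterRow <- ifelse(is.na(masterMap), "-", master[pmax(masterMap, 1L)])
    for (r in seq_along(rows)) {
      if (is.null(rows[[r]])) next
      old <- rows[[r]]
      padded <- ifelse(is.na(masterMap), "-", old[pmax(masterMap, 1L)])
      rows[[r]] <- padded
    }
    master <- newMasterRow
    rows[[i]] <- outRow
  }
  do.call(rbind, rows)
}

#' Derive subfamily-diagnostic nucleotides for one family
#'
#' Aligns the family's subfamily consensuses and reports every alignment
#' column at which exactly one subfamily carries a base different from the
#' single base shared by all other subfamilies (all non-gap). With two
#' subfamilies each differing column yields a site for both. Sites are
#' sorted by alignment column.
#'
#' @param library A \code{\link{TELibrary}}.
#' @param family One of \code{"Alu"}, \code{"L1"}, \code{"SVA"}, \code{"LTR"}.
#' @return A \code{DataFrame} of diagnostic sites (0-based \code{column} in
#'   the alignment, \code{base}, 0-based \code{consensus_pos} on the
#'   subfamily's own consensus).
#' @export
deriveDiagnostics <- function(library, family) {
  sel <- teFamilies(library) == family
  if (sum(sel) < 2L)
    stop("need >= 2 subfamilies in family '", family, "' to derive diagnostics")
  seqs <- as.character(consensusSeqs(library)[sel])
  subs <- teSubfamilies(library)[sel]
  aln <- alignSubfamilies(seqs)           # rows x columns character matrix
  nsub <- nrow(aln)
  ## ungapped position of each column per row (0-based)
  upos <- apply(aln != "-", 1L, cumsum)   # columns x rows
  out <- list()
  for (col in seq_len(ncol(aln))) {
    bases <- aln[, col]
    if (any(!bases %in% c("A", "C", "G", "T"))) next
    for (s in seq_len(nsub)) {
      others <- bases[-s]
      if (length(unique(others)) == 1L && others[1L] != bases[s]) {
        out[[length(out) + 1L]] <- data.frame(
          family = family, subfamily = subs[s],
          column = col - 1L, base = bases[s],
          consensus_pos = upos[col, s] - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(emptyDiagnostics())
  df <- do.call(rbind, out)
  df <- df[order(df$column, df$subfamily), , drop = FALSE]
  rownames(df) <- NULL
  S4Vectors::DataFrame(df)
}

#' Derive diagnostics for every family with at least two subfamilies
#'
#' @param library A \code{\link{TELibrary}}.
#' @return The library with its \code{diagnostics} slot filled.
#' @export
deriveAllDiagnostics <- function(library) {
  fams <- unique(teFamilies(library))
  res <- lapply(fams, function(f) {
    if (sum(teFamilies(library) == f) >= 2L) deriveDiagnostics(library, f)
    else emptyDiagnostics()
  })
  library@diagnostics <- do.call(rbind, res)
  validObject(library)
  library
}

#' Write or read diagnostic sites as a tab-separated file
#'
#' @param library A \code{\link{TELibrary}} (for writing) .
#' @param path Output/input path.
#' @return \code{readDiagnostics} returns the library with diagnostics
#'   replaced by the file contents.
#' @export
writeDiagnostics <- function(library, path) {
  df <- as.data.frame(diagnostics(library))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDiagnostics
#' @export
readDiagnostics <- function(library, path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer",
                                         "character", "integer"))
  library@diagnostics <- S4Vectors::DataFrame(df)
  validObject(library)
  library
}

#' Bundled synthetic TE consensus library
#'
#' Loads the small synthetic consensus library shipped with the package
#' (9 records over the four retrotransposon families, with planted
#' subfamily-private substitutions and poly-A tails on the non-LTR
#' families), with diagnostics derived.
#'
#' @return A \code{\link{TELibrary}}.
#' @export
bundledTELibrary <- function() {
  fa <- system.file("extdata", "te_consensus_synthetic.fa", package = "MEIdetect")
  deriveAllDiagnostics(readTELibrary(fa))
}
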
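#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' TELibrary: a retrotransposon consensus library
#'
#' Holds one consensus sequence per retrotransposon subfamily, the
#' family/subfamily table, and (once derived) the subfamily-diagnostic
#' nucleotide sites used for subfamily annotation of insertion calls.
#'
#' @slot consensus A \link[Biostrings]{DNAStringSet}, one record per
#'   subfamily, named \code{family#subfamily}.
#' @slot meta A \link[S4Vectors]{DataFrame} with columns \code{family} and
#'   \code{subfamily}, parallel to \code{consensus}.
#' @slot diagnostics A \link[S4Vectors]{DataFrame} with columns
#'   \code{family}, \code{subfamily}, \code{column} (0-based position in the
#'   family multiple alignment), \code{base}, and \code{consensus_pos}
#'   (0-based position on the subfamily's ungapped consensus). Empty until
#'   \code{\link{deriveDiagnostics}} is run.
#'
#' @seealso \code{\link{readTELibrary}}, \code{\link{deriveDiagnostics}}
#' @exportClass TELibrary
setClass("TELibrary",
  slots = c(
    consensus = "DNAStringSet",
    meta = "DataFrame",
    diagnostics = "DataFrame"
  )
)

setValidity("TELibrary", function(object) {
  msg <- character(0)
  n <- length(object@consensus)
  if (n == 0L) msg <- c(msg, "library holds no consensus records")
  if (nrow(object@meta) != n)
    msg <- c(msg, "meta table and consensus set have different lengths")
  if (!all(c("family", "subfamily") %in% colnames(object@meta)))
    msg <- c(msg, "meta must have columns 'family' and 'subfamily'")
  else {
    key <- paste(object@meta$family, object@meta$subfamily, sep = "#")
    if (anyDuplicated(key))
      msg <- c(msg, "(family, subfamily) pairs must be unique")
    bad <- !object@meta$family %in% c("Alu", "L1", "SVA", "LTR")
    if (any(bad))
      msg <- c(msg, paste0("unknown family: ",
                           paste(unique(object@meta$family[bad]), collapse = ", ")))
  }
  if (n > 0L) {
    if (any(Biostrings::width(object@consensus) == 0L))
      msg <- c(msg, "empty consensus sequence")
    freq <- Biostrings::alphabetFrequency(object@consensus)
    extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
    if (any(extra > 0))
      msg <- c(msg, "consensus alphabet must be within {A,C,G,T,N}")
  }
  if (nrow(object@diagnostics) > 0L) {
    need <- c("family", "subfamily", "column", "base", "consensus_pos")
    if (!all(need %in% colnames(object@diagnostics)))
      msg <- c(msg, "diagnostics must have columns family, subfamily, column, base, consensus_pos")
    else if (!all(object@diagnostics$subfamily %in% object@meta$subfamily))
      msg <- c(msg, "diagnostics reference subfamilies absent from the library")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TELibrary-class Number of consensus records.
#' @param x,object A \code{TELibrary}.
#' @export
setMethod("length", "TELibrary", function(x) length(x@consensus))

#' Accessors for TELibrary
#'
#' @param x A \code{TELibrary}.
#' @return \code{consensusSeqs} returns the \code{DNAStringSet} of consensus
#'   sequences; \code{teFamilies}/\code{teSubfamilies} return character
#'   vectors; \code{diagnostics} returns the diagnostic-site \code{DataFrame}.
#' @name TELibrary-accessors
#' @export
consensusSeqs <- function(x) x@consensus

#' @rdname TELibrary-accessors
#' @export
teFamilies <- function(x) as.character(x@meta$family)

#' @rdname TELibrary-accessors
#' @export
teSubfamilies <- function(x) as.character(x@meta$subfamily)

#' @rdname TELibrary-accessors
#' @export
diagnostics <- function(x) x@diagnostics

setMethod("show", "TELibrary", function(object) {
  fam <- table(teFamilies(object))
  cat("TELibrary with", length(object), "consensus record(s)\n")
  cat("  families:", paste(sprintf("%s (%d)", names(fam), fam), collapse = ", "), "\n")
  cat("  diagnostic sites:", nrow(object@diagnostics), "\n")
})
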
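## Allele-frequency-spectrum utilities for insertion polymorphisms across
## samples, with the neutral-model expectation used to detect selection:
## under neutrality the expected number of loci with derived-allele count i
## in 2n chromosomes is theta / i.

#' Folded-free allele frequency spectrum from a genotype matrix
#'
#' Rows are loci, columns samples, values 0/1/2 copies of the insertion
#' allele (the insertion is treated as derived; ancestral state is its
#' absence). Monomorphic loci - allele count 0 or 2n (fixed) - are
#' excluded.
#'
#' @param genotypes Integer matrix loci x samples with values in
#'   \{0, 1, 2\}.
#' @return A list of class \code{afSpectrum}: \code{nSamples} and
#'   \code{counts}, where \code{counts[i]} is the number of loci with
#'   derived-allele count i (i = 1 .. 2n-1).
#' @export
computeAFS <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0L, 1L, 2L)))
    stop("genotype values must be 0, 1 or 2")
  n <- ncol(genotypes)
  ac <- rowSums(genotypes)
  ac <- ac[ac > 0L & ac < 2L * n]
  counts <- tabulate(ac, nbins = 2L * n - 1L)
  structure(list(nSamples = n, counts = counts), class = "afSpectrum")
}

#' Neutral-model expected spectrum
#'
#' Expected count of loci with derived-allele count i is theta / i for
#' i = 1 .. 2n - 1, where theta is the insertion diversity parameter.
#'
#' @param theta Diversity parameter (> 0).
#' @param nSamples Number of diploid samples n.
#' @return Numeric vector of length 2n - 1.
#' @export
neutralSpectrum <- function(theta, nSamples) {
  stopifnot(theta > 0, nSamples >= 1)
  i <- seq_len(2L * nSamples - 1L)
  theta / i
}

#' @export
print.afSpectrum <- function(x, ...) {
  cat("afSpectrum over", x$nSamples, "samples;",
      sum(x$counts), "polymorphic loci\n")
  invisible(x)
}

#' Write a spectrum as TSV (alleleCount, observed)
#' @param afs An \code{afSpectrum}.
#' @param path Output path.
#' @export
writeAFS <- function(afs, path) {
  utils::write.table(
    data.frame(alleleCount = seq_along(afs$counts), count = afs$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from a multi-sample VCF or TSV
#'
#' For VCF input the GT fields are translated to 0/1/2 insertion-allele
#' counts; for TSV input the file must be a header-bearing matrix of
#' integers.
#'
#' @param path Input path (\code{.vcf} or tab-separated matrix).
#' @return Integer matrix loci x samples.
#' @export
readGenotypeMatrix <- function(path) {
  if (grepl("\\.vcf$", path)) {
    lines <- readLines(path)
    body <- lines[!grepl("^##", lines)]
    hdr <- strsplit(body[1L], "\t")[[1]]
    stopifnot(length(hdr) > 9L)
    rows <- strsplit(body[-1L], "\t")
    gtOf <- function(f) {
      g <- sub(":.*$", "", f)
      vapply(g, function(x) sum(strsplit(x, "[/|]")[[1]] == "1"), 0L,
             USE.NAMES = FALSE)
    }
    geno <- t(vapply(rows, function(r) gtOf(r[10:length(hdr)]),
                     integer(length(hdr) - 9L)))
    colnames(geno) <- hdr[10:length(hdr)]
    geno
  } else {
    as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                check.names = FALSE))
  }
}
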
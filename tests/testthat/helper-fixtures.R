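## Fixture builders: everything is generated in code at test time.

## write a TELibrary FASTA from named sequences and load it
makeLibrary <- function(seqs, derive = TRUE) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), fa)
  lib <- readTELibrary(fa)
  if (derive) lib <- deriveAllDiagnostics(lib)
  lib
}

randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

## build a small coordinate-sorted indexed BAM from SAM record fields
makeBam <- function(records, refLens, prefix = tempfile()) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(refLens), "\tLN:", refLens))
  sam <- paste0(prefix, ".sam")
  writeLines(c(hdr, records), sam)
  bam <- Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

samLine <- function(qname, flag, chrom, pos1, mapq, cigar, mateChrom = "=",
                    matePos1 = pos1, tlen = 0L, seq, qual = NULL) {
  if (is.null(qual)) qual <- strrep("?", nchar(seq))
  paste(qname, flag, chrom, pos1, mapq, cigar, mateChrom, matePos1, tlen,
        seq, qual, sep = "\t")
}

## shared small end-to-end simulation, computed once per test session
.fixtures <- new.env()

smallSimFixture <- function() {
  if (!is.null(.fixtures$smallSim)) return(.fixtures$smallSim)
  lib <- bundledTELibrary()
  ref <- makeReference(3e5, 2, seed = 7)
  scfg <- simConfig(nInsertions = 8L, depth = 30, seed = 7)
  ds <- simulateDataset(ref, lib, scfg, bamPrefix = tempfile())
  .fixtures$smallSim <- list(lib = lib, ref = ref, scfg = scfg, ds = ds)
  .fixtures$smallSim
}

smallCallsFixture <- function() {
  if (!is.null(.fixtures$smallCalls)) return(.fixtures$smallCalls)
  fx <- smallSimFixture()
  calls <- detectInsertions(fx$ds$bam, fx$ref, fx$lib, meiConfig(), verbose = FALSE)
  .fixtures$smallCalls <- c(fx, list(calls = calls))
  .fixtures$smallCalls
}
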
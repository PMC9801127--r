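## Shared fixtures, generated in code.

## A minimal 76-nt tRNA starting with G and ending in CCA, plain labels.
tiny76 <- function(id = "tiny76") {
  set.seed(760)
  b <- sample(c("A", "C", "G", "U"), 76, replace = TRUE)
  b[1] <- "G"
  b[74:76] <- c("C", "C", "A")
  b[22] <- "A"
  annotatedTRNA(id, paste(b, collapse = ""))
}

## Write a reference list as FASTA + annotation TSV in a temp dir.
writeRefFixture <- function(trnas, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "refs.fasta")
  ann <- file.path(dir, "refs.tsv")
  writeReferences(trnas, fa, ann)
  list(fasta = fa, annotation = ann, dir = dir)
}

## Brute-force single-point enumeration oracle: nested loops, no reuse of
## the library designer's code.
bruteForceVariants <- function(sequence, mutableIdx) {
  bases <- c("A", "C", "G", "U")
  out <- list()
  for (i in mutableIdx) {
    wt <- substr(sequence, i, i)
    for (b in bases) {
      if (b == wt) next
      s <- sequence
      substr(s, i, i) <- b
      out[[length(out) + 1L]] <- list(pos = i, wt = wt, new = b, seq = s)
    }
  }
  out
}

## Brute-force 3'-partial-adapter trim oracle.
bruteTrim <- function(read, adapter, minOverlap) {
  hit <- regexpr(adapter, read, fixed = TRUE)
  if (hit > 0) return(substr(read, 1, hit - 1))
  for (k in seq(nchar(adapter) - 1, minOverlap)) {
    if (k < minOverlap) break
    pre <- substr(adapter, 1, k)
    if (endsWith(read, pre))
      return(substr(read, 1, nchar(read) - k))
  }
  read
}
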
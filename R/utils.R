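## Internal helpers shared across modules.

#' @importFrom methods is new validObject slot
#' @importFrom stats coef lm residuals rbinom runif rnorm setNames t.test var
#' @importFrom utils head read.delim write.table packageVersion
NULL

## Normalize a nucleotide string to the uppercase RNA alphabet.
## DNA input (T) is accepted and converted; anything else is an error.
normalizeRna <- function(x, what = "sequence") {
  x <- toupper(as.character(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(what, " contains characters outside the A/C/G/U(T) alphabet: ",
         paste(head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  x
}

rnaToDna <- function(x) chartr("U", "T", toupper(x))

dnaToRna <- function(x) chartr("T", "U", toupper(x))

## Deterministic sub-seed derivation so that one pipeline seed drives all
## modules without stream collisions.  Kept strictly below 2^31.
deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483647)
}

## Split a sequence string into a character vector of single bases.
seqChars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

writeTsv <- function(x, path) {
  write.table(as.data.frame(x), file = path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## Resolve a reference argument (list of AnnotatedTRNA, named character
## vector, or XStringSet) into a named RNA character vector plus a list of
## per-reference position labels.
resolveReferences <- function(references) {
  if (is(references, "XStringSet")) {
    seqs <- as.character(references)
    references <- setNames(as.list(seqs), names(references))
  }
  if (is.list(references) && length(references) &&
      all(vapply(references, is, logical(1L), "AnnotatedTRNA"))) {
    seqs <- vapply(references, trnaSequence, character(1L))
    ids <- vapply(references, trnaId, character(1L))
    names(seqs) <- ids
    labels <- lapply(references, positionLabels)
    names(labels) <- ids
  } else {
    seqs <- vapply(references, function(s) normalizeRna(s), character(1L))
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
      stop("references must be named", call. = FALSE)
    }
    labels <- lapply(seqs, function(s) as.character(seq_len(nchar(s))))
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate reference ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  list(sequences = seqs, labels = labels)
}
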
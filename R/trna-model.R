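## Annotated tRNA references, variant-library design and T7 cassettes.

#' Construct an annotated tRNA
#'
#' @param id identifier.
#' @param sequence RNA (or DNA, converted) sequence string.
#' @param positionLabels one label per nucleotide; defaults to
#'   \code{"1"..."L"}.
#' @param elements named character vector mapping labels to structural
#'   elements (see [AnnotatedTRNA-class]); may be empty.
#' @return an [AnnotatedTRNA-class] object.
#' @examples
#' t <- annotatedTRNA("toy", "GGGCCA")
#' trnaSequence(t)
#' @export
annotatedTRNA <- function(id, sequence, positionLabels = NULL,
                          elements = character()) {
  sequence <- normalizeRna(sequence, paste0("sequence of '", id, "'"))
  if (is.null(positionLabels))
    positionLabels <- as.character(seq_len(nchar(sequence)))
  new("AnnotatedTRNA", id = as.character(id), sequence = sequence,
      positionLabels = as.character(positionLabels),
      elements = elements)
}

## Index of a position label within a tRNA; errors on unknown labels.
labelIndex <- function(trna, label) {
  i <- match(label, positionLabels(trna))
  if (anyNA(i)) {
    stop("unknown position label(s) for '", trnaId(trna), "': ",
         paste(label[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Base at a labelled position
#'
#' @param trna an [AnnotatedTRNA-class].
#' @param label position label.
#' @return single RNA base.
#' @export
baseAt <- function(trna, label) {
  substr(trnaSequence(trna), labelIndex(trna, label), labelIndex(trna, label))
}

#' Load annotated tRNA references from FASTA plus a TSV annotation
#'
#' The annotation file has columns \code{id}, \code{index} (0-based
#' nucleotide index), \code{label} and \code{element} (empty for
#' unassigned positions).  FASTA ids and annotation ids must correspond
#' one-to-one, with one label per nucleotide.
#'
#' @param fastaPath path to a FASTA file of tRNA sequences (RNA or DNA).
#' @param annotationPath path to the annotation TSV.
#' @return a named list of [AnnotatedTRNA-class] objects.
#' @examples
#' refs <- loadReferences(
#'   system.file("extdata", "example-trna.fasta", package = "trnamap"),
#'   system.file("extdata", "example-trna-annotation.tsv",
#'               package = "trnamap"))
#' refs[[1]]
#' @export
loadReferences <- function(fastaPath, annotationPath) {
  seqs <- Biostrings::readBStringSet(fastaPath)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ann <- read.delim(annotationPath, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("id", "index", "label")
  if (!all(need %in% colnames(ann)))
    stop("annotation must have columns id, index, label (and optionally element)",
         call. = FALSE)
  if (!setequal(ids, unique(ann$id)))
    stop("FASTA ids and annotation ids do not correspond one-to-one",
         call. = FALSE)
  out <- lapply(ids, function(i) {
    a <- ann[ann$id == i, , drop = FALSE]
    a <- a[order(as.integer(a$index)), , drop = FALSE]
    s <- as.character(seqs[[match(i, ids)]])
    if (nrow(a) != nchar(s))
      stop("'", i, "': ", nrow(a), " labels for a ", nchar(s),
           "-nt sequence", call. = FALSE)
    if (!identical(as.integer(a$index), seq_len(nchar(s)) - 1L))
      stop("'", i, "': annotation indices must be 0..length-1", call. = FALSE)
    el <- character()
    if ("element" %in% colnames(a)) {
      keep <- !is.na(a$element) & nzchar(a$element)
      el <- setNames(a$element[keep], a$label[keep])
    }
    annotatedTRNA(i, s, a$label, el)
  })
  setNames(out, ids)
}

#' Write annotated tRNAs back to FASTA + annotation TSV
#'
#' @param trnas list of [AnnotatedTRNA-class].
#' @param fastaPath,annotationPath output paths.
#' @return invisibly, the two paths.
#' @export
writeReferences <- function(trnas, fastaPath, annotationPath) {
  seqs <- Biostrings::RNAStringSet(vapply(trnas, trnaSequence, character(1L)))
  names(seqs) <- vapply(trnas, trnaId, character(1L))
  Biostrings::writeXStringSet(seqs, fastaPath)
  ann <- do.call(rbind, lapply(trnas, function(t) {
    el <- structuralElements(t)
    lab <- positionLabels(t)
    data.frame(id = trnaId(t), index = seq_along(lab) - 1L, label = lab,
               element = ifelse(lab %in% names(el), el[lab], ""),
               stringsAsFactors = FALSE)
  }))
  writeTsv(ann, annotationPath)
  invisible(c(fastaPath, annotationPath))
}

#' Design a single-point substitution variant library
#'
#' For every mutable position, all three possible base substitutions are
#' enumerated, giving \code{3 * length(mutableLabels)} variants.  Variants
#' are ordered by position index and then by base (A < C < G < U) and named
#' \code{<wtBase><label><newBase>} in the RNA alphabet (e.g. \code{"U8A"}).
#' The target (monitored) position is never mutable.
#'
#' @param trna parent [AnnotatedTRNA-class].
#' @param targetLabel label of the monitored modification position.
#' @param mutableLabels labels to mutate.  Default: every label except the
#'   target position and, when the tRNA ends in CCA, the three CCA labels.
#' @return a [VariantLibrary-class].
#' @examples
#' t <- exampleLeuTRNA()
#' lib <- designPointVariantLibrary(t, targetLabel = "22")
#' nrow(variants(lib))
#' @export
designPointVariantLibrary <- function(trna, targetLabel,
                                      mutableLabels = NULL) {
  labels <- positionLabels(trna)
  if (!targetLabel %in% labels)
    stop("unknown target label '", targetLabel, "'", call. = FALSE)
  if (is.null(mutableLabels)) {
    drop <- targetLabel
    if (endsWith(trnaSequence(trna), "CCA"))
      drop <- c(drop, labels[length(labels) - 2:0])
    mutableLabels <- setdiff(labels, drop)
  }
  if (targetLabel %in% mutableLabels)
    stop("the target position '", targetLabel, "' must not be mutable",
         call. = FALSE)
  idx <- labelIndex(trna, mutableLabels)
  ord <- order(idx)
  idx <- idx[ord]
  mutableLabels <- mutableLabels[ord]
  parentSeq <- trnaSequence(trna)
  rows <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    wt <- substr(parentSeq, i, i)
    subs <- setdiff(RNA_BASES, wt)        # already in A<C<G<U order
    seqs <- vapply(subs, function(b) {
      s <- parentSeq
      substr(s, i, i) <- b
      s
    }, character(1L))
    DataFrame(name = paste0(wt, mutableLabels[k], subs),
              positionLabel = mutableLabels[k], wtBase = wt,
              newBase = subs, sequence = unname(seqs))
  })
  v <- if (length(rows)) do.call(rbind, rows) else
    DataFrame(name = character(), positionLabel = character(),
              wtBase = character(), newBase = character(),
              sequence = character())
  new("VariantLibrary", parent = trna, targetLabel = targetLabel,
      variants = v)
}

#' Library capacity arithmetic
#'
#' \code{doubleVariantCount()} is the number of ordered double variants a
#' single-point library of size \code{n} implies (\code{n * (n - 1)});
#' \code{readsPerVariant()} is the average sequencing depth per variant for
#' a given total read yield, rounded down.
#'
#' @param n library size (number of single-point variants), or a
#'   [VariantLibrary-class].
#' @return an integer count.
#' @examples
#' doubleVariantCount(240)           # 57360
#' readsPerVariant(1e7, 240)         # 41666
#' @export
doubleVariantCount <- function(n) {
  if (is(n, "VariantLibrary")) n <- nrow(variants(n))
  as.double(n) * (as.double(n) - 1)
}

#' @param totalReads total number of sequencing reads available.
#' @param nVariants number of variants sharing them.
#' @rdname doubleVariantCount
#' @export
readsPerVariant <- function(totalReads, nVariants) {
  floor(as.double(totalReads) / as.double(nVariants))
}

#' Build a T7 run-off transcription cassette
#'
#' The cassette is \code{promoter + [G] + DNA(tRNA) + [CCA] + tail}: an
#' extra G is prepended when the tRNA does not start with G (T7 initiates
#' poorly otherwise) and the CCA terminus is appended when absent.  The
#' constant tail carries the BsaI site; digestion leaves a template whose
#' run-off transcript ends exactly in CCA.
#'
#' @param trna an [AnnotatedTRNA-class].
#' @return a [TranscriptionCassette-class].
#' @export
buildT7Cassette <- function(trna) {
  s <- trnaSequence(trna)
  if (!nchar(s)) stop("empty tRNA sequence", call. = FALSE)
  extraG <- !startsWith(s, "G")
  addCCA <- !endsWith(s, "CCA")
  insert <- paste0(if (extraG) "G", rnaToDna(s), if (addCCA) "CCA")
  dna <- paste0(T7_PROMOTER, insert, T7_TAIL)
  np <- nchar(T7_PROMOTER)
  new("TranscriptionCassette", id = trnaId(trna), dnaTemplate = dna,
      promoterSpan = c(1L, np),
      trnaSpan = c(np + 1L, np + nchar(insert)),
      tailSpan = c(np + nchar(insert) + 1L, nchar(dna)),
      extraGAdded = extraG, ccaAdded = addCCA)
}

#' Predicted run-off transcript of a cassette
#'
#' Returns the RNA that transcription of the BsaI-digested template yields:
#' the (possibly G-prefixed) tRNA ending in CCA, with no tail nucleotides.
#'
#' @param cassette a [TranscriptionCassette-class].
#' @return RNA sequence string.
#' @export
predictedTranscript <- function(cassette) {
  stopifnot(is(cassette, "TranscriptionCassette"))
  dnaToRna(substr(cassette@dnaTemplate, cassette@trnaSpan[1L],
                  cassette@trnaSpan[2L]))
}

#' Write cassettes or variant libraries as FASTA
#'
#' @param x list of [TranscriptionCassette-class] or a
#'   [VariantLibrary-class].
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
writeCassetteFasta <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(vapply(x, dnaTemplate, character(1L)))
  names(seqs) <- vapply(x, function(c) c@id, character(1L))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeCassetteFasta
#' @export
writeVariantFasta <- function(x, path) {
  stopifnot(is(x, "VariantLibrary"))
  v <- variants(x)
  seqs <- Biostrings::RNAStringSet(as.character(v$sequence))
  names(seqs) <- v$name
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' A synthetic leucine-type tRNA example
#'
#' A deterministic, synthetic 88-nt class-II (long-variable-arm) tRNA used
#' in examples and tests.  It carries Sprinzl-style labels including the
#' D-loop insertion \code{20a} and variable-arm labels \code{45a}-\code{45k},
#' the conserved tertiary-core residues (U8, A14, G18, G19, U54, U55, C56,
#' A58), an A at the monitored position 22, a G start and a CCA end.  It is
#' not a natural tRNA gene.
#'
#' @return an [AnnotatedTRNA-class].
#' @examples
#' exampleLeuTRNA()
#' @export
exampleLeuTRNA <- function() {
  labels <- c(as.character(1:20), "20a", as.character(21:45),
              paste0("45", letters[1:11]), as.character(46:76))
  n <- length(labels)                      # 88
  base <- rep(c("G", "C", "U", "A"), length.out = n)
  names(base) <- labels
  ## conserved core and design constraints
  base[c("1", "73")] <- c("G", "A")
  base[c("8", "13", "14", "18", "19", "20a", "22")] <-
    c("U", "G", "A", "G", "G", "A", "A")
  base[c("54", "55", "56", "58")] <- c("U", "U", "C", "A")
  base[c("74", "75", "76")] <- c("C", "C", "A")
  el <- c(setNames(rep("acceptor_stem", 7), as.character(1:7)),
          setNames(rep("d_arm", 19), c(as.character(8:25), "20a")),
          setNames(rep("anticodon_arm", 18), as.character(26:43)),
          setNames(rep("variable_region", 16),
                   c(as.character(44:48), paste0("45", letters[1:11]))),
          setNames(rep("t_arm", 17), as.character(49:65)),
          setNames(rep("acceptor_stem", 7), as.character(66:72)),
          setNames("discriminator", "73"),
          setNames(rep("cca", 3), as.character(74:76)))
  annotatedTRNA("tRNA-Leu-GAG-like", paste(base, collapse = ""), labels, el)
}
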
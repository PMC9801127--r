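## Seeded FASTQ simulator: RT misincorporation signatures, RT stops,
## uniform sequencing error, skewed pool abundances, 3' adapter.

#' Construct a modification signature
#'
#' @param referenceId reference carrying the modification.
#' @param positionLabel position label of the modified nucleotide.
#' @param misincorporationRate probability in \code{[0,1]} that RT records
#'   a non-templated base there when the molecule is modified.  Strong
#'   Watson-Crick-face methylations (m1A, m1G) under TGIRT reach ~0.8.
#' @param stopRate probability that RT terminates at the position
#'   (truncating the read to the tRNA 3' side, since cDNA synthesis starts
#'   from the 3' adapter).
#' @param substitutionSpectrum optional named distribution over A/C/G/U for
#'   the recorded base; default uniform over the three non-wild-type bases.
#' @return a [ModificationSignature-class].
#' @export
modificationSignature <- function(referenceId, positionLabel,
                                  misincorporationRate, stopRate = 0,
                                  substitutionSpectrum = numeric()) {
  new("ModificationSignature", referenceId = as.character(referenceId),
      positionLabel = as.character(positionLabel),
      misincorporationRate = misincorporationRate,
      substitutionSpectrum = substitutionSpectrum, stopRate = stopRate)
}

#' Pool composition for a simulated sample
#'
#' @param abundances named positive weights per reference (normalized
#'   internally); skew them to emulate uneven pool composition.
#' @param modificationFraction named probabilities in \code{[0,1]} that a
#'   molecule of each reference carries the modification in the treated
#'   sample (unnamed scalar recycled to all members).  Untreated samples
#'   are always unmodified.
#' @return a plain list with class \code{"PoolSpec"} semantics (validated
#'   on use).
#' @export
poolSpec <- function(abundances, modificationFraction = 1) {
  if (is.null(names(abundances)))
    stop("abundances must be named by reference id", call. = FALSE)
  if (any(abundances <= 0)) stop("abundances must be positive", call. = FALSE)
  if (is.null(names(modificationFraction))) {
    if (!length(modificationFraction) %in% c(1L, length(abundances)))
      stop("modificationFraction must be a scalar, match the pool size, ",
           "or be named", call. = FALSE)
    modificationFraction <- setNames(rep_len(modificationFraction,
                                             length(abundances)),
                                     names(abundances))
  }
  if (!all(names(abundances) %in% names(modificationFraction)))
    stop("modificationFraction must cover every pool member", call. = FALSE)
  if (any(modificationFraction < 0 | modificationFraction > 1))
    stop("modificationFraction must lie in [0, 1]", call. = FALSE)
  list(abundances = abundances / sum(abundances),
       modificationFraction = modificationFraction[names(abundances)])
}

#' Simulator configuration
#'
#' @param nReads number of reads to emit.
#' @param errorRate per-base uniform substitution error probability.
#' @param adapter 3' adapter DNA appended to every read (default the
#'   standard small-RNA ligation adapter \code{CTGTAGGCACCATCAAT}).
#' @param seed integer RNG seed; with a fixed seed the FASTQ output is
#'   byte-identical across runs.
#' @param readLengthCap optional maximum emitted read length.
#' @param constantQuality Phred score written for every base (default 37).
#' @return a list of validated simulator settings.
#' @export
simConfig <- function(nReads, errorRate = 0, adapter = DEFAULT_ADAPTER,
                      seed = 1L, readLengthCap = NA_integer_,
                      constantQuality = 37L) {
  if (nReads <= 0) stop("nReads must be positive", call. = FALSE)
  if (errorRate < 0 || errorRate > 1)
    stop("errorRate must lie in [0, 1]", call. = FALSE)
  list(nReads = as.integer(nReads), errorRate = errorRate,
       adapter = toupper(adapter), seed = as.integer(seed),
       readLengthCap = readLengthCap,
       constantQuality = as.integer(constantQuality))
}

## Expected observed non-reference fraction at a position where RT writes a
## non-templated base with probability q and sequencing error is e:
## a wild-type base becomes non-WT with probability e; a misincorporated
## base reverts to WT only when the error (uniform over the three other
## bases) happens to pick it.
expectedMutationRate <- function(q, e) (1 - q) * e + q * (1 - e / 3)

## Core read generator for one reference.  sigs: data.frame with columns
## index (1-based), misinc, stop, plus list-column spectrum (named numeric
## or NULL).  Returns character vector of reads (tRNA sense, DNA, adapter
## appended), plus integer start positions.
simulateReadsOneRef <- function(refDna, nReads, modified, sigs, config) {
  L <- nchar(refDna)
  starts <- rep(1L, nReads)
  ## RT stops: cDNA synthesis proceeds 3'->5', so the 3'-most modified
  ## position is met first; termination there leaves positions (p+1)..L.
  if (nrow(sigs) && any(modified) && any(sigs$stop > 0)) {
    sg <- sigs[order(-sigs$index), , drop = FALSE]
    mod <- which(modified)
    alive <- mod
    for (r in seq_len(nrow(sg))) {
      if (!length(alive) || sg$stop[r] <= 0) next
      hit <- runif(length(alive)) < sg$stop[r]
      starts[alive[hit]] <- sg$index[r] + 1L
      alive <- alive[!hit]
    }
  }
  reads <- substr(rep(refDna, nReads), starts, L)
  edits <- list()
  ## misincorporations at covered signature positions of modified molecules
  if (nrow(sigs) && any(modified)) {
    for (r in seq_len(nrow(sigs))) {
      p <- sigs$index[r]
      cand <- which(modified & starts <= p)
      if (!length(cand) || sigs$misinc[r] <= 0) next
      hit <- cand[runif(length(cand)) < sigs$misinc[r]]
      if (!length(hit)) next
      wt <- substr(refDna, p, p)
      spec <- sigs$spectrum[[r]]
      if (is.null(spec) || !length(spec)) {
        choices <- setdiff(DNA_BASES, wt)
        newb <- sample(choices, length(hit), replace = TRUE)
      } else {
        spec <- spec[setdiff(names(spec), dnaToRna(wt))]
        choices <- rnaToDna(names(spec))
        newb <- sample(choices, length(hit), replace = TRUE,
                       prob = spec / sum(spec))
      }
      edits[[length(edits) + 1L]] <-
        data.frame(read = hit, pos = p - starts[hit] + 1L, base = newb)
    }
  }
  ## uniform sequencing error over the tRNA-derived part
  if (config$errorRate > 0) {
    lens <- L - starts + 1L
    nerr <- stats::rbinom(nReads, lens, config$errorRate)
    err <- which(nerr > 0)
    if (length(err)) {
      readIdx <- rep(err, nerr[err])
      pos <- unlist(lapply(err, function(i)
        sample.int(lens[i], nerr[i])), use.names = FALSE)
      edits[[length(edits) + 1L]] <-
        data.frame(read = readIdx, pos = pos, base = NA_character_)
    }
  }
  if (length(edits)) {
    ed <- do.call(rbind, edits)
    ## misincorporations were generated first, errors second, so an error
    ## can overwrite a misincorporated base
    edRead <- ed$read; edPos <- ed$pos; edBase <- ed$base
    for (j in seq_along(edRead)) {
      i <- edRead[j]; p <- edPos[j]
      b <- edBase[j]
      if (is.na(b)) {
        cur <- substr(reads[i], p, p)
        b <- DNA_BASES[DNA_BASES != cur][sample.int(3L, 1L)]
      }
      substr(reads[i], p, p) <- b
    }
  }
  if (nzchar(config$adapter)) reads <- paste0(reads, config$adapter)
  if (!is.na(config$readLengthCap))
    reads <- substr(reads, 1L, config$readLengthCap)
  list(reads = reads, starts = starts)
}

#' Simulate a treated or untreated FASTQ sample from a tRNA pool
#'
#' Each read is drawn by (1) sampling a reference by abundance, (2)
#' deciding modification status (treated: per-member
#' \code{modificationFraction}; untreated: always unmodified), (3) for
#' modified molecules, applying RT stops (truncation retaining the tRNA 3'
#' side) and misincorporations per signature, (4) applying uniform
#' sequencing error, and (5) appending the 3' adapter.  Reads are emitted
#' in tRNA sense.
#'
#' @param pool a [poolSpec()].
#' @param references references matching the pool ids: a list of
#'   [AnnotatedTRNA-class], a named RNA/DNA character vector, or an
#'   \code{XStringSet}.
#' @param signatures list of [ModificationSignature-class]; every
#'   \code{referenceId} must exist in the pool.
#' @param config a [simConfig()].
#' @param treated logical; untreated samples ignore all signatures.
#' @return a list with elements \code{reads} (named character vector, DNA),
#'   \code{quality} (constant Phred+33 string per read), \code{truth}
#'   (data.frame \code{reference}, \code{label}, \code{expected_rate}: the
#'   expected observed mutation rate per position implied by the draw
#'   parameters) and \code{readInfo} (per-read reference, modification
#'   status and 5' start).
#' @examples
#' pool <- syntheticTRNAPool(2, seed = 5)
#' ps <- poolSpec(c(`synth-tRNA-01` = 1, `synth-tRNA-02` = 1))
#' sig <- modificationSignature("synth-tRNA-01", "22", 0.79)
#' sim <- simulateSample(ps, pool, list(sig), simConfig(200, seed = 7), TRUE)
#' head(sim$truth)
#' @export
simulateSample <- function(pool, references, signatures = list(),
                           config, treated = TRUE) {
  refs <- resolveReferences(references)
  ids <- names(pool$abundances)
  if (!all(ids %in% names(refs$sequences)))
    stop("pool members missing from references: ",
         paste(setdiff(ids, names(refs$sequences)), collapse = ", "),
         call. = FALSE)
  sigRef <- vapply(signatures, function(s) s@referenceId, character(1L))
  if (length(signatures) && !all(sigRef %in% ids))
    stop("signature references not in the pool: ",
         paste(setdiff(sigRef, ids), collapse = ", "), call. = FALSE)

  set.seed(config$seed)
  refDraw <- sample(ids, config$nReads, replace = TRUE,
                    prob = pool$abundances)
  modFrac <- pool$modificationFraction
  modified <- if (treated) runif(config$nReads) < modFrac[refDraw]
              else rep(FALSE, config$nReads)

  reads <- character(config$nReads)
  starts <- integer(config$nReads)
  for (id in ids) {
    sel <- which(refDraw == id)
    if (!length(sel)) next
    labs <- refs$labels[[id]]
    sigsHere <- signatures[sigRef == id]
    sigs <- data.frame(index = integer(), misinc = numeric(),
                       stop = numeric())
    sigs$spectrum <- list()
    if (length(sigsHere)) {
      sigs <- data.frame(
        index = vapply(sigsHere, function(s)
          match(s@positionLabel, labs), integer(1L)),
        misinc = vapply(sigsHere, function(s)
          s@misincorporationRate, numeric(1L)),
        stop = vapply(sigsHere, function(s) s@stopRate, numeric(1L)))
      sigs$spectrum <- lapply(sigsHere, function(s) s@substitutionSpectrum)
      if (anyNA(sigs$index))
        stop("signature position label not found in reference '", id, "'",
             call. = FALSE)
    }
    res <- simulateReadsOneRef(rnaToDna(refs$sequences[[id]]), length(sel),
                               modified[sel], sigs, config)
    reads[sel] <- res$reads
    starts[sel] <- res$starts
  }
  names(reads) <- sprintf("read_%07d", seq_len(config$nReads))

  ## truth table: expected observed mutation rate per reference position
  truth <- do.call(rbind, lapply(ids, function(id) {
    labs <- refs$labels[[id]]
    q <- numeric(length(labs))
    if (treated) {
      for (s in signatures[sigRef == id]) {
        i <- match(s@positionLabel, labs)
        q[i] <- modFrac[[id]] * s@misincorporationRate
      }
    }
    data.frame(reference = id, label = labs,
               expected_rate = expectedMutationRate(q, config$errorRate),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  qual <- vapply(nchar(reads), function(n)
    strrep(rawToChar(as.raw(config$constantQuality + 33L)), n), character(1L))
  list(reads = reads, quality = unname(qual), truth = truth,
       readInfo = data.frame(id = names(reads), reference = refDraw,
                             modified = modified, start = starts,
                             stringsAsFactors = FALSE))
}

#' Simulate a variant-library screen sample
#'
#' As [simulateSample()], but the references are the library's variant
#' sequences (plus the wild-type parent when \code{includeWT}) and, in the
#' treated sample, the misincorporation rate at the target position of
#' variant \code{v} is \code{perVariantEfficiency[v] *
#' misincorporationRate(targetSignature)} -- the per-variant methyl group
#' acceptance activity scales the RT signature.
#'
#' @param library a [VariantLibrary-class].
#' @param targetSignature a [ModificationSignature-class] giving the
#'   signature at full activity (its \code{referenceId} is ignored; its
#'   position must be the library target).
#' @param perVariantEfficiency named numeric in \code{[0,1]} per variant
#'   name; missing variants default to 1 (full activity).
#' @param config a [simConfig()].
#' @param treated logical.
#' @param includeWT include a \code{"WT"} pseudo-variant of the parent
#'   sequence (efficiency defaults to 1).
#' @param abundances optional named weights per variant (default uniform).
#' @return as [simulateSample()].
#' @export
simulateVariantLibrarySample <- function(library, targetSignature,
                                         perVariantEfficiency = numeric(),
                                         config, treated = TRUE,
                                         includeWT = TRUE,
                                         abundances = NULL) {
  stopifnot(is(library, "VariantLibrary"))
  if (targetSignature@positionLabel != targetLabel(library))
    stop("targetSignature position must equal the library target label",
         call. = FALSE)
  v <- variants(library)
  ids <- as.character(v$name)
  seqs <- setNames(as.character(v$sequence), ids)
  if (includeWT) {
    seqs <- c(seqs, WT = trnaSequence(parentTRNA(library)))
    ids <- c(ids, "WT")
  }
  eff <- setNames(rep(1, length(ids)), ids)
  if (length(perVariantEfficiency)) {
    unknown <- setdiff(names(perVariantEfficiency), ids)
    if (length(unknown))
      stop("efficiencies given for unknown variants: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    eff[names(perVariantEfficiency)] <- perVariantEfficiency
  }
  if (is.null(abundances)) abundances <- setNames(rep(1, length(ids)), ids)
  labs <- positionLabels(parentTRNA(library))
  refs <- lapply(ids, function(i) annotatedTRNA(i, seqs[[i]], labs))
  names(refs) <- ids
  sigs <- lapply(ids, function(i)
    modificationSignature(i, targetSignature@positionLabel,
                          eff[[i]] * targetSignature@misincorporationRate,
                          stopRate = targetSignature@stopRate,
                          substitutionSpectrum =
                            targetSignature@substitutionSpectrum))
  sim <- simulateSample(poolSpec(abundances, 1), refs, sigs, config, treated)
  sim$efficiency <- eff
  sim
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' @param sim result of [simulateSample()] (or a named character vector of
#'   reads, in which case a constant Q37 quality is written).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFastq <- function(sim, path) {
  if (is.character(sim))
    sim <- list(reads = sim,
                quality = vapply(nchar(sim), function(n) strrep("F", n),
                                 character(1L)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  rec <- paste0("@", names(sim$reads), "\n", sim$reads, "\n+\n", sim$quality)
  writeLines(rec, con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path (4-line records, uncompressed or gzip).
#' @return named character vector of read sequences (DNA, uppercase).
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}
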
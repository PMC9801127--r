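## Alignment-based per-position mutation profiling with depth filtering,
## background subtraction and modification-site calling.

#' Default alignment scoring
#'
#' Semi-global scoring used by [assignReads()]: match +1, mismatch -1,
#' linear gap -2 per gap position.
#' @return named list of scoring parameters.
#' @export
defaultScoring <- function() list(match = 1L, mismatch = -1L, gap = -2L)

#' Trim the 3' sequencing adapter from reads
#'
#' Removes the first occurrence of the adapter -- or, when the full
#' adapter is absent, a 3'-terminal match to an adapter prefix of at least
#' \code{minOverlap} bases -- and everything 3' of it.  Reads without a
#' hit are returned unchanged and flagged.
#'
#' @param reads character vector of read sequences (DNA).
#' @param adapter adapter DNA string.
#' @param minOverlap minimum 3'-terminal adapter-prefix length.
#' @return \code{DataFrame} with columns \code{sequence} (trimmed) and
#'   \code{adapterFound}.
#' @examples
#' trimAdapter(c("ACGTCTGTAGGCACCATAAT", "ACGT"), "CTGTAGGCAC", minOverlap = 4)
#' @export
trimAdapter <- function(reads, adapter = DEFAULT_ADAPTER, minOverlap = 5L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty", call. = FALSE)
  adapter <- toupper(adapter)
  if (!length(reads))
    return(DataFrame(sequence = character(), adapterFound = logical()))
  reads <- toupper(reads)
  hit <- regexpr(adapter, reads, fixed = TRUE)
  found <- hit > 0L
  out <- reads
  out[found] <- substr(reads[found], 1L, hit[found] - 1L)
  ## partial 3'-terminal adapter: longest prefix wins
  la <- nchar(adapter)
  for (k in seq(min(la - 1L, max(nchar(reads))), minOverlap)) {
    if (k < minOverlap) break
    pre <- substr(adapter, 1L, k)
    cand <- !found & endsWith(out, pre)
    if (any(cand)) {
      out[cand] <- substr(out[cand], 1L, nchar(out[cand]) - k)
      found[cand] <- TRUE
    }
  }
  DataFrame(sequence = unname(out), adapterFound = unname(found),
            row.names = names(reads))
}

#' Assign reads to references by semi-global alignment
#'
#' Each read is aligned semi-globally (read end-to-end, free reference
#' end-gaps, linear gap penalty) against every reference; the best-scoring
#' reference wins.  A read is left unassigned when the best score ties
#' another reference or falls below \code{minScoreFraction} of the maximum
#' attainable score (read length times the match score).
#'
#' Reads that equal a reference exactly take a fast path that skips the
#' dynamic program; it is only used when no reference is a substring of
#' another, so the tie rule is unaffected.
#'
#' @param reads named character vector of read sequences (adapter-trimmed,
#'   DNA or RNA).
#' @param references as in [simulateSample()].
#' @param scoring list with \code{match}, \code{mismatch}, \code{gap}
#'   (see [defaultScoring()]).
#' @param minScoreFraction assignment threshold in \code{(0, 1]}.
#' @param tryReverseComplement also align the reverse complement of each
#'   read and keep the better orientation (enable for real libraries of
#'   unknown orientation; simulator output is emitted in tRNA sense).
#' @return \code{DataFrame} with columns \code{readId},
#'   \code{referenceId} (NA when unassigned), \code{score},
#'   \code{secondScore}, \code{refStart}, \code{refEnd}.  Per-read
#'   alignment events (mismatch/deletion/insertion with reference
#'   positions) are attached as \code{metadata(x)$events} for
#'   [buildProfile()].
#' @export
assignReads <- function(reads, references, scoring = defaultScoring(),
                        minScoreFraction = 0.6,
                        tryReverseComplement = FALSE) {
  refs <- resolveReferences(references)
  if (!length(refs$sequences)) stop("empty reference set", call. = FALSE)
  refDna <- rnaToDna(refs$sequences)
  ids <- names(refDna)
  readSeq <- rnaToDna(unname(reads))
  readIds <- if (is.null(names(reads)))
    sprintf("read_%07d", seq_along(reads)) else names(reads)

  ## exact full-length fast path is safe only if no reference contains
  ## another (otherwise an exact hit could tie a containing reference)
  nested <- FALSE
  if (length(refDna) > 1L) {
    for (a in seq_along(refDna)) {
      if (any(grepl(refDna[a], refDna[-a], fixed = TRUE))) { nested <- TRUE; break }
    }
  }
  pre <- if (nested) integer(length(readSeq))
         else { m <- match(readSeq, refDna); m[is.na(m)] <- 0L; m }

  runBatch <- function(sq, precomp) {
    .alignBatch(sq, unname(refDna), scoring$match, scoring$mismatch,
                scoring$gap, precomp)
  }
  res <- runBatch(readSeq, pre)
  if (tryReverseComplement) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(readSeq)))
    resRC <- runBatch(rc, integer(length(rc)))
    better <- resRC$bestScore > res$bestScore
    for (f in c("best", "bestScore", "secondScore", "refStart", "refEnd"))
      res[[f]][better] <- resRC[[f]][better]
    keepEv <- function(r, take) {
      sel <- take[r$evRead]
      lapply(r[c("evRead", "evPos", "evType")], function(v) v[sel])
    }
    evA <- keepEv(res, !better)
    evB <- keepEv(resRC, better)
    res$evRead <- c(evA$evRead, evB$evRead)
    res$evPos <- c(evA$evPos, evB$evPos)
    res$evType <- c(evA$evType, evB$evType)
  }

  maxScore <- nchar(readSeq) * scoring$match
  tie <- !is.na(res$secondScore) & res$secondScore == res$bestScore
  low <- res$bestScore < minScoreFraction * maxScore
  assigned <- !(tie | low)
  out <- DataFrame(
    readId = readIds,
    referenceId = ifelse(assigned, ids[res$best], NA_character_),
    score = res$bestScore, secondScore = res$secondScore,
    refStart = ifelse(assigned, res$refStart, NA_integer_),
    refEnd = ifelse(assigned, res$refEnd, NA_integer_))
  ev <- DataFrame(readIdx = res$evRead, position = res$evPos,
                  type = c("mismatch", "deletion", "insertion")[res$evType])
  metadata(out)$events <- ev
  metadata(out)$referenceIds <- ids
  out
}

#' Build per-position mutation profiles from read assignments
#'
#' Tallies, per reference position, the read depth and the mutation count
#' (mismatches plus deletions; insertions are tracked but excluded from
#' the numerator unless \code{countInsertions}).  Positions with depth
#' below \code{minDepth} are flagged missing; the depth floor applies per
#' position, so partially covered references yield partial profiles.
#' References whose every position is missing are listed in
#' \code{metadata(x)$notAnalyzable}.
#'
#' @param assignments result of [assignReads()].
#' @param references as in [assignReads()] (provides position labels).
#' @param minDepth per-position depth floor (default 1000, the usual
#'   MaP depth requirement).
#' @param sampleRole \code{"treated"} or \code{"untreated"}.
#' @param countInsertions include insertions in the mutation numerator.
#' @return \code{SimpleList} of [MutationProfile-class], one per
#'   reference, with \code{metadata(x)$notAnalyzable}.
#' @export
buildProfile <- function(assignments, references, minDepth = 1000L,
                         sampleRole = "treated", countInsertions = FALSE) {
  refs <- resolveReferences(references)
  ids <- names(refs$sequences)
  ev <- metadata(assignments)$events
  assignedIdx <- which(!is.na(assignments$referenceId))
  refOfRead <- assignments$referenceId
  profiles <- lapply(ids, function(id) {
    labs <- refs$labels[[id]]
    n <- length(labs)
    sel <- assignedIdx[refOfRead[assignedIdx] == id]
    depth <- integer(n)
    count <- integer(n)
    if (length(sel)) {
      s <- assignments$refStart[sel]
      e <- assignments$refEnd[sel]
      ## coverage by difference array: +1 at each read start, -1 just
      ## after each read end
      depth <- cumsum(tabulate(s, n) - tabulate(e + 1L, n))
      evSel <- ev[ev$readIdx %in% sel, , drop = FALSE]
      types <- c("mismatch", "deletion", if (countInsertions) "insertion")
      evSel <- evSel[evSel$type %in% types & evSel$position >= 1L, ,
                     drop = FALSE]
      count <- tabulate(evSel$position, n)
    }
    missing <- depth < minDepth
    rate <- ifelse(depth > 0L, count / depth, NA_real_)
    rate[missing] <- NA_real_
    new("MutationProfile", referenceId = id, sampleRole = sampleRole,
        data = DataFrame(label = labs, depth = depth, mutationCount = count,
                         rate = rate, missing = missing))
  })
  out <- SimpleList(setNames(profiles, ids))
  metadata(out)$notAnalyzable <- ids[vapply(profiles, function(p)
    all(profileData(p)$missing), logical(1L))]
  out
}

#' @describeIn subtractBackground per-position subtraction for one
#'   reference: \code{rate = max(0, treated - untreated)}, missing where
#'   either input is missing.
#' @export
setMethod("subtractBackground",
          signature("MutationProfile", "MutationProfile"),
  function(treated, untreated) {
    if (referenceId(treated) != referenceId(untreated))
      stop("reference mismatch: ", referenceId(treated), " vs ",
           referenceId(untreated), call. = FALSE)
    dt <- profileData(treated); du <- profileData(untreated)
    if (!identical(as.character(dt$label), as.character(du$label)))
      stop("position label mismatch for '", referenceId(treated), "'",
           call. = FALSE)
    missing <- dt$missing | du$missing
    rate <- pmax(0, dt$rate - du$rate)
    rate[missing] <- NA_real_
    new("MutationProfile", referenceId = referenceId(treated),
        sampleRole = "subtracted",
        data = DataFrame(label = dt$label, depth = dt$depth,
                         mutationCount = NA_integer_, rate = rate,
                         missing = missing))
  })

#' @describeIn subtractBackground elementwise over two profile sets that
#'   share reference names.
#' @export
setMethod("subtractBackground", signature("SimpleList", "SimpleList"),
  function(treated, untreated) {
    ids <- names(treated)
    if (!all(ids %in% names(untreated)))
      stop("untreated profile set lacks references: ",
           paste(setdiff(ids, names(untreated)), collapse = ", "),
           call. = FALSE)
    out <- SimpleList(setNames(lapply(ids, function(i)
      subtractBackground(treated[[i]], untreated[[i]])), ids))
    metadata(out)$notAnalyzable <- ids[vapply(out, function(p)
      all(profileData(p)$missing), logical(1L))]
    out
  })

#' Call modified positions from a subtracted profile
#'
#' A position is called modified when its background-subtracted rate
#' strictly exceeds \code{threshold} and the position is not missing.
#'
#' @param profiles a [MutationProfile-class] or a \code{SimpleList} of
#'   them (normally subtracted).
#' @param threshold mutation-rate threshold (default 0.01).
#' @return \code{DataFrame} with columns \code{reference}, \code{label},
#'   \code{rate}.
#' @export
callModifiedPositions <- function(profiles, threshold = 0.01) {
  if (is(profiles, "MutationProfile")) profiles <- SimpleList(profiles)
  rows <- lapply(profiles, function(p) {
    d <- profileData(p)
    keep <- which(!d$missing & !is.na(d$rate) & d$rate > threshold)
    DataFrame(reference = rep(referenceId(p), length(keep)),
              label = d$label[keep], rate = d$rate[keep])
  })
  do.call(rbind, unname(rows))
}

#' Rate at one labelled position
#'
#' @param profile a [MutationProfile-class].
#' @param label position label.
#' @return numeric rate (NA when missing).
#' @export
rateAt <- function(profile, label) {
  d <- profileData(profile)
  i <- match(label, d$label)
  if (is.na(i)) stop("unknown label '", label, "'", call. = FALSE)
  d$rate[i]
}
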
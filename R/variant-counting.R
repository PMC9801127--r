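## Exact-sequence-match quantification for low-diversity variant
## libraries: per-variant read counting by target-position base and the
## M_rate statistic.  Alignment-based variant calling is deliberately
## avoided here -- with single-point variants the reads are nearly
## identical and alignment cannot attribute them unambiguously.

#' Build the four target-position query sequences
#'
#' For each variant (and optionally the wild-type parent as a
#' \code{"WT"} pseudo-variant), returns the four full-length sequences
#' identical to the variant except for carrying each of A/C/G/U at the
#' target position.  Because every variant differs from every other at its
#' own mutated position, the query sets of distinct variants are disjoint,
#' which is what makes exact counting unambiguous.
#'
#' @param x a [VariantLibrary-class], or an [AnnotatedTRNA-class] for a
#'   single wild-type query set.
#' @param targetLabel target position label; defaults to the library's
#'   target.  Must differ from a variant's own mutated position.
#' @param includeWT for a library, also emit the parent's query set.
#' @return \code{DataFrame} with columns \code{variant}, \code{base}
#'   (RNA base at the target position) and \code{query} (full-length RNA
#'   sequence).
#' @export
buildVariantQueries <- function(x, targetLabel = NULL, includeWT = FALSE) {
  if (is(x, "AnnotatedTRNA")) {
    if (is.null(targetLabel)) stop("targetLabel is required", call. = FALSE)
    i <- labelIndex(x, targetLabel)
    return(targetQueries("WT", trnaSequence(x), i))
  }
  stopifnot(is(x, "VariantLibrary"))
  if (is.null(targetLabel)) targetLabel <- targetLabel(x)
  parent <- parentTRNA(x)
  i <- labelIndex(parent, targetLabel)
  v <- variants(x)
  if (any(v$positionLabel == targetLabel))
    stop("target position coincides with a variant's mutated position",
         call. = FALSE)
  rows <- lapply(seq_len(nrow(v)), function(k)
    targetQueries(v$name[k], v$sequence[k], i))
  if (includeWT)
    rows <- c(rows, list(targetQueries("WT", trnaSequence(parent), i)))
  do.call(rbind, rows)
}

targetQueries <- function(name, sequence, targetIndex) {
  seqs <- vapply(RNA_BASES, function(b) {
    s <- sequence
    substr(s, targetIndex, targetIndex) <- b
    s
  }, character(1L))
  DataFrame(variant = name, base = RNA_BASES, query = unname(seqs))
}

#' Count reads matching each query exactly
#'
#' In \code{"substring"} mode (the default, suitable for untrimmed reads
#' that still carry the 3' adapter) a read increments a query's count iff
#' it contains the query as an exact substring; in \code{"full"} mode the
#' read must equal the query exactly (use on adapter-trimmed reads).  A
#' read with any sequencing error inside the query region matches nothing
#' and simply drops out of \code{Read_Total}; this thins the counts but
#' does not bias M_rate, because errors hit wild-type and mutant reads
#' alike.  Reads matching the queries of more than one variant are counted
#' for each and reported in \code{metadata(x)$ambiguousReads} (0 for a
#' disjoint query set).
#'
#' @param reads character vector of read sequences (DNA or RNA).
#' @param queries result of [buildVariantQueries()] (or a character vector
#'   of query sequences).
#' @param mode \code{"substring"} or \code{"full"}.
#' @return the \code{queries} \code{DataFrame} with an added \code{count}
#'   column and \code{metadata(x)$ambiguousReads}.
#' @export
countExact <- function(reads, queries, mode = c("substring", "full")) {
  mode <- match.arg(mode)
  if (is.character(queries))
    queries <- DataFrame(variant = names(queries) %||%
                           as.character(seq_along(queries)),
                         base = NA_character_, query = unname(queries))
  if (!nrow(queries) || any(!nzchar(queries$query)))
    stop("queries must be non-empty sequences", call. = FALSE)
  if (anyDuplicated(queries$query))
    stop("duplicate query sequences: the query set must be disjoint",
         call. = FALSE)
  qDna <- rnaToDna(as.character(queries$query))
  readsDna <- rnaToDna(unname(as.character(reads)))
  counts <- integer(nrow(queries))
  ambiguous <- 0L
  if (length(readsDna)) {
    if (mode == "full") {
      hit <- match(readsDna, qDna)
      tab <- tabulate(hit[!is.na(hit)], nrow(queries))
      counts <- tab
    } else {
      subj <- Biostrings::DNAStringSet(readsDna)
      widths <- nchar(qDna)
      hitRead <- integer(0)
      hitQuery <- integer(0)
      for (w in unique(widths)) {          # PDict needs constant width
        sel <- which(widths == w)
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(qDna[sel]))
        hits <- Biostrings::vwhichPDict(pd, subj)
        nh <- lengths(hits)
        if (any(nh > 0L)) {
          hitRead <- c(hitRead, rep(seq_along(hits), nh))
          hitQuery <- c(hitQuery, sel[unlist(hits, use.names = FALSE)])
        }
      }
      counts <- tabulate(hitQuery, nrow(queries))
      if (length(hitRead)) {
        vhit <- as.character(queries$variant)[hitQuery]
        nvar <- vapply(split(vhit, hitRead), function(v)
          length(unique(v)), integer(1L))
        ambiguous <- sum(nvar > 1L)
      }
    }
  }
  queries$count <- counts
  metadata(queries)$ambiguousReads <- ambiguous
  queries
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute the M_rate statistic from target-position counts
#'
#' \code{M_rate = Read_Mutant / Read_Total}, where \code{Read_Total} sums
#' the reads carrying any of the four bases at the target position and
#' \code{Read_Mutant} sums the three non-wild-type base classes.  The rate
#' is flagged undefined when \code{Read_Total} falls below \code{minTotal}.
#'
#' @param counts named numeric vector of read counts for bases A/C/G/U at
#'   the target position (RNA names), or the [countExact()] rows of one
#'   variant.
#' @param wtBase wild-type base at the target position.
#' @param variantName identifier carried into the result.
#' @param minTotal minimum \code{Read_Total} before a rate is reported
#'   (default 100).
#' @param sampleRole \code{"treated"} or \code{"untreated"}.
#' @return an [MRateResult-class].
#' @examples
#' computeMRate(c(A = 210, C = 260, G = 270, U = 260), "A")  # M_rate 0.79
#' @export
computeMRate <- function(counts, wtBase, variantName = "variant",
                         minTotal = 100L, sampleRole = "treated") {
  if (is(counts, "DataFrame") || is.data.frame(counts))
    counts <- setNames(as.numeric(counts$count), as.character(counts$base))
  counts <- counts[RNA_BASES]
  names(counts) <- RNA_BASES
  counts[is.na(counts)] <- 0
  wtBase <- dnaToRna(wtBase)
  total <- sum(counts)
  mutant <- total - counts[[wtBase]]
  defined <- total >= minTotal
  new("MRateResult", variantName = variantName, wtBase = wtBase,
      counts = counts, readTotal = total, readMutant = mutant,
      mRate = if (total > 0) mutant / total else NA_real_,
      defined = defined, sampleRole = sampleRole,
      subtractedRate = NA_real_)
}

#' Background-subtract a treated M_rate by its untreated counterpart
#'
#' \code{subtracted = max(0, M_rate(treated) - M_rate(untreated))};
#' undefined when either input is flagged undefined.
#'
#' @param treated,untreated [MRateResult-class] objects for the same
#'   variant.
#' @return the treated object with \code{subtractedRate} filled in and
#'   \code{sampleRole = "subtracted"}.
#' @export
subtractMRate <- function(treated, untreated) {
  stopifnot(is(treated, "MRateResult"), is(untreated, "MRateResult"))
  if (treated@variantName != untreated@variantName)
    stop("variant mismatch: ", treated@variantName, " vs ",
         untreated@variantName, call. = FALSE)
  out <- treated
  out@sampleRole <- "subtracted"
  out@defined <- treated@defined && untreated@defined
  out@subtractedRate <- if (out@defined)
    max(0, treated@mRate - untreated@mRate) else NA_real_
  out
}

#' Count a variant library and compute per-variant M_rates
#'
#' Convenience wrapper: builds the query set, counts treated and untreated
#' reads exactly, computes raw and background-subtracted M_rate per
#' variant.
#'
#' @param treatedReads,untreatedReads character vectors of reads.
#' @param library a [VariantLibrary-class].
#' @param targetLabel target position (default the library target).
#' @param mode matching mode, see [countExact()].
#' @param minTotal see [computeMRate()].
#' @param includeWT include the wild-type pseudo-variant.
#' @return \code{DataFrame} with one row per variant: base counts, totals,
#'   treated/untreated/subtracted M_rate and a \code{defined} flag.
#' @export
countVariantLibrary <- function(treatedReads, untreatedReads, library,
                                targetLabel = NULL,
                                mode = c("substring", "full"),
                                minTotal = 100L, includeWT = TRUE) {
  mode <- match.arg(mode)
  queries <- buildVariantQueries(library, targetLabel,
                                 includeWT = includeWT)
  wt <- baseAt(parentTRNA(library),
               targetLabel %||% targetLabel(library))
  ct <- countExact(treatedReads, queries, mode)
  cu <- countExact(untreatedReads, queries, mode)
  vnames <- unique(queries$variant)
  rows <- lapply(vnames, function(vn) {
    rt <- computeMRate(ct[ct$variant == vn, , drop = FALSE], wt, vn,
                       minTotal, "treated")
    ru <- computeMRate(cu[cu$variant == vn, , drop = FALSE], wt, vn,
                       minTotal, "untreated")
    rs <- subtractMRate(rt, ru)
    DataFrame(variant = vn,
              count_A = rt@counts[["A"]], count_C = rt@counts[["C"]],
              count_G = rt@counts[["G"]], count_U = rt@counts[["U"]],
              readTotal = rt@readTotal, readMutant = rt@readMutant,
              mRateTreated = rt@mRate, mRateUntreated = ru@mRate,
              mRateSubtracted = rs@subtractedRate, defined = rs@defined)
  })
  out <- do.call(rbind, rows)
  metadata(out)$ambiguousReads <- c(treated = metadata(ct)$ambiguousReads,
                                    untreated = metadata(cu)$ambiguousReads)
  out
}
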